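#' Serialize a typing method to YAML
#'
#' The schema is a flat nested list: `combination`, `a_rules` / `b_rules`
#' as lists of \{`components`, `isotype`, `lower`, `upper`\}, and for
#' flow-chart methods a `stage2` block of the same shape.
#'
#' @param method a [typing_method()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_typing_method <- function(method, path) {
  stopifnot(inherits(method, "typing_method"))
  rule_list <- function(rules) {
    lapply(rules, function(r) {
      list(components = as.list(r$components), isotype = r$isotype,
           lower = r$lower, upper = r$upper)
    })
  }
  doc <- list(combination = method$combination,
              a_rules = rule_list(method$a_rules),
              b_rules = rule_list(method$b_rules))
  if (!is.null(method$stage2)) {
    doc$stage2 <- list(a_rules = rule_list(method$stage2$a_rules),
                       b_rules = rule_list(method$stage2$b_rules))
  }
  yaml::write_yaml(doc, path, precision = 17L)
  invisible(path)
}

#' Read a typing method from YAML
#'
#' @param path YAML path written by [write_typing_method()].
#' @return a [typing_method()].
#' @export
read_typing_method <- function(path) {
  doc <- yaml::read_yaml(path)
  rules <- function(lst) {
    lapply(lst, function(r) {
      threshold_rule(unlist(r$components), r$isotype, r$lower, r$upper)
    })
  }
  stage2 <- NULL
  if (!is.null(doc$stage2)) {
    stage2 <- list(a_rules = rules(doc$stage2$a_rules),
                   b_rules = rules(doc$stage2$b_rules))
  }
  typing_method(rules(doc$a_rules), rules(doc$b_rules),
                combination = doc$combination, stage2 = stage2)
}
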