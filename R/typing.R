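#' Threshold rule over a (component, isotype) target
#'
#' A rule partitions the log2 signal range into three bands: positive
#' (signal strictly above `upper`), negative (strictly below `lower`), and
#' unclassified in between. Signals exactly equal to a threshold are
#' unclassified — the conservative convention, favouring accuracy over
#' classification rate. A target is a single component or a set of
#' components whose log2 signals are averaged before banding.
#'
#' @param components character vector of component names.
#' @param isotype `"IgG"` or `"IgM"`.
#' @param lower,upper band thresholds (log2 RFU), `lower <= upper`.
#' @return list of class `threshold_rule`.
#' @export
threshold_rule <- function(components, isotype, lower, upper) {
  isotype <- match.arg(isotype, c("IgG", "IgM"))
  stopifnot(length(components) >= 1, is.numeric(lower), is.numeric(upper),
            is.finite(lower), is.finite(upper), lower <= upper)
  structure(list(components = canonical_component_name(components),
                 isotype = isotype, lower = lower, upper = upper),
            class = "threshold_rule")
}

rule_label <- function(rule) {
  paste0(paste(rule$components, collapse = "+"), ":", rule$isotype)
}

#' Band a signal against a threshold rule
#'
#' @param signal numeric vector of (averaged) log2 signals.
#' @param rule a [threshold_rule()].
#' @return character vector in \{"positive", "negative", "unclassified"\}.
#' @export
band <- function(signal, rule) {
  stopifnot(all(is.finite(signal)))
  band_lu(signal, rule$lower, rule$upper)
}

# shared banding core: positive strictly above upper, negative strictly
# below lower, unclassified otherwise (boundary values unclassified)
band_lu <- function(signal, lower, upper) {
  out <- rep("unclassified", length(signal))
  out[signal > upper] <- "positive"
  out[signal < lower] <- "negative"
  out
}

#' Combine anti-A and anti-B evidence bands into a blood-type call
#'
#' Positive anti-A and anti-B means both determinants are foreign: type O.
#' Negative anti-A with positive anti-B means only B is foreign: type A.
#' Positive anti-A with negative anti-B: type B. Both negative: type AB.
#' Any unclassified band leaves the sample unclassified.
#'
#' @param a_band,b_band character vectors of bands for the anti-A and
#'   anti-B evidence.
#' @return character vector in \{A, B, AB, O, unclassified\}.
#' @export
combine_bands <- function(a_band, b_band) {
  key <- paste(a_band, b_band, sep = "|")
  call <- unname(c("positive|positive" = "O",
                   "negative|positive" = "A",
                   "positive|negative" = "B",
                   "negative|negative" = "AB")[key])
  call[is.na(call)] <- "unclassified"
  call
}

#' Construct a typing method
#'
#' @param a_rules,b_rules lists of [threshold_rule()] objects providing
#'   anti-A and anti-B evidence (at least one each).
#' @param combination `"pairwise"` (exactly one rule per determinant),
#'   `"all_agree"` (every rule for a determinant must give the same
#'   non-unclassified band), or `"flowchart"` (two-stage: all-agree stage 1,
#'   then `stage2` rules for samples stage 1 leaves unclassified).
#' @param stage2 for `"flowchart"`: list with elements `a_rules` and
#'   `b_rules` (stricter bands, fewer targets).
#' @return list of class `typing_method`.
#' @export
typing_method <- function(a_rules, b_rules,
                          combination = c("pairwise", "all_agree", "flowchart"),
                          stage2 = NULL) {
  combination <- match.arg(combination)
  if (inherits(a_rules, "threshold_rule")) a_rules <- list(a_rules)
  if (inherits(b_rules, "threshold_rule")) b_rules <- list(b_rules)
  stopifnot(length(a_rules) >= 1, length(b_rules) >= 1,
            all(vapply(c(a_rules, b_rules), inherits, TRUE, "threshold_rule")))
  if (combination == "pairwise" &&
      (length(a_rules) != 1L || length(b_rules) != 1L)) {
    stop("pairwise combination takes exactly one rule per determinant")
  }
  if (combination == "flowchart") {
    if (is.null(stage2) || !all(c("a_rules", "b_rules") %in% names(stage2))) {
      stop("flowchart combination requires a stage2 block with a_rules and b_rules")
    }
    stopifnot(all(vapply(c(stage2$a_rules, stage2$b_rules),
                         inherits, TRUE, "threshold_rule")))
  }
  structure(list(a_rules = a_rules, b_rules = b_rules,
                 combination = combination, stage2 = stage2),
            class = "typing_method")
}

#' @export
print.typing_method <- function(x, ...) {
  cat("typing_method (", x$combination, ")\n", sep = "")
  show <- function(rules, tag) {
    for (r in rules) {
      cat(sprintf("  %s %-40s [%.2f, %.2f]\n", tag, rule_label(r),
                  r$lower, r$upper))
    }
  }
  show(x$a_rules, "anti-A"); show(x$b_rules, "anti-B")
  if (!is.null(x$stage2)) {
    cat("  stage 2:\n")
    show(x$stage2$a_rules, "anti-A"); show(x$stage2$b_rules, "anti-B")
  }
  invisible(x)
}

# Band every rule for one determinant over all samples and reduce by
# all-agree: a determinant band is assigned only when every rule gives the
# same non-unclassified band.
determinant_bands <- function(profiles, rules) {
  bands <- vapply(rules, function(r) {
    band(target_signal(profiles, r$components, r$isotype), r)
  }, character(nrow(profiles$igg)))
  bands <- matrix(bands, nrow = nrow(profiles$igg))
  agree <- bands[, 1]
  if (ncol(bands) > 1L) {
    same <- rowSums(bands == agree) == ncol(bands)
    agree[!same] <- "unclassified"
  }
  list(band = agree, per_rule = bands)
}

#' Classify every sample in a profile matrix
#'
#' Applies a typing method to all samples at once. For the flow-chart
#' combination, stage 1 is evaluated all-agree over its rules; samples left
#' unclassified are re-evaluated under the stage-2 rules; samples still
#' unclassified carry stage `"none"`.
#'
#' @param profiles a `glycan_profiles` object on the log2 scale.
#' @param method a [typing_method()].
#' @return data.frame with columns `sample_id`, `call`
#'   (A/B/AB/O/unclassified) and `stage` (`"1"`, `"2"` or `"none"`), plus an
#'   attribute `evidence`: a band matrix (samples x rules) for audit.
#' @export
classify_all <- function(profiles, method) {
  stopifnot(inherits(profiles, "glycan_profiles"),
            inherits(method, "typing_method"))
  if (attr(profiles, "scale") != "log2") {
    stop("profiles must be on the log2 scale; see log2_normalize()")
  }
  a1 <- determinant_bands(profiles, method$a_rules)
  b1 <- determinant_bands(profiles, method$b_rules)
  call <- combine_bands(a1$band, b1$band)
  stage <- ifelse(call == "unclassified", "none", "1")

  evidence <- cbind(a1$per_rule, b1$per_rule)
  colnames(evidence) <- c(vapply(method$a_rules, rule_label, ""),
                          vapply(method$b_rules, rule_label, ""))

  if (method$combination == "flowchart") {
    redo <- call == "unclassified"
    if (any(redo)) {
      sub <- subset_samples(profiles, sample_ids(profiles)[redo])
      a2 <- determinant_bands(sub, method$stage2$a_rules)
      b2 <- determinant_bands(sub, method$stage2$b_rules)
      call2 <- combine_bands(a2$band, b2$band)
      call[redo] <- call2
      stage[redo] <- ifelse(call2 == "unclassified", "none", "2")
    }
  }

  out <- data.frame(sample_id = sample_ids(profiles), call = call,
                    stage = stage, stringsAsFactors = FALSE)
  rownames(evidence) <- sample_ids(profiles)
  attr(out, "evidence") <- evidence
  out
}

#' Classify a single sample
#'
#' @param profiles a `glycan_profiles` object.
#' @param sample a sample identifier present in `profiles`.
#' @param method a [typing_method()].
#' @return list with `call`, `stage` and `evidence` (named band vector over
#'   the stage-1 rules).
#' @export
classify <- function(profiles, sample, method) {
  stopifnot(sample %in% sample_ids(profiles))
  res <- classify_all(subset_samples(profiles, sample), method)
  list(call = res$call[1L], stage = res$stage[1L],
       evidence = attr(res, "evidence")[1L, ])
}

#' Component targets of the 10-component two-stage flow-chart method
#'
#' Anti-A evidence: the average IgG signal over four A-determinant glycans
#' (BG-A2-Sp-17, BG-A2-Oct-16, BG-A3-Oct-14, Globo A-09) and the IgM signal
#' to BG-A2-Sp-17. Anti-B evidence: the average IgG signal over four
#' B-determinant glycans (BG-B2-Sp-20, BG-B2-Oct-17, BG-B3-Oct-17,
#' Globo B-12) and the IgM signal to BG-B2-Sp-05.
#'
#' @return list with elements `a_igg` (4 names), `a_igm` (1 name), `b_igg`
#'   (4 names), `b_igm` (1 name).
#' @export
flowchart_targets <- function() {
  list(a_igg = c("BG-A2-Sp-17", "BG-A2-Oct-16", "BG-A3-Oct-14", "Globo A-09"),
       a_igm = "BG-A2-Sp-17",
       b_igg = c("BG-B2-Sp-20", "BG-B2-Oct-17", "BG-B3-Oct-17", "Globo B-12"),
       b_igm = "BG-B2-Sp-05")
}

# Resolve flow-chart target names against the components actually present,
# tolerating the known naming variant BG-A2-Oct-17 for BG-A2-Oct-16 (two
# published spellings of the same quadruplet member) with a warning.
resolve_flowchart_targets <- function(targets, present) {
  present <- canonical_component_name(present)
  fix <- function(names) {
    names <- canonical_component_name(names)
    swap <- c("BG-A2-Oct-16" = "BG-A2-Oct-17", "BG-A2-Oct-17" = "BG-A2-Oct-16")
    for (i in seq_along(names)) {
      if (!names[i] %in% present && names[i] %in% names(swap) &&
          swap[[names[i]]] %in% present) {
        warning("component ", names[i], " not present; using the variant ",
                "spelling ", swap[[names[i]]], call. = FALSE)
        names[i] <- swap[[names[i]]]
      }
    }
    missing <- setdiff(names, present)
    if (length(missing)) {
      stop("component(s) required by the flow chart are missing: ",
           paste(missing, collapse = ", "))
    }
    names
  }
  lapply(targets, fix)
}

#' Fit the default 10-component two-stage flow-chart method
#'
#' Builds the flow-chart typing method on its ten fixed targets (see
#' [flowchart_targets()]) and fits all stage-1 thresholds on labelled
#' training data with [fit_flowchart_thresholds()]. Stage-2 rules are the
#' stage-1 IgG-average rules with the unclassified band widened by
#' `stringency` log2 units on each side and the IgM targets dropped (more
#' stringent thresholds, fewer glycans).
#'
#' @param profiles_train training `glycan_profiles`.
#' @param labels_train named vector sample -> blood type.
#' @param stringency stage-2 widening in log2 units (default 1).
#' @param grid_step threshold grid resolution in log2 units (default 0.25).
#' @return a fitted [typing_method()] with `combination = "flowchart"`.
#' @export
default_flowchart_method <- function(profiles_train, labels_train,
                                     stringency = 1, grid_step = 0.25) {
  targets <- resolve_flowchart_targets(flowchart_targets(),
                                       component_names(profiles_train))
  fit_flowchart_thresholds(profiles_train, labels_train, targets = targets,
                           stringency = stringency, grid_step = grid_step)
}
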