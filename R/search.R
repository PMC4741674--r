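#' Specification for a two-component threshold search
#'
#' @param candidate_a,candidate_b data.frames with columns `component` and
#'   `isotype`, listing anti-A and anti-B candidate targets.
#' @param grid strictly increasing numeric vector of candidate threshold
#'   values (log2 RFU), length >= 2.
#' @param min_classification_rate minimum fraction of samples a method must
#'   classify to be retained (default 0.80).
#' @return list of class `search_spec`.
#' @export
search_spec <- function(candidate_a, candidate_b, grid,
                        min_classification_rate = 0.80) {
  as_cand <- function(x) {
    if (is.character(x)) x <- data.frame(component = x, isotype = "IgG",
                                         stringsAsFactors = FALSE)
    stopifnot(is.data.frame(x), all(c("component", "isotype") %in% names(x)))
    x
  }
  candidate_a <- as_cand(candidate_a); candidate_b <- as_cand(candidate_b)
  if (nrow(candidate_a) == 0L || nrow(candidate_b) == 0L) {
    stop("candidate lists must be non-empty")
  }
  if (length(grid) < 2L) stop("grid must have at least 2 values")
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  stopifnot(min_classification_rate > 0)
  structure(list(candidate_a = candidate_a, candidate_b = candidate_b,
                 grid = grid,
                 min_classification_rate = min_classification_rate),
            class = "search_spec")
}

#' Default threshold grid for a signal vector
#'
#' Steps of `step` log2 units spanning the observed range, extended one
#' step beyond each end so a band can place every observation on one side.
#'
#' @param signal numeric vector of log2 signals.
#' @param step grid resolution (default 0.25 log2 units).
#' @return increasing numeric vector.
#' @export
signal_grid <- function(signal, step = 0.25) {
  lo <- floor(min(signal) / step) * step - step
  hi <- ceiling(max(signal) / step) * step + step
  seq(lo, hi, by = step)
}

# accuracy among classified + classification rate for a call vector
call_metrics <- function(call, labels) {
  classified <- call != "unclassified"
  n_cls <- sum(classified)
  acc <- if (n_cls == 0L) NaN else mean(call[classified] == labels[classified])
  list(n_total = length(call), n_classified = n_cls,
       classification_rate = n_cls / length(call),
       n_correct = if (n_cls == 0L) 0L else sum(call[classified] == labels[classified]),
       accuracy = acc)
}

#' Exhaustive two-component threshold search
#'
#' Evaluates every combination of one anti-A candidate, one anti-B
#' candidate, and banded thresholds `lower <= upper` per candidate drawn
#' from the grid. Methods classifying fewer than `min_classification_rate`
#' of the training samples are excluded. Survivors are ranked by accuracy
#' among classified samples (descending), ties broken by higher
#' classification rate, then smaller total band width, then lexicographic
#' target names, then lower thresholds.
#'
#' @param train a `glycan_profiles` object.
#' @param labels named vector sample -> blood type (reference labels).
#' @param spec a [search_spec()].
#' @return data.frame, one row per retained method, with the candidate
#'   names, thresholds and evaluation metrics, ordered best first. When no
#'   method satisfies the constraint, a zero-row data.frame with attribute
#'   `status` explaining why. Use [as_typing_method()] to materialize a row.
#' @export
grid_search_two_component <- function(train, labels, spec) {
  stopifnot(inherits(train, "glycan_profiles"), inherits(spec, "search_spec"))
  labels <- labels[sample_ids(train)]
  stopifnot(!anyNA(labels))
  g <- spec$grid
  pair_idx <- which(outer(seq_along(g), seq_along(g), "<="), arr.ind = TRUE)
  pair_idx <- pair_idx[order(pair_idx[, 1], pair_idx[, 2]), , drop = FALSE]

  cand_sig <- function(cand) {
    lapply(seq_len(nrow(cand)), function(i) {
      target_signal(train, cand$component[i], cand$isotype[i])
    })
  }
  sig_a <- cand_sig(spec$candidate_a)
  sig_b <- cand_sig(spec$candidate_b)
  # bands per candidate for every (lower, upper) grid pair
  bands_for <- function(sig) {
    lapply(sig, function(s) {
      apply(pair_idx, 1L, function(ij) band_lu(s, g[ij[1]], g[ij[2]]))
    })
  }
  bands_a <- bands_for(sig_a)
  bands_b <- bands_for(sig_b)

  rows <- vector("list", 0L)
  for (ia in seq_along(sig_a)) {
    for (ib in seq_along(sig_b)) {
      for (pa in seq_len(nrow(pair_idx))) {
        ba <- bands_a[[ia]][, pa]
        for (pb in seq_len(nrow(pair_idx))) {
          call <- combine_bands(ba, bands_b[[ib]][, pb])
          m <- call_metrics(call, labels)
          if (m$classification_rate < spec$min_classification_rate) next
          rows[[length(rows) + 1L]] <- data.frame(
            a_component = spec$candidate_a$component[ia],
            a_isotype = spec$candidate_a$isotype[ia],
            b_component = spec$candidate_b$component[ib],
            b_isotype = spec$candidate_b$isotype[ib],
            lower_a = g[pair_idx[pa, 1]], upper_a = g[pair_idx[pa, 2]],
            lower_b = g[pair_idx[pb, 1]], upper_b = g[pair_idx[pb, 2]],
            n_classified = m$n_classified,
            classification_rate = m$classification_rate,
            n_correct = m$n_correct, accuracy = m$accuracy,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(a_component = character(0), a_isotype = character(0),
                      b_component = character(0), b_isotype = character(0),
                      lower_a = numeric(0), upper_a = numeric(0),
                      lower_b = numeric(0), upper_b = numeric(0),
                      n_classified = integer(0),
                      classification_rate = numeric(0),
                      n_correct = integer(0), accuracy = numeric(0))
    attr(out, "status") <- paste0(
      "no candidate/threshold combination reached the minimum ",
      "classification rate of ", spec$min_classification_rate)
    message(attr(out, "status"))
    return(out)
  }
  out <- do.call(rbind, rows)
  width <- (out$upper_a - out$lower_a) + (out$upper_b - out$lower_b)
  ord <- order(-out$accuracy, -out$classification_rate, width,
               out$a_component, out$a_isotype, out$b_component, out$b_isotype,
               out$lower_a, out$upper_a, out$lower_b, out$upper_b)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Materialize a search result row as a typing method
#'
#' @param row a one-row data.frame as returned by
#'   [grid_search_two_component()].
#' @return a pairwise [typing_method()].
#' @export
as_typing_method <- function(row) {
  stopifnot(nrow(row) == 1L)
  typing_method(
    threshold_rule(row$a_component, row$a_isotype, row$lower_a, row$upper_a),
    threshold_rule(row$b_component, row$b_isotype, row$lower_b, row$upper_b),
    combination = "pairwise"
  )
}

# lexicographic objective: accuracy desc, rate desc, width asc, lower asc,
# upper asc; NaN accuracy (nothing classified) loses to everything
obj_key <- function(m, lower, upper, width) {
  acc <- if (is.nan(m$accuracy)) -1 else m$accuracy
  c(acc, m$classification_rate, -width, -lower, -upper)
}

obj_better <- function(k1, k2) {
  d <- k1 - k2
  nz <- which(d != 0)
  length(nz) > 0 && d[nz[1]] > 0
}

#' Fit flow-chart thresholds by coordinate ascent
#'
#' Fits the stage-1 lower/upper thresholds of the 10-component flow chart
#' on labelled training data. Each rule's thresholds range over a grid of
#' `grid_step` log2-unit steps spanning that target's observed signal
#' range. Rules are optimized one at a time by exhaustive search over their
#' grid pairs with the other rules held fixed (coordinate ascent), in the
#' fixed order anti-A IgG average, anti-A IgM, anti-B IgG average, anti-B
#' IgM, for two full sweeps; the objective is training accuracy among
#' classified samples, ties broken by classification rate, then smaller
#' band width. Stage-2 rules are the fitted IgG-average rules with each
#' band widened by `stringency` log2 units on both sides and the IgM
#' targets dropped. Deterministic given its inputs.
#'
#' @param train a `glycan_profiles` object.
#' @param labels named vector sample -> blood type.
#' @param targets list with `a_igg`, `a_igm`, `b_igg`, `b_igm` component
#'   names (defaults to [flowchart_targets()]).
#' @param stringency stage-2 widening in log2 units (default 1).
#' @param grid_step threshold grid resolution (default 0.25).
#' @return fitted [typing_method()] with attribute `train_metrics`.
#' @export
fit_flowchart_thresholds <- function(train, labels,
                                     targets = flowchart_targets(),
                                     stringency = 1, grid_step = 0.25) {
  stopifnot(inherits(train, "glycan_profiles"), stringency >= 0)
  labels <- labels[sample_ids(train)]
  stopifnot(!anyNA(labels))
  targets <- resolve_flowchart_targets(targets, component_names(train))

  iso <- c(a_igg = "IgG", a_igm = "IgM", b_igg = "IgG", b_igm = "IgM")
  sigs <- lapply(names(iso), function(nm) {
    target_signal(train, targets[[nm]], iso[[nm]])
  })
  names(sigs) <- names(iso)
  grids <- lapply(sigs, signal_grid, step = grid_step)

  # anti-A evidence separates {B,O} (foreign A) from {A,AB}; anti-B the converse
  init_mid <- function(nm) {
    foreign <- if (startsWith(nm, "a_")) labels %in% c("B", "O")
               else labels %in% c("A", "O")
    mid <- (mean(sigs[[nm]][foreign]) + mean(sigs[[nm]][!foreign])) / 2
    g <- grids[[nm]]
    g[which.min(abs(g - mid))]
  }
  th <- lapply(names(iso), function(nm) {
    m <- init_mid(nm); c(lower = m, upper = m)
  })
  names(th) <- names(iso)

  eval_th <- function(th) {
    agree2 <- function(x, y) ifelse(x == y, x, "unclassified")
    b <- lapply(names(iso), function(nm) {
      band_lu(sigs[[nm]], th[[nm]]["lower"], th[[nm]]["upper"])
    })
    names(b) <- names(iso)
    call1 <- combine_bands(agree2(b$a_igg, b$a_igm), agree2(b$b_igg, b$b_igm))
    call2 <- combine_bands(
      band_lu(sigs$a_igg, th$a_igg["lower"] - stringency,
              th$a_igg["upper"] + stringency),
      band_lu(sigs$b_igg, th$b_igg["lower"] - stringency,
              th$b_igg["upper"] + stringency))
    final <- ifelse(call1 == "unclassified", call2, call1)
    call_metrics(final, labels)
  }

  width_of <- function(th) sum(vapply(th, function(x) x["upper"] - x["lower"], 0))

  for (sweep in 1:2) {
    for (nm in names(iso)) {
      g <- grids[[nm]]
      best_key <- NULL
      best <- th[[nm]]
      for (i in seq_along(g)) {
        for (j in i:length(g)) {
          cand <- th
          cand[[nm]] <- c(lower = g[i], upper = g[j])
          m <- eval_th(cand)
          key <- obj_key(m, g[i], g[j], width_of(cand))
          if (is.null(best_key) || obj_better(key, best_key)) {
            best_key <- key
            best <- cand[[nm]]
          }
        }
      }
      th[[nm]] <- best
    }
  }

  rule_of <- function(nm) {
    threshold_rule(targets[[nm]], iso[[nm]],
                   th[[nm]][["lower"]], th[[nm]][["upper"]])
  }
  stage2 <- list(
    a_rules = list(threshold_rule(targets$a_igg, "IgG",
                                  th$a_igg[["lower"]] - stringency,
                                  th$a_igg[["upper"]] + stringency)),
    b_rules = list(threshold_rule(targets$b_igg, "IgG",
                                  th$b_igg[["lower"]] - stringency,
                                  th$b_igg[["upper"]] + stringency))
  )
  method <- typing_method(
    a_rules = list(rule_of("a_igg"), rule_of("a_igm")),
    b_rules = list(rule_of("b_igg"), rule_of("b_igm")),
    combination = "flowchart", stage2 = stage2
  )
  attr(method, "train_metrics") <- eval_th(th)
  method
}

#' Flag samples whose typing call contradicts the recorded label
#'
#' A suspect is a sample whose stage-1 call is a definite blood type
#' (not unclassified) different from its recorded label. The margin is the
#' minimum distance, over all stage-1 rule targets, of the (averaged)
#' signal to its nearest threshold — larger margins mean the profile sits
#' further from every decision boundary, so the contradiction is harder to
#' explain by noise. Suspects are returned sorted by descending margin.
#'
#' @param profiles a `glycan_profiles` object.
#' @param labels named vector sample -> recorded blood type.
#' @param method a fitted [typing_method()].
#' @return data.frame with columns `sample_id`, `recorded`, `called`,
#'   `margin`, ordered by descending margin.
#' @export
flag_suspected_mislabels <- function(profiles, labels, method) {
  res <- classify_all(profiles, method)
  labels <- labels[res$sample_id]
  rules <- c(method$a_rules, method$b_rules)
  margins <- vapply(rules, function(r) {
    s <- target_signal(profiles, r$components, r$isotype)
    pmin(abs(s - r$lower), abs(s - r$upper))
  }, numeric(nrow(res)))
  margins <- matrix(margins, nrow = nrow(res))
  margin <- apply(margins, 1L, min)

  suspect <- res$stage == "1" & res$call != "unclassified" & res$call != labels
  out <- data.frame(sample_id = res$sample_id[suspect],
                    recorded = unname(labels[suspect]),
                    called = res$call[suspect],
                    margin = margin[suspect],
                    stringsAsFactors = FALSE)
  out[order(-out$margin, out$sample_id), , drop = FALSE]
}
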