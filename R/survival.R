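#' Kaplan-Meier product-limit estimate
#'
#' Standard product-limit estimator. At tied times, deaths are processed
#' before censorings, so subjects censored at an event time remain in the
#' risk set for that event. The median is the smallest time at which the
#' survival function drops to 0.5 or below; it is `NA` when the curve never
#' reaches 0.5.
#'
#' @param times positive event/censoring times (months).
#' @param events logical (or 0/1) vector; TRUE = death observed.
#' @return object of class `km_curve`: data.frame with columns `time`
#'   (distinct event times), `n_risk`, `n_event`, `n_censor`, `survival`,
#'   plus attributes `median` and `n`.
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) > 0, length(times) == length(events),
            all(times > 0))
  events <- as.logical(events)
  ut <- sort(unique(times[events]))
  n_risk <- vapply(ut, function(t) sum(times >= t), 0L)
  n_event <- vapply(ut, function(t) sum(times == t & events), 0L)
  n_censor <- vapply(ut, function(t) sum(times == t & !events), 0L)
  surv <- cumprod(1 - n_event / n_risk)
  curve <- data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                      n_censor = n_censor, survival = surv)
  med <- if (any(surv <= 0.5)) ut[which(surv <= 0.5)[1L]] else NA_real_
  structure(curve, class = c("km_curve", "data.frame"),
            median = med, n = length(times))
}

#' Median of a Kaplan-Meier curve
#'
#' @param curve a `km_curve`.
#' @return smallest time with survival <= 0.5, or NA.
#' @export
km_median <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  attr(curve, "median")
}

#' Log-rank test for equality of survival curves
#'
#' Standard log-rank chi-square on k groups (k-1 degrees of freedom; the
#' usual 1-df two-group test when k = 2): at each distinct event time the
#' observed deaths per group are compared with their expectation under the
#' hypergeometric law given the pooled risk set, and the summed
#' observed-minus-expected vector is tested against its covariance.
#'
#' @param times,events as in [km_estimate()].
#' @param groups group label per subject (>= 2 distinct labels, >= 1 event
#'   overall).
#' @return list of class `logrank_result`: `chi2`, `df`, `p`, `medians`
#'   (KM median per group), `n` and `observed`/`expected` per group.
#' @export
logrank_test <- function(times, events, groups) {
  events <- as.logical(events)
  groups <- as.character(groups)
  stopifnot(length(times) == length(events), length(times) == length(groups))
  glev <- sort(unique(groups))
  k <- length(glev)
  if (k < 2L) stop("log-rank test needs at least 2 groups")
  if (!any(events)) stop("log-rank test needs at least 1 event")

  ut <- sort(unique(times[events]))
  O <- E <- stats::setNames(numeric(k), glev)
  V <- matrix(0, k, k, dimnames = list(glev, glev))
  for (t in ut) {
    at_risk <- times >= t
    n_t <- sum(at_risk)
    d_t <- sum(times == t & events)
    n_g <- vapply(glev, function(g) sum(at_risk & groups == g), 0)
    d_g <- vapply(glev, function(g) sum(times == t & events & groups == g), 0)
    O <- O + d_g
    E <- E + d_t * n_g / n_t
    if (n_t > 1) {
      hyper <- d_t * (n_t - d_t) / (n_t - 1) / n_t^2
      V <- V + hyper * (diag(n_g, k, k) * n_t - outer(n_g, n_g))
    }
  }
  oe <- (O - E)[-k]
  Vs <- V[-k, -k, drop = FALSE]
  chi2 <- if (all(abs(oe) < 1e-12)) 0 else
    drop(t(oe) %*% solve(Vs, oe))
  p <- stats::pchisq(chi2, df = k - 1, lower.tail = FALSE)

  medians <- vapply(glev, function(g) {
    km_median(km_estimate(times[groups == g], events[groups == g]))
  }, 0)
  structure(list(chi2 = chi2, df = k - 1L, p = p, medians = medians,
                 n = stats::setNames(as.vector(table(factor(groups, glev))), glev),
                 observed = O, expected = E),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("log-rank chi-square = %.4g on %d df, p = %.4g\n",
              x$chi2, x$df, x$p))
  print(data.frame(n = x$n, observed = x$observed, expected = x$expected,
                   median = x$medians))
  invisible(x)
}

#' Odds ratio for a 2x2 table
#'
#' Cross-product odds ratio `(a*d)/(b*c)` with a Woolf 95% confidence
#' interval from the normal approximation on the log scale,
#' `SE = sqrt(1/a + 1/b + 1/c + 1/d)`, and a two-sided Wald p-value on the
#' log odds ratio. When any cell is zero the Haldane-Anscombe correction
#' adds 0.5 to every cell first. A Fisher exact p-value is also reported
#' for reference.
#'
#' @param table 2x2 matrix of nonnegative integer counts (rows: exposure;
#'   columns: outcome).
#' @return list of class `odds_result`: `table` (as used, after any
#'   correction), `or`, `ci_low`, `ci_high`, `p`, `p_fisher`, `corrected`.
#' @export
odds_ratio <- function(table) {
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)), all(table >= 0),
            all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("degenerate 2x2 table: a row or column is all zero")
  }
  p_fisher <- stats::fisher.test(table)$p.value
  corrected <- any(table == 0)
  tab <- if (corrected) table + 0.5 else table
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  se <- sqrt(sum(1 / tab))
  ci_low <- exp(log(or) - 1.96 * se)
  ci_high <- exp(log(or) + 1.96 * se)
  z <- log(or) / se
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(table = tab, or = or, ci_low = ci_low, ci_high = ci_high,
                 p = p, p_fisher = p_fisher, corrected = corrected),
            class = "odds_result")
}

#' @export
print.odds_result <- function(x, ...) {
  cat(sprintf("OR = %.3g (95%% CI %.3g-%.3g), Wald p = %.3g, Fisher p = %.3g%s\n",
              x$or, x$ci_low, x$ci_high, x$p, x$p_fisher,
              if (x$corrected) " [Haldane-Anscombe corrected]" else ""))
  invisible(x)
}

#' Survival relative to model prediction (OS minus predicted survival)
#'
#' Subtracts each patient's model-predicted survival from their observed
#' overall survival and compares the per-group distributions. Patients with
#' a missing prediction are excluded with a message. The group comparison
#' uses a two-tailed t-test (the conventional report) with a Mann-Whitney
#' rank-sum test alongside, since differences of medians are the quantity
#' of interest but a t-test compares means.
#'
#' @param cohort data.frame with columns `os_months`, `hps_months` and the
#'   grouping column.
#' @param group name of the grouping column (default `"abo_group"`).
#' @return list: `diffs` (data.frame with per-patient differences),
#'   `medians` (named vector of group median differences), `t_p`,
#'   `wilcox_p`, `n_excluded`.
#' @export
os_minus_hps <- function(cohort, group = "abo_group") {
  stopifnot(all(c("os_months", "hps_months", group) %in% names(cohort)))
  drop <- is.na(cohort$hps_months) | is.na(cohort$os_months) |
    is.na(cohort[[group]])
  if (any(drop)) {
    message("excluding ", sum(drop), " patient(s) with missing values")
  }
  d <- cohort[!drop, , drop = FALSE]
  d$os_minus_hps <- d$os_months - d$hps_months
  g <- d[[group]]
  medians <- tapply(d$os_minus_hps, g, stats::median)
  t_p <- wilcox_p <- NA_real_
  if (length(unique(g)) == 2L) {
    if (stats::var(d$os_minus_hps) == 0) {
      t_p <- wilcox_p <- 1
    } else {
      # Welch t-test needs >= 2 observations per group; NA otherwise
      t_p <- tryCatch(stats::t.test(os_minus_hps ~ g, data = d)$p.value,
                      error = function(e) NA_real_)
      wilcox_p <- suppressWarnings(
        stats::wilcox.test(os_minus_hps ~ g, data = d)$p.value)
    }
  }
  list(diffs = d[, c(setdiff(names(cohort), "os_minus_hps"), "os_minus_hps")],
       medians = medians, t_p = t_p, wilcox_p = wilcox_p,
       n_excluded = sum(drop))
}

#' Stratify a cohort by blood-group-A foreignness and Forssman response
#'
#' Pools blood types by whether the blood group A antigen is self (A/AB) or
#' foreign (B/O), and marks Forssman responders: patients whose total-Ig
#' signal to the Forssman disaccharide rises at least 4-fold (a difference
#' of at least 2 on the log2 scale, boundary inclusive) between the
#' pre-treatment and the 2-3-month draw. A four-way stratum combines both.
#' Patients with unknown or unclassified blood type get `NA` strata and are
#' counted in a message.
#'
#' @param cohort data.frame with a blood-type column and (for the Forssman
#'   strata) `forssman_pre` / `forssman_post`.
#' @param blood_type name of the blood-type column (default
#'   `"blood_type"`).
#' @return the cohort with added columns `abo_group` (`"A/AB"` or
#'   `"B/O"`), `forssman_responder` (logical) and `stratum`
#'   (e.g. `"B/O responder"`).
#' @export
stratify_cohort <- function(cohort, blood_type = "blood_type") {
  stopifnot(blood_type %in% names(cohort))
  bt <- as.character(cohort[[blood_type]])
  grp <- rep(NA_character_, length(bt))
  grp[bt %in% c("A", "AB")] <- "A/AB"
  grp[bt %in% c("B", "O")] <- "B/O"
  if (anyNA(grp)) {
    message("excluding ", sum(is.na(grp)),
            " patient(s) with unknown/unclassified blood type from strata")
  }
  cohort$abo_group <- grp
  if (all(c("forssman_pre", "forssman_post") %in% names(cohort))) {
    cohort$forssman_responder <-
      (cohort$forssman_post - cohort$forssman_pre) >= 2
    cohort$stratum <- ifelse(
      is.na(grp), NA_character_,
      paste(grp, ifelse(cohort$forssman_responder, "responder", "non-responder"))
    )
  }
  cohort
}
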