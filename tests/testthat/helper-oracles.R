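# Independent brute-force oracles. These are deliberately written from the
# definitions (two-pass sums of squares, explicit truth tables, explicit
# risk-set products, exhaustive enumeration) and share no code with the
# package implementations they check.

# one-way ANOVA F and p from two-pass sums of squares
oracle_anova <- function(sig, g) {
  g <- as.factor(g)
  grand <- mean(sig)
  ssb <- 0; ssw <- 0
  for (lev in levels(g)) {
    x <- sig[g == lev]
    ssb <- ssb + length(x) * (mean(x) - grand)^2
    ssw <- ssw + sum((x - mean(x))^2)
  }
  df1 <- nlevels(g) - 1
  df2 <- length(sig) - nlevels(g)
  if (ssb == 0) return(list(f = 0, p = 1))
  if (ssw == 0) return(list(f = Inf, p = 0))
  f <- (ssb / df1) / (ssw / df2)
  list(f = f, p = pf(f, df1, df2, lower.tail = FALSE))
}

# band/calls truth table, coded directly from the rule statements
oracle_band <- function(s, lower, upper) {
  if (s > upper) "positive" else if (s < lower) "negative" else "unclassified"
}

oracle_pair_call <- function(a, b) {
  if (a == "positive" && b == "positive") return("O")
  if (a == "negative" && b == "positive") return("A")
  if (a == "positive" && b == "negative") return("B")
  if (a == "negative" && b == "negative") return("AB")
  "unclassified"
}

# all-agree reduction of a vector of bands for one determinant
oracle_agree <- function(bands) {
  u <- unique(bands)
  if (length(u) == 1L && u != "unclassified") u else "unclassified"
}

# two-stage flow-chart call from stage-1 bands (IgG avg + IgM per
# determinant) and stage-2 bands (IgG avg only)
oracle_flowchart_call <- function(a_igg1, a_igm1, b_igg1, b_igm1,
                                  a_igg2, b_igg2) {
  call1 <- oracle_pair_call(oracle_agree(c(a_igg1, a_igm1)),
                            oracle_agree(c(b_igg1, b_igm1)))
  if (call1 != "unclassified") return(list(call = call1, stage = "1"))
  call2 <- oracle_pair_call(a_igg2, b_igg2)
  list(call = call2, stage = if (call2 == "unclassified") "none" else "2")
}

# exhaustive two-component search, plain loops, same documented ranking
oracle_grid_search <- function(sig_a_list, sig_b_list, cand_a, cand_b,
                               grid, labels, min_rate) {
  rows <- list()
  for (ia in seq_along(sig_a_list)) for (ib in seq_along(sig_b_list)) {
    for (la in seq_along(grid)) for (ua in la:length(grid)) {
      for (lb in seq_along(grid)) for (ub in lb:length(grid)) {
        call <- mapply(function(sa, sb) {
          oracle_pair_call(oracle_band(sa, grid[la], grid[ua]),
                           oracle_band(sb, grid[lb], grid[ub]))
        }, sig_a_list[[ia]], sig_b_list[[ib]])
        cls <- call != "unclassified"
        rate <- mean(cls)
        if (rate < min_rate) next
        acc <- if (any(cls)) mean(call[cls] == labels[cls]) else NaN
        rows[[length(rows) + 1L]] <- data.frame(
          a_component = cand_a$component[ia], a_isotype = cand_a$isotype[ia],
          b_component = cand_b$component[ib], b_isotype = cand_b$isotype[ib],
          lower_a = grid[la], upper_a = grid[ua],
          lower_b = grid[lb], upper_b = grid[ub],
          n_classified = sum(cls), classification_rate = rate,
          n_correct = if (any(cls)) sum(call[cls] == labels[cls]) else 0L,
          accuracy = acc, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  width <- (out$upper_a - out$lower_a) + (out$upper_b - out$lower_b)
  out <- out[order(-out$accuracy, -out$classification_rate, width,
                   out$a_component, out$a_isotype, out$b_component,
                   out$b_isotype, out$lower_a, out$upper_a, out$lower_b,
                   out$upper_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Kaplan-Meier by explicit product over risk sets
oracle_km_surv <- function(times, events, at) {
  s <- 1
  for (t in sort(unique(times[events]))) {
    if (t > at) break
    n <- sum(times >= t)
    d <- sum(times == t & events)
    s <- s * (1 - d / n)
  }
  s
}

# two-group log-rank statistic for the permutation oracle; standalone code
oracle_logrank_chi2 <- function(times, events, grp1) {
  ut <- sort(unique(times[events]))
  oe <- 0; v <- 0
  for (t in ut) {
    at_risk <- times >= t
    n <- sum(at_risk); n1 <- sum(at_risk & grp1)
    d <- sum(times == t & events)
    d1 <- sum(times == t & events & grp1)
    oe <- oe + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n - d) / (n - 1) * n1 * (n - n1) / n^2
  }
  if (v == 0) 0 else oe^2 / v
}

# permutation p-value for the two-group log-rank test
oracle_logrank_perm_p <- function(times, events, grp1, n_perm, seed = 42) {
  set.seed(seed)
  obs <- oracle_logrank_chi2(times, events, grp1)
  n1 <- sum(grp1)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    perm <- rep(FALSE, length(grp1))
    perm[sample(length(grp1), n1)] <- TRUE
    if (oracle_logrank_chi2(times, events, perm) >= obs - 1e-12) {
      hits <- hits + 1L
    }
  }
  hits / n_perm
}

# odds ratio closed form
oracle_or <- function(a, b, c, d) {
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = or,
       ci_low = exp(log(or) - 1.96 * se),
       ci_high = exp(log(or) + 1.96 * se),
       p = 2 * pnorm(-abs(log(or) / se)))
}

# tiny deterministic profile fixture: k components, n samples per type,
# noise-free signals from the Landsteiner rule
make_sep_profiles <- function(n_per_type = 3, self_mu = 8, foreign_mu = 12) {
  comps <- default_component_panel()
  types <- rep(c("O", "A", "B", "AB"), each = n_per_type)
  n <- length(types)
  igg <- igm <- matrix(self_mu, n, nrow(comps),
                       dimnames = list(sprintf("X%02d", seq_len(n)),
                                       comps$name))
  for (i in seq_len(n)) {
    foreign <- switch(types[i], O = c("A", "B"), A = "B", B = "A",
                      AB = character(0))
    idx <- comps$determinant %in% foreign
    igg[i, idx] <- foreign_mu
    igm[i, idx] <- foreign_mu
  }
  list(profiles = glycan_profiles(igg, igm),
       truth = setNames(types, rownames(igg)))
}
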