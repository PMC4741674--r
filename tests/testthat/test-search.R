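test_that("a separable pair reaches perfect accuracy and full classification", {
  sep <- make_sep_profiles(3)      # noise-free, foreign 12 vs self 8
  spec <- search_spec(
    data.frame(component = "BG-A3-Oct-14", isotype = "IgG"),
    data.frame(component = "BG-B3-Oct-17", isotype = "IgG"),
    grid = c(9, 10, 11))
  res <- grid_search_two_component(sep$profiles, sep$truth, spec)
  expect_equal(res$accuracy[1], 1)
  expect_equal(res$classification_rate[1], 1)
  # every retained method honours the classification-rate constraint
  expect_true(all(res$classification_rate >= spec$min_classification_rate))
})

test_that("search ranking matches exhaustive brute force including tie-breaks", {
  set.seed(77)
  sim <- simulate_profiles(16, seed = 77)
  cand_a <- data.frame(component = c("BG-A3-Oct-14", "BG-A2-Sp-17"),
                       isotype = c("IgG", "IgM"), stringsAsFactors = FALSE)
  cand_b <- data.frame(component = c("BG-B3-Oct-17", "BG-B2-Sp-05"),
                       isotype = c("IgG", "IgM"), stringsAsFactors = FALSE)
  grid <- c(8.5, 9.25, 10, 10.75, 11.5)
  spec <- search_spec(cand_a, cand_b, grid, min_classification_rate = 0.5)
  res <- grid_search_two_component(sim$profiles, sim$truth, spec)

  sig_a <- lapply(seq_len(nrow(cand_a)), function(i) {
    target_signal(sim$profiles, cand_a$component[i], cand_a$isotype[i])
  })
  sig_b <- lapply(seq_len(nrow(cand_b)), function(i) {
    target_signal(sim$profiles, cand_b$component[i], cand_b$isotype[i])
  })
  oracle <- oracle_grid_search(sig_a, sig_b, cand_a, cand_b, grid,
                               sim$truth[sample_ids(sim$profiles)],
                               min_rate = 0.5)
  oracle$a_component <- canonical_component_name(oracle$a_component)
  oracle$b_component <- canonical_component_name(oracle$b_component)
  res$n_classified <- as.integer(res$n_classified)
  oracle$n_classified <- as.integer(oracle$n_classified)
  res$n_correct <- as.integer(res$n_correct)
  oracle$n_correct <- as.integer(oracle$n_correct)
  expect_equal(res, oracle, tolerance = 1e-12)
})

test_that("search output is invariant to candidate and sample order", {
  sim <- simulate_profiles(16, seed = 78)
  cand_a <- data.frame(component = c("BG-A3-Oct-14", "BG-A2-Oct-16"),
                       isotype = "IgG", stringsAsFactors = FALSE)
  cand_b <- data.frame(component = c("BG-B3-Oct-17", "BG-B2-Oct-17"),
                       isotype = "IgG", stringsAsFactors = FALSE)
  grid <- c(9, 10, 11)
  res1 <- grid_search_two_component(sim$profiles, sim$truth,
                                    search_spec(cand_a, cand_b, grid, 0.5))
  res2 <- grid_search_two_component(
    subset_samples(sim$profiles, rev(sample_ids(sim$profiles))), sim$truth,
    search_spec(cand_a[2:1, ], cand_b[2:1, ], grid, 0.5))
  rownames(res2) <- NULL
  expect_equal(res1, res2, tolerance = 1e-12)
})

test_that("an infeasible classification-rate constraint yields an explained empty result", {
  sep <- make_sep_profiles(2)
  spec <- search_spec("BG-A3-Oct-14", "BG-B3-Oct-17", grid = c(9, 10),
                      min_classification_rate = 1.01)
  expect_message(res <- grid_search_two_component(sep$profiles, sep$truth, spec),
                 "no candidate")
  expect_equal(nrow(res), 0)
  expect_match(attr(res, "status"), "classification rate")
})

test_that("flow-chart fitting separates a noise-free training set", {
  sep <- make_sep_profiles(4)
  m <- fit_flowchart_thresholds(sep$profiles, sep$truth)
  tm <- attr(m, "train_metrics")
  expect_equal(tm$accuracy, 1)
  expect_equal(tm$classification_rate, 1)
  # fitted stage-1 bands bracket the margin midpoint (signals 8 vs 12)
  for (r in c(m$a_rules, m$b_rules)) {
    expect_gt(r$lower, 8); expect_lt(r$upper, 12)
  }
})

test_that("zero stringency makes stage 2 equal to the stage-1 IgG rules", {
  sep <- make_sep_profiles(3)
  m <- fit_flowchart_thresholds(sep$profiles, sep$truth, stringency = 0)
  expect_equal(m$stage2$a_rules[[1]], m$a_rules[[1]])
  expect_equal(m$stage2$b_rules[[1]], m$b_rules[[1]])
})

test_that("coordinate ascent attains the exhaustive-search optimum on a small instance", {
  sim <- simulate_profiles(16, seed = 55, model = signal_model(sigma = 0.8))
  m <- fit_flowchart_thresholds(sim$profiles, sim$truth, grid_step = 3)
  tm <- attr(m, "train_metrics")

  # exhaustive joint search over the same per-rule grids, oracle-evaluated
  targets <- flowchart_targets()
  labels <- sim$truth[sample_ids(sim$profiles)]
  iso <- c(a_igg = "IgG", a_igm = "IgM", b_igg = "IgG", b_igm = "IgM")
  sigs <- lapply(names(iso), function(nm) {
    target_signal(sim$profiles, targets[[nm]], iso[[nm]])
  })
  names(sigs) <- names(iso)
  grids <- lapply(sigs, signal_grid, step = 3)
  pairs <- lapply(grids, function(g) {
    idx <- which(outer(seq_along(g), seq_along(g), "<="), arr.ind = TRUE)
    cbind(g[idx[, 1]], g[idx[, 2]])
  })
  # banding coded independently as -1/0/+1 (negative/unclassified/positive)
  bandv <- function(s, l, u) (s > u) - (s < l)
  band_rows <- function(nm) {
    t(apply(pairs[[nm]], 1L, function(lu) bandv(sigs[[nm]], lu[1], lu[2])))
  }
  bands <- lapply(names(iso), band_rows)
  names(bands) <- names(iso)
  s2 <- lapply(c(a = "a_igg", b = "b_igg"), function(nm) {
    t(apply(pairs[[nm]], 1L, function(lu) bandv(sigs[[nm]], lu[1] - 1, lu[2] + 1)))
  })
  # per determinant, pre-reduce every (IgG pair, IgM pair) combo to its
  # agreed band and its stage-2 fallback band
  side_combos <- function(gg, mm, s2gg) {
    combos <- expand.grid(g = seq_len(nrow(gg)), m = seq_len(nrow(mm)))
    list(agree = lapply(seq_len(nrow(combos)), function(r) {
           a <- gg[combos$g[r], ]; b <- mm[combos$m[r], ]
           ifelse(a == b, a, 0)
         }),
         fallback = lapply(seq_len(nrow(combos)), function(r) {
           s2gg[combos$g[r], ]
         }))
  }
  A <- side_combos(bands$a_igg, bands$a_igm, s2$a)
  B <- side_combos(bands$b_igg, bands$b_igm, s2$b)
  call_of <- function(a, b) {  # coded bands -> call; 0 band -> unclassified
    ifelse(a == 1 & b == 1, "O",
           ifelse(a == -1 & b == 1, "A",
                  ifelse(a == 1 & b == -1, "B",
                         ifelse(a == -1 & b == -1, "AB", "unclassified"))))
  }
  best <- c(-2, -2)
  for (ia in seq_along(A$agree)) {
    for (ib in seq_along(B$agree)) {
      c1 <- call_of(A$agree[[ia]], B$agree[[ib]])
      c2 <- call_of(A$fallback[[ia]], B$fallback[[ib]])
      final <- ifelse(c1 == "unclassified", c2, c1)
      cls <- final != "unclassified"
      acc <- if (any(cls)) mean(final[cls] == labels[cls]) else -1
      rate <- mean(cls)
      if (acc > best[1] || (acc == best[1] && rate > best[2])) {
        best <- c(acc, rate)
      }
    }
  }
  expect_equal(tm$accuracy, best[1])
  expect_equal(tm$classification_rate, best[2])
})

test_that("mislabel flagging is empty without mislabels and skips unclassified calls", {
  sim <- simulate_profiles(30, seed = 10, model = signal_model(sigma = 0.3))
  m <- default_flowchart_method(sim$profiles, sim$truth)
  flags <- flag_suspected_mislabels(sim$profiles, sim$truth, m)
  expect_equal(nrow(flags), 0)

  # flip two recorded labels: both flagged, sorted by descending margin
  labs <- sim$truth
  labs[c(1, 2)] <- ifelse(labs[c(1, 2)] == "O", "A", "O")
  flags <- flag_suspected_mislabels(sim$profiles, labs, m)
  expect_setequal(flags$sample_id, names(labs)[1:2])
  expect_true(all(diff(flags$margin) <= 0))

  # unclassified samples are never flagged
  calls <- classify_all(sim$profiles, m)
  expect_false(any(flags$sample_id %in%
                     calls$sample_id[calls$call == "unclassified"]))
})
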