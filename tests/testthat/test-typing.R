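test_that("banding splits the signal range with unclassified boundaries", {
  r <- threshold_rule("C1", "IgG", 8.0, 9.0)
  expect_equal(band(9.5, r), "positive")
  expect_equal(band(7.9, r), "negative")
  expect_equal(band(8.5, r), "unclassified")
  expect_equal(band(8.0, r), "unclassified")  # boundary values unclassified
  expect_equal(band(9.0, r), "unclassified")
  expect_error(threshold_rule("C1", "IgG", 9.0, 8.0))
})

test_that("band combination matches the reverse-typing truth table on all 9 cases", {
  bands <- c("positive", "negative", "unclassified")
  for (a in bands) for (b in bands) {
    expect_equal(combine_bands(a, b), oracle_pair_call(a, b),
                 info = paste(a, b))
  }
  expect_equal(combine_bands("positive", "positive"), "O")
  expect_equal(combine_bands("negative", "positive"), "A")
  expect_equal(combine_bands("unclassified", "negative"), "unclassified")
})

# profiles with one sample per requested signal combination over four
# single-component targets (A-IgG, A-IgM, B-IgG, B-IgM share components CA/CB)
combo_profiles <- function(sig_a_igg, sig_a_igm, sig_b_igg, sig_b_igm) {
  grid <- expand.grid(a_g = sig_a_igg, a_m = sig_a_igm,
                      b_g = sig_b_igg, b_m = sig_b_igm,
                      KEEP.OUT.ATTRS = FALSE)
  n <- nrow(grid)
  ids <- sprintf("S%04d", seq_len(n))
  igg <- cbind(`CA-1` = grid$a_g, `CB-1` = grid$b_g)
  igm <- cbind(`CA-1` = grid$a_m, `CB-1` = grid$b_m)
  rownames(igg) <- rownames(igm) <- ids
  list(profiles = glycan_profiles(igg, igm), grid = grid)
}

test_that("all-agree classification matches the brute-force oracle on all band combinations", {
  lo <- 8; hi <- 9   # representative signals: 7.5 neg, 8.5 uncl, 9.5 pos
  sigs <- c(7.5, 8.5, 9.5)
  cp <- combo_profiles(sigs, sigs, sigs, sigs)  # 81 samples, 3^4 combos
  method <- typing_method(
    a_rules = list(threshold_rule("CA-1", "IgG", lo, hi),
                   threshold_rule("CA-1", "IgM", lo, hi)),
    b_rules = list(threshold_rule("CB-1", "IgG", lo, hi),
                   threshold_rule("CB-1", "IgM", lo, hi)),
    combination = "all_agree")
  res <- classify_all(cp$profiles, method)
  expected <- apply(cp$grid, 1L, function(r) {
    oracle_pair_call(
      oracle_agree(c(oracle_band(r[["a_g"]], lo, hi),
                     oracle_band(r[["a_m"]], lo, hi))),
      oracle_agree(c(oracle_band(r[["b_g"]], lo, hi),
                     oracle_band(r[["b_m"]], lo, hi))))
  })
  expect_equal(res$call, unname(expected))
})

flow_method <- function(l1 = 8, u1 = 9, s = 1) {
  typing_method(
    a_rules = list(threshold_rule("CA-1", "IgG", l1, u1),
                   threshold_rule("CA-1", "IgM", l1, u1)),
    b_rules = list(threshold_rule("CB-1", "IgG", l1, u1),
                   threshold_rule("CB-1", "IgM", l1, u1)),
    combination = "flowchart",
    stage2 = list(a_rules = list(threshold_rule("CA-1", "IgG", l1 - s, u1 + s)),
                  b_rules = list(threshold_rule("CB-1", "IgG", l1 - s, u1 + s))))
}

test_that("flow-chart classification matches the oracle over exhaustive signal regions", {
  # stage-1 band [8, 9], stage-2 band [7, 10]: signal points covering every
  # distinct (stage-1 band, stage-2 band) region including the boundaries
  igg_sigs <- c(6.5, 7, 7.5, 8, 8.5, 9, 9.5, 10, 10.5)
  igm_sigs <- c(7.5, 8, 8.5, 9, 9.5)
  cp <- combo_profiles(igg_sigs, igm_sigs, igg_sigs, igm_sigs)
  res <- classify_all(cp$profiles, flow_method())
  expected <- apply(cp$grid, 1L, function(r) {
    oracle_flowchart_call(
      oracle_band(r[["a_g"]], 8, 9), oracle_band(r[["a_m"]], 8, 9),
      oracle_band(r[["b_g"]], 8, 9), oracle_band(r[["b_m"]], 8, 9),
      oracle_band(r[["a_g"]], 7, 10), oracle_band(r[["b_g"]], 7, 10))
  })
  expect_equal(res$call, vapply(expected, `[[`, "", "call"))
  expect_equal(res$stage, vapply(expected, `[[`, "", "stage"))
  # stage consistency: stage-1 calls are final, stage 2 only for the rest
  s1 <- res$stage == "1"
  expect_true(all(res$call[s1] != "unclassified"))
  expect_true(all(res$call[res$stage == "none"] == "unclassified"))
  # totality
  expect_true(all(res$call %in% c("A", "B", "AB", "O", "unclassified")))
})

test_that("disagreement between isotypes leaves the sample unclassified", {
  # IgG says anti-A positive, IgM says anti-A negative -> no call
  cp <- combo_profiles(9.5, 7.5, 9.5, 9.5)
  method <- typing_method(
    a_rules = list(threshold_rule("CA-1", "IgG", 8, 9),
                   threshold_rule("CA-1", "IgM", 8, 9)),
    b_rules = list(threshold_rule("CB-1", "IgG", 8, 9),
                   threshold_rule("CB-1", "IgM", 8, 9)),
    combination = "all_agree")
  expect_equal(classify_all(cp$profiles, method)$call, "unclassified")
})

test_that("calls are invariant to rule order and sample order", {
  set.seed(31)
  sim <- simulate_profiles(25, seed = 31)
  m <- default_flowchart_method(sim$profiles, sim$truth)
  res <- classify_all(sim$profiles, m)

  m_rev <- m
  m_rev$a_rules <- rev(m$a_rules); m_rev$b_rules <- rev(m$b_rules)
  expect_equal(classify_all(sim$profiles, m_rev)$call, res$call)

  ord <- sample(sample_ids(sim$profiles))
  res_perm <- classify_all(subset_samples(sim$profiles, ord), m)
  expect_equal(res_perm$call[match(res$sample_id, res_perm$sample_id)],
               res$call)
})

test_that("raising an anti-A signal moves its band only toward positive", {
  r <- threshold_rule("CA-1", "IgG", 8, 9)
  rank_of <- c(negative = 1, unclassified = 2, positive = 3)
  sigs <- seq(6, 11, by = 0.1)
  bands <- band(sigs, r)
  expect_true(all(diff(rank_of[bands]) >= 0))
})

test_that("noise-free type-O profiles classify as O at stage 1", {
  model <- signal_model(sigma = 1e-9, crossreact_epsilon = 0)
  sim <- simulate_profiles(4, model = model, seed = 6,
                           true_types = rep("O", 4))
  targets <- flowchart_targets()
  m <- typing_method(
    a_rules = list(threshold_rule(targets$a_igg, "IgG", 9, 10),
                   threshold_rule(targets$a_igm, "IgM", 9, 10)),
    b_rules = list(threshold_rule(targets$b_igg, "IgG", 9, 10),
                   threshold_rule(targets$b_igm, "IgM", 9, 10)),
    combination = "flowchart",
    stage2 = list(a_rules = list(threshold_rule(targets$a_igg, "IgG", 8, 11)),
                  b_rules = list(threshold_rule(targets$b_igg, "IgG", 8, 11))))
  res <- classify_all(sim$profiles, m)
  expect_equal(res$call, rep("O", 4))
  expect_equal(res$stage, rep("1", 4))
})

test_that("missing components are reported by name", {
  sim <- simulate_profiles(4, components = c("BG-A3-Oct-14", "BG-B3-Oct-17"),
                           seed = 1)
  m <- typing_method(threshold_rule("Globo A-09", "IgG", 8, 9),
                     threshold_rule("BG-B3-Oct-17", "IgG", 8, 9),
                     combination = "pairwise")
  expect_error(classify_all(sim$profiles, m), "GloboA-09")
  expect_error(default_flowchart_method(sim$profiles, sim$truth),
               "missing")
})

test_that("the published quadruplet spelling variant is accepted with a warning", {
  panel <- c("BG-A2-Sp-17", "BG-A2-Oct-17", "BG-A3-Oct-14", "Globo A-09",
             "BG-B2-Sp-05", "BG-B2-Sp-20", "BG-B2-Oct-17", "BG-B3-Oct-17",
             "Globo B-12")
  sim <- simulate_profiles(24, components = panel, seed = 44)
  expect_warning(m <- default_flowchart_method(sim$profiles, sim$truth),
                 "BG-A2-Oct-1")
  expect_s3_class(m, "typing_method")
})

test_that("method YAML serialization round-trips", {
  sim <- simulate_profiles(20, seed = 13)
  m <- default_flowchart_method(sim$profiles, sim$truth)
  f <- tempfile(fileext = ".yaml")
  write_typing_method(m, f)
  m2 <- read_typing_method(f)
  expect_equal(classify_all(sim$profiles, m2)$call,
               classify_all(sim$profiles, m)$call)
  expect_equal(m2$a_rules[[1]]$lower, m$a_rules[[1]]$lower)
})
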