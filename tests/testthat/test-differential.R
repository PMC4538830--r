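test_that("per-timepoint differences convert Da to %HDX over n_max", {
  tabs <- simple_pair(c(0.95, 1.0, 1.05), c(1.95, 2.0, 2.05))  # n_max = 10
  fit <- hdx_diff(tabs$free, tabs$bound)
  r <- fit$results
  expect_equal(r$delta_da, 1.0, tolerance = 1e-12)
  expect_equal(r$delta_hdx, 100 * (1 / 1.006277) / 10, tolerance = 1e-12)
  expect_equal(r$delta_hdx, 9.94, tolerance = 1e-3)
  # below the strict 10% threshold despite a strong t-test and 1 Da shift
  expect_false(r$significant)
  expect_identical(r$reasons, "min_delta_pct")
})

test_that("swapping states flips signs but preserves magnitude, p and calls", {
  prot <- make_two_state_protein(80, list(c(20, 45, 100)), seed = 2)
  map <- make_peptide_map(80, seed = 3)
  cond <- labeling_conditions(noise_sd = 0.05)
  uf <- simulate_uptake(prot, "free", map, cond, seed = 4)
  ub <- simulate_uptake(prot, "bound", map, cond, seed = 5)
  fit_ab <- hdx_diff(uf, ub)
  fit_ba <- hdx_diff(ub, uf)
  expect_equal(fit_ba$results$delta_hdx, -fit_ab$results$delta_hdx)
  expect_equal(fit_ba$results$delta_da, -fit_ab$results$delta_da)
  expect_equal(fit_ba$results$p_value, fit_ab$results$p_value)
  expect_identical(fit_ba$results$significant, fit_ab$results$significant)
  swap <- c(decrease = "increase", increase = "decrease", none = "none")
  expect_identical(fit_ba$results$direction,
                   unname(swap[fit_ab$results$direction]))
})

test_that("Delta-HDX is the signed max over timepoints, earliest on ties", {
  n_max <- 20  # 21-residue proline-free peptide
  seqc <- strrep("A", 21)
  da <- function(pct) pct / 100 * n_max * 1.006277
  mk <- function(pcts, state) {
    uptake_table(stats::setNames(
      lapply(pcts, function(p) rep(da(p), 3)), c("3", "30", "300", "3000")),
      sequence = seqc, state = state)
  }
  # diffs {5, 12, 9, 7} -> +12 at 30 s
  fit <- suppressWarnings(
    hdx_diff(mk(c(0, 0, 0, 0), "free"), mk(c(5, 12, 9, 7), "bound")))
  expect_equal(fit$results$delta_hdx, 12, tolerance = 1e-9)
  expect_equal(fit$results$delta_timepoint_s, 30)

  # signed maximum magnitude: {-5, -15, -8, -2} -> -15 at 30 s
  fit2 <- suppressWarnings(
    hdx_diff(mk(c(5, 15, 8, 2), "free"), mk(c(0, 0, 0, 0), "bound")))
  expect_equal(fit2$results$delta_hdx, -15, tolerance = 1e-9)
  expect_equal(fit2$results$delta_timepoint_s, 30)

  # tie {+10, -10, 0, 0} resolves to the earliest timepoint
  fit3 <- suppressWarnings(
    hdx_diff(mk(c(0, 10, 5, 5), "free"), mk(c(10, 0, 5, 5), "bound")))
  expect_equal(fit3$results$delta_hdx, 10, tolerance = 1e-9)
  expect_equal(fit3$results$delta_timepoint_s, 3)
})

test_that("the unpaired pooled t-test matches the closed form", {
  # t = 1 / (0.1 * sqrt(2/3)), df = 4; frozen from 2 * pt(-t, 4)
  p <- hdxmap:::unpaired_t_test(c(1.0, 1.1, 0.9), c(2.0, 2.1, 1.9))
  t_stat <- 1 / (0.1 * sqrt(2 / 3))
  expect_equal(p, 2 * stats::pt(-t_stat, df = 4), tolerance = 1e-12)
  expect_gt(p, 2.4e-4); expect_lt(p, 2.7e-4)

  # symmetry under label swap, invariance under rescaling (#D vs %HDX vs Da)
  expect_equal(hdxmap:::unpaired_t_test(c(2.0, 2.1, 1.9), c(1.0, 1.1, 0.9)),
               p)
  expect_equal(hdxmap:::unpaired_t_test(c(1.0, 1.1, 0.9) * 10,
                                        c(2.0, 2.1, 1.9) * 10), p)

  # degenerate variance
  expect_equal(hdxmap:::unpaired_t_test(c(1, 1), c(1, 1)), 1)
  expect_equal(hdxmap:::unpaired_t_test(c(1, 1), c(2, 2)), 0)
  expect_error(hdxmap:::unpaired_t_test(1, c(1, 2)), "replicates")
})

test_that("the three-criterion call reports every failed criterion", {
  mk_fit <- function(da_diff, n_len, p_fail = FALSE) {
    spread <- if (p_fail) 2 else 0.001
    base <- c(-spread, 0, spread)
    tabs <- simple_pair(1 + base, 1 + da_diff + base, n_len = n_len)
    suppressWarnings(hdx_diff(tabs$free, tabs$bound))
  }
  # 0.6 Da on n_max 5 -> ~12%, all three pass
  f1 <- mk_fit(0.6038, 6L)
  expect_true(f1$results$significant)
  expect_identical(f1$results$reasons, "")
  expect_identical(f1$results$direction, "increase")
  # ~12% but only 0.36 Da -> fails the Da floor alone
  f2 <- mk_fit(0.3623, 4L)
  expect_false(f2$results$significant)
  expect_identical(f2$results$reasons, "min_da")
  # 1.8 Da but 9% on n_max 20 -> fails the %HDX bound alone
  f3 <- mk_fit(1.8113, 21L)
  expect_false(f3$results$significant)
  expect_identical(f3$results$reasons, "min_delta_pct")
  # high replicate spread -> p fails too
  f4 <- mk_fit(0.6038, 6L, p_fail = TRUE)
  expect_match(f4$results$reasons, "p_value")
})

test_that("raising any threshold never enlarges the significant set", {
  prot <- make_two_state_protein(120, list(c(30, 55, 30)), seed = 10)
  map <- make_peptide_map(120, seed = 11)
  cond <- labeling_conditions(noise_sd = 0.08)
  uf <- simulate_uptake(prot, "free", map, cond, seed = 12)
  ub <- simulate_uptake(prot, "bound", map, cond, seed = 13)
  base <- hdx_diff(uf, ub)
  key <- function(f) with(f$results[f$results$significant, ],
                          paste(start, end))
  for (th in list(hdx_thresholds(min_delta_pct = 15),
                  hdx_thresholds(alpha = 0.01),
                  hdx_thresholds(min_da = 1.0),
                  hdx_thresholds(20, 0.001, 2))) {
    expect_true(all(key(hdx_diff(uf, ub, thresholds = th)) %in% key(base)))
  }
})

test_that("planted protection and deprotection call with the right sign", {
  map <- data.frame(start = c(1L, 11L), end = c(10L, 20L))
  cond <- labeling_conditions(noise_sd = 0.01)
  # saturating protection -> decrease everywhere inside the region
  prot <- make_two_state_protein(20, list(c(1, 20, 100)), k_int = 1,
                                 sequence = strrep("A", 20), seed = 1)
  fit <- hdx_diff(simulate_uptake(prot, "free", map, cond, seed = 2),
                  simulate_uptake(prot, "bound", map, cond, seed = 3))
  expect_true(all(fit$results$significant))
  expect_true(all(fit$results$direction == "decrease"))

  # bound state released from protection -> increase
  dep <- make_two_state_protein(20, list(c(1, 20, 0.01)), k_int = 1,
                                pf_free = 100,
                                sequence = strrep("A", 20), seed = 1)
  fit2 <- hdx_diff(simulate_uptake(dep, "free", map, cond, seed = 4),
                   simulate_uptake(dep, "bound", map, cond, seed = 5))
  expect_true(all(fit2$results$direction == "increase"))
})

test_that("no-difference noiseless input yields zero significant peptides", {
  prot <- make_two_state_protein(60, list(), seed = 20)
  map <- make_peptide_map(60, seed = 21)
  cond <- labeling_conditions(noise_sd = 0, n_replicates = 3)
  fit <- hdx_diff(simulate_uptake(prot, "free", map, cond),
                  simulate_uptake(prot, "bound", map, cond))
  expect_equal(sum(fit$results$significant), 0)
  expect_true(all(fit$results$p_value == 1))
})

test_that("grid mismatches are excluded with warnings; disjoint maps error", {
  tabs <- simple_pair(rep(1, 3), rep(2, 3))
  # one-sided peptide
  extra <- tabs$free
  extra$start <- extra$start + 30L; extra$end <- extra$end + 30L
  expect_warning(hdx_diff(rbind(tabs$free, extra), tabs$bound),
                 "only one state")
  # missing timepoint in one state -> excluded, and nothing is left
  b2 <- tabs$bound; b2$timepoint_s <- 30
  expect_warning(try(hdx_diff(tabs$free, b2), silent = TRUE),
                 "mismatched timepoints")
  expect_error(suppressWarnings(hdx_diff(tabs$free, b2)), "no analyzable")
  # single replicate -> excluded
  one_rep <- tabs$bound[tabs$bound$replicate == 1L, ]
  expect_warning(try(hdx_diff(tabs$free, one_rep), silent = TRUE),
                 "2 replicates")
  expect_error(suppressWarnings(hdx_diff(tabs$free, one_rep)),
               "no analyzable")
  # disjoint maps
  expect_error(hdx_diff(tabs$free, extra), "disjoint")
})

test_that("accessors expose the fit the standard way", {
  tabs <- simple_pair(rep(0.5, 3) + c(-0.01, 0, 0.01),
                      rep(3.0, 3) + c(-0.01, 0, 0.01))
  fit <- hdx_diff(tabs$free, tabs$bound)
  expect_s3_class(fit, "hdx_diff")
  expect_named(coef(fit), "p1:1-11")
  df <- as.data.frame(fit)
  expect_false(any(c("diff_pct", "p_by_timepoint") %in% names(df)))
  expect_output(print(fit), "significant: 1")
  expect_output(print(summary(fit)), "1 significant")
})
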