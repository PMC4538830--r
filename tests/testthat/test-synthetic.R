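test_that("two-state proteins plant interface regions exactly", {
  p <- make_two_state_protein(563, list(c(88, 114, 100)), seed = 1)
  expect_identical(p$interface_truth, 88:114)
  expect_equal(p$pf_bound[88:114], p$pf_free[88:114] * 100)
  expect_equal(p$pf_bound[-(88:114)], p$pf_free[-(88:114)])

  p0 <- make_two_state_protein(10, list(), seed = 1)
  expect_identical(p0$pf_bound, p0$pf_free)
  expect_length(p0$interface_truth, 0)

  # deprotection requires headroom in the free-state protection factor
  pd <- make_two_state_protein(563, list(c(171, 184, 0.1)), pf_free = 100,
                               seed = 1)
  expect_identical(pd$interface_truth, 171:184)
  expect_true(all(pd$pf_bound[171:184] < pd$pf_free[171:184]))
  expect_error(make_two_state_protein(20, list(c(5, 10, 0.1))), "pf_free")
})

test_that("region validation catches conflicts and bounds", {
  expect_error(make_two_state_protein(50, list(c(40, 60, 2))), "out of bounds")
  expect_error(
    make_two_state_protein(50, list(c(5, 15, 2), c(10, 20, 3))),
    "conflicting")
  # same factor may overlap
  p <- make_two_state_protein(50, list(c(5, 15, 2), c(10, 20, 2)), seed = 1)
  expect_identical(p$interface_truth, 5:20)
})

test_that("EX2 kinetics: saturation, half-life, protection monotonicity", {
  prot <- make_two_state_protein(21, sequence = strrep("A", 21), k_int = 1,
                                 seed = 1)
  map <- data.frame(start = 1L, end = 21L)
  sat <- labeling_conditions(timepoints = 1e6, noise_sd = 0, n_replicates = 2)
  u <- simulate_uptake(prot, "free", map, sat)
  # 20 exchangeable amides, each at the 80% labeling ceiling
  expect_equal(u$uptake_Da[1], 0.8 * 1.006277 * 20, tolerance = 1e-8)

  half <- labeling_conditions(timepoints = log(2), noise_sd = 0,
                              n_replicates = 2)
  p1 <- make_two_state_protein(2, sequence = "AA", k_int = 1, seed = 1)
  u2 <- simulate_uptake(p1, "free", data.frame(start = 1L, end = 2L), half)
  expect_equal(u2$uptake_Da[1], 0.8 * 0.5 * 1.006277, tolerance = 1e-10)

  # P = 100 exchanges strictly less than P = 1 at every finite timepoint
  pp <- make_two_state_protein(21, list(c(1, 21, 100)),
                               sequence = strrep("A", 21), k_int = 1)
  cond <- labeling_conditions(noise_sd = 0, n_replicates = 2)
  uf <- simulate_uptake(pp, "free", map, cond)
  ub <- simulate_uptake(pp, "bound", map, cond)
  expect_true(all(ub$uptake_Da < uf$uptake_Da))
})

test_that("noiseless uptake is monotone in time and bounded by the ceiling", {
  prot <- make_two_state_protein(60, list(c(10, 30, 50)), seed = 7)
  map <- make_peptide_map(60, seed = 8)
  cond <- labeling_conditions(noise_sd = 0, n_replicates = 2)
  for (state in c("free", "bound")) {
    u <- simulate_uptake(prot, state, map, cond)
    u1 <- u[u$replicate == 1L, ]
    for (k in seq_len(nrow(map))) {
      pk <- u1[u1$start == map$start[k] & u1$end == map$end[k], ]
      pk <- pk[order(pk$timepoint_s), ]
      expect_true(all(diff(pk$uptake_Da) >= -1e-12))
      n_ex <- count_exchangeable(pk$sequence[1])
      expect_true(all(pk$uptake_Da <= 1.006277 * 0.8 * n_ex + 1e-9))
    }
  }
})

test_that("states are identical without planted differences and noise", {
  prot <- make_two_state_protein(40, list(), seed = 3)
  map <- make_peptide_map(40, seed = 4)
  cond <- labeling_conditions(noise_sd = 0, n_replicates = 2)
  uf <- simulate_uptake(prot, "free", map, cond)
  ub <- simulate_uptake(prot, "bound", map, cond)
  expect_identical(uf$uptake_Da, ub$uptake_Da)
})

test_that("simulation is byte-identical under a fixed seed", {
  prot <- make_two_state_protein(50, list(c(10, 20, 10)), seed = 5)
  map <- make_peptide_map(50, seed = 6)
  cond <- labeling_conditions()
  expect_identical(simulate_uptake(prot, "free", map, cond, seed = 11),
                   simulate_uptake(prot, "free", map, cond, seed = 11))
  expect_false(identical(simulate_uptake(prot, "free", map, cond, seed = 11),
                         simulate_uptake(prot, "free", map, cond, seed = 12)))
  expect_identical(make_two_state_protein(50, seed = 9),
                   make_two_state_protein(50, seed = 9))
})

test_that("peptides outside the sequence are rejected", {
  prot <- make_two_state_protein(30, seed = 1)
  cond <- labeling_conditions(noise_sd = 0, n_replicates = 2)
  expect_error(
    simulate_uptake(prot, "free", data.frame(start = 25L, end = 35L), cond),
    "outside")
})

test_that("peptide maps tile the protein as specified", {
  m <- make_peptide_map(30, mean_len = 10, step = 5, len_jitter = 0)
  expect_equal(m$start, c(1, 6, 11, 16, 21))
  expect_equal(m$end, c(10, 15, 20, 25, 30))

  expect_equal(make_peptide_map(8, mean_len = 10),
               data.frame(start = 1L, end = 8L))

  # union of spans covers every residue, for any seed, when step is small
  for (s in 1:10) {
    m <- make_peptide_map(97, mean_len = 9, step = 5, len_jitter = 2,
                          seed = s)
    covered <- sort(unique(unlist(mapply(seq, m$start, m$end,
                                         SIMPLIFY = FALSE))))
    expect_identical(covered, 1:97)
  }
})

test_that("crosslink observation simulator emits doublets and lone decoys", {
  obs <- simulate_xlink_observations(615.35917, n_decoys = 0, ppm_sd = 0)
  expect_equal(nrow(obs), 2)
  expect_equal(diff(sort(obs$mass)), 4.025108, tolerance = 1e-9)

  null_obs <- simulate_xlink_observations(numeric(0), n_decoys = 5,
                                          ppm_sd = 0, seed = 42)
  expect_equal(nrow(null_obs), 5)
  gaps <- outer(null_obs$mass, null_obs$mass, function(a, b) b - a)
  expect_false(any(abs(gaps - 4.025108) < 0.02))

  expect_identical(
    simulate_xlink_observations(c(800, 900), 10, 5, seed = 2),
    simulate_xlink_observations(c(800, 900), 10, 5, seed = 2))
})
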