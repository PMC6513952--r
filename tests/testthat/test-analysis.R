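test_that("category occupancy sums to one and averages square waves", {
  const <- make_telegraph_fixture(50, list(1L))
  occ <- category_occupancy(const)
  expect_true(all(occ$series[, 1] == 1))
  expect_equal(unname(occ$average), c(1, 0, 0, 0, 0, 0))

  wave <- make_telegraph_fixture(rep(100, 10), list(1L, 11L))
  occw <- category_occupancy(wave)
  expect_true(all(abs(rowSums(occw$series) - 1) < 1e-12))
  expect_equal(unname(occw$average[1]), 0.5, tolerance = 0.01)
  expect_equal(unname(occw$average[5]), 0.5, tolerance = 0.01)
  expect_error(category_occupancy(structure(list(time = numeric(0)),
                                            class = "sim_trajectory")),
               "no samples")
})

test_that("landscape is a normalised occupancy over the 144 cells", {
  const <- make_telegraph_fixture(20, list(11L))
  L <- landscape(const)
  expect_equal(dim(L), c(12L, 12L))
  expect_equal(L[11, 11], 1)
  expect_equal(sum(L), 1)

  traj <- run_simulation(sim_config(N = 10, duration = 300, seed = 12,
                                    initial_condition = "uniform_random"))
  L2 <- landscape(traj)
  expect_true(all(L2 >= 0))
  expect_equal(sum(L2), 1)
  # aggregating landscape cells by category must reproduce the category
  # averages (two independent aggregation paths)
  cats <- classify_category(rep(1:12, times = 12), rep(1:12, each = 12))
  by_cat <- vapply(1:6, function(k) sum(L2[matrix(cats == k, nrow = 12)]),
                   numeric(1))
  expect_equal(by_cat, unname(category_occupancy(traj)$average),
               tolerance = 1e-12)
})

test_that("regime classification separates bistable, dominant and other runs", {
  # 10 alternating 100-unit epochs: lifetimes 100 >= 40, >= 2 round trips
  bi <- make_telegraph_fixture(rep(100, 10), list(1L, 11L))
  call_bi <- classify_regime(bi)
  expect_equal(call_bi$regime, "bistable")
  expect_gte(call_bi$transitions[["active_to_silent"]], 2)
  expect_gte(call_bi$transitions[["silent_to_active"]], 2)

  expect_equal(classify_regime(make_telegraph_fixture(500, list(1L)))$regime,
               "active")
  expect_equal(classify_regime(make_telegraph_fixture(500, list(11L)))$regime,
               "silent")

  # short epochs: many transitions but mean lifetime 10 < 40 -> never
  # bistable; the call falls through to the dominance test
  flicker <- classify_regime(make_telegraph_fixture(rep(10, 40), list(1L, 11L)))
  expect_false(flicker$regime == "bistable")
  expect_lt(flicker$mean_lifetime[["active"]], 40)
  # with a clearly non-dominant mixture the fallback is "other"
  tri <- make_telegraph_fixture(rep(10, 39), list(1L, 11L, 8L))
  expect_equal(classify_regime(tri)$regime, "other")

  # asymmetric short epochs: dominance fallback -> active
  asym <- make_telegraph_fixture(rep(c(30, 10), 12), list(1L, 11L))
  expect_equal(classify_regime(asym)$regime, "active")
})

test_that("regime classification depends only on the time series, not labels", {
  set.seed(14)
  traj <- run_simulation(sim_config(N = 10, duration = 500, seed = 14,
                                    nurd = 0.25))
  a <- classify_regime(traj)
  b <- classify_regime(traj, bistability_params())
  expect_identical(a$regime, b$regime)
  # strict mode on a clean square wave agrees with lenient
  wave <- make_telegraph_fixture(rep(100, 10), list(1L, 11L))
  expect_equal(classify_regime(wave, bistability_params(mode = "strict"))$regime,
               "bistable")
})

test_that("bistability detector is validated on telegraph dwell times", {
  # true dwell 100 units: accept; true dwell 5 units: reject
  accept <- make_telegraph_fixture(rep(100, 10), list(1L, 11L))
  reject <- make_telegraph_fixture(rep(5, 80), list(1L, 11L))
  expect_equal(classify_regime(accept)$regime, "bistable")
  expect_false(classify_regime(reject)$regime == "bistable")
})

test_that("tail coexistence counts K4/36me within K27me3-bearing halves", {
  expect_equal(tail_coexistence(make_telegraph_fixture(10, list(9L))), 1)
  expect_equal(tail_coexistence(make_telegraph_fixture(10, list(12L))), 0)
  expect_true(is.nan(tail_coexistence(make_telegraph_fixture(10, list(1L)))))
  mixed <- make_telegraph_fixture(c(10, 10), list(9L, c(12L, 12L, 12L, 12L)))
  frac <- tail_coexistence(mixed)
  expect_gt(frac, 0)
  expect_lt(frac, 1)
})

test_that("pairwise bivalent fractions count nucleosome-level co-occurrence", {
  expect_equal(pairwise_bivalent_fraction(
    make_telegraph_fixture(10, list(c(4L, 12L))), "K27ac", "K27me3"), 1)
  expect_equal(pairwise_bivalent_fraction(
    make_telegraph_fixture(10, list(1L)), "K27me3", "K4/36me"), 0)
  expect_equal(pairwise_bivalent_fraction(
    make_telegraph_fixture(10, list(2L)), "H2Aub", "K27ac"), 1)
  expect_error(pairwise_bivalent_fraction(
    make_telegraph_fixture(10, list(1L)), "K27me3", "bogus"), "marks")
  expect_error(pairwise_bivalent_fraction(
    make_telegraph_fixture(10, list(1L)), "K27me3", "H2Aub"), "opposing")
})

test_that("K27me3:K4me ratio in double-marked nucleosomes counts halves", {
  expect_equal(mark_ratio_in_double_marked(
    make_telegraph_fixture(10, list(c(12L, 5L)))), 1)
  expect_equal(mark_ratio_in_double_marked(
    make_telegraph_fixture(10, list(c(9L, 12L)))), 2)
  expect_true(is.nan(mark_ratio_in_double_marked(
    make_telegraph_fixture(10, list(1L)))))
})

test_that("cat5 occupancy rises with NURD and the K27me3:K4me ratio falls", {
  # silent -> active sweep: scaled-down companion of the sweep invariants
  vals <- c(0.0625, 0.5, 4)
  avg5 <- numeric(3)
  ratio <- numeric(3)
  for (i in seq_along(vals)) {
    traj <- run_simulation(sim_config(nurd = vals[i], duration = 5000,
                                      seed = 77))
    avg5[i] <- category_occupancy(traj)$average[5]
    ratio[i] <- mark_ratio_in_double_marked(traj)
  }
  expect_gt(avg5[3], avg5[1] + 0.3)
  # the K27me3:K4me ratio is higher in the silent regime than the active one
  expect_gt(ratio[3], ratio[1])
})
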