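test_that("draw_move converts four uniforms to competing exponential times", {
  for (seed in c(2, 17, 91)) {
    set.seed(seed)
    u <- runif(4)
    expected <- c(-log(u[1]), -log(u[2]) / 0.1, -log(u[3]) / 0.25,
                  -log(u[4]) / 0.15)
    set.seed(seed)
    mv <- draw_move(beta = 0.1, dn = 0.25, dp = 0.15)
    expect_equal(unname(mv$t), expected)
    expect_equal(mv$dt, min(expected))
    expect_equal(mv$channel,
                 c("recruitment", "beta", "nurd", "prdub")[which.min(expected)])
  }
  # zero rates give infinite increments but still consume their uniform
  set.seed(4)
  mv <- draw_move(beta = 0, dn = 0, dp = 0)
  expect_equal(mv$channel, "recruitment")
  expect_equal(unname(mv$t[2:4]), rep(Inf, 3))
  set.seed(4)
  runif(4)
  expect_equal(runif(1), {set.seed(4); mv <- draw_move(0, 0, 0); runif(1)})
  expect_error(draw_move(-1, 0, 0), ">= 0")
})

test_that("recruitment_step honours recruiter sets, inhibitions and self-exclusion", {
  set.seed(8)
  # state 8 recruits nothing: an all-unmodified array can never change
  for (i in 1:50) {
    expect_equal(recruitment_step(rep(8L, 6)), rep(8L, 6))
  }
  # recruiter 12 on target 8 can only ubiquitinate (7) or methylate K27 (12)
  seen <- integer(0)
  for (i in 1:300) {
    out <- recruitment_step(c(12L, 8L))
    if (out[2] != 8L) seen <- union(seen, out[2])
    expect_equal(out[1], 12L)  # a half never modifies itself
  }
  expect_setequal(seen, c(7L, 12L))
  # recruiter 4 cannot push an H2Aub target towards K4/36me (TRXG inhibited)
  for (i in 1:300) {
    out <- recruitment_step(c(4L, 7L))
    expect_false(out[2] == 6L)
    expect_true(out[2] %in% c(7L, 3L))
  }
})

test_that("a zero multiplier suppresses that enzyme's moves", {
  set.seed(9)
  m <- rate_modifiers(prc1 = 0)
  for (i in 1:200) {
    out <- recruitment_step(c(12L, 8L), m)
    expect_false(out[2] == 7L)  # PRC1 ubiquitination never accepted
  }
})

test_that("replication resets halves independently with probability one half", {
  set.seed(21)
  arr <- rep(1L, 400)
  out <- replicate_array(arr)
  expect_true(all(out %in% c(1L, 8L)))
  frac <- mean(out == 8L)
  expect_gt(frac, 0.5 - 3 * sqrt(0.25 / 400))
  expect_lt(frac, 0.5 + 3 * sqrt(0.25 / 400))
  # the mask is exactly the next length(arr) uniforms compared to 0.5
  set.seed(33)
  mask <- runif(10) < 0.5
  set.seed(33)
  out <- replicate_array(rep(c(1L, 11L), 5))
  expect_equal(out == 8L, mask)
})

test_that("compiled engine reproduces the R reference stepper bit for bit", {
  configs <- list(
    sim_config(N = 10, duration = 40, seed = 42, beta = 0.2,
               nurd = 0.7, prdub = 0.3, replication_on = TRUE,
               generation_time = 10),
    sim_config(N = 4, duration = 25, seed = 7, beta = 0.05,
               initial_condition = "uniform_random"),
    sim_config(N = 20, duration = 30, seed = 123, nurd = 2,
               multipliers = rate_modifiers(trxg = 0.5, prc2 = 2))
  )
  for (cfg in configs) {
    ref <- run_reference(cfg)
    got <- run_simulation(cfg)
    expect_equal(unname(got$states), ref$states)
    expect_equal(got$time, ref$time)
    expect_equal(got$repl_times, ref$repl_times)
  }
})

test_that("runs are deterministic given the seed and respect the duration", {
  cfg <- sim_config(N = 8, duration = 100, seed = 99)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$states, b$states)
  expect_identical(a$time, b$time)
  cfg0 <- sim_config(duration = 0, seed = 1)
  t0 <- run_simulation(cfg0)
  expect_equal(nrow(t0$states), 1L)
  expect_equal(t0$time, 0)
  expect_equal(unname(t0$states[1, ]), rep(8L, 20))
})

test_that("sample times are regular and replication events sit on the generation grid", {
  cfg <- sim_config(N = 10, duration = 210, seed = 31, replication_on = TRUE,
                    generation_time = 20)
  traj <- run_simulation(cfg)
  expect_equal(traj$time, seq(0, 210, by = 1))
  traj$repl_times <- traj$repl_times[1:10]
  # each event fires at the first move crossing the 20-unit boundary
  expect_true(all(traj$repl_times >= seq(20, 200, by = 20)))
  expect_lt(max(traj$repl_times - seq(20, 200, by = 20)), 2)
})

test_that("recruitment-off dynamics reach the product-form stationary law", {
  # all recruited moves rejected, direct NURD/PR-DUB off, beta only: per-site
  # stationary law is (1/2, 1/4, 1/4) on K27 x (1/2, 1/2) on K4/36 x
  # (1/2, 1/2) on H2A (scaled-down companion of the full acceptance check)
  cfg <- sim_config(beta = 1, nurd = 0, prdub = 0,
                    multipliers = rate_modifiers(0, 0, 0, 0, 0, 0, 0),
                    duration = 1500, seed = 3,
                    initial_condition = "uniform_random")
  traj <- run_simulation(cfg)
  emp <- tabulate(traj$states, 12) / length(traj$states)
  theo <- c(rep(1 / 16, 4), rep(1 / 8, 4), rep(1 / 16, 4))
  expect_lt(max(abs(emp - theo)), 0.02)
  expect_equal(sum(traj$summary$enzyme_accepts), 0)
})

test_that("with PcG channels disabled the system holds active dominance", {
  cfg <- sim_config(nurd = 0, beta = 0.01,
                    multipliers = rate_modifiers(prc1 = 0, prc2 = 0,
                                                 kdm = 0, nurd = 0),
                    duration = 2000, seed = 5)
  avg <- category_occupancy(run_simulation(cfg))$average
  expect_gt(avg[1], 0.8)
})

test_that("config validation rejects bad inputs before stepping", {
  expect_error(sim_config(N = 7), "even")
  expect_error(sim_config(N = 0), "even")
  expect_error(sim_config(beta = -1), "non-negative")
  expect_error(sim_config(sample_interval = 0), "> 0")
  expect_error(rate_modifiers(prc1 = -0.5), "non-negative")
  expect_error(run_simulation(list()), "sim_config")
})
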