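# Independent R-level reference stepper for the compiled engine. It is built
# from the exported single-move operations (draw_move, recruitment_step,
# direct_conversion, direct_nurd, direct_prdub, replicate_array) and consumes
# the RNG stream in the same frozen order as the C++ loop, so fixed-seed
# trajectories must agree bit for bit.
run_reference <- function(config) {
  set.seed(config$seed)
  array <- switch(config$initial_condition,
    all_unmodified = rep(8L, config$N),
    all_active = rep(1L, config$N),
    all_silent = rep(11L, config$N),
    uniform_random = sample.int(12L, config$N, replace = TRUE))
  N <- config$N
  t_raw <- 0
  last_rep <- 0
  gen_raw <- if (config$replication_on) config$generation_time * N else -1
  n_samples <- floor(config$duration / config$sample_interval + 1e-9) + 1
  times <- numeric(n_samples)
  states <- matrix(0L, n_samples, N)
  times[1] <- 0
  states[1, ] <- array
  nexts <- 2
  repl_times <- numeric(0)
  while (nexts <= n_samples) {
    mv <- draw_move(config$beta, config$nurd_direct, config$prdub_direct)
    t_new <- t_raw + mv$dt
    while (nexts <= n_samples &&
           (nexts - 1) * config$sample_interval <= t_new / N) {
      times[nexts] <- (nexts - 1) * config$sample_interval
      states[nexts, ] <- array
      nexts <- nexts + 1
    }
    if (mv$channel == "recruitment") {
      array <- recruitment_step(array, config$multipliers)
    } else if (mv$channel == "beta") {
      h <- floor(runif(1) * N) + 1
      site <- c("K27", "K436", "H2A")[floor(runif(1) * 3) + 1]
      f <- half_state_fields(array[h])
      u <- if (site == "K27" && f$k27 == "none") runif(1) else 0.5
      array[h] <- direct_conversion(array[h], site, u)
    } else if (mv$channel == "nurd") {
      h <- floor(runif(1) * N) + 1
      to <- direct_nurd(array[h])
      if (!is.na(to)) array[h] <- to
    } else {
      h <- floor(runif(1) * N) + 1
      to <- direct_prdub(array[h])
      if (!is.na(to)) array[h] <- to
    }
    t_raw <- t_new
    if (gen_raw > 0 && t_raw - last_rep >= gen_raw) {
      array <- replicate_array(array)
      last_rep <- t_raw
      repl_times <- c(repl_times, t_raw / N)
    }
  }
  list(time = times, states = states, repl_times = repl_times)
}

# brute-force mark recount straight from the field encoding (kept independent
# of mark_counts / classify_category)
brute_counts <- function(i, j) {
  f <- enumerate_half_states()[c(i, j), ]
  c(active = sum(f$k27 == "ac") + sum(f$k436 == "me"),
    silent = sum(f$k27 == "me3") + sum(f$h2a == "ub"))
}

brute_category <- function(i, j) {
  ct <- brute_counts(i, j)
  a <- ct[["active"]]
  s <- ct[["silent"]]
  if (a == 0 && s == 0) return(6L)
  if (s == 0) return(1L)
  if (a == 0) return(5L)
  fr <- s / (a + s)
  if (fr < 0.5) 2L else if (fr > 0.5) 4L else 3L
}
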