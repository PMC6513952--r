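# Parameter sweeps and phase diagrams: grids of simulations over one or two
# parameters, with a regime call per cell (majority vote over replicate
# seeds). Per-cell seeds are derived deterministically from the base seed so
# cells are independent of execution order.

.SWEEP_PARAMS <- c("beta", "nurd", "prdub", "nurd_direct", "prdub_direct",
                   "trxg", "utx", "cbp", "prc1", "prc2", "kdm")

# set one named parameter on a config, rebuilding it through sim_config()
set_sweep_param <- function(config, param, value) {
  if (!param %in% .SWEEP_PARAMS) {
    stop("unknown sweep parameter '", param, "'; valid: ",
         paste(.SWEEP_PARAMS, collapse = ", "), call. = FALSE)
  }
  m <- config$multipliers
  args <- list(
    N = config$N, beta = config$beta,
    nurd_direct = config$nurd_direct, prdub_direct = config$prdub_direct,
    multipliers = m,
    replication_on = config$replication_on,
    generation_time = config$generation_time,
    duration = config$duration, seed = config$seed,
    sample_interval = config$sample_interval,
    initial_condition = config$initial_condition
  )
  if (param == "beta") {
    args$beta <- value
  } else if (param == "nurd") {
    # the NURD knob scales both the direct channel and the recruited
    # PRC2:KDM:NURD deacetylation
    args$nurd_direct <- value
    args$multipliers[["PRC2_KDM_NURD"]] <- value
  } else if (param == "prdub") {
    args$prdub_direct <- value
  } else if (param == "nurd_direct") {
    args$nurd_direct <- value
  } else if (param == "prdub_direct") {
    args$prdub_direct <- value
  } else {
    slot <- c(trxg = "TRXG", utx = "TRXG_UTX", cbp = "TRXG_CBP",
              prc1 = "PRC1", prc2 = "PRC2", kdm = "PRC2_KDM")[[param]]
    args$multipliers[[slot]] <- value
  }
  do.call(sim_config, args)
}

# deterministic per-cell seed, hashed from the base seed, the parameter
# values and the replicate index so cells are independent of execution
# order; always in [1, 2^31)
cell_seed <- function(base_seed, x_value, y_value, rep) {
  key <- paste(format(x_value, digits = 15), format(y_value, digits = 15),
               rep, sep = "|")
  h <- as.double(base_seed) %% 2147483629
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% 2147483629
  h + 1
}

#' Two-fold default ladder around a centre value
#'
#' @param centre Centre value.
#' @param half_steps Number of 2-fold steps on each side.
#' @return Numeric vector `centre * 2^(-half_steps..half_steps)`.
#' @export
twofold_ladder <- function(centre = 1, half_steps = 3L) {
  centre * 2^seq(-half_steps, half_steps)
}

#' Sweep one or two parameters and assemble a phase diagram
#'
#' Runs `seeds_per_cell` simulations per parameter combination, classifies
#' each with [classify_regime()], and records per-cell majority-vote regime
#' calls alongside average category occupancies.
#'
#' @param base A [sim_config()] giving all fixed parameters.
#' @param x_param,x_values First axis: parameter name (one of `beta`,
#'   `nurd`, `prdub`, `nurd_direct`, `prdub_direct`, `trxg`, `utx`, `cbp`,
#'   `prc1`, `prc2`, `kdm`) and its values.
#' @param y_param,y_values Optional second axis.
#' @param seeds_per_cell Replicate runs per cell; seeds are derived
#'   deterministically from `base$seed` per cell and replicate.
#' @param params Classifier settings from [bistability_params()].
#' @return A `phase_diagram`: list with `runs` (one row per run: axis values,
#'   seed, regime, `avg_cat1..avg_cat6`) and `cells` (majority-vote regime
#'   per cell).
#' @export
grid_sweep <- function(base, x_param, x_values,
                       y_param = NULL, y_values = NULL,
                       seeds_per_cell = 3L,
                       params = bistability_params()) {
  stopifnot(inherits(base, "sim_config"))
  if (is.null(y_param)) {
    y_param <- NA_character_
    y_values <- NA_real_
  }
  # validate parameter names before any run
  for (p in c(x_param, y_param)) {
    if (!is.na(p) && !p %in% .SWEEP_PARAMS) {
      stop("unknown sweep parameter '", p, "'", call. = FALSE)
    }
  }
  rows <- list()
  for (ix in seq_along(x_values)) {
    for (iy in seq_along(y_values)) {
      cfg <- set_sweep_param(base, x_param, x_values[ix])
      if (!is.na(y_param)) {
        cfg <- set_sweep_param(cfg, y_param, y_values[iy])
      }
      for (r in seq_len(seeds_per_cell)) {
        cfg$seed <- as.integer(cell_seed(base$seed, x_values[ix],
                                         y_values[iy], r))
        call <- classify_regime(run_simulation(cfg), params)
        rows[[length(rows) + 1L]] <- data.frame(
          param_x = x_param, value_x = x_values[ix],
          param_y = y_param, value_y = y_values[iy],
          seed = cfg$seed, regime = call$regime,
          avg_cat1 = call$average[1], avg_cat2 = call$average[2],
          avg_cat3 = call$average[3], avg_cat4 = call$average[4],
          avg_cat5 = call$average[5], avg_cat6 = call$average[6],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  runs <- do.call(rbind, rows)
  row.names(runs) <- NULL
  cells <- stats::aggregate(
    regime ~ value_x + value_y, data = transform(runs, value_y =
      ifelse(is.na(value_y), 0, value_y)),
    FUN = majority_vote
  )
  cells$value_y[is.na(y_param)] <- NA_real_
  structure(list(runs = runs, cells = cells,
                 x_param = x_param, y_param = y_param),
            class = "phase_diagram")
}

majority_vote <- function(x) {
  tab <- sort(table(x), decreasing = TRUE)
  names(tab)[1]
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("<phase_diagram> %s x %s, %d runs\n",
              x$x_param, ifelse(is.na(x$y_param), "-", x$y_param),
              nrow(x$runs)))
  print(table(x$runs$regime))
  invisible(x)
}

#' Scan one parameter along a geometric ladder of values
#'
#' Runs the base configuration at `v0 * factor^k` for each `k` in `k_range`
#' (in increasing order) and classifies each run, locating where the system
#' switches between active and silent dominance. Useful for finding the
#' active / bistable / silent reference triplet along e.g. the NURD axis.
#'
#' @param base A [sim_config()].
#' @param parameter Parameter name, as in [grid_sweep()].
#' @param v0 Ladder centre (the value at `k = 0`).
#' @param factor Step factor between consecutive values (default 2-fold).
#' @param k_range Integer exponents to scan, in increasing order.
#' @param params Classifier settings.
#' @return Data frame with one row per ladder value: `k`, `value`, `regime`,
#'   `avg_cat1`, `avg_cat5`. Attributes `first_silent` and `first_active`
#'   give the first `k` achieving silent / active dominance (`NA` when no
#'   switch is found within the ladder; flagged, not an error).
#' @export
boundary_scan <- function(base, parameter, v0 = 1, factor = 2,
                          k_range = -4:6,
                          params = bistability_params()) {
  stopifnot(inherits(base, "sim_config"))
  rows <- lapply(k_range, function(k) {
    cfg <- set_sweep_param(base, parameter, v0 * factor^k)
    call <- classify_regime(run_simulation(cfg), params)
    data.frame(k = k, value = v0 * factor^k, regime = call$regime,
               avg_cat1 = call$average[1], avg_cat5 = call$average[5],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  silent_k <- out$k[out$avg_cat5 > params$dominance_avg_threshold]
  active_k <- out$k[out$avg_cat1 > params$dominance_avg_threshold]
  attr(out, "first_silent") <- if (length(silent_k)) min(silent_k) else NA_integer_
  attr(out, "first_active") <- if (length(active_k)) min(active_k) else NA_integer_
  out
}

#' Locate the active / bistable / silent reference triptych
#'
#' Finds the three reference NURD settings whose simulations give an
#' active-dominant, a bistable and a silent-dominant run, 2-fold apart: a
#' two-fold change in the H3K27 deacetylation rate in either direction away
#' from the bistable point switches the system to a stable state. The
#' procedure is: (1) step the NURD knob in 2-fold increments from `v0` until
#' the run is silent-dominant, then keep halving until one is
#' active-dominant, giving a bracket; (2) bisect the bracket geometrically
#' and take as the bistable centre `b` the bisection run called bistable
#' whose category-1 and category-5 averages are most balanced (the paper's
#' intermediate situation, with occupancy peaks at both extreme corners);
#' (3) rerun at `b / 2` and `2 b` for the flanking settings. All runs use
#' `base$seed`.
#'
#' @param base A [sim_config()] providing all other parameters.
#' @param v0 Starting NURD value for the 2-fold ladder.
#' @param k_up,k_down Maximum number of 2-fold steps searched upwards /
#'   downwards from `v0`.
#' @param n_bisect Number of geometric bisection steps inside the bracket.
#' @param params Classifier settings.
#' @return List with elements `active`, `bistable`, `silent`, each holding
#'   `value` (the NURD rate), `call` (a [classify_regime()] result) and
#'   `trajectory`; plus `ladder`, a data frame of every run performed.
#' @export
reference_triptych <- function(base, v0 = 1, k_up = 6L, k_down = 10L,
                               n_bisect = 6L,
                               params = bistability_params()) {
  stopifnot(inherits(base, "sim_config"))
  ladder <- list()
  run_at <- function(value) {
    cfg <- set_sweep_param(base, "nurd", value)
    traj <- run_simulation(cfg)
    out <- list(value = value, call = classify_regime(traj, params),
                trajectory = traj)
    ladder[[length(ladder) + 1L]] <<- data.frame(
      value = value, regime = out$call$regime,
      avg_cat1 = out$call$average[1], avg_cat5 = out$call$average[5])
    out
  }
  thr <- params$dominance_avg_threshold
  # 2-fold ladder: up to the silent side, then down to the active side
  k_silent <- NULL
  for (k in 0:k_up) {
    if (run_at(v0 * 2^k)$call$average[5] > thr) {
      k_silent <- k
      break
    }
  }
  if (is.null(k_silent)) {
    stop("no silent-dominant setting found within the NURD ladder",
         call. = FALSE)
  }
  k_active <- NULL
  lo_silent <- k_silent
  for (k in seq(k_silent - 1L, k_silent - k_down)) {
    cand <- run_at(v0 * 2^k)
    if (cand$call$average[5] > thr) lo_silent <- k
    if (cand$call$average[1] > thr) {
      k_active <- k
      break
    }
  }
  if (is.null(k_active)) {
    stop("no active-dominant setting found within the NURD ladder",
         call. = FALSE)
  }
  # geometric bisection of the bracket on the sign of cat1 - cat5
  a <- v0 * 2^k_active
  s <- v0 * 2^lo_silent
  best <- NULL
  for (i in seq_len(n_bisect)) {
    m <- sqrt(a * s)
    cand <- run_at(m)
    bal <- abs(cand$call$average[1] - cand$call$average[5])
    if (cand$call$regime == "bistable" &&
        (is.null(best) || bal < abs(best$call$average[1] -
                                      best$call$average[5]))) {
      best <- cand
    }
    if (cand$call$average[1] > cand$call$average[5]) a <- m else s <- m
  }
  if (is.null(best)) {
    stop("no bistable run found inside the active/silent bracket",
         call. = FALSE)
  }
  list(active = run_at(best$value / 2),
       bistable = best,
       silent = run_at(best$value * 2),
       ladder = do.call(rbind, ladder))
}
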