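# Simulation configuration and the event-based update loop.
#
# Rates and conventions: the recruitment channel has total rate 1 for the
# whole array; the recruitment-independent channel has rate `beta`; direct
# NURD deacetylation and direct PR-DUB deubiquitination have rates
# `nurd_direct` and `prdub_direct`. Per-enzyme multipliers modulate the
# acceptance of recruited moves (see `rate_modifiers`). Plotted time = raw
# event time / N, i.e. recruitment attempts per half-nucleosome.

#' Per-enzyme rate multipliers
#'
#' A multiplier \eqn{m_e \ge 0} per recruited complex. An otherwise
#' acceptable recruited move by enzyme \eqn{e} is accepted with probability
#' \eqn{m_e / \max(1, \max_e m_e)}: lowering a rate below 1 reduces that
#' enzyme's acceptance; raising one above 1 instead attenuates all the
#' others, keeping the total recruitment attempt rate at 1.
#'
#' The `nurd` convenience knob in [sim_config()] scales both this
#' `PRC2_KDM_NURD` multiplier and the direct deacetylation rate, since both
#' represent NURD activity; `prdub` maps to the direct deubiquitination rate
#' (PR-DUB acts only through the direct channel).
#'
#' @param trxg,utx,cbp,prc1,prc2,kdm,nurd Non-negative multipliers for TRXG,
#'   TRXG:UTX, TRXG:CBP, PRC1, PRC2, PRC2:KDM and PRC2:KDM:NURD.
#' @return Named numeric vector of length 7 in the order of [enzymes()].
#' @export
rate_modifiers <- function(trxg = 1, utx = 1, cbp = 1, prc1 = 1,
                           prc2 = 1, kdm = 1, nurd = 1) {
  m <- c(TRXG = trxg, TRXG_UTX = utx, TRXG_CBP = cbp, PRC1 = prc1,
         PRC2 = prc2, PRC2_KDM = kdm, PRC2_KDM_NURD = nurd)
  if (anyNA(m) || any(m < 0)) {
    stop("rate multipliers must be non-negative", call. = FALSE)
  }
  m
}

#' Simulation configuration
#'
#' Defaults are the reference parameterisation used throughout: all
#' transition rates 1.0 except `beta = 0.1` and `prdub = 0.15`, a system of
#' `N = 20` half-nucleosomes (10 whole nucleosomes, about 2 kb of
#' chromatin), 50,000 plotted time units, no replication.
#'
#' @param N Even number of half-nucleosomes (>= 2); halves `2k - 1` and `2k`
#'   form whole nucleosome `k`.
#' @param beta Rate of recruitment-independent conversions.
#' @param nurd Convenience knob for NURD activity: sets `nurd_direct` and the
#'   `PRC2_KDM_NURD` multiplier (both times this value).
#' @param prdub Rate of direct PR-DUB deubiquitination (`prdub_direct`).
#' @param nurd_direct,prdub_direct Direct-channel rates; default to `nurd`
#'   and `prdub`.
#' @param multipliers Enzyme multipliers from [rate_modifiers()]; the
#'   `PRC2_KDM_NURD` entry is additionally scaled by `nurd`.
#' @param replication_on If `TRUE`, every half-nucleosome is reset to the
#'   unmodified state 8 with probability 0.5 every `generation_time` plotted
#'   units (replication-coupled histone dilution).
#' @param generation_time Plotted time units between replications.
#' @param duration Simulated duration in plotted time units.
#' @param seed Integer RNG seed; every source of randomness in a run flows
#'   from it.
#' @param sample_interval Plotted time units between recorded samples.
#' @param initial_condition One of `"all_unmodified"` (state 8),
#'   `"all_active"` (state 1), `"all_silent"` (state 11), `"uniform_random"`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(N = 20L, beta = 0.1, nurd = 1, prdub = 0.15,
                       nurd_direct = NULL, prdub_direct = NULL,
                       multipliers = rate_modifiers(),
                       replication_on = FALSE, generation_time = 20,
                       duration = 50000, seed = 1L, sample_interval = 1,
                       initial_condition = c("all_unmodified", "all_active",
                                             "all_silent", "uniform_random")) {
  N <- as.integer(N)
  if (is.na(N) || N < 2L || N %% 2L != 0L) {
    stop("'N' must be an even integer >= 2", call. = FALSE)
  }
  rates <- c(beta = beta, nurd = nurd, prdub = prdub,
             generation_time = generation_time,
             sample_interval = sample_interval)
  if (anyNA(rates) || any(rates < 0)) {
    stop("rates and intervals must be non-negative", call. = FALSE)
  }
  if (is.na(duration) || duration < 0) {
    stop("'duration' must be >= 0", call. = FALSE)
  }
  if (sample_interval <= 0) {
    stop("'sample_interval' must be > 0", call. = FALSE)
  }
  multipliers <- rate_modifiers(trxg = multipliers[["TRXG"]],
                                utx = multipliers[["TRXG_UTX"]],
                                cbp = multipliers[["TRXG_CBP"]],
                                prc1 = multipliers[["PRC1"]],
                                prc2 = multipliers[["PRC2"]],
                                kdm = multipliers[["PRC2_KDM"]],
                                nurd = multipliers[["PRC2_KDM_NURD"]] * nurd)
  structure(list(
    N = N,
    beta = beta,
    nurd_direct = if (is.null(nurd_direct)) nurd else nurd_direct,
    prdub_direct = if (is.null(prdub_direct)) prdub else prdub_direct,
    multipliers = multipliers,
    replication_on = isTRUE(replication_on),
    generation_time = generation_time,
    duration = duration,
    seed = as.integer(seed),
    sample_interval = sample_interval,
    initial_condition = match.arg(initial_condition)
  ), class = "sim_config")
}

initial_array <- function(config) {
  switch(config$initial_condition,
    all_unmodified = rep(8L, config$N),
    all_active = rep(1L, config$N),
    all_silent = rep(11L, config$N),
    uniform_random = sample.int(12L, config$N, replace = TRUE)
  )
}

#' Draw the next move type and waiting time
#'
#' Draws four independent exponential waiting times, one per move channel
#' (recruitment at rate 1, beta conversion, direct NURD, direct PR-DUB), and
#' selects the channel with the smallest increment. Exactly four uniforms are
#' consumed, in that fixed order, regardless of which rates are zero (a zero
#' rate gives an infinite increment).
#'
#' @param beta,dn,dp Non-negative channel rates (recruitment is fixed at 1).
#' @return List with `channel` (one of `"recruitment"`, `"beta"`, `"nurd"`,
#'   `"prdub"`), `dt` (the minimum increment, raw time units) and `t` (all
#'   four increments).
#' @export
draw_move <- function(beta, dn, dp) {
  if (any(c(beta, dn, dp) < 0)) stop("rates must be >= 0", call. = FALSE)
  u <- stats::runif(4)
  t <- c(recruitment = -log(u[1]),
         beta  = if (beta > 0) -log(u[2]) / beta else Inf,
         nurd  = if (dn > 0) -log(u[3]) / dn else Inf,
         prdub = if (dp > 0) -log(u[4]) / dp else Inf)
  k <- which.min(t)
  list(channel = names(t)[k], dt = unname(t[k]), t = t)
}

#' One recruitment move on a half-nucleosome array
#'
#' A recruiting half-nucleosome is chosen uniformly; if its state recruits no
#' complex (state 8) nothing happens. Otherwise one of its recruited enzymes
#' is chosen uniformly, then a target is chosen uniformly among the other
#' `N - 1` halves (a half never modifies itself). If the enzyme can change
#' the target, the change is accepted with probability
#' `m_e / max(1, max(m))`.
#'
#' This is the reference R implementation of a single move; [run_simulation()]
#' executes the same logic (and RNG draw order) in compiled code.
#'
#' @param array Integer vector of half-nucleosome states.
#' @param multipliers Multipliers from [rate_modifiers()].
#' @return The (possibly unchanged) array.
#' @export
recruitment_step <- function(array, multipliers = rate_modifiers()) {
  N <- length(array)
  recruiter <- floor(stats::runif(1) * N) + 1
  enz <- recruited_complexes(array[recruiter])
  if (length(enz) == 0L) return(array)
  e <- enz[floor(stats::runif(1) * length(enz)) + 1]
  target <- floor(stats::runif(1) * (N - 1)) + 1
  if (target >= recruiter) target <- target + 1
  to <- apply_enzyme(e, array[target])
  if (!is.na(to)) {
    accept <- multipliers[[e]] / max(1, max(multipliers))
    if (stats::runif(1) < accept) array[target] <- to
  }
  array
}

#' Replication reset of a half-nucleosome array
#'
#' Each half-nucleosome is independently replaced by the unmodified state 8
#' with probability 0.5, emulating random partitioning of parental histones
#' at DNA replication. Pairing is positional and therefore preserved.
#'
#' @param array Integer vector of half-nucleosome states.
#' @return The array after replication.
#' @export
replicate_array <- function(array) {
  reset <- stats::runif(length(array)) < 0.5
  array[reset] <- 8L
  array
}

#' Run a stochastic simulation
#'
#' Executes the event-based update loop: at each step four competing
#' exponential waiting times are drawn (recruitment, beta conversion, direct
#' NURD, direct PR-DUB), the channel with the smallest increment attempts its
#' move, and raw time advances by the minimum increment whether or not the
#' attempt succeeds. If replication is enabled, each crossing of the
#' generation boundary resets every half to state 8 with probability 0.5.
#' The array is sampled every `sample_interval` plotted time units.
#'
#' Runs are deterministic given `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @return A `sim_trajectory`: list with `time` (plotted sample times),
#'   `states` (samples x N integer matrix of half-nucleosome states),
#'   `repl_times` (plotted times of replication events), `config`, and a
#'   `summary` of event counts per channel and per enzyme.
#' @export
run_simulation <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("'config' must be a sim_config object", call. = FALSE)
  }
  set.seed(config$seed)
  init <- initial_array(config)
  recruiters <- unname(lapply(1:12, function(s) {
    which(vapply(.ENZYMES, function(e) s %in% .RECRUITERS[[e]], logical(1)))
  }))
  actions <- .ACTIONS
  actions[is.na(actions)] <- 0L
  res <- run_engine_cpp(
    init = init,
    beta = config$beta, dn = config$nurd_direct, dp = config$prdub_direct,
    mult = unname(config$multipliers),
    recruiters = recruiters,
    actions = actions,
    generation_raw = if (config$replication_on)
      config$generation_time * config$N else -1,
    duration = config$duration,
    sample_interval = config$sample_interval
  )
  structure(list(
    time = res$time,
    states = res$states,
    repl_times = res$repl_times,
    config = config,
    summary = list(
      channel_events = stats::setNames(res$channel_events,
                                       c("recruitment", "beta", "nurd", "prdub")),
      enzyme_attempts = stats::setNames(res$enzyme_attempts, .ENZYMES),
      enzyme_accepts = stats::setNames(res$enzyme_accepts, .ENZYMES),
      repl_count = res$repl_count,
      end_time = res$end_time
    )
  ), class = "sim_trajectory")
}

#' @export
print.sim_trajectory <- function(x, ...) {
  cat(sprintf(
    "<sim_trajectory> N = %d half-nucleosomes, %d samples over %.6g plotted units, %d replication events\n",
    ncol(x$states), length(x$time), max(x$time), length(x$repl_times)))
  invisible(x)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> N = %d, beta = %g, nurd_direct = %g, prdub_direct = %g, duration = %g, seed = %d\n",
    x$N, x$beta, x$nurd_direct, x$prdub_direct, x$duration, x$seed))
  cat("  multipliers:",
      paste(sprintf("%s=%g", names(x$multipliers), x$multipliers), collapse = " "),
      "\n")
  cat(sprintf("  replication: %s (generation time %g), init: %s\n",
              if (x$replication_on) "on" else "off",
              x$generation_time, x$initial_condition))
  invisible(x)
}
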