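# Trajectory summaries: category occupancy, 144-state landscapes, regime
# classification (active / silent / bistable), and co-occurrence statistics
# for opposing marks.
#
# Samples are taken at a fixed interval, so time-weighted averages over the
# run reduce to plain means over samples; no burn-in is discarded.

check_trajectory <- function(traj) {
  if (!inherits(traj, "sim_trajectory")) {
    stop("expected a 'sim_trajectory' object", call. = FALSE)
  }
  if (length(traj$time) == 0L) {
    stop("trajectory has no samples", call. = FALSE)
  }
  invisible(traj)
}

# category per whole nucleosome per sample: samples x (N/2) integer matrix
sample_categories <- function(traj) {
  st <- traj$states
  N <- ncol(st)
  first <- st[, seq(1L, N, by = 2L), drop = FALSE]
  second <- st[, seq(2L, N, by = 2L), drop = FALSE]
  matrix(.CAT144[cbind(as.vector(first), as.vector(second))], nrow = nrow(st))
}

#' Category occupancy over time and its average
#'
#' For each sample, the fraction of whole nucleosomes in each of the six
#' categories (see [classify_category()]); and the time-weighted average of
#' those fractions over the full run.
#'
#' @param traj A `sim_trajectory` from [run_simulation()] or
#'   [make_telegraph_fixture()].
#' @return List with `time`, `series` (samples x 6 matrix of fractions, rows
#'   summing to 1) and `average` (length-6 vector).
#' @export
category_occupancy <- function(traj) {
  check_trajectory(traj)
  cats <- sample_categories(traj)
  n_nuc <- ncol(cats)
  series <- t(apply(cats, 1L, function(row) tabulate(row, nbins = 6L))) / n_nuc
  colnames(series) <- paste0("cat", 1:6)
  list(time = traj$time, series = series, average = colMeans(series))
}

#' Time-averaged occupancy landscape over the 144 whole-nucleosome states
#'
#' @param traj A `sim_trajectory`.
#' @return A 12 x 12 matrix; entry `(i, j)` is the probability that a whole
#'   nucleosome has its first half in state `i` and its second in state `j`,
#'   averaged over nucleosomes and samples. Entries sum to 1.
#' @export
landscape <- function(traj) {
  check_trajectory(traj)
  st <- traj$states
  N <- ncol(st)
  first <- as.vector(st[, seq(1L, N, by = 2L), drop = FALSE])
  second <- as.vector(st[, seq(2L, N, by = 2L), drop = FALSE])
  counts <- table(factor(first, levels = 1:12), factor(second, levels = 1:12))
  out <- unclass(counts) / length(first)
  dimnames(out) <- list(first = 1:12, second = 1:12)
  out
}

#' Parameters of the bistability / dominance classifier
#'
#' @param dominance_threshold Category fraction a sample must exceed to count
#'   as being in the active (category 1) or silent (category 5) zone.
#' @param min_mean_lifetime Minimum mean epoch lifetime, plotted time units,
#'   required of both epoch types for a bistable call.
#' @param min_round_trips Minimum number of transitions in each direction
#'   (active to silent and silent to active).
#' @param dominance_avg_threshold Time-averaged occupancy above which a
#'   non-bistable run is called active (category 1) or silent (category 5).
#' @param mode `"lenient"` treats samples in neither zone as continuation of
#'   the current epoch; `"strict"` ends an epoch at the first out-of-zone
#'   sample.
#' @return A list of class `bistability_params`.
#' @export
bistability_params <- function(dominance_threshold = 0.6,
                               min_mean_lifetime = 40,
                               min_round_trips = 2L,
                               dominance_avg_threshold = 0.5,
                               mode = c("lenient", "strict")) {
  if (dominance_threshold <= 0.5 || dominance_threshold > 1) {
    stop("'dominance_threshold' must be in (0.5, 1]", call. = FALSE)
  }
  structure(list(dominance_threshold = dominance_threshold,
                 min_mean_lifetime = min_mean_lifetime,
                 min_round_trips = as.integer(min_round_trips),
                 dominance_avg_threshold = dominance_avg_threshold,
                 mode = match.arg(mode)),
            class = "bistability_params")
}

#' Classify a trajectory as active, silent, bistable or other
#'
#' Samples with more than `dominance_threshold` of whole nucleosomes in
#' category 1 (resp. 5) define active (resp. silent) zone visits. Zone visits
#' are segmented into epochs; a run is *bistable* when there are at least
#' `min_round_trips` transitions in each direction and the mean epoch
#' lifetime of both epoch types is at least `min_mean_lifetime` plotted time
#' units. Otherwise the run is *active* (*silent*) if the time-averaged
#' category-1 (category-5) occupancy exceeds `dominance_avg_threshold`, and
#' *other* if neither dominates.
#'
#' @param traj A `sim_trajectory`.
#' @param params A [bistability_params()] object.
#' @return List of class `regime_call` with `regime`, the average category
#'   occupancies, epoch counts and mean lifetimes per epoch type, and the
#'   transition counts.
#' @export
classify_regime <- function(traj, params = bistability_params()) {
  check_trajectory(traj)
  occ <- category_occupancy(traj)
  zone <- integer(nrow(occ$series))          # +1 active, -1 silent, 0 neither
  zone[occ$series[, 1] > params$dominance_threshold] <- 1L
  zone[occ$series[, 5] > params$dominance_threshold] <- -1L

  ep <- segment_epochs(occ$time, zone, params$mode)
  n_as <- sum(ep$type == 1L & c(ep$type[-1], 0L) == -1L)
  n_sa <- sum(ep$type == -1L & c(ep$type[-1], 0L) == 1L)
  mean_life_a <- if (any(ep$type == 1L)) mean(ep$length[ep$type == 1L]) else NA_real_
  mean_life_s <- if (any(ep$type == -1L)) mean(ep$length[ep$type == -1L]) else NA_real_

  bistable <- !is.na(mean_life_a) && !is.na(mean_life_s) &&
    n_as >= params$min_round_trips && n_sa >= params$min_round_trips &&
    mean_life_a >= params$min_mean_lifetime &&
    mean_life_s >= params$min_mean_lifetime

  regime <- if (bistable) {
    "bistable"
  } else if (occ$average[1] > params$dominance_avg_threshold) {
    "active"
  } else if (occ$average[5] > params$dominance_avg_threshold) {
    "silent"
  } else {
    "other"
  }

  structure(list(
    regime = regime,
    average = occ$average,
    n_epochs = c(active = sum(ep$type == 1L), silent = sum(ep$type == -1L)),
    mean_lifetime = c(active = mean_life_a, silent = mean_life_s),
    transitions = c(active_to_silent = n_as, silent_to_active = n_sa),
    params = params
  ), class = "regime_call")
}

# Epochs from a zone series. Lenient mode: keep only in-zone samples and run-
# length encode their signs; an epoch lasts from its first in-zone sample to
# the first sample of the next opposite-zone run (the last epoch ends at the
# final sample). Strict mode: an epoch is a maximal run of consecutive
# in-zone samples of one sign, measured to the first sample after the run.
segment_epochs <- function(time, zone, mode = "lenient") {
  if (mode == "lenient") {
    keep <- zone != 0L
    if (!any(keep)) return(list(type = integer(0), length = numeric(0)))
    z <- zone[keep]
    tt <- time[keep]
    r <- rle(z)
    starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
    entry <- tt[starts]
    exit <- c(entry[-1], time[length(time)])
    list(type = r$values, length = exit - entry)
  } else {
    r <- rle(zone)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values != 0L
    entry <- time[starts[keep]]
    exit_idx <- pmin(ends[keep] + 1L, length(time))
    list(type = r$values[keep], length = time[exit_idx] - entry)
  }
}

#' @export
print.regime_call <- function(x, ...) {
  cat(sprintf("<regime_call> %s (avg cat1 = %.3f, cat5 = %.3f; %d/%d transitions; mean lifetimes %.1f/%.1f)\n",
              x$regime, x$average[1], x$average[5],
              x$transitions[1], x$transitions[2],
              x$mean_lifetime[1], x$mean_lifetime[2]))
  invisible(x)
}

# per-mark half-state membership
.MARK_STATES <- list(
  K27me3 = c(9L, 10L, 11L, 12L),
  K27ac  = c(1L, 2L, 3L, 4L),
  `K4/36me` = c(1L, 2L, 5L, 6L, 9L, 10L),
  H2Aub  = c(2L, 3L, 6L, 7L, 10L, 11L)
)

#' Co-occurrence of K4/36 methylation on H3K27me3 tails
#'
#' Time-averaged fraction of H3K27me3-bearing half-nucleosomes (states 9-12)
#' that also carry H3K4/36 methylation (states 9, 10). The tail-level
#' counterpart of bivalency: both marks on the same H3 tail.
#'
#' @param traj A `sim_trajectory`.
#' @return A fraction in `[0, 1]`, or `NaN` when no H3K27me3 tails occur.
#' @export
tail_coexistence <- function(traj) {
  check_trajectory(traj)
  st <- traj$states
  num <- sum(st == 9L | st == 10L)
  den <- num + sum(st == 11L | st == 12L)
  if (den == 0L) NaN else num / den
}

#' Fraction of whole nucleosomes carrying a pair of opposing marks
#'
#' A nucleosome carries a mark when either of its halves does; the fraction
#' of nucleosome-samples carrying both marks is averaged over the run.
#'
#' @param traj A `sim_trajectory`.
#' @param markA,markB Mark names among `"K27me3"`, `"K27ac"`, `"K4/36me"`,
#'   `"H2Aub"`; one must be active and the other silent.
#' @return A fraction in `[0, 1]`.
#' @export
pairwise_bivalent_fraction <- function(traj, markA, markB) {
  check_trajectory(traj)
  marks <- names(.MARK_STATES)
  if (!markA %in% marks || !markB %in% marks) {
    stop("marks must be among: ", paste(marks, collapse = ", "), call. = FALSE)
  }
  silent_marks <- c("K27me3", "H2Aub")
  if ((markA %in% silent_marks) == (markB %in% silent_marks)) {
    stop("'markA' and 'markB' must be an opposing (active/silent) pair",
         call. = FALSE)
  }
  st <- traj$states
  N <- ncol(st)
  i1 <- seq(1L, N, by = 2L)
  i2 <- seq(2L, N, by = 2L)
  hasA <- matrix(st %in% .MARK_STATES[[markA]], nrow = nrow(st))
  hasB <- matrix(st %in% .MARK_STATES[[markB]], nrow = nrow(st))
  both <- (hasA[, i1, drop = FALSE] | hasA[, i2, drop = FALSE]) &
          (hasB[, i1, drop = FALSE] | hasB[, i2, drop = FALSE])
  mean(both)
}

#' K27me3 : K4/36me ratio within double-marked nucleosomes
#'
#' Among whole nucleosomes carrying both H3K27me3 and H3K4/36me (on the same
#' or different halves), the ratio of H3K27me3-bearing half count to
#' K4/36me-bearing half count, aggregated over all such nucleosome-samples.
#' This ratio drops as the system shifts from silent towards active.
#'
#' @param traj A `sim_trajectory`.
#' @return A positive ratio, or `NaN` when no double-marked nucleosomes
#'   occur.
#' @export
mark_ratio_in_double_marked <- function(traj) {
  check_trajectory(traj)
  st <- traj$states
  N <- ncol(st)
  i1 <- seq(1L, N, by = 2L)
  i2 <- seq(2L, N, by = 2L)
  me3 <- matrix(st %in% .MARK_STATES$K27me3, nrow = nrow(st))
  k4 <- matrix(st %in% .MARK_STATES$`K4/36me`, nrow = nrow(st))
  me3_1 <- me3[, i1, drop = FALSE]; me3_2 <- me3[, i2, drop = FALSE]
  k4_1 <- k4[, i1, drop = FALSE];  k4_2 <- k4[, i2, drop = FALSE]
  both <- (me3_1 | me3_2) & (k4_1 | k4_2)
  num <- sum((me3_1 + me3_2)[both])
  den <- sum((k4_1 + k4_2)[both])
  if (den == 0L) NaN else num / den
}
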