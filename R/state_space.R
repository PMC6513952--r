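#' @useDynLib chromsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Frozen numbering of the 12 half-nucleosome states.
#
# A half-nucleosome is one H3 tail plus one H2A tail. Its state is the
# combination of three sites: H3K27 (unmodified / acetylated / trimethylated;
# acetylation and methylation are mutually exclusive on one tail), fused
# H3K4/36 methylation (absent / present) and H2A K118/119 monoubiquitination
# (absent / present) -- 3 x 2 x 2 = 12 states. The index assignment below is
# the unique one consistent with the numbered constraints used throughout:
# states 1-4 carry H3K27ac, 9-12 carry H3K27me3, 8 is unmodified, the
# ubiquitinated states are {2,3,6,7,10,11} and the K4/36-methylated states are
# {1,2,5,6,9,10}.

.K27_LEVELS  <- c("none", "ac", "me3")
.K436_LEVELS <- c("none", "me")
.H2A_LEVELS  <- c("none", "ub")

.HALF_STATES <- data.frame(
  index = 1:12,
  k27  = c("ac", "ac", "ac", "ac",
           "none", "none", "none", "none",
           "me3", "me3", "me3", "me3"),
  k436 = c("me", "me", "none", "none",
           "me", "me", "none", "none",
           "me", "me", "none", "none"),
  h2a  = c("none", "ub", "ub", "none",
           "none", "ub", "ub", "none",
           "none", "ub", "ub", "none"),
  stringsAsFactors = FALSE
)

# Per-state mark counts: active marks are H3K27ac and H3K4/36me, silent marks
# are H3K27me3 and H2Aub.
.HALF_ACTIVE <- (.HALF_STATES$k27 == "ac") + (.HALF_STATES$k436 == "me")
.HALF_SILENT <- (.HALF_STATES$k27 == "me3") + (.HALF_STATES$h2a == "ub")

#' Enumerate the 12 half-nucleosome modification states
#'
#' Returns the full table of allowed half-nucleosome states in index order.
#' Each state is a combination of the H3K27 site (`none`, `ac` or `me3`;
#' acetylation and trimethylation are mutually exclusive on the same tail),
#' the fused H3K4/36 methylation site (`none` or `me`) and the H2A
#' ubiquitination site (`none` or `ub`).
#'
#' @return A data frame with 12 rows and columns `index`, `k27`, `k436`,
#'   `h2a`.
#' @examples
#' enumerate_half_states()
#' @export
enumerate_half_states <- function() {
  .HALF_STATES
}

#' Map a half-nucleosome state to its index
#'
#' @param k27 One of `"none"`, `"ac"`, `"me3"`.
#' @param k436 One of `"none"`, `"me"`.
#' @param h2a One of `"none"`, `"ub"`.
#' @return Integer index in 1..12 (state 8 is the unmodified state).
#' @seealso [half_state_fields()] for the inverse.
#' @examples
#' half_state_index("none", "none", "none")  # 8
#' half_state_index("me3", "none", "ub")     # 11
#' @export
half_state_index <- function(k27, k436, h2a) {
  k27  <- match.arg(k27, .K27_LEVELS)
  k436 <- match.arg(k436, .K436_LEVELS)
  h2a  <- match.arg(h2a, .H2A_LEVELS)
  hit <- which(.HALF_STATES$k27 == k27 &
                 .HALF_STATES$k436 == k436 &
                 .HALF_STATES$h2a == h2a)
  .HALF_STATES$index[hit]
}

#' Fields of a half-nucleosome state given its index
#'
#' @param index Integer vector with values in 1..12.
#' @return Data frame with columns `index`, `k27`, `k436`, `h2a`, one row per
#'   input element.
#' @export
half_state_fields <- function(index) {
  index <- check_state_index(index)
  .HALF_STATES[index, , drop = FALSE]
}

check_state_index <- function(index) {
  index <- as.integer(index)
  if (length(index) == 0L || anyNA(index) || any(index < 1L | index > 12L)) {
    stop("half-nucleosome state indices must be integers in 1..12",
         call. = FALSE)
  }
  index
}

#' Active and silent mark counts of a whole nucleosome
#'
#' A whole nucleosome is an ordered pair of half-nucleosome states (ordered by
#' array position). Active marks are H3K27ac and H3K4/36me; silent marks are
#' H3K27me3 and H2Aub. Each count ranges over 0..4 (up to two marks per half).
#'
#' @param first,second Integer state indices (1..12) of the two halves;
#'   vectors are accepted elementwise.
#' @return A data frame with columns `active` and `silent`.
#' @examples
#' mark_counts(1, 1)    # fully active: 4 active, 0 silent
#' mark_counts(11, 11)  # fully silent: 0 active, 4 silent
#' @export
mark_counts <- function(first, second) {
  first <- check_state_index(first)
  second <- check_state_index(second)
  data.frame(
    active = .HALF_ACTIVE[first] + .HALF_ACTIVE[second],
    silent = .HALF_SILENT[first] + .HALF_SILENT[second]
  )
}

#' Classify a whole nucleosome into one of six categories
#'
#' Categories follow the proportion of silent among all marks carried:
#' \describe{
#'   \item{1}{active only (no silent marks, at least one active mark)}
#'   \item{2}{active bivalent (mixed, silent fraction < 1/2)}
#'   \item{3}{balanced bivalent (mixed, silent fraction = 1/2)}
#'   \item{4}{silent bivalent (mixed, silent fraction > 1/2)}
#'   \item{5}{silent only}
#'   \item{6}{unmodified}
#' }
#' Bivalent nucleosomes are those in categories 2-4: they carry at least one
#' active and at least one silent mark, on the same or different halves.
#'
#' @inheritParams mark_counts
#' @return Integer vector of categories in 1..6.
#' @examples
#' classify_category(8, 8)   # 6, unmodified
#' classify_category(1, 11)  # 3, balanced bivalent
#' @export
classify_category <- function(first, second) {
  mc <- mark_counts(first, second)
  a <- mc$active
  s <- mc$silent
  out <- integer(length(a))
  out[a == 0 & s == 0] <- 6L
  out[a > 0 & s == 0] <- 1L
  out[a == 0 & s > 0] <- 5L
  mixed <- a > 0 & s > 0
  frac <- s[mixed] / (a[mixed] + s[mixed])
  out[mixed] <- ifelse(frac < 0.5, 2L, ifelse(frac > 0.5, 4L, 3L))
  out
}

# 12 x 12 lookup: category of the ordered whole-nucleosome state (i, j).
.CAT144 <- matrix(
  classify_category(rep(1:12, times = 12), rep(1:12, each = 12)),
  nrow = 12
)

#' Enumerate the 144 ordered whole-nucleosome states
#'
#' @return Data frame with columns `first`, `second`, `category`, `active`,
#'   `silent`, one row per ordered pair of half-nucleosome states.
#' @export
enumerate_whole_states <- function() {
  grid <- expand.grid(first = 1:12, second = 1:12)
  mc <- mark_counts(grid$first, grid$second)
  data.frame(
    first = grid$first,
    second = grid$second,
    category = classify_category(grid$first, grid$second),
    active = mc$active,
    silent = mc$silent
  )
}

#' Count whole-nucleosome forms per category
#'
#' Over the 144 ordered pairs the classification yields 15 active-only forms,
#' 15 silent-only forms, 1 unmodified form and 113 bivalent forms (categories
#' 2-4 together).
#'
#' @return Named integer vector of length 6 (names `"1"`..`"6"`), summing to
#'   144.
#' @export
count_category_forms <- function() {
  counts <- table(factor(enumerate_whole_states()$category, levels = 1:6))
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}
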