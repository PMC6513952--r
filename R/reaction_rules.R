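# Recruited enzyme complexes and direct conversion channels.
#
# Seven read-write or read-erase complexes act through recruitment: a complex
# reads marks on one half-nucleosome and writes to (or erases from) another.
# Compound complexes (e.g. PRC2:KDM:NURD) are recruited through the reader
# subunit but only the last-listed enzyme is catalytic. Three further channels
# act without recruitment: a generic conversion channel (rate `beta`), direct
# NURD deacetylation and direct PR-DUB deubiquitination.

#' The seven recruited enzyme complexes
#'
#' @return Character vector of complex names in their fixed internal order:
#'   `TRXG` (H3K4/36 methyltransferase), `TRXG_UTX` (H3K27me3 demethylase),
#'   `TRXG_CBP` (H3K27 acetyltransferase), `PRC1` (H2A ubiquitin ligase),
#'   `PRC2` (H3K27 methyltransferase), `PRC2_KDM` (H3K4/36 demethylase) and
#'   `PRC2_KDM_NURD` (H3K27 deacetylase).
#' @export
enzymes <- function() .ENZYMES

.ENZYMES <- c("TRXG", "TRXG_UTX", "TRXG_CBP", "PRC1", "PRC2",
              "PRC2_KDM", "PRC2_KDM_NURD")

# Recruiter sets. Encoded constraints:
#  * TRXG is recruited via H3K27ac (states 1-4) but not by H2Aub-bearing
#    states 2,3 (H2Aub inhibits the K36 methyltransferase) and not by
#    H3K27me3 states.
#  * TRXG_UTX and TRXG_CBP are compounds whose catalytic subunit is not
#    blocked by H2Aub, so all of 1-4 recruit them; TRXG_CBP is additionally
#    recruited via H3K4me (states 1,2,5,6) but not by 9,10 (these recruit
#    PRC1, which inhibits CBP).
#  * PRC1 is recruited via H3K27me3 (states 9-12).
#  * PRC2 is recruited via H3K27me3 (11,12) and H2Aub (3,7,11); states 9,10
#    carry H3K4/36me which inhibits PRC2 catalysis, so functional PRC2 is not
#    recruited there.
#  * PRC2_KDM and PRC2_KDM_NURD bind via H3K27me3 or H2Aub to every state
#    carrying either mark (2,3,6,7,9-12); their catalytic subunits are not
#    inhibited by H3K4/36me.
#  * State 8 (unmodified) recruits nothing.
.RECRUITERS <- list(
  TRXG          = c(1L, 4L),
  TRXG_UTX      = c(1L, 2L, 3L, 4L),
  TRXG_CBP      = c(1L, 2L, 3L, 4L, 5L, 6L),
  PRC1          = c(9L, 10L, 11L, 12L),
  PRC2          = c(3L, 7L, 11L, 12L),
  PRC2_KDM      = c(2L, 3L, 6L, 7L, 9L, 10L, 11L, 12L),
  PRC2_KDM_NURD = c(2L, 3L, 6L, 7L, 9L, 10L, 11L, 12L)
)

#' Complexes recruited by a half-nucleosome state
#'
#' @param state Integer state index in 1..12.
#' @return Character vector of recruited complex names (possibly empty; state
#'   8 recruits nothing).
#' @examples
#' recruited_complexes(12)
#' recruited_complexes(8)
#' @export
recruited_complexes <- function(state) {
  state <- check_state_index(state)
  if (length(state) != 1L) stop("'state' must be a single index", call. = FALSE)
  .ENZYMES[vapply(.ENZYMES, function(e) state %in% .RECRUITERS[[e]], logical(1))]
}

# Action table: new state per (enzyme, target state); NA = no-op. Inhibition
# rules are baked in:
#  * TRXG writes K4/36me only on targets without H2Aub (H2Aub inhibits it);
#    H3K27me3 alone does not block writing (12 -> 9).
#  * PRC2 writes K27me3 only on targets without K4/36me and without K27ac.
#  * Adders are no-ops when the mark is present; erasers when absent.
# The transitions 3->2, 7->6, 11->10 (K4/36me onto H2Aub targets) and 5->9,
# 6->10 (K27me3 onto K4/36me targets) are therefore reachable only through
# the recruitment-independent beta channel.
.ACTIONS <- {
  m <- matrix(NA_integer_, nrow = 7, ncol = 12,
              dimnames = list(.ENZYMES, NULL))
  m["TRXG", c(4, 8, 12)] <- c(1L, 5L, 9L)
  m["TRXG_UTX", 9:12] <- c(5L, 6L, 7L, 8L)
  m["TRXG_CBP", 5:8] <- c(1L, 2L, 3L, 4L)
  m["PRC1", c(1, 4, 5, 8, 9, 12)] <- c(2L, 3L, 6L, 7L, 10L, 11L)
  m["PRC2", c(7, 8)] <- c(11L, 12L)
  m["PRC2_KDM", c(1, 2, 5, 6, 9, 10)] <- c(4L, 3L, 8L, 7L, 12L, 11L)
  m["PRC2_KDM_NURD", 1:4] <- c(5L, 6L, 7L, 8L)
  m
}

#' Apply a recruited enzyme to a target half-nucleosome
#'
#' @param enzyme Complex name, see [enzymes()].
#' @param target Integer state index of the target half in 1..12.
#' @return The new state index, or `NA` if the enzyme cannot change this
#'   target (a no-op, not an error).
#' @examples
#' apply_enzyme("TRXG", 12)  # 9: K27me3 does not block TRXG writing
#' apply_enzyme("TRXG", 7)   # NA: H2Aub inhibits TRXG
#' @export
apply_enzyme <- function(enzyme, target) {
  enzyme <- match.arg(enzyme, .ENZYMES)
  target <- check_state_index(target)
  unname(.ACTIONS[enzyme, target])
}

#' Recruitment-independent (beta) conversion of one site
#'
#' Models all histone-modification-independent conversions (non-specific DNA
#' binding, turnover, remodelling) lumped into a single rate. One of the three
#' sites of a half-nucleosome is altered: the K4/36 and H2A sites toggle;
#' H3K27 loses an existing ac/me3 mark, and an unmodified K27 gains ac or me3
#' with equal probability (`u < 0.5` gives ac).
#'
#' @param state Integer state index in 1..12.
#' @param site One of `"K27"`, `"K436"`, `"H2A"`.
#' @param u Uniform variate in `[0, 1)`; only consulted for an unmodified K27.
#' @return The new state index (always a change).
#' @export
direct_conversion <- function(state, site = c("K27", "K436", "H2A"), u = 0.5) {
  state <- check_state_index(state)
  site <- match.arg(site)
  f <- .HALF_STATES[state, ]
  if (site == "K27") {
    f$k27 <- if (f$k27 == "none") (if (u < 0.5) "ac" else "me3") else "none"
  } else if (site == "K436") {
    f$k436 <- if (f$k436 == "me") "none" else "me"
  } else {
    f$h2a <- if (f$h2a == "ub") "none" else "ub"
  }
  half_state_index(f$k27, f$k436, f$h2a)
}

#' Direct (non-recruited) NURD deacetylation
#'
#' @param state Integer state index in 1..12.
#' @return New state with H3K27ac removed, or `NA` if the state carries no
#'   acetyl mark (no-op).
#' @export
direct_nurd <- function(state) {
  state <- check_state_index(state)
  unname(.DIRECT_NURD[state])
}

.DIRECT_NURD <- c(5L, 6L, 7L, 8L, rep(NA_integer_, 8))

#' Direct (non-recruited) PR-DUB deubiquitination
#'
#' @param state Integer state index in 1..12.
#' @return New state with H2Aub removed, or `NA` if the state carries no
#'   ubiquitin mark (no-op).
#' @export
direct_prdub <- function(state) {
  state <- check_state_index(state)
  unname(.DIRECT_PRDUB[state])
}

.DIRECT_PRDUB <- c(NA, 1L, 4L, NA, NA, 5L, 8L, NA, NA, 9L, 12L, NA)

#' Tables of recruiters and enzyme actions
#'
#' @return A list with elements `recruiters` (data frame: `enzyme`,
#'   `recruiter_states` as comma-separated indices) and `actions` (data
#'   frame: `enzyme`, `from_state`, `to_state`), suitable for auditing or TSV
#'   export.
#' @export
rule_tables <- function() {
  recruiters <- data.frame(
    enzyme = .ENZYMES,
    recruiter_states = vapply(.ENZYMES, function(e)
      paste(.RECRUITERS[[e]], collapse = ","), character(1)),
    row.names = NULL
  )
  idx <- which(!is.na(.ACTIONS), arr.ind = TRUE)
  actions <- data.frame(
    enzyme = .ENZYMES[idx[, 1]],
    from_state = as.integer(idx[, 2]),
    to_state = .ACTIONS[idx]
  )
  actions <- actions[order(match(actions$enzyme, .ENZYMES), actions$from_state), ]
  row.names(actions) <- NULL
  list(recruiters = recruiters, actions = actions)
}
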