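# Selection criteria: plain genomic selection on the total predicted
# breeding value, and OSGS on a weighted rank index of the two
# origin-specific components.

new_selection_index <- function(bv, method, omega, ebv) {
  out <- tibble::tibble(
    line = bv$line, method = method, omega = omega,
    ebv = ebv, a_hat = bv$a_hat
  )
  class(out) <- c("selection_index", class(out))
  out
}

#' Genomic selection index
#'
#' The GS criterion is simply the total predicted breeding value: lines
#' with the largest `a_hat` are selected. For a trait whose favorable
#' direction is "lower" the criterion is negated so that a larger `ebv`
#' is always better.
#'
#' @param bv A [predict_breeding_values()] result.
#' @return A tibble of class `selection_index` with columns `line`,
#'   `method`, `omega` (`NA` for GS), `ebv` and `a_hat`.
#' @export
gs_index <- function(bv) {
  sgn <- if (favorable_direction_of(bv) == "lower") -1 else 1
  new_selection_index(bv, "GS", NA_real_, sgn * bv$a_hat)
}

#' OSGS weighted rank index
#'
#' Ranks the primary and secondary breeding-value components so that the
#' most favorable value gets the highest rank (ascending ranks, average
#' ranks on ties) and combines them as
#' `ebv = rank(a1_hat) * omega + rank(a2_hat) * (1 - omega)`.
#' `omega = 1` reproduces ordering on the primary component alone and
#' `omega = 0` on the secondary component alone; because only ranks enter,
#' the index is invariant to strictly increasing transforms of either
#' component.
#'
#' @param bv A [predict_breeding_values()] result.
#' @param omega Selection weight on the primary-parent component, in
#'   `[0, 1]`.
#' @return A tibble of class `selection_index`; `ebv` lies in
#'   `[1, n_lines]`.
#' @export
osgs_index <- function(bv, omega) {
  if (!is.numeric(omega) || length(omega) != 1 || is.na(omega) ||
      omega < 0 || omega > 1) {
    abort("omega must be a single number in [0, 1]")
  }
  sgn <- if (favorable_direction_of(bv) == "lower") -1 else 1
  r1 <- rank(sgn * bv$a1_hat, ties.method = "average")
  r2 <- rank(sgn * bv$a2_hat, ties.method = "average")
  new_selection_index(bv, "OSGS", omega, r1 * omega + r2 * (1 - omega))
}

#' Select the top lines of a selection index
#'
#' Picks the `k` lines with the largest criterion value. Ties at the cutoff
#' are broken by larger total predicted breeding value, then by input
#' order, so repeated calls are deterministic.
#'
#' @param index A [gs_index()] or [osgs_index()] result.
#' @param k Number of lines to keep (`1 <= k <= n`).
#' @return A tibble with columns `line`, `ebv`, `a_hat` and `rank`
#'   (1 = best), in selection order.
#' @export
select_top <- function(index, k) {
  n <- nrow(index)
  if (k < 1 || k > n) abort("k must be between 1 and the number of lines")
  ord <- order(-index$ebv, -index$a_hat, seq_len(n))[seq_len(k)]
  out <- index[ord, c("line", "ebv", "a_hat")]
  out$rank <- seq_len(k)
  tibble::as_tibble(out)
}

#' Half-diallel crosses
#'
#' All unordered pairs among a set of parents: `k(k-1)/2` crosses, no
#' selfs, no reciprocals.
#'
#' @param parents Character vector of at least two distinct line ids.
#' @return A tibble with columns `parent1`, `parent2`.
#' @export
#' @examples
#' half_diallel(c("A", "B", "C", "D"))  # 6 crosses
half_diallel <- function(parents) {
  parents <- as.character(parents)
  if (length(parents) < 2) abort("need at least two parents")
  if (anyDuplicated(parents)) abort("duplicate parent identifiers")
  prs <- combn(parents, 2)
  tibble::tibble(parent1 = prs[1, ], parent2 = prs[2, ])
}
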