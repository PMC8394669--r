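#' Diagonal run-length measures and block invariant
#'
#' For every diagonal index n of a banded binary recurrence matrix, computes
#' the three run-length measures and the block invariant:
#' \itemize{
#'   \item `t_block` (block time): length of the maximal vertical run of 1s in
#'     column n containing the diagonal entry — the apparent trapping
#'     duration seen from frame n;
#'   \item `t_perp` (neighbouring time): length of the maximal anti-diagonal
#'     run of 1s through (n, n) — the width of the colocalizing window around
#'     frame n;
#'   \item `t_par` (persistence time): length of the maximal run of 1s
#'     parallel to the main diagonal through the lower-left extremity of the
#'     anti-diagonal run — how long colocalization persists;
#'   \item `nu = t_block / (t_par + t_perp - 1)`: equals 1 at every point of
#'     an ideal block and collapses towards 1/N on free stretches.
#' }
#' All runs truncate at matrix borders. Both extremities of the anti-diagonal
#' run give the same persistence time on a symmetric matrix; the lower-left
#' one is used.
#'
#' @param B a `"binary_recurrence"` whose diagonal is all ones (guaranteed
#'   after [add_diagonal_bands()]).
#' @return a data frame with columns `frame`, `t_block`, `t_perp`, `t_par`,
#'   `nu` (one row per diagonal index).
#' @export
diagonal_measures <- function(B) {
  stopifnot(inherits(B, "binary_recurrence"))
  V <- B$values
  if (any(diag(V) != 1L)) {
    stop("diagonal entries must all be 1; add the diagonal band first")
  }
  m <- cpp_diagonal_measures(V)
  data.frame(frame = seq_len(nrow(V)),
             t_block = m$t_block, t_perp = m$t_perp, t_par = m$t_par,
             nu = m$t_block / (m$t_par + m$t_perp - 1))
}

#' Block times of an (unbanded) binary recurrence matrix
#'
#' Vertical run length of 1s through each diagonal entry; 0 where the
#' diagonal entry itself is 0 (possible before the diagonal band is added).
#' Used by the band-count calibration.
#'
#' @param B a `"binary_recurrence"`.
#' @return integer vector of length N.
#' @export
block_times <- function(B) {
  stopifnot(inherits(B, "binary_recurrence"))
  cpp_diagonal_measures(B$values)$t_block
}

#' Extract candidate trapped blocks from the invariant profile
#'
#' A frame is inside a candidate block when its invariant `nu` is strictly
#' larger than the critical value `nu_c`; blocks are the maximal runs of such
#' frames.
#'
#' @param measures data frame from [diagonal_measures()] (needs a `nu`
#'   column).
#' @param nu_c critical invariant value; default 3/4 tolerates moderately
#'   deformed blocks.
#' @return data frame with columns `start`, `end` (1-based, inclusive),
#'   `size`.
#' @export
candidate_blocks <- function(measures, nu_c = 0.75) {
  nu <- measures$nu
  stopifnot(is.numeric(nu), length(nu) >= 1L)
  r <- rle(nu > nu_c)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             size = r$lengths[keep])
}

#' Filter candidate blocks by minimal significant size
#'
#' Keeps exactly the blocks whose size reaches `min_block`, the minimal block
#' size that is statistically incompatible with free motion at the chosen
#' p-value (see [calibrate_null_blocks()] and [min_block_size()]).
#'
#' @param blocks data frame from [candidate_blocks()].
#' @param min_block integer >= 1.
#' @return the filtered data frame.
#' @export
filter_blocks <- function(blocks, min_block) {
  min_block <- as.integer(min_block)
  if (min_block < 1L) stop("min_block must be >= 1")
  blocks[blocks$size >= min_block, , drop = FALSE]
}
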