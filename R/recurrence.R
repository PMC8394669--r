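#' Gaussian-weight recurrence matrix of a trajectory
#'
#' Entry (i, j) is `exp(-(|x_i - x_j| / lambda)^2 / 2)`, with `|.|` the
#' Euclidean distance in 2 or 3 dimensions. Values are in (0, 1], close to 1
#' when the two positions colocalize within the test lengthscale `lambda` and
#' decaying fast beyond it. A trapped stretch of the trajectory of size about
#' `lambda` appears as a square block of near-one entries on the diagonal.
#'
#' @param traj a [trajectory]; standardize first (see [standardize()]) for
#'   scale-free analysis.
#' @param lambda test lengthscale, in the trajectory's length units
#'   (standardized units after [standardize()]); must be positive.
#' @return an object of class `"recurrence_matrix"`: list with `values`
#'   (N x N symmetric numeric matrix, unit diagonal), `lambda`, `mu`
#'   (smoothing half-width applied so far, 0 here).
#' @export
recurrence_matrix <- function(traj, lambda) {
  stopifnot(inherits(traj, "trajectory"))
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0) {
    stop("lambda must be a positive number")
  }
  M <- cpp_gauss_recurrence(traj$positions, lambda)
  structure(list(values = M, lambda = lambda, mu = 0L),
            class = "recurrence_matrix")
}

# cache of kernel/normalization FFTs keyed by (N, mu): smoothing is called
# thousands of times on same-sized matrices during calibration
.smooth_cache <- new.env(parent = emptyenv())

#' Box-smooth a recurrence matrix
#'
#' Replaces each entry by the mean over a (2*mu+1) x (2*mu+1) window. Near
#' the borders the mean is taken over the in-bounds window cells only
#' (edge-corrected normalization), so values near trajectory endpoints are
#' not artificially suppressed. Smoothing damps the frame-to-frame noise of
#' the recurrence matrix and removes the effect of isolated outlier
#' positions inside a trapped block.
#'
#' Two numerically equivalent engines are provided: `"box"` (summed-area
#' table, exact windowed mean in O(N^2), the default) and `"fft"`
#' (convolution through the fast Fourier transform). They agree to well
#' below 1e-10 and with direct windowed averaging.
#'
#' @param M a `"recurrence_matrix"`.
#' @param mu smoothing half-width (non-negative integer); the window is
#'   (2*mu+1) square and must not exceed the matrix size.
#' @param method smoothing engine, `"box"` or `"fft"`.
#' @return a smoothed `"recurrence_matrix"` (exactly symmetric).
#' @export
smooth_recurrence <- function(M, mu, method = c("box", "fft")) {
  stopifnot(inherits(M, "recurrence_matrix"))
  method <- match.arg(method)
  mu <- as.integer(mu)
  if (mu < 0L) stop("mu must be >= 0")
  n <- nrow(M$values)
  if (2L * mu + 1L > n) stop("smoothing window (2*mu+1) exceeds matrix size")
  if (mu == 0L) {
    M$mu <- 0L
    return(M)
  }
  S <- if (method == "fft") box_smooth_fft(M$values, mu) else
    box_smooth_sat(M$values, mu)
  S <- (S + t(S)) / 2            # kill FFT round-off asymmetry
  S <- pmin(pmax(S, 0), 1)
  structure(list(values = S, lambda = M$lambda, mu = mu),
            class = "recurrence_matrix")
}

box_smooth_fft <- function(A, mu) {
  n <- nrow(A)
  k <- 2L * mu + 1L
  p <- nextn(n + k - 1L, c(2, 3, 5))
  key <- paste(n, mu, p, sep = "|")
  cached <- .smooth_cache[[key]]
  if (is.null(cached)) {
    ker <- matrix(0, p, p)
    ker[1:k, 1:k] <- 1
    fker <- fft(ker)
    ones <- matrix(0, p, p)
    ones[1:n, 1:n] <- 1
    counts <- Re(fft(fft(ones) * fker, inverse = TRUE)) / p^2
    counts <- counts[(mu + 1L):(mu + n), (mu + 1L):(mu + n)]
    counts <- round(counts)      # exact in-window cell counts
    cached <- list(fker = fker, counts = counts)
    .smooth_cache[[key]] <- cached
  }
  pad <- matrix(0, p, p)
  pad[1:n, 1:n] <- A
  conv <- Re(fft(fft(pad) * cached$fker, inverse = TRUE)) / p^2
  conv[(mu + 1L):(mu + n), (mu + 1L):(mu + n)] / cached$counts
}

# exact windowed mean via running sums (C++)
box_smooth_sat <- function(A, mu) cpp_box_smooth(A, mu)

# reference implementation used by the engine-equality contract tests
box_smooth_direct <- function(A, mu) {
  n <- nrow(A)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      ri <- max(1L, i - mu):min(n, i + mu)
      rj <- max(1L, j - mu):min(n, j + mu)
      S[i, j] <- mean(A[ri, rj, drop = FALSE])
    }
  }
  S
}

#' Threshold a smoothed recurrence matrix into a binary matrix
#'
#' Sets to 1 every value strictly larger than the critical value `pc`. With
#' the default `pc = exp(-1)`, two (unsmoothed) positions are considered
#' colocalizing when they are within `lambda * sqrt(2)` of each other.
#'
#' @param M a (smoothed) `"recurrence_matrix"`.
#' @param pc critical value in (0, 1); default `exp(-1)`.
#' @return an object of class `"binary_recurrence"`: list with integer 0/1
#'   `values`, `lambda`, `mu`, `n_d` (diagonal band half-width added so far,
#'   0 here).
#' @export
threshold_recurrence <- function(M, pc = exp(-1)) {
  stopifnot(inherits(M, "recurrence_matrix"))
  if (!is.numeric(pc) || length(pc) != 1L || pc <= 0 || pc >= 1) {
    stop("pc must be in (0, 1)")
  }
  B <- M$values > pc
  storage.mode(B) <- "integer"
  structure(list(values = B, lambda = M$lambda, mu = M$mu, n_d = 0L),
            class = "binary_recurrence")
}

#' Fill lacunarities (enclosed holes) in a binary recurrence matrix
#'
#' Random excursions of a trapped particle punch 0-holes inside diagonal
#' blocks; every 0-region (4-connected) not reachable from the matrix border
#' is set to 1. Entries equal to 1 never change.
#'
#' @param B a `"binary_recurrence"`.
#' @return a `"binary_recurrence"` with holes filled.
#' @export
fill_lacunarities <- function(B) {
  stopifnot(inherits(B, "binary_recurrence"))
  B$values <- cpp_fill_holes(B$values)
  B
}

#' Add diagonal bands to a binary recurrence matrix
#'
#' Sets to 1 every entry with |i - j| <= n_d. For ideal free motion the
#' banded matrix is (2*n_d+1)-diagonal, so the persistence time of free
#' points spans nearly the whole trajectory and the block invariant collapses
#' towards 0 outside real blocks, sharpening block transitions.
#'
#' @param B a `"binary_recurrence"`.
#' @param n_d band half-width (non-negative integer), typically from
#'   [calibrate_band_count()].
#' @return a `"binary_recurrence"` with the band set and `n_d` recorded.
#' @export
add_diagonal_bands <- function(B, n_d) {
  stopifnot(inherits(B, "binary_recurrence"))
  n_d <- as.integer(n_d)
  if (n_d < 0L) stop("n_d must be >= 0")
  V <- B$values
  n <- nrow(V)
  for (d in 0:min(n_d, n - 1L)) {
    i <- seq_len(n - d)
    V[cbind(i + d, i)] <- 1L
    V[cbind(i, i + d)] <- 1L
  }
  B$values <- V
  B$n_d <- n_d
  B
}

#' Run the matrix pipeline from trajectory to banded binary matrix
#'
#' Convenience wrapper applying, in order: [recurrence_matrix()],
#' [smooth_recurrence()], [threshold_recurrence()], [fill_lacunarities()]
#' and (when `n_d` is not `NULL`) [add_diagonal_bands()].
#'
#' @param traj a standardized [trajectory].
#' @param lambda test lengthscale.
#' @param mu smoothing half-width.
#' @param n_d diagonal band half-width, or `NULL` to stop before banding.
#' @param pc threshold critical value.
#' @return a `"binary_recurrence"`.
#' @export
binary_recurrence_pipeline <- function(traj, lambda, mu = 2L, n_d = NULL,
                                       pc = exp(-1)) {
  B <- threshold_recurrence(smooth_recurrence(recurrence_matrix(traj, lambda),
                                              mu), pc)
  B <- fill_lacunarities(B)
  if (!is.null(n_d)) B <- add_diagonal_bands(B, n_d)
  B
}
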