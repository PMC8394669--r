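#' Geometry of a trapped trajectory portion
#'
#' The trap centre is estimated as the coordinate-wise median of the trapped
#' portion; the trap radius as the nearest-rank 95th percentile of the
#' Euclidean distances to that centre — the distance of the point further
#' away than 95% of the portion's points, which ignores isolated outliers.
#'
#' @param traj a [trajectory].
#' @param block one-row data frame (or list) with `start` and `end` frame
#'   indices (1-based, inclusive); at least 2 frames.
#' @return a list with `centre`, `radius`, `duration`, `block`.
#' @export
trap_geometry <- function(traj, block) {
  stopifnot(inherits(traj, "trajectory"))
  start <- as.integer(block$start[1])
  end <- as.integer(block$end[1])
  n <- n_frames(traj)
  if (start < 1L || end > n || start > end) stop("block outside trajectory")
  if (end - start + 1L < 2L) stop("block must span at least 2 frames")
  pts <- traj$positions[start:end, , drop = FALSE]
  centre <- apply(pts, 2, median)
  d <- sqrt(rowSums(sweep(pts, 2, centre)^2))
  radius <- nearest_rank_quantile(d, 0.95)
  list(centre = centre, radius = radius, duration = end - start + 1L,
       block = data.frame(start = start, end = end,
                          size = end - start + 1L))
}

#' Time-averaged mean squared displacement (TAMSD)
#'
#' For each lag n, the time average of the squared displacement over all
#' start frames, computed per coordinate and summed over coordinates:
#' `delta2(n) = 1/(N-n) * sum_k |x_{k+n} - x_k|^2`.
#'
#' @param x a [trajectory] or an N x dim numeric position matrix.
#' @param max_lag largest lag (frames); must be < N.
#' @return numeric vector `delta2` of length `max_lag` (lags 1..max_lag).
#' @export
tamsd <- function(x, max_lag) {
  pos <- if (inherits(x, "trajectory")) x$positions else as.matrix(x)
  n <- nrow(pos)
  max_lag <- as.integer(max_lag)
  if (max_lag >= n) stop("max_lag must be smaller than the portion length")
  if (max_lag < 1L) stop("max_lag must be >= 1")
  vapply(seq_len(max_lag), function(lag) {
    d <- pos[(1L + lag):n, , drop = FALSE] - pos[1L:(n - lag), , drop = FALSE]
    mean(rowSums(d^2))
  }, numeric(1))
}

#' Fit the anomalous-diffusion TAMSD model
#'
#' Nonlinear least-squares fit of `delta2(n) = 2*dim*D_alpha*t^alpha +
#' 2*dim*sigma_err^2` (for 2D: `4 D_alpha n^alpha + 4 sigma_err^2`) to the
#' TAMSD over a short lag range, with positivity constraints and multi-start
#' over alpha to avoid the local minima of ill-conditioned 3-parameter
#' power-law fits. Lags are converted to seconds via `frame_interval`, so
#' `D_alpha` carries units length^2 / time^alpha.
#'
#' @param delta2 TAMSD values at lags `1:length(delta2)` (frames), e.g. from
#'   [tamsd()].
#' @param lag_range integer pair, fitted lag window (default `c(1, 5)`); at
#'   least 3 lags.
#' @param frame_interval frame interval in seconds.
#' @param dim trajectory dimension (sets the 2*dim prefactor; default 2).
#' @return a list of class `"tamsd_fit"`: `D_alpha`, `alpha`, `sigma_err`,
#'   `converged`, `rss`; non-convergence is flagged, not raised.
#' @export
fit_tamsd <- function(delta2, lag_range = c(1, 5), frame_interval = 1,
                      dim = 2) {
  lags <- lag_range[1]:lag_range[2]
  if (length(lags) < 3L) stop("need at least 3 lags to fit 3 parameters")
  if (max(lags) > length(delta2)) stop("lag_range exceeds available lags")
  y <- delta2[lags]
  t <- lags * frame_interval
  pref <- 2 * dim
  best <- NULL
  for (a0 in c(0.5, 1.0, 1.5)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ pref * D * t^alpha + pref * s2,
        start = list(D = max(y[1], 1e-8) / pref, alpha = a0, s2 = 0),
        lower = c(D = 1e-12, alpha = 1e-6, s2 = 0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(residuals(fit)^2)
      if (is.null(best) || rss < best$rss) {
        best <- list(fit = fit, rss = rss)
      }
    }
  }
  if (is.null(best)) {
    return(structure(list(D_alpha = NA_real_, alpha = NA_real_,
                          sigma_err = NA_real_, converged = FALSE,
                          rss = NA_real_),
                     class = "tamsd_fit"))
  }
  p <- coef(best$fit)
  structure(list(D_alpha = unname(p["D"]), alpha = unname(p["alpha"]),
                 sigma_err = sqrt(unname(p["s2"])), converged = TRUE,
                 rss = best$rss),
            class = "tamsd_fit")
}

#' @export
print.tamsd_fit <- function(x, ...) {
  cat(sprintf("<tamsd_fit: D_alpha=%.4g, alpha=%.3f, sigma_err=%.4g%s>\n",
              x$D_alpha, x$alpha, x$sigma_err,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Free trajectory portions of a segmentation
#'
#' Maximal runs of frames labelled free, returned as position matrices;
#' portions shorter than `min_length` frames are dropped (short portions
#' give unreliable TAMSD fits).
#'
#' @param traj the segmented [trajectory].
#' @param segmentation its `"trap_segmentation"`.
#' @param min_length minimal portion length in frames.
#' @return list of numeric position matrices.
#' @export
free_portions <- function(traj, segmentation, min_length = 50) {
  stopifnot(inherits(traj, "trajectory"),
            inherits(segmentation, "trap_segmentation"))
  labels <- segmentation$labels
  if (length(labels) != n_frames(traj)) {
    stop("segmentation does not match trajectory length")
  }
  r <- rle(labels == "free")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_length)
  lapply(keep, function(k) {
    traj$positions[starts[k]:ends[k], , drop = FALSE]
  })
}

#' Fraction of trapped frames per group of trajectories
#'
#' Pools all trajectories of each group (e.g. all trajectories of one cell)
#' and reports total trapped frames over total frames.
#'
#' @param results list of `"trap_segmentation"` objects.
#' @param grouping character/factor vector, one group per result (recycled
#'   to a single group when omitted).
#' @return data frame with `group`, `fraction_trapped`, `n_frames`.
#' @export
fraction_trapped <- function(results, grouping = NULL) {
  if (inherits(results, "trap_segmentation")) results <- list(results)
  if (is.null(grouping)) grouping <- rep("all", length(results))
  if (length(grouping) != length(results)) {
    stop("grouping must have one entry per segmentation")
  }
  groups <- unique(as.character(grouping))
  out <- do.call(rbind, lapply(groups, function(g) {
    sel <- results[as.character(grouping) == g]
    total <- sum(vapply(sel, function(s) length(s$labels), numeric(1)))
    if (total == 0) {
      warning("group '", g, "' has no frames; excluded")
      return(NULL)
    }
    trapped <- sum(vapply(sel, function(s) sum(s$labels == "trapped"),
                          numeric(1)))
    data.frame(group = g, fraction_trapped = trapped / total,
               n_frames = total)
  }))
  out
}
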