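# Reference-motion simulation shared by both calibration stages
simulate_reference <- function(model, dim, n_steps, hurst = 0.35) {
  if (model == "bm") simulate_bm(n_steps, dim) else
    simulate_fbm(n_steps, dim, hurst = hurst)
}

#' Calibrate the diagonal band count n_d
#'
#' Simulates free reference motion (Brownian or subdiffusive fractional
#' Brownian), runs the matrix pipeline through lacunarity filling (no
#' banding), pools the block times of all frames of all trajectories and
#' returns their 10th percentile (nearest rank) as the number of diagonal
#' lines to add on each side of the diagonal — a compromise between
#' sensitivity (separating nearby traps) and change-point precision.
#'
#' @param model reference free motion, `"bm"` or `"fbm"`.
#' @param dim 2 or 3.
#' @param lambda test lengthscale (standardized units).
#' @param mu smoothing half-width.
#' @param n_traj number of reference trajectories.
#' @param n_steps steps per trajectory.
#' @param hurst Hurst exponent for the fbm reference.
#' @param pool `"all"` pools the block time of every frame (0 where the
#'   diagonal entry is 0); `"positive"` pools only frames whose diagonal
#'   entry survives thresholding. See the methods vignette for why
#'   `"positive"` is the default.
#' @param seed optional integer seed.
#' @return integer band half-width `n_d`.
#' @export
calibrate_band_count <- function(model = c("bm", "fbm"), dim = 2, lambda,
                                 mu = 2, n_traj = 1000, n_steps = 2000,
                                 hurst = 0.35, pool = c("positive", "all"),
                                 seed = NULL) {
  model <- match.arg(model)
  pool <- match.arg(pool)
  with_seed(seed, {
    pooled <- vector("list", n_traj)
    for (i in seq_len(n_traj)) {
      tr <- standardize(simulate_reference(model, dim, n_steps, hurst))
      B <- binary_recurrence_pipeline(tr, lambda, mu, n_d = NULL)
      pooled[[i]] <- block_times(B)
    }
    tb <- unlist(pooled)
    if (pool == "positive") tb <- tb[tb > 0L]
    if (length(tb) == 0L) return(0L)
    as.integer(nearest_rank_quantile(tb, 0.10))
  })
}

#' Calibrate the null distribution of candidate block sizes
#'
#' Even purely free motion produces candidate blocks, because escaping a
#' region of size lambda takes a random finite time. This routine simulates
#' free reference trajectories, runs the full detection pipeline (including
#' banding with the calibrated `n_d`), collects the sizes of all runs with
#' `nu > nu_c`, and returns their empirical cumulative distribution, from
#' which [min_block_size()] derives the minimal significant block size.
#'
#' @inheritParams calibrate_band_count
#' @param n_d diagonal band half-width from [calibrate_band_count()].
#' @param nu_c critical invariant value.
#' @return an object of class `"block_ecdf"`: list with sorted unique
#'   `sizes`, their cumulative probabilities `cumprob`, and the number of
#'   null blocks `n_blocks`.
#' @export
calibrate_null_blocks <- function(model = c("bm", "fbm"), dim = 2, lambda,
                                  mu = 2, n_d, n_traj = 1000, n_steps = 10000,
                                  nu_c = 0.75, hurst = 0.35, seed = NULL) {
  model <- match.arg(model)
  with_seed(seed, {
    sizes <- vector("list", n_traj)
    for (i in seq_len(n_traj)) {
      tr <- standardize(simulate_reference(model, dim, n_steps, hurst))
      B <- binary_recurrence_pipeline(tr, lambda, mu, n_d = n_d)
      sizes[[i]] <- candidate_blocks(diagonal_measures(B), nu_c)$size
    }
    block_ecdf(unlist(sizes))
  })
}

#' Build a block-size ECDF object
#'
#' @param sizes integer vector of observed null block sizes.
#' @return a `"block_ecdf"` object.
#' @export
block_ecdf <- function(sizes) {
  sizes <- as.integer(sizes)
  if (length(sizes) == 0L) {
    return(structure(list(sizes = integer(0), cumprob = numeric(0),
                          n_blocks = 0L), class = "block_ecdf"))
  }
  tab <- table(sizes)
  structure(list(sizes = as.integer(names(tab)),
                 cumprob = cumsum(as.numeric(tab)) / length(sizes),
                 n_blocks = length(sizes)),
            class = "block_ecdf")
}

#' Minimal significant block size at a given p-value
#'
#' Smallest block size s whose null cumulative probability reaches
#' `1 - p_value`: a detected block at least this large is rejected as
#' free-motion chance at level `p_value`.
#'
#' @param e a `"block_ecdf"` from [calibrate_null_blocks()].
#' @param p_value p-value in (0, 1).
#' @return integer minimal significant size (tau_pval).
#' @export
min_block_size <- function(e, p_value) {
  stopifnot(inherits(e, "block_ecdf"), p_value > 0, p_value < 1)
  if (e$n_blocks == 0L) stop("empty null block-size distribution")
  idx <- which(e$cumprob >= 1 - p_value)
  if (length(idx) == 0L) return(max(e$sizes) + 1L)
  e$sizes[idx[1]]
}

cal_key <- function(model, dim, lambda, mu) {
  paste(model, dim, format(lambda), mu, sep = "|")
}

#' Build a calibration table
#'
#' Runs both calibration stages for every combination of reference model,
#' dimension and test lengthscale and stores the band counts, null block
#' ECDFs and minimal significant sizes in one lookup table that detection
#' functions consume and that can be persisted as JSON.
#'
#' @param models character subset of `c("bm", "fbm")`.
#' @param dims integer subset of `c(2, 3)`.
#' @param lambdas numeric vector of test lengthscales.
#' @param mu smoothing half-width.
#' @param p_values p-values at which to pre-compute tau_pval.
#' @param n_traj_band,n_steps_band simulation size for the band-count stage.
#' @param n_traj_null,n_steps_null simulation size for the null-block stage.
#' @param nu_c critical invariant value.
#' @param hurst Hurst exponent of the fbm reference.
#' @param seed integer seed; each (model, dim, lambda) cell derives its own
#'   sub-seed so the table is reproducible and order-independent.
#' @return an object of class `"calibration_table"`.
#' @export
build_calibration <- function(models = "bm", dims = 2, lambdas = 1,
                              mu = 2, p_values = 0.05,
                              n_traj_band = 1000, n_steps_band = 2000,
                              n_traj_null = 1000, n_steps_null = 10000,
                              nu_c = 0.75, hurst = 0.35, seed = 1) {
  entries <- list()
  cells <- expand.grid(model = models, dim = dims, lambda = lambdas,
                       stringsAsFactors = FALSE)
  for (r in seq_len(nrow(cells))) {
    model <- cells$model[r]; dim <- cells$dim[r]; lambda <- cells$lambda[r]
    sub_seed <- (seed + 7919L * r) %% .Machine$integer.max
    n_d <- calibrate_band_count(model, dim, lambda, mu,
                                n_traj = n_traj_band, n_steps = n_steps_band,
                                hurst = hurst, seed = sub_seed)
    e <- calibrate_null_blocks(model, dim, lambda, mu, n_d = n_d,
                               n_traj = n_traj_null, n_steps = n_steps_null,
                               nu_c = nu_c, hurst = hurst, seed = sub_seed + 1L)
    tau <- vapply(p_values, function(p) min_block_size(e, p), integer(1))
    entries[[cal_key(model, dim, lambda, mu)]] <-
      list(model = model, dim = as.integer(dim), lambda = lambda,
           mu = as.integer(mu), n_d = n_d,
           ecdf_sizes = e$sizes, ecdf_cumprob = e$cumprob,
           n_blocks = e$n_blocks,
           tau_pval = as.list(stats::setNames(tau, format(p_values))))
  }
  structure(list(entries = entries,
                 metadata = list(n_traj_band = n_traj_band,
                                 n_steps_band = n_steps_band,
                                 n_traj_null = n_traj_null,
                                 n_steps_null = n_steps_null,
                                 nu_c = nu_c, hurst = hurst, seed = seed)),
            class = "calibration_table")
}

#' Look up a calibration entry
#'
#' @param table a `"calibration_table"`.
#' @param model,dim,lambda,mu calibration cell.
#' @return the entry (list with `n_d`, ECDF, `tau_pval`).
#' @export
cal_lookup <- function(table, model, dim, lambda, mu = 2) {
  stopifnot(inherits(table, "calibration_table"))
  entry <- table$entries[[cal_key(model, dim, lambda, mu)]]
  if (is.null(entry)) {
    stop(sprintf("no calibration for (%s, %dD, lambda=%s, mu=%d)",
                 model, dim, format(lambda), mu))
  }
  entry
}

#' @export
print.calibration_table <- function(x, ...) {
  cat(sprintf("<calibration_table: %d entries>\n", length(x$entries)))
  for (e in x$entries) {
    cat(sprintf("  %s %dD lambda=%s mu=%d: n_d=%d, %d null blocks, tau=%s\n",
                e$model, e$dim, format(e$lambda), e$mu, e$n_d, e$n_blocks,
                paste(sprintf("%s:%d", names(e$tau_pval),
                              unlist(e$tau_pval)), collapse = " ")))
  }
  invisible(x)
}

#' Persist a calibration table as JSON
#' @param table a `"calibration_table"`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(table, path) {
  stopifnot(inherits(table, "calibration_table"))
  jsonlite::write_json(unclass(table), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a calibration table from JSON
#' @param path JSON path written by [write_calibration()].
#' @return a `"calibration_table"`.
#' @export
read_calibration <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  entries <- lapply(raw$entries, function(e) {
    e$dim <- as.integer(e$dim)
    e$mu <- as.integer(e$mu)
    e$n_d <- as.integer(e$n_d)
    e$ecdf_sizes <- as.integer(e$ecdf_sizes)
    e$ecdf_cumprob <- as.numeric(e$ecdf_cumprob)
    e$n_blocks <- as.integer(e$n_blocks)
    e$tau_pval <- lapply(as.list(e$tau_pval), as.integer)
    e
  })
  structure(list(entries = entries, metadata = raw$metadata),
            class = "calibration_table")
}

# entry -> block_ecdf object
entry_ecdf <- function(entry) {
  structure(list(sizes = as.integer(entry$ecdf_sizes),
                 cumprob = as.numeric(entry$ecdf_cumprob),
                 n_blocks = as.integer(entry$n_blocks)),
            class = "block_ecdf")
}
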