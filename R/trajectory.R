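#' Construct a trajectory object
#'
#' A trajectory is an ordered set of N positions of one particle in 2 or 3
#' dimensions, with integer frame indices. Length units are arbitrary
#' (experimental data are typically in micrometres); frames are 1-based.
#'
#' @param positions numeric matrix, N rows by 2 or 3 columns.
#' @param id trajectory identifier (coerced to character).
#' @param frames integer vector of frame indices, strictly increasing;
#'   defaults to `1:N`.
#' @param frame_interval time between consecutive frames, in seconds.
#' @return an object of class `"trajectory"` with fields `id`, `dim`,
#'   `frames`, `positions`, `frame_interval`.
#' @examples
#' tr <- trajectory(cbind(rnorm(10), rnorm(10)), id = "a")
#' tr$dim
#' @export
trajectory <- function(positions, id = "traj", frames = NULL,
                       frame_interval = 1) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  n <- nrow(positions)
  d <- ncol(positions)
  if (n < 2L) stop("a trajectory needs at least 2 positions")
  if (!d %in% c(2L, 3L)) stop("dim must be 2 or 3")
  if (anyNA(positions)) stop("positions contain missing coordinates")
  if (is.null(frames)) frames <- seq_len(n)
  frames <- as.integer(frames)
  if (length(frames) != n) stop("frames and positions lengths differ")
  if (any(diff(frames) <= 0L)) stop("frames must be strictly increasing")
  structure(
    list(id = as.character(id), dim = d, frames = frames,
         positions = positions, frame_interval = as.numeric(frame_interval)),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory '%s': %d frames, %dD, frame interval %gs>\n",
              x$id, nrow(x$positions), x$dim, x$frame_interval))
  invisible(x)
}

#' Number of positions in a trajectory
#' @param x a `trajectory`.
#' @return integer.
#' @export
n_frames <- function(x) nrow(x$positions)

#' Read trajectories from CSV
#'
#' Expects one row per localisation with a trajectory id, a frame index and
#' x, y (and optionally z) coordinates. Column names can be remapped through
#' `dialect`. Rows are sorted by frame within each id; the dimension is
#' inferred from the presence of a z column.
#'
#' @param path CSV file path (header required, UTF-8).
#' @param dialect named character vector mapping the roles
#'   `id`, `frame`, `x`, `y`, `z` to column names in the file.
#' @param frame_interval frame interval (seconds) stamped on every trajectory.
#' @return a named list of [trajectory] objects.
#' @export
read_trajectories <- function(path,
                              dialect = c(id = "traj_id", frame = "frame",
                                          x = "x", y = "y", z = "z"),
                              frame_interval = 1) {
  def <- c(id = "traj_id", frame = "frame", x = "x", y = "y", z = "z")
  def[names(dialect)] <- dialect
  dialect <- def
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- dialect[c("id", "frame", "x", "y")]
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  has_z <- dialect[["z"]] %in% names(df)
  ids <- as.character(df[[dialect[["id"]]]])
  out <- lapply(split(seq_len(nrow(df)), factor(ids, levels = unique(ids))),
                function(rows) {
    sub <- df[rows, , drop = FALSE]
    ord <- order(sub[[dialect[["frame"]]]])
    sub <- sub[ord, , drop = FALSE]
    fr <- sub[[dialect[["frame"]]]]
    if (anyDuplicated(fr)) {
      stop("duplicate frames within trajectory '", sub[[dialect[["id"]]]][1], "'")
    }
    if (length(fr) > 2L && length(unique(diff(fr))) > 1L) {
      warning("non-uniform frame spacing in trajectory '",
              sub[[dialect[["id"]]]][1], "'; gaps treated as contiguous steps")
    }
    pos <- cbind(sub[[dialect[["x"]]]], sub[[dialect[["y"]]]])
    if (has_z) pos <- cbind(pos, sub[[dialect[["z"]]]])
    trajectory(pos, id = sub[[dialect[["id"]]]][1], frames = fr,
               frame_interval = frame_interval)
  })
  names(out) <- vapply(out, function(t) t$id, character(1))
  out
}

#' Write trajectories to CSV
#'
#' Inverse of [read_trajectories()]: columns `traj_id,frame,x,y[,z]`.
#'
#' @param trajs a `trajectory` or list of trajectories.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajs, path) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  fmt <- function(v) sprintf("%.17g", v)  # round-trips doubles bit-exactly
  dfs <- lapply(trajs, function(t) {
    df <- data.frame(traj_id = t$id, frame = t$frames,
                     x = fmt(t$positions[, 1]), y = fmt(t$positions[, 2]))
    if (t$dim == 3L) df$z <- fmt(t$positions[, 3])
    df
  })
  out <- do.call(rbind, dfs)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Standardize a trajectory by its increment standard deviation
#'
#' Rescales one-step displacements on each coordinate by their empirical
#' (sample, mean-subtracted) standard deviation and rebuilds positions as the
#' cumulative sum of rescaled increments from the original first position.
#' Detection results on standardized trajectories are independent of the
#' diffusion coefficient of the underlying free motion.
#'
#' @param traj a [trajectory] with at least 3 positions.
#' @return a standardized `trajectory`; idempotent and scale-invariant.
#' @export
standardize <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  n <- n_frames(traj)
  if (n < 3L) stop("standardization needs at least 3 positions")
  inc <- diff(traj$positions)
  s <- apply(inc, 2, sd)
  if (any(s <= 0 | !is.finite(s))) {
    stop("degenerate trajectory: zero increment variance on a coordinate")
  }
  inc <- sweep(inc, 2, s, "/")
  pos <- rbind(traj$positions[1, ],
               sweep(apply(inc, 2, cumsum), 2, traj$positions[1, ], "+"))
  trajectory(pos, id = traj$id, frames = traj$frames,
             frame_interval = traj$frame_interval)
}
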