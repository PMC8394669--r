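# cumulative positions from an increment matrix; robust to single-row input
positions_from_increments <- function(inc, origin) {
  cs <- apply(inc, 2, cumsum)
  if (!is.matrix(cs)) cs <- matrix(cs, nrow = 1L)
  rbind(origin, sweep(cs, 2, origin, "+"))
}

#' Simulate Brownian motion
#'
#' Increments are i.i.d. Gaussian with per-coordinate standard deviation
#' `sigma` per frame; `sigma = 1` corresponds to a diffusion coefficient
#' D = 1/2 (per coordinate, per frame).
#'
#' @param n_steps number of positions N (>= 2).
#' @param dim 2 or 3.
#' @param sigma one-step standard deviation per coordinate.
#' @param origin starting position (length `dim`).
#' @param seed optional integer seed (local to this call).
#' @return a [trajectory].
#' @export
simulate_bm <- function(n_steps, dim = 2, sigma = 1, origin = rep(0, dim),
                        seed = NULL) {
  stopifnot(n_steps >= 2, dim %in% c(2, 3), sigma > 0)
  with_seed(seed, {
    inc <- matrix(rnorm((n_steps - 1) * dim, sd = sigma), ncol = dim)
    trajectory(positions_from_increments(inc, origin), id = "bm")
  })
}

# fractional Gaussian noise by Davies-Harte circulant embedding (exact
# covariance); falls back to Cholesky when the embedding is not nonnegative.
# Returns n increments with Var = sigma^2 and autocovariance
# gamma(k) = sigma^2/2 (|k+1|^2H - 2|k|^2H + |k-1|^2H).
.fgn_cache <- new.env(parent = emptyenv())

fgn_gamma <- function(k, hurst, sigma = 1) {
  0.5 * sigma^2 * (abs(k + 1)^(2 * hurst) - 2 * abs(k)^(2 * hurst) +
                     abs(k - 1)^(2 * hurst))
}

simulate_fgn <- function(n, hurst, sigma = 1) {
  if (n == 1L) return(rnorm(1, sd = sigma))
  key <- paste(n, signif(hurst, 12), sep = "|")
  cached <- .fgn_cache[[key]]
  if (is.null(cached)) {
    g <- fgn_gamma(0:n, hurst)
    lam <- Re(fft(c(g[1:n], g[n + 1], rev(g[2:n]))))
    if (min(lam) < -1e-8 * max(lam)) {
      cached <- list(method = "chol",
                     L = chol(outer(1:n, 1:n,
                                    function(i, j) fgn_gamma(i - j, hurst))))
    } else {
      cached <- list(method = "dh", lam = pmax(lam, 0))
    }
    .fgn_cache[[key]] <- cached
  }
  if (cached$method == "chol") {
    return(sigma * drop(crossprod(cached$L, rnorm(n))))
  }
  lam <- cached$lam
  m <- 2L * n
  z <- complex(m)
  z[1] <- sqrt(lam[1]) * rnorm(1)
  z[n + 1] <- sqrt(lam[n + 1]) * rnorm(1)
  k <- 2:n
  z[k] <- sqrt(lam[k] / 2) * complex(real = rnorm(n - 1),
                                     imaginary = rnorm(n - 1))
  z[m + 2 - k] <- Conj(z[k])
  sigma * Re(fft(z))[1:n] / sqrt(m)
}

#' Simulate fractional Brownian motion
#'
#' Each coordinate is an independent exact-covariance fractional Brownian
#' path built from fractional Gaussian noise (Davies-Harte circulant
#' embedding, Cholesky fallback). The Hurst (Holder) exponent H sets the
#' MSD anomalous exponent alpha = 2H; the default H = 0.35 gives the
#' subdiffusive alpha = 0.7 used as crowded-environment reference motion.
#'
#' @inheritParams simulate_bm
#' @param hurst Hurst exponent in (0, 1).
#' @return a [trajectory].
#' @export
simulate_fbm <- function(n_steps, dim = 2, hurst = 0.35, sigma = 1,
                         origin = rep(0, dim), seed = NULL) {
  stopifnot(n_steps >= 2, dim %in% c(2, 3), hurst > 0, hurst < 1, sigma > 0)
  with_seed(seed, {
    inc <- vapply(seq_len(dim),
                  function(d) simulate_fgn(n_steps - 1L, hurst, sigma),
                  numeric(n_steps - 1L))
    inc <- matrix(inc, ncol = dim)
    trajectory(positions_from_increments(inc, origin), id = "fbm")
  })
}

#' Simulate trapped (confined) motion in a disk or sphere
#'
#' Reflected Brownian motion of diffusion coefficient D = sigma^2/2 inside a
#' disk (2D) or sphere (3D) of radius `radius`, integrated with sub-steps of
#' duration `dt` and radial (specular) reflection at the boundary, sampled
#' every 1/dt sub-steps. When the per-sub-step diffusion length exceeds a
#' third of the radius (`sqrt(2 D dt) > radius/3`) the stationary regime is
#' reached within a frame and positions are drawn i.i.d. uniform in the
#' disk/sphere instead.
#'
#' @inheritParams simulate_bm
#' @param radius trap radius (> 0).
#' @param dt integration sub-step, in frames.
#' @param centre trap centre (length `dim`).
#' @param start starting position; defaults to `centre`. Ignored in the
#'   uniform-fill regime.
#' @return a [trajectory]; every position is within `radius` of `centre`.
#' @export
simulate_trapped <- function(n_steps, dim = 2, radius, sigma = 1, dt = 0.5,
                             centre = rep(0, dim), start = NULL, seed = NULL) {
  stopifnot(n_steps >= 2, dim %in% c(2, 3), radius > 0, sigma > 0, dt > 0)
  D <- sigma^2 / 2
  with_seed(seed, {
    if (sqrt(2 * D * dt) > radius / 3) {
      pos <- runif_ball(n_steps, dim, radius)
    } else {
      nsub <- max(1L, round(1 / dt))
      x <- if (is.null(start)) rep(0, dim) else start - centre
      if (sqrt(sum(x^2)) > radius) stop("start lies outside the trap")
      pos <- matrix(0, n_steps, dim)
      pos[1, ] <- x
      for (i in 2:n_steps) {
        for (s in seq_len(nsub)) {
          x <- x + rnorm(dim, sd = sigma * sqrt(dt))
          r <- sqrt(sum(x^2))
          while (r > radius) {          # radial specular reflection
            x <- x * (2 * radius - r) / r
            r <- abs(2 * radius - r)
          }
        }
        pos[i, ] <- x
      }
    }
    trajectory(sweep(pos, 2, centre, "+"), id = "trapped")
  })
}

# i.i.d. uniform points in a dim-ball of given radius
runif_ball <- function(n, dim, radius) {
  u <- matrix(rnorm(n * dim), ncol = dim)
  u <- u / sqrt(rowSums(u^2))
  u * radius * runif(n)^(1 / dim)
}

#' Simulate a two-state (free/trapped) trajectory with ground truth
#'
#' Alternates free motion (Brownian or fractional Brownian) with trapped
#' motion in a disk/sphere, starting in the free state. State durations are
#' Poisson-distributed (zero draws redrawn as 1); the trap is centred at the
#' particle's position on entry and the free motion resumes from the last
#' trapped position, so the path is continuous. Trap radii are either fixed
#' or drawn uniformly from a range; the trapped mean duration is either a
#' fixed `tau_trap` or the radius-dependent rule `6 R^2 + 50`. Optional
#' localisation noise is added after the ground-truth labels are recorded.
#'
#' @inheritParams simulate_bm
#' @param free_model `"bm"` or `"fbm"` for the free segments.
#' @param hurst Hurst exponent for fBm free segments (each free segment is an
#'   independent fBm path).
#' @param tau_free mean free-state duration, frames.
#' @param tau_trap mean trapped-state duration, frames; 0 gives an entirely
#'   free trajectory. Ignored when `trap_rule = "radius"`.
#' @param trap_rule `"poisson"` (mean `tau_trap`) or `"radius"` (mean
#'   `6 R^2 + 50` for the drawn radius R).
#' @param radius trap radius: a single value, or a length-2 range from which
#'   each trap's radius is drawn uniformly.
#' @param noise_sigma localisation noise standard deviation (0 for none).
#' @param dt trapped-motion integration sub-step, frames.
#' @return an object of class `"labelled_trajectory"`: list with
#'   `trajectory` (noisy if `noise_sigma > 0`), `truth` (character vector
#'   over `"free"`/`"trapped"`), and `traps` (data frame of centres, radii
#'   and frame ranges).
#' @export
simulate_alternating <- function(n_steps, dim = 2, free_model = c("bm", "fbm"),
                                 hurst = 0.35, sigma = 1, tau_free,
                                 tau_trap = NULL,
                                 trap_rule = c("poisson", "radius"),
                                 radius = 1, noise_sigma = 0, dt = 0.5,
                                 seed = NULL) {
  free_model <- match.arg(free_model)
  trap_rule <- match.arg(trap_rule)
  stopifnot(n_steps >= 2, dim %in% c(2, 3), tau_free > 0)
  if (trap_rule == "poisson" && is.null(tau_trap)) {
    stop("tau_trap is required with trap_rule = 'poisson'")
  }
  with_seed(seed, {
    pos <- matrix(0, 0, dim)
    truth <- character(0)
    traps <- list()
    cur <- rep(0, dim)
    state <- "free"
    while (nrow(pos) < n_steps) {
      if (state == "free") {
        dur <- max(1L, rpois(1, tau_free))
        seg <- if (free_model == "bm") {
          simulate_bm(dur + 1L, dim, sigma, origin = cur)
        } else {
          simulate_fbm(dur + 1L, dim, hurst, sigma, origin = cur)
        }
        segpos <- seg$positions[-1L, , drop = FALSE]
        if (nrow(pos) == 0L) {           # include the starting position
          segpos <- rbind(cur, segpos)
        }
        pos <- rbind(pos, segpos)
        truth <- c(truth, rep("free", nrow(segpos)))
        state <- "trapped"
      } else {
        R <- if (length(radius) == 2L) runif(1, radius[1], radius[2]) else radius
        mean_dur <- if (trap_rule == "radius") 6 * R^2 + 50 else tau_trap
        if (mean_dur <= 0) {            # no trapping regime: stay free
          state <- "free"
          next
        }
        dur <- max(1L, rpois(1, mean_dur))
        centre <- cur
        seg <- simulate_trapped(dur + 1L, dim, radius = R, sigma = sigma,
                                dt = dt, centre = centre, start = cur)
        segpos <- seg$positions[-1L, , drop = FALSE]
        start_fr <- nrow(pos) + 1L
        pos <- rbind(pos, segpos)
        truth <- c(truth, rep("trapped", nrow(segpos)))
        traps[[length(traps) + 1L]] <-
          c(centre, R, start_fr, nrow(pos))
        state <- "free"
      }
      cur <- pos[nrow(pos), ]
    }
    pos <- pos[seq_len(n_steps), , drop = FALSE]
    truth <- truth[seq_len(n_steps)]
    traps_df <- if (length(traps) > 0L) {
      tm <- do.call(rbind, traps)
      df <- as.data.frame(tm)
      names(df) <- c(paste0("centre_", c("x", "y", "z")[seq_len(dim)]),
                     "radius", "start", "end")
      df$start <- as.integer(df$start)
      df$end <- as.integer(pmin(df$end, n_steps))
      df[df$start <= n_steps, , drop = FALSE]
    } else {
      empty <- as.data.frame(matrix(numeric(0), 0, dim + 3L))
      names(empty) <- c(paste0("centre_", c("x", "y", "z")[seq_len(dim)]),
                        "radius", "start", "end")
      empty
    }
    clean <- trajectory(pos, id = "alternating")
    traj <- if (noise_sigma > 0) add_noise(clean, noise_sigma) else clean
    structure(list(trajectory = traj, clean = clean, truth = truth,
                   traps = traps_df),
              class = "labelled_trajectory")
  })
}

#' Add localisation noise to a trajectory
#'
#' Adds i.i.d. Gaussian noise of standard deviation `noise_sigma`
#' independently to every coordinate of every frame, modelling the
#' localisation error of single-particle imaging.
#'
#' @param traj a [trajectory].
#' @param noise_sigma noise standard deviation (>= 0; 0 returns the
#'   trajectory unchanged).
#' @param seed optional integer seed (local to this call).
#' @return a [trajectory].
#' @export
add_noise <- function(traj, noise_sigma, seed = NULL) {
  stopifnot(inherits(traj, "trajectory"), noise_sigma >= 0)
  if (noise_sigma == 0) return(traj)
  with_seed(seed, {
    noisy <- traj$positions +
      matrix(rnorm(length(traj$positions), sd = noise_sigma),
             nrow = nrow(traj$positions))
    trajectory(noisy, id = traj$id, frames = traj$frames,
               frame_interval = traj$frame_interval)
  })
}
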