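# Independent reference implementations used as oracles in the tests.
# They are deliberately naive (double loops, BFS) and share no code with the
# package internals.

# wrap a 0/1 matrix as the binary class the measure functions expect
as_binary <- function(V, lambda = 1, mu = 0L, n_d = 0L) {
  storage.mode(V) <- "integer"
  structure(list(values = V, lambda = lambda, mu = mu, n_d = n_d),
            class = "binary_recurrence")
}

as_recurrence <- function(V, lambda = 1) {
  structure(list(values = V, lambda = lambda, mu = 0L),
            class = "recurrence_matrix")
}

# exhaustive per-line run scan of the three diagonal measures
oracle_measures <- function(V) {
  n <- nrow(V)
  run_through <- function(cells) {
    # cells: k-indexed coordinates, row 0 is the centre; count the maximal
    # run of 1s containing the centre
    len <- 1L
    k <- 1L
    while (!is.null(p <- cells(k)) && V[p[1], p[2]] == 1L) {
      len <- len + 1L
      k <- k + 1L
    }
    kk <- 1L
    while (!is.null(p <- cells(-kk)) && V[p[1], p[2]] == 1L) {
      len <- len + 1L
      kk <- kk + 1L
    }
    len
  }
  inb <- function(i, j) if (i >= 1 && i <= n && j >= 1 && j <= n) c(i, j) else NULL
  t_block <- t_perp <- t_par <- integer(n)
  for (m in seq_len(n)) {
    t_block[m] <- run_through(function(k) inb(m + k, m))
    t_perp[m] <- run_through(function(k) inb(m + k, m - k))
    # lower-left extremity of the anti-diagonal run
    k <- 0L
    while (!is.null(p <- inb(m + k + 1L, m - k - 1L)) && V[p[1], p[2]] == 1L) {
      k <- k + 1L
    }
    i0 <- m + k; j0 <- m - k
    t_par[m] <- run_through(function(kk) inb(i0 + kk, j0 + kk))
  }
  data.frame(t_block = t_block, t_perp = t_perp, t_par = t_par,
             nu = t_block / (t_par + t_perp - 1))
}

# BFS flood fill of 4-connected 0-regions from the border; enclosed 0s -> 1
oracle_fill <- function(V) {
  n <- nrow(V); m <- ncol(V)
  outside <- matrix(FALSE, n, m)
  queue <- list()
  push <- function(i, j) {
    if (i >= 1 && i <= n && j >= 1 && j <= m && !outside[i, j] && V[i, j] == 0L) {
      outside[i, j] <<- TRUE
      queue[[length(queue) + 1L]] <<- c(i, j)
    }
  }
  for (i in seq_len(n)) { push(i, 1L); push(i, m) }
  for (j in seq_len(m)) { push(1L, j); push(n, j) }
  while (length(queue) > 0L) {
    p <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    push(p[1] - 1L, p[2]); push(p[1] + 1L, p[2])
    push(p[1], p[2] - 1L); push(p[1], p[2] + 1L)
  }
  V[V == 0L & !outside] <- 1L
  V
}

# brute-force TAMSD, double loop over start frames
oracle_tamsd <- function(pos, max_lag) {
  n <- nrow(pos)
  sapply(seq_len(max_lag), function(lag) {
    acc <- 0
    for (k in seq_len(n - lag)) {
      acc <- acc + sum((pos[k + lag, ] - pos[k, ])^2)
    }
    acc / (n - lag)
  })
}

# random symmetric 0/1 matrix with unit diagonal
random_symmetric_binary <- function(n, p = 0.4) {
  V <- matrix(as.integer(runif(n * n) < p), n, n)
  V[lower.tri(V)] <- t(V)[lower.tri(V)]
  diag(V) <- 1L
  V
}

# ideal banded matrix with all-ones square blocks on the diagonal;
# blocks = data.frame(start, end)
ideal_block_matrix <- function(n, blocks, n_d = 0L) {
  V <- matrix(0L, n, n)
  for (r in seq_len(nrow(blocks))) {
    idx <- blocks$start[r]:blocks$end[r]
    V[idx, idx] <- 1L
  }
  for (d in 0:n_d) {
    i <- seq_len(n - d)
    V[cbind(i + d, i)] <- 1L
    V[cbind(i, i + d)] <- 1L
  }
  V
}

# tiny shared calibration table for detection tests (cached across files)
test_calibration <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      tab <<- build_calibration(models = "bm", dims = 2, lambdas = 1,
                                mu = 2, p_values = 0.05,
                                n_traj_band = 20, n_steps_band = 500,
                                n_traj_null = 40, n_steps_null = 1000,
                                seed = 99)
    }
    tab
  }
})
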