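test_that("Brownian increments have the requested scale and MSD slope", {
  tr <- simulate_bm(1e5, dim = 2, sigma = 1.5, seed = 1)
  inc <- diff(tr$positions)
  expect_equal(apply(inc, 2, sd), c(1.5, 1.5), tolerance = 0.01)
  # MSD at lag n ~ 2*dim*D*n with D = sigma^2/2: use the increments directly
  msd5 <- mean(rowSums((tr$positions[6:1e5, ] - tr$positions[1:(1e5 - 5), ])^2))
  expect_equal(msd5, 2 * 2 * (1.5^2 / 2) * 5, tolerance = 0.05)
})

test_that("simulators are deterministic under a seed and leave the RNG state alone", {
  a <- simulate_bm(100, seed = 5)
  b <- simulate_bm(100, seed = 5)
  expect_identical(a$positions, b$positions)
  f1 <- simulate_fbm(100, hurst = 0.35, seed = 5)
  f2 <- simulate_fbm(100, hurst = 0.35, seed = 5)
  expect_identical(f1$positions, f2$positions)
  set.seed(123); x <- rnorm(1)
  set.seed(123); invisible(simulate_bm(50, seed = 9)); y <- rnorm(1)
  expect_identical(x, y)
})

test_that("fGn matches the closed-form increment autocovariance", {
  H <- 0.35
  n <- 400
  set.seed(20)
  reps <- 400
  X <- replicate(reps, recurtrap:::simulate_fgn(n, H))
  gam <- recurtrap:::fgn_gamma(0:5, H)
  expect_equal(mean(apply(X, 2, var)), gam[1], tolerance = 0.05)
  for (k in 1:5) {
    est <- vapply(seq_len(reps), function(j) {
      mean(X[1:(n - k), j] * X[(1 + k):n, j])
    }, numeric(1))
    se <- sd(est) / sqrt(reps)
    expect_lt(abs(mean(est) - gam[k + 1]), 3 * se + 1e-3)
  }
})

test_that("fBm at H = 0.5 reduces to uncorrelated Brownian increments", {
  set.seed(21)
  tr <- simulate_fbm(2e4, dim = 2, hurst = 0.5)
  inc <- diff(tr$positions)
  ac <- cor(inc[-nrow(inc), 1], inc[-1, 1])
  expect_lt(abs(ac), 0.03)
})

test_that("trapped motion stays inside the trap and fills it uniformly", {
  centre <- c(2, -1)
  tr <- simulate_trapped(5000, dim = 2, radius = 1, centre = centre, seed = 3)
  d <- sqrt(rowSums(sweep(tr$positions, 2, centre)^2))
  expect_true(all(d <= 1 + 1e-12))
  # stationary distribution in a disk: E[r^2] = R^2/2 (uniform-fill regime)
  expect_equal(mean(d^2), 0.5, tolerance = 0.05)
})

test_that("reflected integration branch: large traps reproduce free Brownian steps", {
  # radius >> sigma*sqrt(n): reflections never trigger
  tr <- simulate_trapped(5000, dim = 2, radius = 1000, sigma = 1, dt = 0.5,
                         seed = 4)
  inc <- diff(tr$positions)
  expect_equal(apply(inc, 2, sd), c(1, 1), tolerance = 0.03)
  # small trap in the reflected regime (radius > 3*sigma*sqrt(dt)) is confined
  tr2 <- simulate_trapped(2000, dim = 3, radius = 2.5, sigma = 1, dt = 0.5,
                          seed = 5)
  expect_true(all(sqrt(rowSums(tr2$positions^2)) <= 2.5 + 1e-12))
})

test_that("alternating simulation respects durations, labels and confinement", {
  lt <- simulate_alternating(3000, dim = 2, tau_free = 10, tau_trap = 30,
                             radius = 1, seed = 6)
  expect_equal(length(lt$truth), 3000L)
  expect_setequal(unique(lt$truth), c("free", "trapped"))
  # pre-noise trapped positions lie inside their trap
  for (r in seq_len(nrow(lt$traps))) {
    idx <- lt$traps$start[r]:lt$traps$end[r]
    centre <- unlist(lt$traps[r, c("centre_x", "centre_y")])
    d <- sqrt(rowSums(sweep(lt$clean$positions[idx, , drop = FALSE],
                            2, centre)^2))
    expect_true(all(d <= lt$traps$radius[r] + 1e-9))
    expect_true(all(lt$truth[idx] == "trapped"))
  }
  # frames inside no trap are labelled free
  in_trap <- rep(FALSE, 3000)
  for (r in seq_len(nrow(lt$traps))) {
    in_trap[lt$traps$start[r]:lt$traps$end[r]] <- TRUE
  }
  expect_true(all(lt$truth[!in_trap] == "free"))
})

test_that("trapped durations are Poisson with the requested mean", {
  set.seed(30)
  durs <- integer(0)
  while (length(durs) < 300) {
    lt <- simulate_alternating(5000, dim = 2, tau_free = 5, tau_trap = 25,
                               radius = 1)
    tr <- lt$traps[lt$traps$end < 5000, , drop = FALSE]  # drop truncated tail
    durs <- c(durs, tr$end - tr$start + 1L)
  }
  se <- sqrt(25 / length(durs))
  expect_lt(abs(mean(durs) - 25), 3 * se + 0.5)
})

test_that("the radius rule 6R^2+50 sets the mean trapped duration", {
  set.seed(31)
  durs <- integer(0)
  while (length(durs) < 200) {
    lt <- simulate_alternating(8000, dim = 2, tau_free = 5,
                               trap_rule = "radius", radius = c(2, 2))
    tr <- lt$traps[lt$traps$end < 8000, , drop = FALSE]
    durs <- c(durs, tr$end - tr$start + 1L)
  }
  expect_equal(mean(durs), 6 * 4 + 50, tolerance = 0.05)
})

test_that("tau_trap = 0 yields an entirely free trajectory", {
  lt <- simulate_alternating(500, dim = 2, tau_free = 10, tau_trap = 0,
                             radius = 1, seed = 7)
  expect_true(all(lt$truth == "free"))
  expect_equal(nrow(lt$traps), 0L)
})

test_that("localisation noise has the requested variance and zero noise is a no-op", {
  tr <- simulate_bm(5e4, dim = 2, seed = 8)
  expect_identical(add_noise(tr, 0)$positions, tr$positions)
  noisy <- add_noise(tr, 0.5, seed = 9)
  resid <- noisy$positions - tr$positions
  expect_equal(apply(resid, 2, var), c(0.25, 0.25), tolerance = 0.02)
})
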