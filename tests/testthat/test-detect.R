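test_that("recognition score is the frame-level agreement", {
  truth <- rep(c("free", "trapped"), each = 10)
  expect_equal(recognition_score(truth, truth), 1)
  flipped <- ifelse(truth == "free", "trapped", "free")
  expect_equal(recognition_score(flipped, truth), 0)
  half <- truth
  half[seq(1, 20, by = 2)] <- ifelse(half[seq(1, 20, by = 2)] == "free",
                                     "trapped", "free")
  expect_equal(recognition_score(half, truth), 0.5)
  expect_error(recognition_score(truth[-1], truth), "lengths")
})

test_that("a trajectory fully inside a trap is detected as one dominant block", {
  tab <- test_calibration()
  tr <- simulate_trapped(600, dim = 2, radius = 1, seed = 50)
  seg <- detect_single_scale(tr, 1, tab, reference = "bm")
  expect_gte(mean(seg$labels == "trapped"), 0.9)
  expect_gte(max(seg$blocks$size), 0.9 * 600)
})

test_that("alternating trajectories are recovered with high frame agreement", {
  tab <- test_calibration()
  set.seed(51)
  scores <- vapply(1:8, function(i) {
    lt <- simulate_alternating(1000, dim = 2, tau_free = 20, tau_trap = 60,
                               radius = 1, noise_sigma = 0.1)
    recognition_score(detect_single_scale(lt$trajectory, 1, tab,
                                          reference = "bm"), lt)
  }, numeric(1))
  expect_gte(mean(scores), 0.8)
})

test_that("multiscale union equals single scale for one lambda and is a superset", {
  tab <- test_calibration()
  lt <- simulate_alternating(800, dim = 2, tau_free = 15, tau_trap = 50,
                             radius = 1, seed = 52)
  single <- detect_single_scale(lt$trajectory, 1, tab, reference = "bm")
  multi1 <- detect_multiscale(lt$trajectory, 1, tab, reference = "bm")
  expect_identical(multi1$labels, single$labels)
  expect_true(all(is.na(multi1$blocks$lambda)))
  expect_true(all(which(single$labels == "trapped") %in%
                    which(multi1$labels == "trapped")))
})

test_that("detection is deterministic and labels stay consistent with blocks", {
  tab <- test_calibration()
  lt <- simulate_alternating(700, dim = 2, tau_free = 20, tau_trap = 40,
                             radius = 1, seed = 53)
  s1 <- detect_single_scale(lt$trajectory, 1, tab, reference = "bm")
  s2 <- detect_single_scale(lt$trajectory, 1, tab, reference = "bm")
  expect_identical(s1$labels, s2$labels)
  # every frame inside a block is trapped, and vice versa
  lab <- rep("free", length(s1$labels))
  for (r in seq_len(nrow(s1$blocks))) {
    lab[s1$blocks$start[r]:s1$blocks$end[r]] <- "trapped"
  }
  expect_identical(lab, s1$labels)
})

test_that("trajectories shorter than the minimal block come back all-free with a warning", {
  tab <- test_calibration()
  min_block <- min_block_size(recurtrap:::entry_ecdf(
    cal_lookup(tab, "bm", 2, 1, 2)), 0.05)
  tr <- simulate_trapped(max(3, min_block - 1), dim = 2, radius = 0.5,
                         seed = 54)
  expect_warning(seg <- detect_single_scale(tr, 1, tab, reference = "bm"),
                 "shorter")
  expect_true(all(seg$labels == "free"))
})

test_that("strong noise lowers the recognition score only marginally", {
  tab <- test_calibration()
  mean_score <- function(noise, seed0) {
    mean(vapply(1:15, function(i) {
      lt <- simulate_alternating(1000, dim = 2, tau_free = 20, tau_trap = 60,
                                 radius = 1, noise_sigma = noise,
                                 seed = seed0 + i)
      recognition_score(detect_single_scale(lt$trajectory, 1, tab,
                                            reference = "bm"), lt)
    }, numeric(1)))
  }
  low <- mean_score(0.1, 700)
  strong <- mean_score(1.0, 700)
  expect_gte(strong, low - 0.1)
})

test_that("small-lengthscale detection flags large traps far above the false-positive rate", {
  tab <- test_calibration()
  set.seed(57)
  recall <- fp <- numeric(6)
  for (i in 1:6) {
    lt <- simulate_alternating(1000, dim = 2, tau_free = 20,
                               trap_rule = "radius", radius = c(3, 3),
                               noise_sigma = 0.5)
    seg <- detect_single_scale(lt$trajectory, 1, tab, reference = "bm")
    recall[i] <- mean(seg$labels[lt$truth == "trapped"] == "trapped")
    fp[i] <- mean(seg$labels[lt$truth == "free"] == "trapped")
  }
  # partial cross-scale sensitivity: trapped frames of radius-3 traps are
  # flagged at a rate clearly above the leakage onto free frames (which here
  # includes block-boundary bleed over the short free interludes)
  expect_gt(mean(recall), 2 * mean(fp))
  expect_gt(mean(recall), 0.1)
})

test_that("benchmark grid returns one scored row per cell", {
  tab <- test_calibration()
  grid <- benchmark_grid(tau_free_values = 20, tau_conf_values = c(0, 60),
                         noise_sigmas = 0.1, radius = 1, lambda = 1,
                         calibration = tab, n_traj = 3, n_steps = 300,
                         reference = "bm", seed = 55)
  expect_equal(nrow(grid), 2L)
  expect_true(all(grid$mean_score >= 0 & grid$mean_score <= 1))
  # no-confinement cell scores at least as well as chance would suggest
  expect_gte(grid$mean_score[grid$tau_conf == 0], 0.8)
})

test_that("segmentation CSV output has the documented schema", {
  tab <- test_calibration()
  lt <- simulate_alternating(400, dim = 2, tau_free = 20, tau_trap = 60,
                             radius = 1, seed = 56)
  seg <- detect_single_scale(lt$trajectory, 1, tab, reference = "bm")
  f <- tempfile(fileext = ".csv")
  write_segmentation(seg, f)
  df <- read.csv(f)
  expect_equal(names(df), c("traj_id", "frame", "label", "block_id"))
  expect_equal(nrow(df), 400L)
  expect_setequal(unique(df$label), unique(seg$labels))
  expect_true(file.exists(sub("\\.csv$", ".blocks.json", f)))
})
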