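test_that("segmentation recovers the drawn root and flags empty frames", {
  sim <- simulate_root_image_series(45, start_angle = 45)
  drawn <- sim$frames[[1]] > 0.5
  mask <- segment_root(sim$frames[[1]])
  ## differences confined to a 1-px band at the drawn boundary
  diffpx <- which(mask != drawn, arr.ind = TRUE)
  if (nrow(diffpx) > 0) {
    interior <- drawn &
      rbind(FALSE, drawn[-nrow(drawn), ]) & rbind(drawn[-1, ], FALSE) &
      cbind(FALSE, drawn[, -ncol(drawn)]) & cbind(drawn[, -1], FALSE)
    expect_false(any(interior[diffpx]))
  }
  expect_null(segment_root(matrix(0, 60, 60)))

  ## two roots: the larger wins
  two <- matrix(0, 80, 80)
  two[10:60, 20:24] <- 1   # 51 x 5
  two[10:30, 60:64] <- 1   # 21 x 5
  m2 <- segment_root(two, min_area_px = 20)
  expect_true(all(m2[15:55, 21:23]))
  expect_false(any(m2[, 58:66]))
})

test_that("tip angle follows the drawn terminal tangent", {
  ## axis-aligned and diagonal straight roots
  expect_lt(abs(measure_tip_angle(segment_root(
    simulate_root_image_series(90)$frames[[1]])) - 90), 1)
  expect_lt(abs(measure_tip_angle(segment_root(
    simulate_root_image_series(45, start_angle = 45)$frames[[1]])) - 45), 2)
  ## curved root with known terminal tangent
  expect_lt(abs(measure_tip_angle(segment_root(
    simulate_root_image_series(30)$frames[[1]])) - 30), 3)
  ## tiny skeleton is flagged
  expect_true(is.na(measure_tip_angle(matrix(c(TRUE), 1, 1))))
})

test_that("tip angle is consistent under rotation of the drawn root", {
  ## same bend magnitude drawn at rotated orientations
  base <- measure_tip_angle(segment_root(
    simulate_root_image_series(50)$frames[[1]]))
  for (phi in c(30, 60)) {
    rot <- measure_tip_angle(segment_root(
      simulate_root_image_series(50 + phi,
                                 start_angle = 90 + phi)$frames[[1]]))
    expect_lt(abs((rot - base) - phi), 2)
  }
})

test_that("measured zero-noise trajectories track the truth within 3 deg", {
  times <- seq(0, 180, by = 3)
  traj <- 90 - logistic_curve(times, 60, 0.7, 20)
  sim <- simulate_root_image_series(traj)
  ser <- measure_series(sim$frames, times)
  expect_equal(length(ser$angles), 61)
  expect_lt(max(abs(ser$angles - traj)), 3)
})

test_that("series assembly interpolates single gaps only", {
  times <- seq(0, 27, by = 3)
  a <- c(10, 20, NA, 44, 50, NA, NA, NA, 70, 72)
  s <- build_series(a, times)
  expect_equal(length(s$angles), length(times))
  expect_equal(s$angles[3], (20 + 44) / 2)  # 40/44-neighbour midpoint rule
  expect_equal(s$flags[3], "interpolated")
  expect_true(all(is.na(s$angles[6:8])))
  expect_equal(s$flags[6:8], rep("missing", 3))
  expect_error(build_series(c(NA, 5, NA), c(0, 3, 6)), "2 valid")
  expect_error(build_series(c(1, 2), c(3, 3)), "strictly increasing")
})

test_that("initial-angle subtraction is a shift and is idempotent", {
  times <- seq(0, 30, by = 3)
  s <- build_series(17 + seq(0, 40, length.out = 11), times)
  z <- subtract_initial(s)
  expect_equal(z$angles[1], 0)
  expect_equal(diff(z$angles), diff(s$angles))
  expect_identical(subtract_initial(z), z)
  ## constant series maps to all zeros
  cs <- subtract_initial(build_series(rep(5, 11), times))
  expect_true(all(cs$angles == 0))
  ## missing first frame: earliest valid frame substitutes, recorded
  m <- build_series(c(NA, NA, 20, 24, 28, 30, 31, 31, 31, 31, 31), times)
  zm <- subtract_initial(m)
  expect_equal(zm$angles[3], 0)
  expect_match(zm$initial_source, "substituted")
})

test_that("line averaging computes pairwise-complete means and SEM", {
  times <- seq(0, 9, by = 3)
  mk <- function(a, id, line) build_series(a, times, id = id, line = line)
  sl <- list(mk(c(10, 10, 10, 10), "s1", "L1"),
             mk(c(10, 10, 10, 10), "s2", "L1"),
             mk(c(10, 10, 10, 20), "s3", "L2"),
             mk(c(10, 10, 10, 10), "s4", "L2"),
             mk(c(1, 2, 3, 4), "s5", "L3"))
  expect_warning(lm_ <- average_by_line(sl, lines = c("L1", "L2", "L3", "L9")),
                 "L9")
  l1 <- lm_[lm_$line == "L1", ]
  expect_equal(l1$mean, rep(10, 4))
  expect_equal(l1$sem, rep(0, 4))
  l2 <- lm_[lm_$line == "L2", ]
  expect_equal(l2$mean[4], 15)
  expect_equal(l2$sem[4], 5)  # SD of {10,20} = 7.071, /sqrt(2)
  expect_true(all(is.na(lm_[lm_$line == "L3", "sem"])))  # n = 1
  mat <- line_mean_matrix(lm_)
  expect_equal(unname(mat["L2", 4]), 15)
})

test_that("group comparison matches hand-computed pooled t and Tukey letters", {
  times <- c(0, 3)
  g1 <- matrix(c(1, 1.1), 2, 2)
  g2 <- matrix(c(2, 2.1), 2, 2)
  tt <- compare_groups(list(a = g1, b = g2), times, test_times = 3,
                       method = "ttest")
  expect_equal(abs(tt$tests[[1]]$statistic), 14.1421, tolerance = 1e-4)

  ## identical groups: F ~ 0, one shared letter
  set.seed(1)
  base <- matrix(rnorm(10, 50, 1), 5, 2)
  cg <- compare_groups(list(a = base, b = base), times, test_times = 3)
  expect_lt(cg$tests[[1]]$statistic, 1e-20)
  expect_equal(unname(cg$tests[[1]]$letters["a"]),
               unname(cg$tests[[1]]$letters["b"]))

  ## one far-shifted group earns its own letter
  g3 <- base + 40
  cg3 <- compare_groups(list(a = base, b = base + 0.1, c = g3), times,
                        test_times = 3, alpha = 0.1)
  le <- cg3$tests[[1]]$letters
  expect_equal(unname(le["a"]), unname(le["b"]))
  expect_false(any(strsplit(le["c"], "")[[1]] %in%
                     strsplit(le["a"], "")[[1]]))

  ## exact ties: zero variance everywhere
  z1 <- matrix(5, 3, 2); z2 <- matrix(5, 3, 2); z3 <- matrix(7, 3, 2)
  expect_equal(compare_groups(list(a = z1, b = z2), times,
                              test_times = 3)$tests[[1]]$p, 1)
  expect_equal(compare_groups(list(a = z1, b = z3), times,
                              test_times = 3)$tests[[1]]$p, 0)
  expect_error(compare_groups(list(a = z1), times), "at least 2")
  expect_error(compare_groups(list(a = z1[1, , drop = FALSE], b = z2),
                              times), "n >= 2")
})
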