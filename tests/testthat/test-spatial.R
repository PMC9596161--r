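test_that("find_mate picks uniformly among males inside the circle", {
  set.seed(31)
  # brute-force distance filter as oracle
  mx <- runif(1000)
  my <- runif(1000)
  fx <- 0.5
  fy <- 0.5
  r <- 0.04
  inside <- which((mx - fx)^2 + (my - fy)^2 <= r^2)
  picks <- replicate(3000, find_mate(fx, fy, mx, my, r))
  expect_true(all(picks %in% inside))
  tab <- table(factor(picks, levels = inside))
  cs <- suppressWarnings(stats::chisq.test(tab))
  expect_gt(cs$p.value, 0.001)
  # empty circle -> no mate; single candidate -> certainty
  expect_equal(find_mate(0.5, 0.5, 0.9, 0.9, 0.01), 0L)
  expect_equal(find_mate(0.5, 0.5, c(0.505, 0.9), c(0.5, 0.9), 0.01), 1L)
})

test_that("local fecundity matches the density-ratio arithmetic", {
  # local density equal to the landscape expectation: no scaling
  k <- 50000
  cnt_at_k <- k * pi * 0.01^2
  expect_equal(local_fecundity(1, cnt_at_k, k, 10), 1)
  expect_equal(local_fecundity(1, 0, k, 10), 10)
  # 16 individuals in the 0.01 circle -> rho_i ~ 50,930
  expect_equal(local_fecundity(1, 16, 50000, 10),
               10 / (9 * (16 / (pi * 1e-4)) / 50000 + 1))
  expect_lt(abs(local_fecundity(1, 16, 50000, 10) - 0.985), 0.005)
})

test_that("offspring dispersal is Gaussian with redraw at the border", {
  set.seed(32)
  n <- 1e5
  pos <- disperse_offspring(rep(0.5, n), rep(0.5, n), 0.04)
  d <- sqrt((pos$x - 0.5)^2 + (pos$y - 0.5)^2)
  # Rayleigh mean sigma * sqrt(pi/2) ~ 0.0501
  expect_lt(abs(mean(d) - 0.04 * sqrt(pi / 2)) / (0.04 * sqrt(pi / 2)), 0.005)
  # zero migration: offspring at the mother's position
  still <- disperse_offspring(0.3, 0.7, 0)
  expect_equal(still, list(x = 0.3, y = 0.7))
  # near a border every accepted position is inside, and the accepted
  # distribution matches a rejection-sampling oracle, not a clip
  pos2 <- disperse_offspring(rep(0.001, 2e4), rep(0.5, 2e4), 0.04)
  expect_true(all(pos2$x >= 0 & pos2$x <= 1 & pos2$y >= 0 & pos2$y <= 1))
  expect_lt(mean(pos2$x == 0), 1e-9)  # no mass piled on the border
  oracle <- local({
    xs <- 0.001 + stats::rnorm(2e5, 0, 0.04)
    ys <- 0.5 + stats::rnorm(2e5, 0, 0.04)
    ok <- xs >= 0 & xs <= 1 & ys >= 0 & ys <= 1
    xs[ok]
  })
  expect_gt(suppressWarnings(stats::ks.test(pos2$x, oracle))$p.value, 0.001)
})

test_that("Green's coefficient agrees with a brute-force histogram", {
  set.seed(33)
  for (i in 1:50) {
    n <- sample(50:2000, 1)
    if (i %% 3 == 0) {
      # clustered point sets exercise the upper range
      cx <- runif(1)
      cy <- runif(1)
      x <- pmin(pmax(cx + stats::rnorm(n, 0, 0.05), 0), 1)
      y <- pmin(pmax(cy + stats::rnorm(n, 0, 0.05), 0), 1)
    } else {
      x <- runif(n)
      y <- runif(n)
    }
    expect_equal(greens_coefficient(x, y), oracle_greens(x, y),
                 tolerance = 1e-12)
  }
})

test_that("Green's coefficient hits its closed-form landmarks", {
  # all points in one section -> exactly 1
  set.seed(34)
  x <- runif(200, 0.40, 0.49)
  y <- runif(200, 0.40, 0.49)
  expect_equal(greens_coefficient(x, y), 1)
  # alternating 2/0 over the 64 cells: G = (64/63 - 1)/63
  xs <- ys <- c()
  k <- 0
  for (i in 0:7) for (j in 0:7) {
    k <- k + 1
    if (k %% 2 == 0) next
    xs <- c(xs, rep(i / 8 + 0.05, 2))
    ys <- c(ys, rep(j / 8 + 0.05, 2))
  }
  expect_equal(greens_coefficient(xs, ys), (64 / 63 - 1) / 63)
  # uniform points ~ Poisson: G ~ 0
  gs <- replicate(20, greens_coefficient(runif(6400), runif(6400)))
  expect_lt(abs(mean(gs)), 0.002)
  # degenerate inputs
  expect_true(is.na(greens_coefficient(0.5, 0.5)))
  expect_true(is.na(greens_coefficient(numeric(), numeric())))
})

test_that("chase detection finds the earlier of G-max and wt-min", {
  # G peaks at t = 40, wild-type count bottoms at t = 43
  tt <- 1:100
  g <- 0.5 - abs(tt - 40) / 100
  wt <- 1000 + 30 * abs(tt - 43)
  expect_equal(detect_chase_start(g, wt, time = tt), 40)
  # monotone series (suppression without chasing): nothing to find
  expect_true(is.na(detect_chase_start(seq(0, 1, length.out = 60),
                                       seq(5000, 0, length.out = 60))))
  expect_true(is.na(detect_chase_start(rep(0.1, 60), rep(4000, 60))))
  # the reported time honours the time axis offset
  expect_equal(detect_chase_start(g, wt, time = tt + 7), 47)
})

test_that("outcomes classify by elimination, drive loss, and chasing", {
  rec <- function(n_last, dr_last, len = 200) tibble::tibble(
    generation = c(-1, seq_len(len)),
    n = c(10000, rep(8000, len - 1), n_last),
    dr = c(0, rep(500, len - 1), dr_last),
    fertile_females = c(5000, rep(2000, len))
  )
  out <- classify_outcome(rec(0, 0, 120), NA, max_time = 1000)
  expect_equal(as.character(out$outcome), "suppression_no_chase")
  out2 <- classify_outcome(rec(0, 0, 200), chase_start = 60, max_time = 1000)
  expect_equal(as.character(out2$outcome), "suppression_after_chase")
  expect_equal(out2$time_to_elimination_from_chase, 140)
  expect_equal(out2$chase_duration, 140)
  out3 <- classify_outcome(rec(8000, 600, 1000), chase_start = 55,
                           max_time = 1000)
  expect_equal(as.character(out3$outcome), "long_term_chase")
  out4 <- classify_outcome(rec(8000, 0, 300), chase_start = 50, max_time = 1000)
  expect_equal(as.character(out4$outcome), "drive_loss_after_chase")
  out5 <- classify_outcome(rec(8000, 0, 300), NA, max_time = 1000)
  expect_equal(as.character(out5$outcome), "drive_loss_no_chase")
  expect_equal(out2$fertile_female_ratio, 2000 / 5000)
})

test_that("spatial runs keep every position inside the arena and start
           with about K/2 fertile females", {
  run <- run_discrete_spatial("nosF3", capacity = 4000, max_time = 40,
                              burn_in = 5, seed = 35)
  rec <- tidy(run)
  pre <- rec[rec$generation == -1, ]
  expect_within_se(pre$fertile_females, pre$n / 2, sqrt(pre$n * 0.25))
  # dispersal redraw guarantees the arena bound; check via a raw step
  set.seed(36)
  p <- drivesim:::.pop(2000, spatial = TRUE)
  kids <- drivesim:::.step_spatial(p, drive_params("wildtype"), 2000, 10,
                                   0.2, 0.05)
  expect_true(all(kids$x >= 0 & kids$x <= 1 & kids$y >= 0 & kids$y <= 1))
})

test_that("with arena-wide interaction radii the spatial model collapses
           to the panmictic one", {
  # with arena-wide mating and a density radius large against the
  # dispersal scale, the spatial model should approach the panmictic one;
  # the residual census offset is the border band of the density circle
  k <- 2000
  run_sp <- run_discrete_spatial("wildtype", capacity = k, max_time = 40,
                                 migration = 2, density_radius = 0.05,
                                 seed = 37)
  run_pan <- run_discrete_panmictic("wildtype", capacity = k, max_time = 40,
                                    seed = 37)
  expect_lt(abs(mean(tidy(run_sp)$n) - mean(tidy(run_pan)$n)) / k, 0.10)
  sp2 <- run_discrete_spatial("nosF3", capacity = k, max_time = 80,
                              migration = 2, density_radius = 0.05,
                              seed = 38)
  pan2 <- run_discrete_panmictic("nosF3", capacity = k, max_time = 80,
                                 seed = 38)
  expect_equal(sp2$end, "elimination")
  expect_equal(pan2$end, "elimination")
})
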