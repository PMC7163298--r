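# Single-molecule tracking analytics: linking, D*, thresholds, survival
# fitting, bleach correction.

mk_locs <- function(frame, x, y, ws = 130, wl = 150) {
  data.frame(frame = frame, x_um = x, y_um = y,
             w_short_nm = ws, w_long_nm = wl, intensity = 1000)
}

test_that("consecutive localizations within the window form one track", {
  locs <- mk_locs(1:10, seq(0, 0.9, by = 0.1), rep(0, 10))
  tr <- link_tracks(locs)
  expect_equal(length(unique(tr$track_id)), 1L)
  expect_equal(nrow(tr), 10L)
})

test_that("a single missing frame is tolerated; two are not", {
  locs <- mk_locs(c(1:4, 6:9), rep(0.1 * (1:8)), rep(0, 8))
  expect_equal(length(unique(link_tracks(locs)$track_id)), 1L)
  expect_equal(length(unique(link_tracks(locs, max_gap = 0L)$track_id)), 2L)
  locs2 <- mk_locs(c(1:4, 7:9), rep(0, 7), rep(0, 7))
  expect_equal(length(unique(link_tracks(locs2)$track_id)), 2L)
})

test_that("conflicting links minimize the summed step distance", {
  # open tracks at x = 0 and 0.2; detections at 0.19 and 0.40: the greedy
  # closest-pair choice (0.2 -> 0.19) forces 0 -> 0.40 (sum 0.41); the
  # optimal assignment is 0 -> 0.19, 0.2 -> 0.40 (sum 0.39)
  locs <- rbind(mk_locs(1, c(0, 0.2), c(0, 0)),
                mk_locs(2, c(0.19, 0.40), c(0, 0)))
  tr <- link_tracks(locs, radius_um = 0.48)
  t1 <- tr$track_id[tr$frame == 1][order(tr$x_um[tr$frame == 1])]
  t2 <- tr$track_id[tr$frame == 2][order(tr$x_um[tr$frame == 2])]
  expect_equal(t1, t2) # 0 -> 0.19 and 0.2 -> 0.40
})

test_that("frame-to-frame assignment agrees with exhaustive enumeration", {
  for (seed in 1:30) {
    set.seed(seed)
    nr <- sample(1:5, 1); nc <- sample(1:5, 1)
    dm <- matrix(runif(nr * nc, 0, 1), nr, nc)
    got <- mukaxis:::assign_links(dm, radius = 0.6)
    want <- oracle_assignment(dm, radius = 0.6)
    expect_equal(sum(!is.na(got)), sum(!is.na(want)), info = paste("seed", seed))
    cost <- function(a) sum(dm[cbind(which(!is.na(a)), a[!is.na(a)])])
    expect_equal(cost(got), cost(want), tolerance = 1e-12,
                 info = paste("seed", seed))
  }
})

test_that("apparent diffusion follows the stepwise MSD formula", {
  # stationary track
  tr <- mk_locs(1:10, rep(1, 10), rep(2, 10))
  expect_equal(apparent_diffusion(tr, frame_time = 0.02), 0)
  # constant step length d every frame: D* = d^2 / (4 dt)
  d <- 0.05; dt <- 0.01548
  tr <- mk_locs(1:9, cumsum(rep(d, 9)), rep(0, 9))
  expect_equal(apparent_diffusion(tr, frame_time = dt), d^2 / (4 * dt))
  # shorter than min_steps -> omitted
  expect_true(is.na(apparent_diffusion(mk_locs(1:4, 1:4 * 0.1, rep(0, 4)),
                                       frame_time = dt)))
})

test_that("D* is invariant to translation/rotation and scales quadratically", {
  set.seed(2)
  x <- cumsum(rnorm(20, 0, 0.1)); y <- cumsum(rnorm(20, 0, 0.1))
  tr <- mk_locs(1:20, x, y)
  d0 <- apparent_diffusion(tr, 0.02)
  th <- 0.7
  tr_rot <- mk_locs(1:20, cos(th) * x - sin(th) * y + 5,
                    sin(th) * x + cos(th) * y - 3)
  expect_equal(apparent_diffusion(tr_rot, 0.02), d0)
  tr_scaled <- mk_locs(1:20, 2 * x, 2 * y)
  expect_equal(apparent_diffusion(tr_scaled, 0.02), 4 * d0)
})

test_that("D* of simulated Brownian tracks is unbiased within 3 percent", {
  set.seed(31)
  D <- 0.3; dt <- 0.02; nsteps <- 12L; ntracks <- 8000L
  dstars <- replicate(ntracks, {
    dx <- rnorm(nsteps, 0, sqrt(2 * D * dt)); dy <- rnorm(nsteps, 0, sqrt(2 * D * dt))
    sum(dx^2 + dy^2) / (4 * nsteps * dt)
  })
  expect_equal(mean(dstars), D, tolerance = 0.03)
  # same through the track interface on a subsample
  tr <- mk_locs(1:13, cumsum(c(0, rnorm(12, 0, sqrt(2 * D * dt)))),
                cumsum(c(0, rnorm(12, 0, sqrt(2 * D * dt)))))
  expect_true(is.finite(apparent_diffusion(tr, dt)))
})

test_that("bound threshold: reference quantile and packaged default", {
  expect_equal(bound_threshold(rep(0.1, 50)), 0.1)
  expect_equal(bound_threshold(), 0.0875)
  set.seed(4)
  expect_equal(bound_threshold(runif(1e5)), 0.05, tolerance = 0.05)
  expect_error(bound_threshold(numeric(0)), "empty")
})

test_that("bound fraction counts strictly-below-threshold molecules", {
  expect_equal(bound_fraction(c(0.01, 0.02), 0.1), 1)
  expect_equal(bound_fraction(c(0.01, 0.02), 0), 0)
  expect_error(bound_fraction(numeric(0), 0.1), "empty")
  # monotone in the threshold
  set.seed(8); d <- runif(500)
  th <- seq(0, 1, by = 0.1)
  expect_true(all(diff(vapply(th, bound_fraction, numeric(1), dstars = d)) >= 0))
})

test_that("spot-width filter removes wide spots with strict bounds", {
  locs <- data.frame(frame = 1:4, x_um = 0, y_um = 0,
                     w_short_nm = c(150, 150, 160, 100),
                     w_long_nm = c(190, 250, 199, 200))
  kept <- spot_width_filter(locs)
  expect_equal(kept$frame, 1L) # (150,190) kept; boundary/oversize removed
})

test_that("empirical survival is right-continuous with S(0) = 1", {
  s <- residency_survival(5)
  expect_equal(s$surv[s$t == 0], 1)
  expect_equal(s$surv[s$t == 5], 0)
  set.seed(10)
  x <- rexp(4000, 1 / 65)
  s <- residency_survival(x)
  expect_equal(s$surv[1L], 1)
  expect_true(all(diff(s$surv) <= 0))
  # close to the true exponential curve
  expect_lt(max(abs(s$surv - exp(-s$t / 65))), 0.04)
})

test_that("double-exponential fit recovers mixture parameters from a curve", {
  set.seed(12)
  n <- 10000L
  dur <- ifelse(runif(n) < 0.5, rexp(n, 1 / 2), rexp(n, 1 / 50))
  fit <- fit_double_exponential(residency_survival(dur))
  expect_equal(fit$tau_slow, 50, tolerance = 0.10)
  expect_equal(fit$tau_fast, 2, tolerance = 0.25)
  expect_gt(fit$A1, 0); expect_gt(fit$A2, 0)
  expect_gte(fit$tau_slow, fit$tau_fast)
  # cross-check against a maximum-likelihood oracle on the raw durations
  mle <- oracle_mixture_mle(dur)
  expect_equal(fit$tau_slow, mle$tau_slow, tolerance = 0.10)
})

test_that("single-exponential data yields the documented degenerate contract", {
  set.seed(13)
  dur <- rexp(8000, 1 / 30)
  fit <- fit_double_exponential(residency_survival(dur))
  degenerate_ok <- (fit$tau_slow / max(fit$tau_fast, 1e-9) < 2) ||
    (min(fit$A1 * fit$tau_fast, fit$A2 * fit$tau_slow) <
       0.10 * max(fit$A1 * fit$tau_fast, fit$A2 * fit$tau_slow))
  expect_true(degenerate_ok)
  expect_equal(fit$tau_dominant, 30, tolerance = 0.1)
  single <- fit_single_exponential(residency_survival(dur))
  expect_equal(single$tau, 30, tolerance = 0.05)
})

test_that("fit errors are informative on inadequate curves", {
  expect_error(fit_double_exponential(data.frame(t = 1:5, surv = 0.5)),
               "at least 10")
})

test_that("bleach correction follows t_meas * t_bleach / (t_bleach - t_meas)", {
  expect_equal(bleach_correct(28.2, 48.8), 28.2 * 48.8 / (48.8 - 28.2))
  expect_equal(bleach_correct(28.2, 48.8), 66.80, tolerance = 0.001)
  expect_equal(bleach_correct(30, Inf), 30)
  expect_error(bleach_correct(48.8, 48.8), "pole|uncorrectable")
  # exact inverse of the competing-rates identity: t_meas from 65 s binding
  # under 48.8 s bleaching corrects back to 65 s
  t_meas <- 1 / (1 / 65 + 1 / 48.8)
  expect_equal(bleach_correct(t_meas, 48.8), 65, tolerance = 1e-12)
})

test_that("mature fluorophore fraction follows 1/(1 + t_mat/t_gen)", {
  expect_equal(mature_fraction(11.9, 116), 1 / (1 + 11.9 / 116))
  expect_equal(round(mature_fraction(11.9, 116), 2), 0.91)
  expect_equal(mature_fraction(0, 100), 1)
  expect_equal(mature_fraction(100, 100), 0.5)
})
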