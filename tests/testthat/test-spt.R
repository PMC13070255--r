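# Trajectory filtering, MSD, MSS classification, confinement size.

test_that("precision and length filters match hand enumeration", {
  tr <- function(id, n, prec) {
    data.frame(id = id, frame = 0:(n - 1), x = rnorm(n, sd = 50),
               y = rnorm(n, sd = 50), precision = prec)
  }
  set.seed(1)
  tracks <- rbind(tr(1, 50, 10), tr(2, 50, 30), tr(3, 10, 10),
                  tr(4, 50, 24.9), tr(5, 50, 25.1))
  out <- filter_trajectories(tracks, max_precision_nm = 25, min_length = 20)
  expect_setequal(unique(out$id), c(1, 4))
  expect_equal(unname(attr(out, "removed")["precision"]), 2)
  expect_equal(unname(attr(out, "removed")["length"]), 1)

  all_good <- rbind(tr(1, 30, 10), tr(2, 30, 10))
  expect_equal(nrow(filter_trajectories(all_good)), 60)
})

test_that("msd matches the double-loop oracle and the two-point case", {
  two <- data.frame(id = 1, frame = 0:1, x = c(0, 100), y = c(0, 0))
  expect_equal(msd(two, max_lag_fraction = 0.5, frame_interval = 1)$msd,
               10000)

  still <- data.frame(id = 1, frame = 0:20, x = rep(3, 21), y = rep(-7, 21))
  expect_true(all(msd(still)$msd == 0))

  g <- gen_trajectories(motion_spec("brownian", n_tracks = 3,
                                    track_length = 60, seed = 14))
  for (i in 1:3) {
    tr <- g$tracks[g$tracks$id == i, ]
    m <- msd(tr)
    expect_equal(m$msd, oracle_msd(tr$x, tr$y, max(m$lag_frames)),
                 tolerance = 1e-12)
  }
})

test_that("diffusion fits recover D and absorb constant offsets", {
  D <- 0.05
  lag_s <- (1:10) * 0.1
  exact <- data.frame(lag_frames = 1:10, lag_s = lag_s,
                      msd = 4 * D * 1e6 * lag_s)
  expect_equal(diffusion_coefficient(exact), D, tolerance = 1e-12)
  offset <- exact
  offset$msd <- offset$msd + 4 * 20^2        # localization-error offset
  expect_equal(diffusion_coefficient(offset), D, tolerance = 1e-12)
  expect_error(diffusion_coefficient(exact[1, , drop = FALSE]), "2 lags")
})

test_that("MSS separates the three motion regimes", {
  gb <- gen_trajectories(motion_spec("brownian", D = 0.1, n_tracks = 60,
                                     track_length = 100,
                                     localization_error_sd = 20, seed = 41))
  res_b <- analyze_tracks(gb)
  expect_gt(mean(res_b$mss_slope), 0.4)
  expect_lt(mean(res_b$mss_slope), 0.6)

  # near-immobile track: slope ~ 0
  gi <- gen_trajectories(motion_spec("confined", D = 0.1,
                                     corral_diameter = 100, n_tracks = 20,
                                     track_length = 100,
                                     localization_error_sd = 10, seed = 42))
  res_i <- analyze_tracks(gi)
  expect_lt(mean(res_i$mss_slope), 0.1)
  expect_true(all(res_i$motion_class == "confined"))

  expect_equal(classify_motion(0.5), "free")
  expect_equal(classify_motion(0.1), "confined")
  expect_equal(classify_motion(0.8), "directed")
  expect_error(classify_motion(NaN), "finite")
})

test_that("confinement diameter is calibrated on the uniform disk", {
  # the projection constant itself, re-derived by numerical convolution
  x <- seq(-1, 1, length.out = 8001)
  f <- 2 * sqrt(pmax(0, 1 - x^2)) / pi
  f <- f / sum(f)
  g <- stats::convolve(f, f, type = "open")
  z <- abs(seq(-2, 2, length.out = length(g)))
  o <- order(z)
  cdf <- cumsum(g[o]) / sum(g)
  q90 <- z[o][min(which(cdf >= 0.9))] / 2    # unit-diameter disk
  expect_equal(q90, efferoquant:::UNIFORM_DISK_PROJ_Q90, tolerance = 2e-3)

  # many points uniform on a 200 nm disk -> estimate within 15% of 200
  set.seed(5)
  r <- 100 * sqrt(runif(800)); th <- runif(800, 0, 2 * pi)
  disk <- data.frame(id = 1, frame = 0:799,
                     x = r * cos(th), y = r * sin(th))
  est <- confinement_diameter(disk)
  expect_equal(est, 200, tolerance = 0.15)

  # rotation/translation invariance
  phi <- 0.7
  rot <- data.frame(id = 1, frame = disk$frame,
                    x = cos(phi) * disk$x - sin(phi) * disk$y + 5000,
                    y = sin(phi) * disk$x + cos(phi) * disk$y - 2000)
  expect_equal(confinement_diameter(rot), est, tolerance = 1e-9)

  still <- data.frame(id = 1, frame = 0:30, x = rep(1, 31), y = rep(2, 31))
  expect_warning(d0 <- confinement_diameter(still), "point-mass")
  expect_equal(d0, 0)
})

test_that("anisotropic confinement tracks the major axis", {
  set.seed(6)
  # ellipse: 300 nm major axis (x), 100 nm minor
  n <- 600
  pts <- matrix(NA_real_, 0, 2)
  while (nrow(pts) < n) {
    p <- cbind(runif(n, -150, 150), runif(n, -50, 50))
    keep <- (p[, 1] / 150)^2 + (p[, 2] / 50)^2 <= 1
    pts <- rbind(pts, p[keep, ])
  }
  tr <- data.frame(id = 1, frame = seq_len(n) - 1,
                   x = pts[1:n, 1], y = pts[1:n, 2])
  est <- confinement_diameter(tr)
  expect_gt(est, 250)
  expect_lt(est, 350)
})

test_that("class composition summaries count correctly", {
  gb <- gen_trajectories(motion_spec("brownian", n_tracks = 30,
                                     track_length = 100, seed = 51))
  res <- analyze_tracks(gb)
  res$motion_class <- "free"        # force homogeneity for the count check
  summ <- fraction_confined(res, seed = 1)
  expect_equal(summ$fraction[summ$motion_class == "free"], 1)
  expect_equal(summ$fraction[summ$motion_class == "confined"], 0)
  expect_error(fraction_confined(res[0, ]), "no results")

  # 50:50 mix
  gc <- gen_trajectories(motion_spec("confined", corral_diameter = 200,
                                     n_tracks = 30, track_length = 100,
                                     seed = 52))
  res2 <- rbind(analyze_tracks(gb), analyze_tracks(gc))
  summ2 <- fraction_confined(res2, seed = 2)
  frac_conf <- summ2$fraction[summ2$motion_class == "confined"]
  expect_equal(frac_conf, 0.5, tolerance = 0.12)
})
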