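# Generators: ground truth, invariants, determinism.

test_that("csr patterns have Poisson counts and CSR nearest-neighbour law", {
  spec <- pattern_spec(field_size = 10000, mode = "csr",
                       species_densities = c(0.4, 0.4),
                       localization_precision_sd = 0, seed = 101)
  pat <- gen_point_pattern(spec)
  nA <- sum(pat$table$species == "A")
  # Poisson(40): +-4 sd
  expect_gt(nA, 40 - 4 * sqrt(40))
  expect_lt(nA, 40 + 4 * sqrt(40))

  # NN distances of a dense CSR pattern follow 1 - exp(-lambda*pi*r^2)
  dense <- gen_point_pattern(pattern_spec(
    field_size = 10000, mode = "csr", species_densities = c(15, 15),
    localization_precision_sd = 0, seed = 7))
  A <- dense$table[dense$table$species == "A", ]
  d <- as.matrix(stats::dist(cbind(A$x, A$y)))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  expect_gt(nrow(A), 1000)
  lambda <- nrow(A) / 1e8          # per nm^2
  # mutual nearest neighbours tie exactly; the KS statistic is unaffected
  ks <- suppressWarnings(
    stats::ks.test(nn, function(r) 1 - exp(-lambda * pi * r^2)))
  expect_gt(ks$p.value, 0.01)
})

test_that("coclustered points stay near their cluster centres", {
  spec <- pattern_spec(mode = "coclustered", n_clusters = 20,
                       cluster_diameter = 120, cluster_occupancy = c(10, 10),
                       localization_precision_sd = 10, seed = 11)
  pat <- gen_point_pattern(spec)
  expect_equal(nrow(pat$table), 400)
  cen <- pat$centers
  dist_to_centre <- vapply(seq_len(nrow(pat$table)), function(i) {
    p <- pat$table[i, ]
    ci <- cen[cen$cluster == p$cluster & cen$species == p$species, ]
    sqrt((p$x - ci$x)^2 + (p$y - ci$y)^2)
  }, numeric(1))
  expect_true(all(dist_to_centre <= 60 + 4 * 10))
  expect_gte(mean(dist_to_centre <= 60 + 3 * 10), 0.99)
})

test_that("contacting clusters sit edge-to-edge at the configured gap", {
  spec <- pattern_spec(mode = "contacting", n_clusters = 10,
                       cluster_diameter = 120, contact_gap = 0,
                       localization_precision_sd = 0, seed = 3)
  pat <- gen_point_pattern(spec)
  cen <- pat$centers
  for (k in unique(cen$cluster)) {
    a <- cen[cen$cluster == k & cen$species == "A", ]
    b <- cen[cen$cluster == k & cen$species == "B", ]
    cc <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2)
    expect_equal(cc, 120, tolerance = 1e-9)   # centre dist = 2R + gap
  }
})

test_that("pattern generation is bit-identical for a fixed seed", {
  s <- pattern_spec(mode = "coclustered", seed = 42)
  expect_identical(gen_point_pattern(s), gen_point_pattern(s))
  expect_false(identical(
    gen_point_pattern(pattern_spec(mode = "csr", seed = 1))$table,
    gen_point_pattern(pattern_spec(mode = "csr", seed = 2))$table))
})

test_that("bleach traces are exact staircases at zero noise", {
  g <- gen_bleach_trace(trace_spec(n_steps = 3, unit_intensity = 100,
                                   noise_sd = 0, seed = 5))
  x <- g$trace$intensity
  drops <- which(diff(x) < 0)
  expect_length(g$step_frames, 3)
  expect_true(all(diff(x) <= 0))
  expect_setequal(g$trace$t[drops + 1], unique(g$step_frames))
  expect_equal(x[1], 300)
  expect_equal(x[length(x)], 0)

  flat <- gen_bleach_trace(trace_spec(n_steps = 0, baseline = 7, seed = 1))
  expect_true(all(flat$trace$intensity == 7))
  expect_length(flat$step_frames, 0)

  big <- gen_bleach_trace(trace_spec(n_steps = 28, noise_sd = 20, seed = 9))
  expect_length(big$step_frames, 28)
})

test_that("brownian trajectories obey the Einstein relation", {
  g <- gen_trajectories(motion_spec("brownian", D = 0.1, n_tracks = 200,
                                    track_length = 100,
                                    localization_error_sd = 0, seed = 21))
  # ensemble MSD at lag 1..5 vs 4 D tau
  msds <- sapply(split(g$tracks, g$tracks$id), function(tr) {
    msd(tr, max_lag_fraction = 0.05)$msd
  })
  lag_s <- (1:5) * 0.1
  ratio <- rowMeans(msds) / (4 * 0.1 * 1e6 * lag_s)
  expect_true(all(abs(ratio - 1) < 0.1))
})

test_that("confined trajectories stay in the corral and plateau at d^2/4", {
  g <- gen_trajectories(motion_spec("confined", D = 0.1,
                                    corral_diameter = 200, n_tracks = 200,
                                    track_length = 100,
                                    localization_error_sd = 0, seed = 22))
  r <- sqrt(g$tracks$true_x^2 + g$tracks$true_y^2)
  expect_true(all(r <= 100 + 1e-9))
  # long-lag ensemble MSD plateau ~ corral^2 / 4
  plateau <- mean(sapply(split(g$tracks, g$tracks$id), function(tr) {
    m <- msd(tr, max_lag_fraction = 0.5)
    mean(m$msd[m$lag_frames >= 20])
  }))
  expect_equal(plateau, 200^2 / 4, tolerance = 0.15)
})

test_that("zero-diffusivity tracks only jitter by localization error", {
  g <- gen_trajectories(motion_spec("brownian", D = 0, n_tracks = 5,
                                    track_length = 50,
                                    localization_error_sd = 15, seed = 2))
  expect_true(all(g$tracks$true_x == 0 & g$tracks$true_y == 0))
  expect_lt(max(abs(g$tracks$x)), 15 * 6)
})

test_that("directed tracks drift at the configured velocity", {
  g <- gen_trajectories(motion_spec("directed", D = 0.01, velocity = 1,
                                    n_tracks = 50, track_length = 100,
                                    localization_error_sd = 0, seed = 31))
  disp <- sapply(split(g$tracks, g$tracks$id), function(tr) {
    sqrt((tr$true_x[100] - tr$true_x[1])^2 + (tr$true_y[100] - tr$true_y[1])^2)
  })
  # 99 frames at 100 nm/frame drift
  expect_equal(mean(disp), 9900, tolerance = 0.05)
})

test_that("the FRET forward model and estimator are mutual inverses", {
  co <- fret_coefficients(alpha = 0.05, beta = 0.12, gamma = 0.18,
                          background = c(50, 40, 60))
  set.seed(1)
  E <- matrix(runif(400, 0, FITC_ORB_EMAX), 20, 20)
  st <- gen_fret_stack(fret_forward_spec(
    E, matrix(800, 20, 20), matrix(1000, 20, 20), co, noise_sd = 0))
  mp <- compute_ea(st, co)
  expect_lt(max(abs(mp$E_A - E)), 1e-10)

  # donor-only control: Iaa is background only
  d_only <- gen_fret_stack(fret_forward_spec(
    E * 0, matrix(800, 20, 20), matrix(0, 20, 20), co, noise_sd = 0))
  expect_true(all(d_only$Iaa == 60))
})

test_that("uptake scenes carry exact ground truth", {
  sc <- gen_uptake_scene(2, 3, 2, seed = 8)
  expect_equal(sc$truth$index, 3)
  expect_equal(sc$truth$bound, 2)
  expect_equal(sum(sc$targets$internal), 6)
  # dye channel integrates to dye_per_target per target
  expect_equal(sum(sc$channels$dye), 10 * 1000, tolerance = 1e-9)
  empty <- gen_uptake_scene(2, 0, 1, seed = 9)
  expect_equal(empty$truth$index, 0)
})
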