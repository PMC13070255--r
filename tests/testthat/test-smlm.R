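# Radial distribution, randomization and OPTICS cluster relations.

test_that("G(r) matches the hand-computed toy annulus counts", {
  # one reference at field centre; targets at 50 and 300 nm
  ref <- data.frame(x = 500, y = 500)
  tgt <- data.frame(x = c(550, 800), y = c(500, 500))
  roi <- rect_roi(1000, 1000)
  rd <- radial_distribution(ref, tgt, bins = c(0, 100, 400), roi)
  lambda <- 2 / 1e6
  expect_equal(rd$g[1], 1 / (lambda * pi * 100^2))
  expect_equal(rd$g[2], 1 / (lambda * pi * (400^2 - 100^2)))
  expect_equal(rd$g_scaled, c(1, 0))
})

test_that("grid-accelerated G(r) equals the brute-force oracle exactly", {
  roi <- rect_roi(3000, 3000)
  bins <- seq(0, 400, by = 50)
  for (k in 1:20) {
    set.seed(k)
    ref <- data.frame(x = runif(sample(20:250, 1), 0, 3000),
                      y = runif(1, 0, 3000))
    n_r <- nrow(ref)
    ref$y <- runif(n_r, 0, 3000)
    tgt <- data.frame(x = runif(sample(20:250, 1), 0, 3000),
                      y = runif(1, 0, 3000))
    tgt$y <- runif(nrow(tgt), 0, 3000)
    rd <- radial_distribution(ref, tgt, bins, roi)
    expect_equal(rd$g, oracle_gr(ref, tgt, bins, roi), tolerance = 1e-12)
  }
})

test_that("independent CSR species give flat G(r) near 1", {
  devs <- sapply(1:3, function(s) {
    pat <- gen_point_pattern(pattern_spec(
      field_size = 10000, mode = "csr", species_densities = c(50, 50),
      localization_precision_sd = 0, seed = 600 + s))
    A <- pat$table[pat$table$species == "A", ]
    B <- pat$table[pat$table$species == "B", ]
    rd <- radial_distribution(A, B, seq(0, 500, 10), pat$roi)
    mean(rd$g, na.rm = TRUE)
  })
  expect_lt(abs(mean(devs) - 1), 0.05)
})

test_that("coclustered patterns are enriched at short range, above the envelope", {
  pat <- gen_point_pattern(pattern_spec(
    mode = "coclustered", field_size = 10000, n_clusters = 20,
    cluster_diameter = 120, cluster_occupancy = c(10, 10), seed = 2))
  A <- pat$table[pat$table$species == "A", ]
  B <- pat$table[pat$table$species == "B", ]
  bins <- seq(0, 500, 25)
  rd <- radial_distribution(A, B, bins, pat$roi)
  env <- mc_envelope(A, B, bins, pat$roi, n_reps = 50, seed = 3)
  short <- rd$r_hi <= 100
  expect_true(all(rd$g[short] > 10))          # strong enrichment below 100 nm
  expect_true(all(rd$g[short] > env$high[short]))
})

test_that("position randomization is uniform, label-preserving, seeded", {
  pat <- gen_point_pattern(pattern_spec(mode = "coclustered", seed = 4))
  roi <- pat$roi
  r1 <- randomize_positions(pat$table, roi, seed = 9)
  r2 <- randomize_positions(pat$table, roi, seed = 9)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), nrow(pat$table))
  expect_identical(r1$species, pat$table$species)

  # pooled quadrant counts over several seeds are uniform
  counts <- c(0, 0, 0, 0)
  for (s in 1:10) {
    r <- randomize_positions(pat$table, roi, seed = s)
    q <- 1 + (r$x > 5000) + 2 * (r$y > 5000)
    counts <- counts + tabulate(q, 4)
  }
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)

  empty <- pat$table[0, ]
  expect_equal(nrow(randomize_positions(empty, roi, seed = 1)), 0)
})

test_that("the envelope requires enough replicates", {
  pat <- gen_point_pattern(pattern_spec(mode = "csr", seed = 4))
  A <- pat$table[pat$table$species == "A", ]
  B <- pat$table[pat$table$species == "B", ]
  expect_error(mc_envelope(A, B, roi = pat$roi, n_reps = 1), "n_reps")
})

test_that("OPTICS extraction matches single-linkage components on blobs", {
  set.seed(12)
  blob <- function(cx, cy, n = 10) {
    data.frame(x = cx + rnorm(n, 0, 15), y = cy + rnorm(n, 0, 15))
  }
  tab <- rbind(blob(0, 0), blob(1000, 1000))
  tab$species <- "A"; tab$frame <- 0L; tab$precision <- 5
  cs <- extract_clusters(tab, min_points = 5, max_reach_nm = 60)
  expect_length(cs$clusters, 2)
  sl <- oracle_single_linkage(tab$x, tab$y, 60)
  for (cl in cs$clusters) {
    expect_length(unique(sl[cl$members]), 1)
  }
  expect_setequal(unlist(lapply(cs$clusters, `[[`, "members")), 1:20)
})

test_that("sparse CSR points are mostly noise; blob diameter is recovered", {
  pat <- gen_point_pattern(pattern_spec(
    mode = "csr", species_densities = c(0.4, 0.4),
    localization_precision_sd = 0, seed = 31))
  A <- pat$table[pat$table$species == "A", ]
  cs <- extract_clusters(A, min_points = 10, max_reach_nm = 50)
  expect_gte(length(cs$noise) / nrow(A), 0.9)

  one <- gen_point_pattern(pattern_spec(
    mode = "coclustered", n_clusters = 1, cluster_diameter = 120,
    cluster_occupancy = c(60, 60), localization_precision_sd = 5, seed = 8))
  cs1 <- extract_clusters(one$table, min_points = 5, max_reach_nm = 60)
  expect_length(cs1$clusters, 1)
  expect_equal(cs1$clusters[[1]]$diameter, 120, tolerance = 2 * 5 * 4 / 120)
})

test_that("cluster relations classify the constructed 3-cluster layout exactly", {
  # B: one 100x100 nm dense cluster; A: one intermixed, one at 10 nm edge
  # gap, one 1 um away; contact_dist 20 nm -> (1/3, 1/3, 1/3)
  b_tab <- grid_points(0, 100, 0, 100)
  a_tab <- rbind(grid_points(20, 80, 20, 80),
                 grid_points(110, 210, 0, 100),
                 grid_points(1200, 1300, 1200, 1300))
  ca <- extract_clusters(a_tab, min_points = 3, max_reach_nm = 15)
  cb <- extract_clusters(b_tab, min_points = 3, max_reach_nm = 15)
  expect_length(ca$clusters, 3)
  rel <- classify_cluster_relations(ca, cb, contact_dist_nm = 20,
                                    intermix_frac = 0.5)
  expect_equal(rel$colocalized_fraction, 1 / 3)
  expect_equal(rel$contacting_fraction, 1 / 3)
  expect_equal(rel$neither_fraction, 1 / 3)
  expect_equal(rel$colocalized_fraction + rel$contacting_fraction +
                 rel$neither_fraction, 1, tolerance = 1e-9)
})

test_that("identical cluster sets are fully colocalized; distant ones are neither", {
  tab <- grid_points(0, 100, 0, 100)
  cs <- extract_clusters(tab, min_points = 3, max_reach_nm = 15)
  rel <- classify_cluster_relations(cs, cs)
  expect_equal(rel$colocalized_fraction, 1)

  far <- grid_points(5000, 5100, 5000, 5100)
  cf <- extract_clusters(far, min_points = 3, max_reach_nm = 15)
  rel2 <- classify_cluster_relations(cs, cf, contact_dist_nm = 20)
  expect_equal(rel2$neither_fraction, 1)
})

test_that("cluster relations are invariant under rotation and translation", {
  pat <- gen_point_pattern(pattern_spec(
    mode = "contacting", n_clusters = 8, contact_gap = 5,
    cluster_occupancy = c(30, 30), localization_precision_sd = 2, seed = 17))
  A <- pat$table[pat$table$species == "A", ]
  B <- pat$table[pat$table$species == "B", ]
  rel0 <- classify_cluster_relations(
    extract_clusters(A, 5, 60), extract_clusters(B, 5, 60))
  th <- 33 * pi / 180
  rot <- function(df, dx, dy) {
    out <- df
    out$x <- cos(th) * df$x - sin(th) * df$y + dx
    out$y <- sin(th) * df$x + cos(th) * df$y + dy
    out
  }
  rel1 <- classify_cluster_relations(
    extract_clusters(rot(A, 777, -333), 5, 60),
    extract_clusters(rot(B, 777, -333), 5, 60))
  expect_equal(rel1$colocalized_fraction, rel0$colocalized_fraction)
  expect_equal(rel1$contacting_fraction, rel0$contacting_fraction)
  expect_equal(rel1$neither_fraction, rel0$neither_fraction)
})

test_that("randomized baselines do not exceed observed co-clustering", {
  pat <- gen_point_pattern(pattern_spec(
    mode = "coclustered", field_size = 10000, n_clusters = 15,
    cluster_occupancy = c(50, 50), seed = 2))
  A <- pat$table[pat$table$species == "A", ]
  B <- pat$table[pat$table$species == "B", ]
  rel <- classify_cluster_relations(
    extract_clusters(A, 5, 60), extract_clusters(B, 5, 60),
    roi = pat$roi, seed = 5)
  expect_equal(rel$colocalized_fraction, 1)
  expect_lte(rel$randomized_colocalized, rel$colocalized_fraction)
  expect_lte(rel$randomized_contacting + rel$randomized_colocalized,
             rel$colocalized_fraction + rel$contacting_fraction)
})
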