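# Sensitized-emission FRET: coefficients, E_A, masking, ROI summaries.

mk <- function(v, n = 32) matrix(v, n, n)

test_that("coefficients equal their defining ratios on ideal controls", {
  # controls carry a flat background of 10 counts in every channel
  Idd <- mk(500)
  donor_only <- fret_stack(Idd = Idd + 10, Ida = 0.1 * Idd + 10,
                           Iaa = mk(10))
  Iaa <- mk(1000)
  acceptor_only <- fret_stack(Idd = 0.05 * Iaa + 10, Ida = 0.2 * Iaa + 10,
                              Iaa = Iaa + 10)
  set.seed(2)
  unstained <- fret_stack(Idd = mk(rnorm(1024, 10, 1)),
                          Ida = mk(rnorm(1024, 10, 1)),
                          Iaa = mk(rnorm(1024, 10, 1)))
  co <- estimate_coefficients(donor_only, acceptor_only, unstained)
  expect_equal(co$beta, 0.1, tolerance = 0.02)
  expect_equal(co$alpha, 0.05, tolerance = 0.02)
  expect_equal(co$gamma, 0.2, tolerance = 0.02)
  expect_equal(co$background, rep(10, 3), tolerance = 0.05)
})

test_that("coefficients are recovered within 2% from noisy forward-model controls", {
  true <- fret_coefficients(alpha = 0.05, beta = 0.12, gamma = 0.18,
                            background = c(50, 40, 60),
                            background_sd = c(2, 2, 2))
  z <- mk(0, 64)
  donor_only <- gen_fret_stack(fret_forward_spec(
    z, mk(800, 64), z, true, noise_sd = 5, seed = 3))
  acceptor_only <- gen_fret_stack(fret_forward_spec(
    z, z, mk(1000, 64), true, noise_sd = 5, seed = 4))
  unstained <- gen_fret_stack(fret_forward_spec(
    z, z, z, true, noise_sd = 5, seed = 5))
  est <- estimate_coefficients(donor_only, acceptor_only, unstained)
  expect_equal(est$alpha, 0.05, tolerance = 0.02)
  expect_equal(est$beta, 0.12, tolerance = 0.02)
  expect_equal(est$gamma, 0.18, tolerance = 0.02)
  # delta's defining ratio on acceptor-only cells is alpha/gamma
  expect_equal(est$delta, 0.05 / 0.18, tolerance = 0.02)
})

test_that("E_A reproduces the true efficiency and respects the clamp", {
  co <- fret_coefficients(alpha = 0.05, beta = 0.12, gamma = 0.18)
  st0 <- gen_fret_stack(fret_forward_spec(mk(0), mk(800), mk(1000), co))
  expect_true(all(abs(compute_ea(st0, co)$E_A) < 1e-12))

  st2 <- gen_fret_stack(fret_forward_spec(mk(0.2), mk(800), mk(1000), co))
  expect_equal(as.vector(compute_ea(st2, co)$E_A), rep(0.2, 1024),
               tolerance = 1e-12)

  # heavy noise: clamp holds on every defined pixel
  stn <- gen_fret_stack(fret_forward_spec(mk(0.3), mk(800), mk(1000), co,
                                          noise_sd = 300, seed = 6))
  ea <- compute_ea(stn, co)$E_A
  expect_true(all(ea[!is.na(ea)] <= FITC_ORB_EMAX + 1e-12))
  expect_true(all(ea[!is.na(ea)] >= 0))
})

test_that("E_A is invariant under uniform intensity rescaling", {
  co <- fret_coefficients(alpha = 0.05, beta = 0.12, gamma = 0.18)
  st <- gen_fret_stack(fret_forward_spec(mk(0.15), mk(500), mk(900), co,
                                         noise_sd = 10, seed = 8))
  sc <- fret_stack(Idd = st$Idd * 3.7, Ida = st$Ida * 3.7,
                   Iaa = st$Iaa * 3.7)
  expect_equal(compute_ea(sc, co)$E_A, compute_ea(st, co)$E_A,
               tolerance = 1e-12)
})

test_that("the Otsu AND mask matches construction and footprints", {
  half <- matrix(0, 40, 40); half[1:20, ] <- 1
  m <- build_mask(half, half)
  expect_true(all(m[1:21, ]))        # bright half plus one dilated column
  expect_false(any(m[23:40, ]))

  a <- matrix(0, 40, 40); a[1:10, ] <- 1
  b <- matrix(0, 40, 40); b[30:40, ] <- 1
  expect_false(any(build_mask(a, b)))

  expect_error(build_mask(matrix(1, 5, 5), matrix(1, 5, 5)), "constant")

  # synthetic cell footprint recovered with Jaccard >= 0.9
  foot <- matrix(FALSE, 96, 96); foot[25:72, 25:72] <- TRUE
  co <- fret_coefficients(alpha = 0.05, beta = 0.12, gamma = 0.18)
  st <- gen_fret_stack(fret_forward_spec(
    matrix(0.1, 96, 96), 800 * foot, 1000 * foot, co,
    noise_sd = 20, seed = 9))
  msk <- build_mask(st$Iaa, st$Idd)
  expect_gte(sum(msk & foot) / sum(msk | foot), 0.9)
})

test_that("ROI quantification averages masked E_A; activation lowers FRET", {
  co <- fret_coefficients(alpha = 0.05, beta = 0.12, gamma = 0.18)
  # efferocytic-cup scene: E = 0.05 inside the cup disk (active, extended
  # integrins), 0.25 outside (inactive, bent, high FRET)
  n <- 64; px <- 100
  cx <- (col(mk(0, n)) * 0 + seq_len(n) - 0.5) * px
  E <- mk(0.25, n)
  centre <- c(32.5 * px, 32.5 * px)
  xs <- (row(E) - 0.5) * px; ys <- (col(E) - 0.5) * px
  cup <- (xs - centre[1])^2 + (ys - centre[2])^2 <= (12 * px)^2
  E[cup] <- 0.05
  st <- gen_fret_stack(fret_forward_spec(E, mk(800, n), mk(1000, n), co,
                                         noise_sd = 5, seed = 10))
  # mask away the top rows; both ROIs below stay masked-in
  manual_mask <- matrix(TRUE, n, n); manual_mask[, 61:64] <- FALSE
  mp <- apply_mask(compute_ea(st, co), manual_mask)
  expect_true(all(is.na(mp$E_A[, 61:64])))
  cup_roi <- efferoquant:::as_polygon(cbind(
    centre[1] + 10 * px * cos(seq(0, 2 * pi, length.out = 33)[-33]),
    centre[2] + 10 * px * sin(seq(0, 2 * pi, length.out = 33)[-33])))
  outside_roi <- rect_roi(1200, 1200, origin = c(100, 100))
  in_cup <- roi_fret(mp, cup_roi)
  out_cup <- roi_fret(mp, outside_roi)
  expect_equal(in_cup$mean_ea, 0.05, tolerance = 0.01)
  expect_equal(out_cup$mean_ea, 0.25, tolerance = 0.01)
  expect_lt(in_cup$mean_ea, out_cup$mean_ea)   # activation = E_A decrease

  # display conversion is monotone decreasing in E_A
  disp <- activation_display(mp)
  o <- order(mp$E_A[!is.na(mp$E_A)])
  dv <- disp[!is.na(mp$E_A)][o]
  expect_true(all(diff(dv) <= 0))

  # ROI fully outside the mask errors
  expect_error(roi_fret(mp, rect_roi(400, 300, origin = c(100, 6050))),
               "intersect")
})
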