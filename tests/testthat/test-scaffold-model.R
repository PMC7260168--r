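# Rigid-scaffold model: optimal tube radius against a grid search, the
# tether limit, phase boundary self-consistency and agreement with
# brute-force classification, critical-radius behavior, and the
# binding-energy bound with its monotonicity and scale invariance.

test_that("optimal tube radius approaches the tether radius for a straight scaffold", {
  m <- membrane_params(10, 0.02)
  h <- helix_spec(1e-4, 1e5)   # essentially straight centerline
  r <- suppressWarnings(optimal_tube_radius(h, m))
  expect_equal(as.numeric(r), sqrt(10 / (2 * 0.02)), tolerance = 1e-4)
})

test_that("optimal tube radius agrees with a dense grid search", {
  h <- helix_spec(29.2, 8.451)
  m <- membrane_params(10, 0.02)
  r_opt <- optimal_tube_radius(h, m)
  kc <- helix_curvature(h)
  grid <- seq(0.5, 0.99 / kc, length.out = 20000)
  es <- vapply(grid, function(r) helical_tube_energy_per_axial(
    suppressWarnings(tube_geometry(h, r)), m), numeric(1))
  expect_equal(as.numeric(r_opt), grid[which.min(es)], tolerance = 1e-3)
  # bracketing certificate: energies at the bracket ends exceed the optimum
  br <- attr(r_opt, "bracket")
  e_at <- function(r) helical_tube_energy_per_axial(
    suppressWarnings(tube_geometry(h, r)), m)
  expect_gt(e_at(br[1] + 1e-6), e_at(as.numeric(r_opt)))
  expect_gt(e_at(br[2] - 1e-6), e_at(as.numeric(r_opt)))
})

test_that("optimal tube radius strictly decreases when tension doubles", {
  h <- helix_spec(29.2, 8.451)
  r1 <- as.numeric(optimal_tube_radius(h, membrane_params(10, 0.01)))
  r2 <- as.numeric(optimal_tube_radius(h, membrane_params(10, 0.02)))
  expect_lt(r2, r1)
})

test_that("shape preference follows the binding energy at its extremes", {
  h <- helix_spec(29.2, 8.451)
  m <- membrane_params(10, 0.02)
  # mu = 0 at moderate tension: nothing pays for the membrane cost of helicity
  s0 <- shape_preference(h, m, binding_config(0))
  expect_identical(s0$state, "straight")
  expect_gt(s0$gap, 0)
  # huge mu: helical
  s1 <- shape_preference(h, m, binding_config(100))
  expect_identical(s1$state, "helical")
  # and helical at high tension even with mu = 0 (thin tube beats the
  # radius-R cylinder on area)
  s2 <- shape_preference(h, membrane_params(10, 1), binding_config(0))
  expect_identical(s2$state, "helical")
})

test_that("the gap vanishes on the computed phase boundary", {
  h <- helix_spec(29.2, 8.451)
  p <- h$reduced_pitch_P / h$radius_R
  kappa <- 10
  for (Sigma in c(1, 5, 12, 20)) {
    M <- phase_boundary(Sigma, p)
    if (M == 0) next
    m <- membrane_params(kappa, Sigma * kappa / h$radius_R^2)
    b <- binding_config(mu_per_length = M * kappa / h$radius_R)
    s <- shape_preference(h, m, b)
    expect_lt(abs(s$gap) / s$energy_straight, 1e-7)
  }
})

test_that("phase boundary matches brute-force grid classification", {
  h <- helix_spec(29.2, 8.451)
  p <- h$reduced_pitch_P / h$radius_R
  kappa <- 10
  sig_grid <- seq(0.5, 28, length.out = 20)
  mb <- phase_boundary(sig_grid, p)
  for (i in seq_along(sig_grid)) {
    m <- membrane_params(kappa, sig_grid[i] * kappa / h$radius_R^2)
    for (dM in c(-0.05, 0.05)) {
      M <- mb[i] + dM
      if (M < 0) next
      s <- shape_preference(h, m,
                            binding_config(M * kappa / h$radius_R))
      expect_identical(s$state, if (dM > 0) "helical" else "straight")
    }
  }
})

test_that("phase boundary is non-increasing on the falling branch and zero at high tension", {
  p <- fixture_shape_ratio()
  lm <- escrtube:::gap_landmarks(p)
  sig <- seq(lm$sigma_peak, lm$sigma0 * 1.3, length.out = 25)
  mb <- phase_boundary(sig, p)
  expect_true(all(diff(mb) <= 1e-9))
  expect_identical(mb[length(mb)], 0)
})

test_that("critical radius is consistent with the boundary and monotone", {
  p <- fixture_shape_ratio()
  M_max <- always_helical_threshold(p)
  Ms <- seq(0.2, M_max * 0.98, length.out = 8)
  rcs <- vapply(Ms, critical_radius, numeric(1), h_shape = p)
  # r_c grows with the binding energy and is maximal just below threshold
  expect_true(all(diff(rcs) > 0))
  # r_c equals the optimal radius at the boundary tension (definition)
  h <- helix_spec(29.2, 8.451)
  kappa <- 10
  M <- Ms[4]
  lm <- escrtube:::gap_landmarks(p)
  a_dl <- sqrt(1 + p^2) / p
  sigma_b <- uniroot(function(S) escrtube:::gap0_dl(S, p) - M * 4 * a_dl,
                     c(lm$sigma_peak, lm$sigma0 * 2), tol = 1e-12)$root
  r_star <- optimal_tube_radius(h, membrane_params(kappa,
                                                   sigma_b * kappa / h$radius_R^2))
  expect_equal(rcs[4], as.numeric(r_star) / h$radius_R, tolerance = 1e-5)
  # along the boundary, r_c is non-increasing in tension
  sig <- seq(lm$sigma_peak, lm$sigma0, length.out = 15)
  rho <- vapply(sig, function(S) as.numeric(escrtube:::rho_opt_dl(S, p)),
                numeric(1))
  expect_true(all(diff(rho) < 0))
  expect_error(critical_radius(M_max * 1.01, p),
               class = "escrtube_always_helical")
})

test_that("the binding-energy bound responds correctly to the observed radius", {
  h <- helix_spec(29.2, 8.451)
  b <- binding_config()
  m <- membrane_params(10, 0.01)
  # thin observed tubes are unconstraining
  tiny <- min_mu_for_observed(2, h, b, m)
  expect_identical(tiny$mu_rescaled, 0)
  expect_identical(tiny$regime, "unconstrained")
  # the bound is non-decreasing in r_exp
  r_grid <- c(2, 5, 6, 7, 8, 10, 12.1, 15)
  bounds <- vapply(r_grid, function(r)
    min_mu_for_observed(r, h, b, m)$mu_per_monomer, numeric(1))
  expect_true(all(diff(bounds) >= 0))
  # mid-range radii invert the critical-radius curve
  mid <- min_mu_for_observed(6, h, b, m)
  expect_identical(mid$regime, "boundary")
  expect_equal(critical_radius(mid$mu_rescaled, h$reduced_pitch_P / h$radius_R),
               6 / 29.2, tolerance = 1e-6)
  # radii beyond the zero-tension optimum are unattainable
  expect_error(min_mu_for_observed(25, h, b, m),
               class = "escrtube_infeasible")
})

test_that("the bound scales like kappa/R and linearly with the monomer arc", {
  h <- helix_spec(29.2, 8.451)
  b <- binding_config()
  bound1 <- min_mu_for_observed(12.1, h, b, membrane_params(10, 0.01))
  bound2 <- min_mu_for_observed(12.1, h, b, membrane_params(20, 0.01))
  expect_equal(bound2$mu_per_monomer, 2 * bound1$mu_per_monomer,
               tolerance = 1e-9)
  b2 <- binding_config(monomer_arc = 2 * b$monomer_arc)
  bound3 <- min_mu_for_observed(12.1, h, b2, membrane_params(10, 0.01))
  expect_equal(bound3$mu_per_monomer, 2 * bound1$mu_per_monomer,
               tolerance = 1e-9)
})

test_that("rescaled model-1 outputs are invariant under joint length rescaling", {
  set.seed(3)
  p <- fixture_shape_ratio()
  for (s in c(0.25, 3, 17)) {
    h1 <- helix_spec(29.2, 29.2 * p)
    h2 <- helix_spec(29.2 * s, 29.2 * s * p)
    kappa <- 10
    # same Sigma in both systems
    Sigma <- 4.4
    m1 <- membrane_params(kappa, Sigma * kappa / h1$radius_R^2)
    m2 <- membrane_params(kappa, Sigma * kappa / h2$radius_R^2)
    r1 <- as.numeric(optimal_tube_radius(h1, m1)) / h1$radius_R
    r2 <- as.numeric(optimal_tube_radius(h2, m2)) / h2$radius_R
    expect_equal(r1, r2, tolerance = 1e-6)
    # rescaled bound at matched rescaled observed radius
    b <- binding_config()
    m_1 <- min_mu_for_observed(0.25 * h1$radius_R, h1, b, m1)$mu_rescaled
    m_2 <- min_mu_for_observed(0.25 * h2$radius_R, h2, b, m2)$mu_rescaled
    expect_equal(m_1, m_2, tolerance = 1e-7)
  }
})

test_that("phase diagram labels, boundary and critical radii are mutually consistent", {
  p <- fixture_shape_ratio()
  pd <- phase_diagram(p, n = 25)
  # labels vs boundary: helical iff mu >= boundary at that tension
  for (i in seq_len(nrow(pd$grid))) {
    mb <- pd$boundary$mu_boundary[
      pd$boundary$sigma_rescaled == pd$grid$sigma_rescaled[i]]
    expect_identical(pd$grid$label[i],
                     if (pd$grid$mu_rescaled[i] >= mb) "helical" else "straight")
  }
  # the r_c curve on the boundary equals the optimal rescaled radius
  j <- which(pd$boundary$mu_boundary > 0)[5]
  expect_equal(pd$boundary$r_c_over_R[j],
               as.numeric(escrtube:::rho_opt_dl(pd$boundary$sigma_rescaled[j],
                                                p)),
               tolerance = 1e-9)
})
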