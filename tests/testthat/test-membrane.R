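# Membrane energetics: pointwise canal-surface quantities, the cylinder
# closed form, the brute-force surface-integral oracle, and the qualitative
# structure of the energy (torsion independence, helicity cost,
# monotonicity in material parameters).

test_that("canal mean curvature and area element match frozen values", {
  expect_equal(canal_mean_curvature(10, 0, 1.3), 0.1)
  expect_equal(canal_mean_curvature(11.95, 0.03160, pi / 2), 1 / 11.95,
               tolerance = 1e-12)
  expect_equal(canal_mean_curvature(11.95, 0.03160, 0), 0.032907,
               tolerance = 1e-4)
  expect_equal(area_element(7, 0, 2.2), 7)
  expect_equal(area_element(11.95, 0.03160, 0), 7.438, tolerance = 1e-3)
  expect_error(canal_mean_curvature(40, 0.03, 0),
               class = "escrtube_embedding_error")
})

test_that("area element integrates to 2 pi r for any admissible curvature", {
  for (kc in c(0, 0.01, 0.05)) {
    val <- integrate(function(phi) area_element(11.95, kc, phi), 0, 2 * pi,
                     rel.tol = 1e-10)$value
    expect_equal(val, 2 * pi * 11.95, tolerance = 1e-8)
  }
})

test_that("quadrature reduces to the cylinder closed form at zero curvature", {
  m <- membrane_params(1, 0)
  # nearly-straight centerline: energy per centerline length -> pi*kappa/r
  t <- tube_geometry(helix_spec(1e-5, 1e4), 10)
  e <- helical_tube_energy_per_axial(t, m) / arc_per_axial(t$centerline)
  expect_equal(e, pi / 10, tolerance = 1e-8)
  m2 <- membrane_params(2.5, 0.03)
  e2 <- helical_tube_energy_per_axial(tube_geometry(helix_spec(1e-5, 1e4), 7),
                                      m2)
  expect_equal(e2, pi * 2.5 / 7 + 2 * pi * 0.03 * 7, tolerance = 1e-8)
})

test_that("straight-tube energy matches the closed form and the tether radius", {
  expect_equal(straight_tube_energy_per_axial(29.2, membrane_params(1, 0)),
               0.10758, tolerance = 1e-4)
  # tether: at sigma = kappa/(2 R^2) the energy is stationary at R
  m <- membrane_params(1, 0.5)
  expect_equal(straight_tube_energy_per_axial(1, m), 2 * pi)
  rs <- seq(0.5, 2, by = 0.01)
  es <- vapply(rs, straight_tube_energy_per_axial, numeric(1), m = m)
  expect_equal(rs[which.min(es)], 1, tolerance = 0.02)
})

test_that("helical tube energy agrees with the shape-operator surface oracle", {
  t <- fixture_tube()
  h <- t$centerline
  m <- membrane_params(10, 0.01)
  e_quad <- helical_tube_energy_per_axial(t, m)
  e_oracle <- canal_energy_oracle(h$radius_R, h$reduced_pitch_P,
                                  t$tube_radius_r, 10, 0.01)
  expect_equal(e_quad, e_oracle, tolerance = 1e-6)
})

test_that("energy per centerline length depends on the centerline only through curvature", {
  # two helices with equal curvature, different torsion
  h1 <- helix_from_curvature_torsion(0.03, 0.01)
  h2 <- helix_from_curvature_torsion(0.03, 0.02)
  m <- membrane_params(8, 0.02)
  e1 <- helical_tube_energy_per_axial(tube_geometry(h1, 9), m) /
    arc_per_axial(h1)
  e2 <- helical_tube_energy_per_axial(tube_geometry(h2, 9), m) /
    arc_per_axial(h2)
  expect_equal(e1, e2, tolerance = 1e-10)
})

test_that("helicity always costs membrane energy at equal tube radius", {
  m <- membrane_params(10, 0.02)
  set.seed(5)
  for (i in 1:20) {
    h <- helix_spec(runif(1, 10, 50), runif(1, 5, 40))
    r <- runif(1, 2, 0.9 / helix_curvature(h))
    e_hel <- suppressWarnings(helical_tube_energy_per_axial(
      suppressWarnings(tube_geometry(h, r)), m)) / arc_per_axial(h)
    e_cyl <- straight_tube_energy_per_axial(r, m)
    expect_gt(e_hel, e_cyl)
  }
})

test_that("energy is monotone increasing in stiffness and tension", {
  t <- fixture_tube()
  e <- function(k, s) helical_tube_energy_per_axial(t, membrane_params(k, s))
  expect_gt(e(12, 0.01), e(10, 0.01))
  expect_gt(e(10, 0.02), e(10, 0.01))
})

test_that("Gauss-Legendre order is converged at the default", {
  m <- membrane_params(10, 0.01)
  t <- fixture_tube()
  e64 <- helical_tube_energy_per_axial(t, m, n_nodes = 64)
  e128 <- helical_tube_energy_per_axial(t, m, n_nodes = 128)
  expect_lt(abs(e64 - e128) / e128, 1e-12)
  # near the embedding limit the integrand is sharply peaked: low orders
  # show visible error, the default does not
  h <- helix_spec(10, 1)
  t2 <- suppressWarnings(tube_geometry(h, 0.95 / helix_curvature(h)))
  f <- function(n) helical_tube_energy_per_axial(t2, m, n_nodes = n)
  expect_gt(abs(f(8) - f(256)) / f(256), 1e-8)
  expect_lt(abs(f(64) - f(256)) / f(256), 1e-10)
})
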