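# Independent numerical oracles. These deliberately avoid the closed forms
# under test: curvature/torsion come from finite-difference derivatives of
# the parametrized curve, and the membrane energy from a dense-grid
# numerical shape operator on the parametrized canal surface.

# Frenet curvature and torsion of the helix (R cos t, R sin t, P t) from
# 4th-order finite differences of the curve
frenet_fd <- function(R, P, t0 = 0.37, h = 1e-2) {
  f <- function(t) c(R * cos(t), R * sin(t), P * t)
  d1 <- (-f(t0 + 2 * h) + 8 * f(t0 + h) - 8 * f(t0 - h) + f(t0 - 2 * h)) /
    (12 * h)
  d2 <- (-f(t0 + 2 * h) + 16 * f(t0 + h) - 30 * f(t0) + 16 * f(t0 - h) -
           f(t0 - 2 * h)) / (12 * h^2)
  d3 <- (f(t0 - 3 * h) - 8 * f(t0 - 2 * h) + 13 * f(t0 - h) -
           13 * f(t0 + h) + 8 * f(t0 + 2 * h) - f(t0 + 3 * h)) / (8 * h^3)
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  v <- cr(d1, d2)
  list(curvature = sqrt(sum(v^2)) / sum(d1^2)^1.5,
       torsion = sum(v * d3) / sum(v^2))
}

# Membrane energy of the canal surface per unit AXIAL length by brute force:
# parametrize X(t, phi), differentiate by 4th-order finite differences on a
# dense grid, build the fundamental forms, integrate (kappa/2)(2H)^2 + sigma
# over the surface spanned by one helical turn, divide by the axial extent.
canal_energy_oracle <- function(R, P, r, kappa, sigma,
                                n_t = 64, n_phi = 256) {
  # centerline frame from elementary derivatives of the parametrization
  frame <- function(t) {
    d1 <- rbind(-R * sin(t), R * cos(t), rep(P, length(t)))
    d2 <- rbind(-R * cos(t), -R * sin(t), rep(0, length(t)))
    Tt <- d1 / rep(sqrt(colSums(d1^2)), each = 3)
    w <- d2 - Tt * rep(colSums(d2 * Tt), each = 3)
    Nn <- w / rep(sqrt(colSums(w^2)), each = 3)
    Bb <- rbind(Tt[2, ] * Nn[3, ] - Tt[3, ] * Nn[2, ],
                Tt[3, ] * Nn[1, ] - Tt[1, ] * Nn[3, ],
                Tt[1, ] * Nn[2, ] - Tt[2, ] * Nn[1, ])
    list(T = Tt, N = Nn, B = Bb)
  }
  Xfun <- function(t, phi) {
    fr <- frame(t)
    cbind(R * cos(t) + r * (cos(phi) * fr$N[1, ] + sin(phi) * fr$B[1, ]),
          R * sin(t) + r * (cos(phi) * fr$N[2, ] + sin(phi) * fr$B[2, ]),
          P * t + r * (cos(phi) * fr$N[3, ] + sin(phi) * fr$B[3, ]))
  }
  # integration grid (trapezoid on a periodic smooth integrand) and a much
  # smaller step for the finite-difference derivatives
  tg <- (seq_len(n_t) - 1) * 2 * pi / n_t
  pg <- (seq_len(n_phi) - 1) * 2 * pi / n_phi
  grid_t <- rep(tg, times = n_phi)
  grid_p <- rep(pg, each = n_t)
  ht <- 1e-3
  hp <- 1e-3
  shift <- function(dt, dp) Xfun(grid_t + dt * ht, grid_p + dp * hp)
  X0 <- shift(0, 0)
  d4 <- function(m2, m1, p1, p2, h) (m2 - 8 * m1 + 8 * p1 - p2) / (12 * h)
  Xu <- d4(shift(-2, 0), shift(-1, 0), shift(1, 0), shift(2, 0), ht)
  Xv <- d4(shift(0, -2), shift(0, -1), shift(0, 1), shift(0, 2), hp)
  Xuu <- (-shift(-2, 0) + 16 * shift(-1, 0) - 30 * X0 + 16 * shift(1, 0) -
            shift(2, 0)) / (12 * ht^2)
  Xvv <- (-shift(0, -2) + 16 * shift(0, -1) - 30 * X0 + 16 * shift(0, 1) -
            shift(0, 2)) / (12 * hp^2)
  # cross derivative: 4th-order derivative in phi of the t-derivative
  Xu_at <- function(dp) d4(shift(-2, dp), shift(-1, dp), shift(1, dp),
                           shift(2, dp), ht)
  Xuv <- d4(Xu_at(-2), Xu_at(-1), Xu_at(1), Xu_at(2), hp)
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  E <- rowSums(Xu * Xu); F <- rowSums(Xu * Xv); G <- rowSums(Xv * Xv)
  nvec <- cr(Xu, Xv)
  nn <- sqrt(rowSums(nvec^2))
  nvec <- nvec / nn
  L <- rowSums(Xuu * nvec); M <- rowSums(Xuv * nvec); N2 <- rowSums(Xvv * nvec)
  H2 <- (E * N2 - 2 * F * M + G * L) / (E * G - F^2)   # 2H
  dA <- sqrt(E * G - F^2)
  total <- sum(((kappa / 2) * H2^2 + sigma) * dA) *
    (2 * pi / n_t) * (2 * pi / n_phi)
  total / (2 * pi * P)   # one turn spans an axial extent of 2*pi*P
}

# measured mean geometries used throughout the tests
fixture_tube <- function() tube_from_measurements(82.3, 53.1, 23.9)
fixture_shape_ratio <- function() {
  t <- fixture_tube()
  t$centerline$reduced_pitch_P / t$centerline$radius_R
}
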