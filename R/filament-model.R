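# Deformable-filament model (model 2). The scaffold is no longer rigid: the
# polar and equatorial filament bundles are Kirchhoff rods with bending and
# torsional persistence lengths (lp, lt, in nm, energies in k_BT) and
# helical rest shapes taken from the tube-less ribbon geometries. Both
# species follow the tube's centerline helix; they differ only in rest shape
# and in the binding term (-n_pol * mu per unit polar filament length). The
# total energy per unit axial length is minimized over (R, P, r); conversely,
# requiring stationarity at an observed geometry is a linear system in the
# unknown (sigma, lt, mu), which is how the inference operators work:
#   dE/dr = 0   involves only the membrane        -> sigma
#   dE/dR = 0, dE/dP = 0  are affine in (lt, mu)  -> lt, mu   (given lp)

#' Elastic parameters of a filament species
#'
#' A filament is a Kirchhoff rod whose energy per unit contour length is
#' `(1/2) [lp (kappa - kappa0)^2 + lt (tau - tau0)^2]` in k_BT/nm, with
#' `(kappa0, tau0)` the curvature and torsion of its helical rest shape.
#'
#' @param lp Bending persistence length (nm), non-negative.
#' @param lt Torsional persistence length (nm), non-negative.
#' @param rest A [helix_spec()] giving the rest (tube-less) shape.
#' @return An object of class `filament_params` with fields `lp`, `lt`,
#'   `rest_curvature`, `rest_torsion` and `rest`.
#' @export
filament_params <- function(lp, lt, rest) {
  check_number(lp, "lp", lower = 0)
  check_number(lt, "lt", lower = 0)
  rest <- as_helix_spec(rest, "rest")
  structure(
    list(lp = lp, lt = lt,
         rest_curvature = helix_curvature(rest),
         rest_torsion = helix_torsion(rest),
         rest = rest),
    class = "filament_params"
  )
}

as_filament_params <- function(f, name = "f") {
  if (!inherits(f, "filament_params"))
    stop_escrtube(sprintf("`%s` must be a filament_params", name),
                  "escrtube_invalid_input")
  f
}

#' Elastic energy density of a deformed filament
#'
#' @param actual_curvature Curvature of the deformed shape (1/nm).
#' @param actual_torsion Torsion of the deformed shape (1/nm).
#' @param f A [filament_params()].
#' @return Energy per unit filament length (k_BT/nm); zero at the rest
#'   shape.
#' @examples
#' f <- filament_params(250, 0, helix_spec(23.1, 39.8 / (2 * pi)))
#' rod_energy_per_length(f$rest_curvature + 0.01, 0, f) # 0.5*250*1e-4
#' @export
rod_energy_per_length <- function(actual_curvature, actual_torsion, f) {
  f <- as_filament_params(f)
  0.5 * (f$lp * (actual_curvature - f$rest_curvature)^2 +
           f$lt * (actual_torsion - f$rest_torsion)^2)
}

#' Filament bundle around a membrane tube
#'
#' The full mechanical description of the two filament populations: the
#' polar species (rest shape from the zigzag tube-less ribbons, binding the
#' membrane with the interface perpendicular to the helix axis) and the
#' equatorial species (rest shape from the sinusoidal ribbons, interface
#' parallel to the axis). By default the two species share `(lp, lt)`, as
#' expected for the same Snf7/Vps24/Vps2 copolymer in two binding
#' orientations; pass a distinct `equatorial` to override.
#'
#' @param polar A [filament_params()] for the polar species.
#' @param equatorial A [filament_params()] for the equatorial species, or
#'   `NULL` to reuse the polar rigidities with the equatorial rest shape.
#' @param equatorial_rest Rest helix used when `equatorial` is `NULL`.
#' @param polar_count,equatorial_count Strand counts (defaults 4 and 2: two
#'   polar clusters of two double-strands and one equatorial cluster).
#' @param mu_per_length Differential binding energy (k_BT/nm), gained by
#'   each polar strand.
#' @param monomer_arc Contour length per subunit (nm), for per-monomer
#'   conversion of `mu`.
#' @return An object of class `bundle_model`.
#' @seealso [reference_bundle_model()] for the bundle built from the
#'   measured ribbon geometries.
#' @export
bundle_model <- function(polar, equatorial = NULL,
                         equatorial_rest = NULL,
                         polar_count = 4, equatorial_count = 2,
                         mu_per_length = 0,
                         monomer_arc = default_monomer_arc()) {
  polar <- as_filament_params(polar, "polar")
  if (is.null(equatorial)) {
    if (is.null(equatorial_rest))
      stop_escrtube("supply either `equatorial` or `equatorial_rest`",
                    "escrtube_invalid_input")
    equatorial <- filament_params(polar$lp, polar$lt, equatorial_rest)
  } else {
    equatorial <- as_filament_params(equatorial, "equatorial")
  }
  check_number(polar_count, "polar_count", lower = 1)
  check_number(equatorial_count, "equatorial_count", lower = 1)
  check_number(mu_per_length, "mu_per_length")
  check_number(monomer_arc, "monomer_arc", lower = 0, strict_lower = TRUE)
  structure(
    list(polar = polar, equatorial = equatorial,
         polar_count = polar_count, equatorial_count = equatorial_count,
         mu_per_length = mu_per_length, monomer_arc = monomer_arc),
    class = "bundle_model"
  )
}

as_bundle_model <- function(b, name = "b") {
  if (!inherits(b, "bundle_model"))
    stop_escrtube(sprintf("`%s` must be a bundle_model", name),
                  "escrtube_invalid_input")
  b
}

#' Bundle model with the measured rest geometries
#'
#' Convenience constructor: polar rest from the zigzag ribbons
#' (diameter 46.2 nm, pitch 39.8 nm), equatorial rest from the sinusoidal
#' ribbons (diameter 34.1 nm, pitch 55.7 nm), default strand counts 4 and 2.
#'
#' @inheritParams bundle_model
#' @param lp,lt Shared persistence lengths (nm).
#' @return A [bundle_model()].
#' @export
reference_bundle_model <- function(lp, lt, mu_per_length = 0,
                                   polar_count = 4, equatorial_count = 2,
                                   monomer_arc = default_monomer_arc()) {
  rests <- reference_rest_helices()
  bundle_model(
    polar = filament_params(lp, lt, rests$polar),
    equatorial = filament_params(lp, lt, rests$equatorial),
    polar_count = polar_count, equatorial_count = equatorial_count,
    mu_per_length = mu_per_length, monomer_arc = monomer_arc
  )
}

# ---- total energy and its analytic gradient ---------------------------------

# rod + binding energy per unit centerline length at (kc, tu)
bundle_energy_per_length <- function(kc, tu, b) {
  b$polar_count * 0.5 *
    (b$polar$lp * (kc - b$polar$rest_curvature)^2 +
       b$polar$lt * (tu - b$polar$rest_torsion)^2) +
    b$equatorial_count * 0.5 *
    (b$equatorial$lp * (kc - b$equatorial$rest_curvature)^2 +
       b$equatorial$lt * (tu - b$equatorial$rest_torsion)^2) -
    b$polar_count * b$mu_per_length
}

#' Total energy of the filament-membrane system per unit axial length
#'
#' Membrane (Helfrich + tension) energy of the helical tube, plus the rod
#' energies of both filament species evaluated on the centerline helix,
#' minus the polar binding gain, all per unit axial length of the
#' superhelix.
#'
#' @param R Centerline helix radius (nm).
#' @param P Reduced pitch (nm), positive.
#' @param r Tube radius (nm); must satisfy the embedding constraint.
#' @param b A [bundle_model()].
#' @param m A [membrane_params()].
#' @return Energy per unit axial length (k_BT/nm).
#' @export
total_energy <- function(R, P, r, b, m) {
  b <- as_bundle_model(b)
  m <- as_membrane_params(m)
  check_number(R, "R", lower = 0, strict_lower = TRUE)
  check_number(P, "P", lower = 0, strict_lower = TRUE)
  check_number(r, "r", lower = 0, strict_lower = TRUE)
  q <- R^2 + P^2
  kc <- R / q
  check_embedding(r, kc)
  tu <- P / q
  a <- sqrt(q) / P
  a * (canal_energy_per_length(r, kc, m$kappa, m$sigma) +
         bundle_energy_per_length(kc, tu, b))
}

# unchecked scalar energy for optimizers; +Inf outside the admissible domain
total_energy_raw <- function(x, b, m) {
  R <- x[1]; P <- x[2]; r <- x[3]
  if (!all(is.finite(x)) || R <= 0 || P <= 0 || r <= 0) return(Inf)
  q <- R^2 + P^2
  kc <- R / q
  if (r * kc >= 0.99) return(Inf)
  tu <- P / q
  sqrt(q) / P * (canal_energy_per_length(r, kc, m$kappa, m$sigma) +
                   bundle_energy_per_length(kc, tu, b))
}

# analytic gradient of the total per-axial energy wrt (R, P, r)
total_energy_grad <- function(x, b, m) {
  R <- x[1]; P <- x[2]; r <- x[3]
  q <- R^2 + P^2
  kc <- R / q
  tu <- P / q
  a <- sqrt(q) / P
  kc_R <- (P^2 - R^2) / q^2
  kc_P <- -2 * R * P / q^2
  tu_R <- -2 * R * P / q^2
  tu_P <- (R^2 - P^2) / q^2
  a_R <- R / (P * sqrt(q))
  a_P <- -R^2 / (P^2 * sqrt(q))
  W <- canal_energy_per_length(r, kc, m$kappa, m$sigma) +
    bundle_energy_per_length(kc, tu, b)
  S_kc <- b$polar_count * b$polar$lp * (kc - b$polar$rest_curvature) +
    b$equatorial_count * b$equatorial$lp * (kc - b$equatorial$rest_curvature)
  S_tu <- b$polar_count * b$polar$lt * (tu - b$polar$rest_torsion) +
    b$equatorial_count * b$equatorial$lt * (tu - b$equatorial$rest_torsion)
  M_kc <- canal_energy_dkc(r, kc, m$kappa, m$sigma)
  c(a_R * W + a * ((M_kc + S_kc) * kc_R + S_tu * tu_R),
    a_P * W + a * ((M_kc + S_kc) * kc_P + S_tu * tu_P),
    a * canal_energy_dr(r, kc, m$kappa, m$sigma))
}

# rescaled stationarity residual: energy change per unit relative coordinate
# change, normalized by the energy scale
stationarity_residual <- function(x, b, m) {
  g <- total_energy_grad(x, b, m)
  scale <- max(1, abs(total_energy_raw(x, b, m)))
  max(abs(g * x)) / scale
}

#' Equilibrium shape of the filament-membrane system
#'
#' Local minimizer of [total_energy()] over `(R, P, r)`. The energy is only
#' locally stable: for strong binding it decreases without bound as the
#' superhelix winds up (`P -> 0`), so the physically relevant state is the
#' local minimum continuously connected to the polar rest helix, which is
#' where the solver starts (with the membrane tether radius
#' `sqrt(kappa/(2 sigma))` as the initial tube radius). Deterministic: BFGS
#' in log coordinates followed by Newton polishing of the analytic gradient.
#'
#' @param b A [bundle_model()].
#' @param m A [membrane_params()] with `sigma > 0`.
#' @param init Optional starting point `c(R, P, r)` (nm).
#' @param tol Rescaled gradient-norm certificate required at the solution.
#' @return A list with `R`, `P`, `r`, `helix` ([helix_spec()]), `tube`
#'   ([tube_geometry()]), `energy`, `residual` (the certificate) and
#'   `converged`.
#' @export
equilibrium_shape <- function(b, m, init = NULL, tol = 1e-8) {
  b <- as_bundle_model(b)
  m <- as_membrane_params(m)
  if (m$sigma <= 0 && b$polar$lp <= 0 && b$equatorial$lp <= 0)
    stop_escrtube("need sigma > 0 or a species with lp > 0",
                  "escrtube_invalid_input")
  if (is.null(init)) {
    r0 <- if (m$sigma > 0) sqrt(m$kappa / (2 * m$sigma)) else
      0.5 / helix_curvature(b$polar$rest)
    init <- c(b$polar$rest$radius_R, b$polar$rest$reduced_pitch_P, r0)
    # keep the start embeddable
    kc0 <- helix_curvature(b$polar$rest)
    init[3] <- min(init[3], 0.9 / kc0)
  }
  fn_log <- function(u) total_energy_raw(exp(u), b, m)
  gr_log <- function(u) {
    x <- exp(u)
    total_energy_grad(x, b, m) * x
  }
  fit <- optim(log(init), fn_log, gr_log, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  x <- exp(fit$par)
  # Newton polish on the analytic gradient
  for (i in seq_len(30)) {
    g <- total_energy_grad(x, b, m)
    if (stationarity_residual(x, b, m) < tol * 1e-2) break
    J <- jacobian_fd(function(y) total_energy_grad(y, b, m), x)
    step <- tryCatch(solve(J, g), error = function(e) NULL)
    if (is.null(step)) break
    # damped update staying in the admissible domain
    lam <- 1
    repeat {
      x_new <- x - lam * step
      if (all(x_new > 0) && is.finite(total_energy_raw(x_new, b, m))) break
      lam <- lam / 2
      if (lam < 1e-8) { x_new <- x; break }
    }
    x <- x_new
  }
  res <- stationarity_residual(x, b, m)
  if (res >= tol)
    stop_escrtube(sprintf(
      "equilibrium solver did not converge: rescaled gradient %.3g >= %.3g",
      res, tol), "escrtube_no_convergence")
  helix <- helix_spec(x[1], x[2])
  list(R = x[1], P = x[2], r = x[3], helix = helix,
       tube = suppressWarnings(tube_geometry(helix, x[3])),
       energy = total_energy_raw(x, b, m), residual = res,
       converged = TRUE)
}

# central-difference Jacobian of a vector function
jacobian_fd <- function(f, x, h = 1e-6) {
  n <- length(x)
  f0 <- f(x)
  J <- matrix(0, length(f0), n)
  for (i in seq_len(n)) {
    hi <- h * max(1, abs(x[i]))
    xp <- x; xp[i] <- xp[i] + hi
    xm <- x; xm[i] <- xm[i] - hi
    J[, i] <- (f(xp) - f(xm)) / (2 * hi)
  }
  J
}

# ---- stationarity inversion -------------------------------------------------

# Solve the three stationarity equations at an observed geometry for
# (sigma, lt, mu) given lp. dE/dr = 0 involves only the membrane and yields
# sigma in closed form; dE/dR = dE/dP = 0 are then affine in (lt, mu).
solve_stationarity <- function(lp, observed, b, m, feas_tol = 1e-9) {
  observed <- as_tube_geometry(observed, "observed")
  b <- as_bundle_model(b)
  m <- as_membrane_params(m)
  check_number(lp, "lp", lower = 0)
  R <- observed$centerline$radius_R
  P <- observed$centerline$reduced_pitch_P
  r <- observed$tube_radius_r
  kc <- helix_curvature(observed$centerline)
  e <- r * kc
  # dE/dr = 0: pi*kappa*(2e^2-1)/(r^2 (1-e^2)^{3/2}) + 2*pi*sigma = 0
  sigma <- m$kappa / (2 * r^2) * (1 - 2 * e^2) / (1 - e^2)^1.5
  m_hat <- membrane_params(m$kappa, max(sigma, 0))
  # keep the algebraic sigma even if negative; membrane_params would reject it
  m_hat$sigma <- sigma
  grad_rp <- function(lt, mu) {
    bb <- bundle_model(
      polar = filament_params(lp, lt, b$polar$rest),
      equatorial = filament_params(lp, lt, b$equatorial$rest),
      polar_count = b$polar_count, equatorial_count = b$equatorial_count,
      mu_per_length = 0, monomer_arc = b$monomer_arc)
    bb$mu_per_length <- mu   # mu may be negative during the solve
    total_energy_grad(c(R, P, r), bb, m_hat)[1:2]
  }
  g0 <- grad_rp(0, 0)
  A <- cbind(grad_rp(1, 0) - g0, grad_rp(0, 1) - g0)
  sol <- tryCatch(solve(A, -g0), error = function(e)
    stop_escrtube("stationarity system is singular at the observed geometry",
                  "escrtube_no_convergence"))
  lt <- sol[1]; mu <- sol[2]
  resid <- max(abs(c(A %*% sol + g0)))
  feasible <- sigma >= -feas_tol && lt >= -feas_tol * max(1, abs(lt)) &&
    mu >= -feas_tol * max(1, abs(mu))
  list(lp = lp, sigma = sigma, lt = unname(lt),
       mu_per_length = unname(mu),
       mu_per_monomer = unname(mu) * b$monomer_arc,
       residual = resid, feasible = feasible)
}

# The stationarity solution is affine in lp (the system matrix does not
# depend on lp and the inhomogeneity is linear in it). Returns intercepts
# and slopes for (sigma, lt, mu_per_length), verified on a third point.
stationarity_family <- function(observed, b, m) {
  s0 <- solve_stationarity(0, observed, b, m)
  s1 <- solve_stationarity(1, observed, b, m)
  x0 <- c(sigma = s0$sigma, lt = s0$lt, mu = s0$mu_per_length)
  x1 <- c(sigma = s1$sigma, lt = s1$lt, mu = s1$mu_per_length)
  slope <- x1 - x0
  s2 <- solve_stationarity(100, observed, b, m)
  x2 <- c(sigma = s2$sigma, lt = s2$lt, mu = s2$mu_per_length)
  if (max(abs(x0 + 100 * slope - x2)) > 1e-6 * max(1, max(abs(x2))))
    stop_escrtube("stationarity family is not affine in lp (internal error)",
                  "escrtube_no_convergence")
  list(intercept = x0, slope = slope)
}

# feasible lp interval from non-negativity of sigma, lt and mu along the
# affine family; returns c(lo, hi) or NULL when empty
feasible_lp_interval <- function(observed, b, m, lp_upper = 1e4) {
  fam <- stationarity_family(observed, b, m)
  lo <- 0; hi <- lp_upper
  for (k in c("sigma", "lt", "mu")) {
    a0 <- fam$intercept[[k]]; a1 <- fam$slope[[k]]
    if (abs(a1) < 1e-14) {
      if (a0 < -1e-12) return(NULL)
    } else if (a1 > 0) {
      lo <- max(lo, -a0 / a1)
    } else {
      hi <- min(hi, -a0 / a1)
    }
  }
  if (lo > hi) return(NULL)
  c(lo = lo, hi = hi)
}

#' Torsional persistence length and binding energy at fixed bending rigidity
#'
#' Solves the stationarity conditions of [total_energy()] at the observed
#' tube geometry for the unknowns (tension, torsional persistence length,
#' differential binding energy), with the bending persistence length fixed
#' (e.g. to the literature value of 250 nm for Snf7 homopolymers). The
#' system is exactly determined: the tube-radius equation yields the
#' tension, and the radius and pitch equations are affine in `(lt, mu)`. If
#' any unknown is negative the solution is mechanically infeasible and a
#' classed warning (`escrtube_infeasible`) is raised; the exact algebraic
#' solution is returned either way, with its residual certificate.
#'
#' @param lp_fixed Bending persistence length (nm).
#' @param observed A [tube_geometry()] (the tube-bound filament geometry).
#' @param b A [bundle_model()] carrying the rest shapes, strand counts and
#'   monomer arc (its `lp`, `lt`, `mu` fields are ignored).
#' @param m A [membrane_params()] (its `kappa` is used; `sigma` is inferred).
#' @return A list with `lp`, `sigma` (k_BT/nm^2), `lt` (nm),
#'   `mu_per_length` (k_BT/nm), `mu_per_monomer` (k_BT), `residual`, and
#'   `feasible`.
#' @examples
#' obs <- reference_tube_geometry()
#' b <- reference_bundle_model(lp = 250, lt = 0)
#' suppressWarnings(infer_lt_mu_at_fixed_lp(250, obs, b, membrane_params(10, 0.01)))
#' @export
infer_lt_mu_at_fixed_lp <- function(lp_fixed, observed, b, m) {
  sol <- solve_stationarity(lp_fixed, observed, b, m)
  if (!sol$feasible)
    warn_escrtube(sprintf(
      paste0("stationarity solution at lp = %.4g nm is infeasible ",
             "(sigma = %.4g, lt = %.4g, mu = %.4g per length); ",
             "lp lies outside the feasible interval"),
      lp_fixed, sol$sigma, sol$lt, sol$mu_per_length),
      "escrtube_infeasible")
  sol
}

#' Smallest bending persistence length admitting a feasible equilibrium
#'
#' Bisects on `lp` for the smallest value at which the stationarity system
#' of [total_energy()] at the observed geometry admits a solution with
#' non-negative tension, torsional persistence length and binding energy
#' difference. Returns 0 when the system is feasible down to `lp = 0`
#' (the non-negativity constraints then bound `lp` from above, not below;
#' see the package vignette for why this happens for the measured
#' geometries).
#'
#' @inheritParams infer_lt_mu_at_fixed_lp
#' @param lp_upper Upper end of the search range (nm).
#' @param tol Bisection tolerance on `lp` (nm).
#' @return A list with `lp_min` (nm), `solution_at_min` (the stationarity
#'   solution there), `feasible_interval` (the full feasible `lp` range)
#'   and `binding_constraint` (which sign constraint sets the bound, or
#'   `"none"`).
#' @export
infer_lp_min <- function(observed, b, m, lp_upper = 1e4, tol = 1e-6) {
  interval <- feasible_lp_interval(observed, b, m, lp_upper)
  if (is.null(interval))
    stop_escrtube(
      "no feasible lp: the stationarity system has no non-negative solution at any lp",
      "escrtube_infeasible")
  # bisection against the feasibility indicator (the affine interval gives
  # the bracket; bisection is kept as the defining computation)
  feas <- function(lp) solve_stationarity(lp, observed, b, m)$feasible
  lo_bound <- interval[["lo"]]
  if (lo_bound <= 0 || feas(0)) {
    lp_min <- 0
    constraint <- "none"
  } else {
    lo <- max(0, lo_bound - 1); hi <- lo_bound + 1
    if (feas(lo)) lo <- 0
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (feas(mid)) hi <- mid else lo <- mid
    }
    lp_min <- hi
    sol <- solve_stationarity(lp_min, observed, b, m)
    constraint <- c("sigma", "lt", "mu")[
      which.min(c(sol$sigma, sol$lt, sol$mu_per_length))]
  }
  list(lp_min = lp_min,
       solution_at_min = solve_stationarity(lp_min, observed, b, m),
       feasible_interval = interval,
       binding_constraint = constraint)
}

#' Lower bound on the differential binding energy from filament elasticity
#'
#' The stationarity system at the observed geometry defines a one-parameter
#' family of solutions indexed by the bending persistence length; this
#' returns the infimum of the binding energy difference `mu` over the
#' feasible (all-non-negative) part of that family, converted to k_BT per
#' monomer. Because the family is affine in `lp`, the infimum is attained
#' at an endpoint of the feasible interval.
#'
#' @inheritParams infer_lp_min
#' @return A list with `mu_per_monomer`, `mu_per_length`, `lp_at_inf` (the
#'   `lp` attaining the infimum) and `feasible_interval`.
#' @export
infer_mu_bound <- function(observed, b, m, lp_upper = 1e4) {
  b <- as_bundle_model(b)
  interval <- feasible_lp_interval(observed, b, m, lp_upper)
  if (is.null(interval))
    stop_escrtube("no feasible lp for the stationarity system",
                  "escrtube_infeasible")
  fam <- stationarity_family(observed, b, m)
  mu_at <- function(lp) fam$intercept[["mu"]] + lp * fam$slope[["mu"]]
  mus <- c(mu_at(interval[["lo"]]), mu_at(interval[["hi"]]))
  i <- which.min(mus)
  list(mu_per_monomer = mus[i] * b$monomer_arc,
       mu_per_length = mus[i],
       lp_at_inf = unname(interval[i]),
       feasible_interval = interval)
}
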