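# Rigid-scaffold model (model 1). A non-deformable helical scaffold of
# radius R and reduced pitch P encloses either a helical membrane tube
# (radius r, free to relax) or a straight cylinder of radius R. Polar-bound
# filament strands gain a differential binding energy mu per unit filament
# length in the helical configuration only. The competition is governed by
# two dimensionless groups: the rescaled tension Sigma = sigma R^2 / kappa
# and the rescaled binding energy M = mu R / kappa, at fixed shape ratio
# p = P/R. All model-1 internals work in these rescaled variables (lengths
# in R, energies per axial length in kappa/R) and use the canal-surface
# closed form; the public quadrature operators are tested against them.

#' Binding configuration of the filament bundle
#'
#' @param mu_per_length Differential binding energy of the polar versus the
#'   equatorial membrane-binding mode, per unit filament length
#'   (k_BT/nm). Positive values favor polar binding and hence helical tubes.
#' @param polar_multiplicity Effective number of filament strands paying or
#'   gaining `mu` (default 4: two polar clusters of two double-strands).
#'   Plausible conventions span 2--6.
#' @param monomer_arc Filament contour length per subunit (nm), used to
#'   convert `mu` between per-length and per-monomer units. Default from the
#'   measured helical symmetry, [monomer_arc_length()]`(23.1, 6.7, 1.06)`.
#' @return An object of class `binding_config`.
#' @export
binding_config <- function(mu_per_length = 0, polar_multiplicity = 4,
                           monomer_arc = default_monomer_arc()) {
  check_number(mu_per_length, "mu_per_length")
  check_number(polar_multiplicity, "polar_multiplicity", lower = 1)
  check_number(monomer_arc, "monomer_arc", lower = 0, strict_lower = TRUE)
  structure(
    list(mu_per_length = mu_per_length,
         polar_multiplicity = polar_multiplicity,
         monomer_arc = monomer_arc),
    class = "binding_config"
  )
}

as_binding_config <- function(b, name = "b") {
  if (!inherits(b, "binding_config"))
    stop_escrtube(sprintf("`%s` must be a binding_config", name),
                  "escrtube_invalid_input")
  b
}

# ---- dimensionless core -----------------------------------------------------

# admissible range of rho = r/R for shape ratio p = P/R: embedding
# rho * (R kappa_c) <= 0.99 and adjacent-turn clearance 2 rho < 2 pi p
rho_bounds <- function(p) {
  c_dl <- 1 / (1 + p^2)              # R * kappa_c
  c(lo = 1e-6, hi = min(0.99 / c_dl, pi * p))
}

# helical-tube energy per axial length in units of kappa/R
energy_hel_dl <- function(rho, Sigma, p) {
  c_dl <- 1 / (1 + p^2)
  a_dl <- sqrt(1 + p^2) / p
  a_dl * (pi / (rho * sqrt(1 - (c_dl * rho)^2)) + 2 * pi * Sigma * rho)
}

# optimal rescaled tube radius, with boundary flag
rho_opt_dl <- function(Sigma, p) {
  b <- rho_bounds(p)
  op <- optimize(energy_hel_dl, c(b["lo"], b["hi"]), Sigma = Sigma, p = p,
                 tol = 1e-12)
  rho <- op$minimum
  attr(rho, "on_boundary") <-
    (rho - b["lo"] < 1e-5 * diff(b)) || (b["hi"] - rho < 1e-5 * diff(b))
  rho
}

# mu = 0 energy gap (helical minus straight) per axial length, in kappa/R
gap0_dl <- function(Sigma, p) {
  rho <- rho_opt_dl(Sigma, p)
  energy_hel_dl(as.numeric(rho), Sigma, p) - pi * (1 + 2 * Sigma)
}

# Sigma at which the mu = 0 gap peaks, and related landmarks; the gap rises
# from Sigma = 0 to a single maximum and then decreases without bound
gap_landmarks <- function(p) {
  op <- optimize(function(S) gap0_dl(S, p), c(1e-6, 200), maximum = TRUE,
                 tol = 1e-10)
  sigma_peak <- op$maximum
  gap_max <- op$objective
  # largest zero of the gap (upper edge of the straight wedge); the gap is
  # negative for all larger Sigma
  hi <- sigma_peak * 2
  while (gap0_dl(hi, p) > 0 && hi < 1e6) hi <- hi * 2
  sigma0 <- uniroot(function(S) gap0_dl(S, p), c(sigma_peak, hi),
                    tol = 1e-12)$root
  list(sigma_peak = sigma_peak, gap_max = gap_max, sigma0 = sigma0)
}

#' Rescaled binding energy on the helical-straight phase boundary
#'
#' For a rescaled tension `Sigma = sigma R^2/kappa` and scaffold shape ratio
#' `h_shape = P/R`, returns the rescaled differential binding energy
#' `M = mu R/kappa` at which helical and straight tubes have equal energy.
#' The energy gap is linear in `M`, so the boundary is explicit:
#' `M*(Sigma) = max(0, gap0(Sigma) / (n_pol * arc_per_axial))`, where
#' `gap0` is the `mu = 0` gap between the optimal helical tube and the
#' straight cylinder. A zero means helical tubes are favored for every
#' `mu >= 0` at that tension.
#'
#' @param sigma_rescaled Rescaled tension(s) `sigma R^2/kappa`, positive.
#'   Vectorized.
#' @param h_shape Shape ratio `P/R` of the scaffold helix.
#' @param polar_multiplicity Number of strands gaining `mu` (see
#'   [binding_config()]).
#' @return Rescaled boundary binding energy (vector, same length as
#'   `sigma_rescaled`).
#' @export
phase_boundary <- function(sigma_rescaled, h_shape,
                           polar_multiplicity = 4) {
  check_number(h_shape, "h_shape", lower = 0, strict_lower = TRUE)
  check_number(polar_multiplicity, "polar_multiplicity", lower = 1)
  a_dl <- sqrt(1 + h_shape^2) / h_shape
  vapply(sigma_rescaled, function(S) {
    check_number(S, "sigma_rescaled", lower = 0, strict_lower = TRUE)
    max(0, gap0_dl(S, h_shape) / (polar_multiplicity * a_dl))
  }, numeric(1))
}

#' Threshold binding energy above which helical tubes are always favored
#'
#' The maximum of the phase boundary over all tensions. For
#' `mu R / kappa` above this value the helical tube is favored at every
#' `sigma R^2 / kappa >= 0` and no critical radius exists.
#'
#' @inheritParams phase_boundary
#' @return Rescaled threshold `M_max`.
#' @export
always_helical_threshold <- function(h_shape, polar_multiplicity = 4) {
  check_number(h_shape, "h_shape", lower = 0, strict_lower = TRUE)
  a_dl <- sqrt(1 + h_shape^2) / h_shape
  gap_landmarks(h_shape)$gap_max / (polar_multiplicity * a_dl)
}

#' Critical tube radius at the helical-to-straight transition
#'
#' Starting from high tension (where helical tubes are favored) and lowering
#' `sigma R^2/kappa`, the optimal tube radius grows until the system
#' transitions to a straight tube at a tension that depends on the rescaled
#' binding energy `mu R/kappa`. This returns the rescaled tube radius
#' `r_c/R` at that transition -- the largest tube radius reachable before
#' the transition. Above [always_helical_threshold()] no transition exists
#' and a classed error (`escrtube_always_helical`) is signalled.
#'
#' @param mu_rescaled Rescaled binding energy `mu R/kappa`, non-negative and
#'   below the always-helical threshold.
#' @inheritParams phase_boundary
#' @return `r_c/R` (dimensionless).
#' @export
critical_radius <- function(mu_rescaled, h_shape, polar_multiplicity = 4) {
  check_number(mu_rescaled, "mu_rescaled", lower = 0)
  check_number(h_shape, "h_shape", lower = 0, strict_lower = TRUE)
  lm <- gap_landmarks(h_shape)
  a_dl <- sqrt(1 + h_shape^2) / h_shape
  target <- mu_rescaled * polar_multiplicity * a_dl
  if (target >= lm$gap_max)
    stop_escrtube(sprintf(
      "no transition: mu R/kappa = %.4g is at or above the always-helical threshold %.4g",
      mu_rescaled, lm$gap_max / (polar_multiplicity * a_dl)),
      "escrtube_always_helical")
  # transition tension: the gap crosses the binding gain on its decreasing
  # branch (the first crossing met when lowering tension from the helical side)
  hi <- lm$sigma_peak * 2
  while (gap0_dl(hi, h_shape) > target && hi < 1e6) hi <- hi * 2
  sigma_b <- uniroot(function(S) gap0_dl(S, h_shape) - target,
                     c(lm$sigma_peak, hi), tol = 1e-12)$root
  as.numeric(rho_opt_dl(sigma_b, h_shape))
}

# ---- absolute-unit operators ------------------------------------------------

#' Optimal radius of the helical membrane tube
#'
#' Minimizes [helical_tube_energy_per_axial()] over the tube radius for a
#' fixed scaffold helix, subject to the embedding constraint
#' `kappa_c * r <= 0.99` and the adjacent-turn clearance `2 r < 2 pi P`. The
#' minimizer is unique (the energy is strictly convex-unimodal in `r` on the
#' admissible interval); if it sits against a constraint boundary this is
#' reported via the `on_boundary` attribute and a warning, not an error.
#'
#' @param h A [helix_spec()] describing the scaffold.
#' @param m A [membrane_params()] with `sigma > 0` (at zero tension and zero
#'   curvature the optimal radius diverges).
#' @param n_nodes Quadrature order passed to the energy.
#' @return Optimal tube radius (nm) with attributes `on_boundary` (logical)
#'   and `bracket` (the admissible interval searched).
#' @examples
#' h <- helix_spec(29.2, 8.451)
#' optimal_tube_radius(h, membrane_params(10, 0.02))
#' @export
optimal_tube_radius <- function(h, m, n_nodes = 64) {
  h <- as_helix_spec(h)
  m <- as_membrane_params(m)
  if (m$sigma <= 0)
    stop_escrtube("optimal_tube_radius requires sigma > 0",
                  "escrtube_invalid_input")
  kc <- helix_curvature(h)
  R <- h$radius_R
  p <- h$reduced_pitch_P / R
  b <- rho_bounds(p) * R
  fn <- function(r) helical_tube_energy_per_axial(
    suppressWarnings(tube_geometry(h, r)), m, n_nodes)
  op <- optimize(fn, b, tol = 1e-10 * R)
  r <- op$minimum
  on_boundary <- (r - b[1] < 1e-5 * diff(b)) || (b[2] - r < 1e-5 * diff(b))
  if (on_boundary)
    warn_escrtube("optimal tube radius sits on a constraint boundary",
                  "escrtube_boundary_minimum")
  structure(r, on_boundary = on_boundary, bracket = unname(b))
}

#' Energetically preferred tube shape under a rigid scaffold
#'
#' Compares the energy per unit axial length of the optimal helical tube,
#' minus the polar binding gain `n_pol * mu * arc_per_axial`, against the
#' straight cylinder of the scaffold radius. Negative gap: helical wins.
#'
#' @param h A [helix_spec()] (the rigid scaffold).
#' @param m A [membrane_params()] with `sigma > 0`.
#' @param b A [binding_config()].
#' @param n_nodes Quadrature order.
#' @param tol Gap magnitude (k_BT/nm) below which the state is reported as
#'   `"boundary"`.
#' @return A list with `state` (`"helical"`, `"straight"` or `"boundary"`),
#'   `gap` (k_BT per nm axial; helical minus straight), and `r_opt` (nm).
#' @export
shape_preference <- function(h, m, b, n_nodes = 64, tol = 1e-8) {
  h <- as_helix_spec(h)
  m <- as_membrane_params(m)
  b <- as_binding_config(b)
  r_opt <- optimal_tube_radius(h, m, n_nodes)
  e_hel <- helical_tube_energy_per_axial(
    suppressWarnings(tube_geometry(h, as.numeric(r_opt))), m, n_nodes)
  gain <- b$polar_multiplicity * b$mu_per_length * arc_per_axial(h)
  e_str <- straight_tube_energy_per_axial(h$radius_R, m)
  gap <- e_hel - gain - e_str
  state <- if (abs(gap) <= tol) "boundary" else if (gap < 0) "helical" else "straight"
  list(state = state, gap = gap, r_opt = as.numeric(r_opt),
       energy_helical = e_hel, energy_straight = e_str, binding_gain = gain)
}

#' Minimal binding energy compatible with an observed tube radius

#'
#' Helical tubes thicker than the critical radius `r_c(mu R/kappa)` cannot
#' occur, so observing a tube of radius `r_exp` bounds `mu` from below. The
#' bound has three regimes: (i) `r_exp` below the smallest critical radius
#' (reached at `mu = 0`): any `mu >= 0` is compatible and the bound is 0;
#' (ii) `r_exp` within the range of critical radii on the boundary: the
#' bound inverts `r_c(M) = r_exp`; (iii) `r_exp` above every critical radius
#' on the boundary but no larger than the zero-tension optimal radius: such
#' thick tubes require the always-helical regime, and the bound is
#' [always_helical_threshold()]. Radii beyond the zero-tension optimum are
#' unattainable at equilibrium and signal a classed error.
#'
#' @param r_exp Observed mean tube radius (nm), positive and smaller than
#'   the scaffold radius.
#' @param h A [helix_spec()] (the scaffold).
#' @param b A [binding_config()] (multiplicity and monomer arc used).
#' @param m A [membrane_params()] (only `kappa` enters: the bound is
#'   inferred without knowledge of the tension).
#' @return A list with `mu_per_monomer` (k_BT), `mu_per_length` (k_BT/nm),
#'   `mu_rescaled` (`mu R/kappa`), and `regime` (one of `"unconstrained"`,
#'   `"boundary"`, `"always_helical"`).
#' @examples
#' h <- helix_spec(29.2, 8.451)
#' min_mu_for_observed(12.1, h, binding_config(), membrane_params(10, 0.01))
#' @export
min_mu_for_observed <- function(r_exp, h, b, m) {
  h <- as_helix_spec(h)
  b <- as_binding_config(b)
  m <- as_membrane_params(m)
  R <- h$radius_R
  check_number(r_exp, "r_exp", lower = 0, strict_lower = TRUE,
               upper = R, strict_upper = TRUE)
  p <- h$reduced_pitch_P / R
  check_embedding(r_exp, helix_curvature(h))
  lm <- gap_landmarks(p)
  a_dl <- sqrt(1 + p^2) / p
  rho_exp <- r_exp / R
  rc_at_zero_mu <- as.numeric(rho_opt_dl(lm$sigma0, p))
  rc_max_on_boundary <- as.numeric(rho_opt_dl(lm$sigma_peak, p))
  rho_attainable_max <- as.numeric(rho_opt_dl(0, p))
  M_max <- lm$gap_max / (b$polar_multiplicity * a_dl)
  if (rho_exp <= rc_at_zero_mu) {
    M_min <- 0
    regime <- "unconstrained"
  } else if (rho_exp <= rc_max_on_boundary) {
    M_min <- uniroot(
      function(M) critical_radius(M, p, b$polar_multiplicity) - rho_exp,
      c(1e-10, M_max * (1 - 1e-9)), tol = 1e-12)$root
    regime <- "boundary"
  } else if (rho_exp <= rho_attainable_max) {
    M_min <- M_max
    regime <- "always_helical"
  } else {
    stop_escrtube(sprintf(
      "r_exp = %.3g nm exceeds the largest attainable equilibrium radius %.3g nm",
      r_exp, rho_attainable_max * R), "escrtube_infeasible")
  }
  mu_per_length <- M_min * m$kappa / R
  list(mu_per_monomer = mu_per_length * b$monomer_arc,
       mu_per_length = mu_per_length,
       mu_rescaled = M_min,
       regime = regime)
}

#' Helical-versus-straight phase diagram
#'
#' Classifies every point of a rescaled-tension x rescaled-binding-energy
#' grid as favoring the helical or the straight tube, and computes the phase
#' boundary and the critical-radius curve along it.
#'
#' @param h_shape Shape ratio `P/R` of the scaffold helix.
#' @param sigma_range Range of `sigma R^2/kappa` (length 2, positive).
#' @param mu_range Range of `mu R/kappa` (length 2, non-negative).
#' @param n Grid resolution per axis (default 50).
#' @param polar_multiplicity See [binding_config()].
#' @return An object of class `phase_diagram`: a list with `grid` (data
#'   frame: `sigma_rescaled`, `mu_rescaled`, `label`, `r_over_R`),
#'   `boundary` (data frame: `sigma_rescaled`, `mu_boundary`,
#'   `r_c_over_R`), and the inputs. Grid points on the boundary (zero gap)
#'   are labelled helical, so the helical region is closed.
#' @seealso [plot_phase_diagram()], [plot_critical_radius()]
#' @export
phase_diagram <- function(h_shape, sigma_range = c(0.05, 30),
                          mu_range = c(0, 3.5), n = 50,
                          polar_multiplicity = 4) {
  check_number(h_shape, "h_shape", lower = 0, strict_lower = TRUE)
  stopifnot(length(sigma_range) == 2, length(mu_range) == 2, n >= 2)
  sig <- seq(sigma_range[1], sigma_range[2], length.out = n)
  mu <- seq(mu_range[1], mu_range[2], length.out = n)
  mb <- phase_boundary(sig, h_shape, polar_multiplicity)
  rho <- vapply(sig, function(S) as.numeric(rho_opt_dl(S, h_shape)),
                numeric(1))
  grid <- expand.grid(sigma_rescaled = sig, mu_rescaled = mu,
                      KEEP.OUT.ATTRS = FALSE)
  i <- match(grid$sigma_rescaled, sig)
  grid$label <- ifelse(grid$mu_rescaled >= mb[i], "helical", "straight")
  grid$r_over_R <- rho[i]
  boundary <- data.frame(sigma_rescaled = sig, mu_boundary = mb,
                         r_c_over_R = rho)
  structure(
    list(grid = grid, boundary = boundary, h_shape = h_shape,
         polar_multiplicity = polar_multiplicity),
    class = "phase_diagram"
  )
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf(
    "<phase_diagram> P/R = %.4g, n_pol = %g, %d x %d grid (%.1f%% helical)\n",
    x$h_shape, x$polar_multiplicity,
    length(unique(x$grid$sigma_rescaled)), length(unique(x$grid$mu_rescaled)),
    100 * mean(x$grid$label == "helical")))
  invisible(x)
}

#' Plot the phase diagram
#'
#' @param pd A [phase_diagram()].
#' @return A ggplot object: labelled regions with the phase boundary drawn
#'   where it is positive.
#' @export
plot_phase_diagram <- function(pd) {
  stopifnot(inherits(pd, "phase_diagram"))
  bnd <- pd$boundary[pd$boundary$mu_boundary > 0, ]
  ggplot2::ggplot(pd$grid, ggplot2::aes(
    x = .data$sigma_rescaled, y = .data$mu_rescaled)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$label)) +
    ggplot2::geom_line(
      data = bnd,
      ggplot2::aes(x = .data$sigma_rescaled, y = .data$mu_boundary),
      inherit.aes = FALSE, colour = "purple", linewidth = 1) +
    ggplot2::scale_fill_manual(
      values = c(helical = "#9ecae1", straight = "#fdd0a2"), name = NULL) +
    ggplot2::labs(
      x = expression(sigma * R^2 / kappa),
      y = expression(mu * R / kappa),
      title = "Energetically favored tube shape") +
    ggplot2::theme_minimal()
}

#' Plot the critical radius along the phase boundary
#'
#' @param pd A [phase_diagram()].
#' @return A ggplot object of `r_c/R` against the rescaled tension on the
#'   portion of the grid where the boundary is positive.
#' @export
plot_critical_radius <- function(pd) {
  stopifnot(inherits(pd, "phase_diagram"))
  bnd <- pd$boundary[pd$boundary$mu_boundary > 0, ]
  ggplot2::ggplot(bnd, ggplot2::aes(
    x = .data$sigma_rescaled, y = .data$r_c_over_R)) +
    ggplot2::geom_line(colour = "purple", linewidth = 1) +
    ggplot2::labs(
      x = expression(sigma * R^2 / kappa),
      y = expression(r[c] / R),
      title = "Rescaled critical radius at the transition") +
    ggplot2::theme_minimal()
}
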