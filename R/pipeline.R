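# Pipeline drivers: resolved configuration, and four reproducible commands
# that tie the modules together and write CSV/JSON/figure outputs. Every
# physical default lives in the configuration, not in code constants, so
# reproducing the reference analysis versus exploring conventions is a
# config diff. Each driver is deterministic given its config (seeds
# included) and embeds the hash of the resolved config in its report.

#' Default pipeline configuration
#'
#' The resolved list of every tunable the pipeline uses. Membrane stiffness
#' defaults to 10 k_BT (not separately measured for these membranes;
#' model-1 rescaled quantities do not depend on it, model-2 absolute
#' inferences scale with it and [run_filament_inference()] reports a
#' sensitivity sweep). `use_r_exp` selects the quoted mean tube radius
#' 12.1 nm rather than half the mean diameter for the model-1 bound.
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  list(
    version = 1L,
    seed = 1L,
    membrane = list(kappa = 10, sigma = 0.01),
    geometry = list(use_r_exp = TRUE),
    model1 = list(
      polar_multiplicity = 4,
      grid_n = 50,
      sigma_range = c(0.05, 30),
      mu_range = c(0, 3.5)
    ),
    model2 = list(
      lp_fixed = 250,
      polar_count = 4,
      equatorial_count = 2,
      lp_upper = 1e4,
      require_feasible = FALSE,
      kappa_sweep = c(5, 10, 15, 20, 25)
    ),
    simulate = list(
      lp_true = 250, lt_true = 45, mu_per_monomer_true = 3,
      sigma_true = 0.0315,
      n_measurements = 30, n_replicates = 100, n_boot = 200,
      noise_sd = c(outer_diameter = 6.1, axial_pitch = 7.6,
                   tube_diameter = 3.7)
    )
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file and merges it over [default_config()] (missing entries
#' keep their defaults). Unknown top-level keys and malformed values give a
#' classed error (`escrtube_config_error`).
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return The resolved configuration list, with a `hash` attribute.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path))
      stop_escrtube(sprintf("config file not found: %s", path),
                    "escrtube_config_error")
    user <- tryCatch(yaml::read_yaml(path), error = function(e)
      stop_escrtube(sprintf("cannot parse YAML config %s: %s", path,
                            conditionMessage(e)), "escrtube_config_error"))
    if (!is.list(user))
      stop_escrtube("config must be a YAML mapping", "escrtube_config_error")
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop_escrtube(sprintf("unknown config key(s): %s",
                            paste(unknown, collapse = ", ")),
                    "escrtube_config_error")
    cfg <- modifyList(cfg, user)
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  ck <- function(ok, msg) if (!ok)
    stop_escrtube(paste0("config: ", msg), "escrtube_config_error")
  ck(is.numeric(cfg$membrane$kappa) && cfg$membrane$kappa > 0,
     "membrane.kappa must be > 0")
  ck(is.numeric(cfg$membrane$sigma) && cfg$membrane$sigma >= 0,
     "membrane.sigma must be >= 0")
  ck(cfg$model1$polar_multiplicity >= 1 && cfg$model1$polar_multiplicity <= 6,
     "model1.polar_multiplicity must be in [1, 6]")
  ck(cfg$model1$grid_n >= 2, "model1.grid_n must be >= 2")
  ck(length(cfg$model1$sigma_range) == 2 && all(cfg$model1$sigma_range > 0),
     "model1.sigma_range must be two positive numbers")
  ck(length(cfg$model1$mu_range) == 2 && all(cfg$model1$mu_range >= 0),
     "model1.mu_range must be two non-negative numbers")
  ck(cfg$model2$lp_fixed >= 0, "model2.lp_fixed must be >= 0")
  ck(cfg$simulate$n_boot >= 100, "simulate.n_boot must be >= 100")
  ck(cfg$simulate$n_replicates >= 1, "simulate.n_replicates must be >= 1")
  attr(cfg, "hash") <- NULL
  attr(cfg, "hash") <- rlang::hash(cfg)
  cfg
}

report_header <- function(cfg, what) {
  list(command = what,
       config_hash = attr(cfg, "hash"),
       config = cfg,
       generated_by = paste0("escrtube ",
                             as.character(utils::packageVersion("escrtube"))))
}

write_report <- function(report, out_dir, file) {
  path <- file.path(out_dir, file)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  path
}

#' Compute and export the helical-versus-straight phase diagram
#'
#' Runs [phase_diagram()] for the scaffold shape taken from the built-in
#' measured geometry, writes `phase_diagram.csv` (grid with labels and
#' optimal radii), `phase_boundary.csv`, and the two figures
#' `phase_diagram.png` and `critical_radius.png`.
#'
#' @param config A resolved configuration (see [load_config()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the `phase_diagram` object and the output
#'   paths.
#' @export
run_phase_diagram <- function(config = load_config(), out_dir = ".") {
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  obs <- reference_tube_geometry()
  h_shape <- obs$centerline$reduced_pitch_P / obs$centerline$radius_R
  t0 <- Sys.time()
  pd <- phase_diagram(
    h_shape,
    sigma_range = config$model1$sigma_range,
    mu_range = config$model1$mu_range,
    n = config$model1$grid_n,
    polar_multiplicity = config$model1$polar_multiplicity)
  grid_path <- file.path(out_dir, "phase_diagram.csv")
  write.csv(pd$grid, grid_path, row.names = FALSE)
  boundary_path <- file.path(out_dir, "phase_boundary.csv")
  write.csv(pd$boundary, boundary_path, row.names = FALSE)
  fig1 <- file.path(out_dir, "phase_diagram.png")
  ggplot2::ggsave(fig1, plot_phase_diagram(pd), width = 6, height = 4,
                  dpi = 150)
  fig2 <- file.path(out_dir, "critical_radius.png")
  ggplot2::ggsave(fig2, plot_critical_radius(pd), width = 6, height = 4,
                  dpi = 150)
  message(sprintf(
    "phase diagram: %d x %d grid, P/R = %.4g, %.2f s",
    config$model1$grid_n, config$model1$grid_n, h_shape,
    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(list(phase_diagram = pd,
                 paths = c(grid_path, boundary_path, fig1, fig2)))
}

#' Rigid-scaffold lower bound on the binding energy difference
#'
#' Runs [min_mu_for_observed()] on the built-in measured geometry and writes
#' a JSON report (`model1_bound.json`) with the bound, the conventions used
#' and the observed inputs.
#'
#' @inheritParams run_phase_diagram
#' @return Invisibly, the report list.
#' @export
run_scaffold_bound <- function(config = load_config(), out_dir = ".") {
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  obs <- reference_tube_geometry()
  r_exp <- observed_tube_radius(config$geometry$use_r_exp)
  b <- binding_config(polar_multiplicity = config$model1$polar_multiplicity)
  m <- membrane_params(config$membrane$kappa, config$membrane$sigma)
  bound <- min_mu_for_observed(r_exp, obs$centerline, b, m)
  report <- c(report_header(config, "model1-bound"), list(
    inputs = list(
      scaffold_radius_nm = obs$centerline$radius_R,
      scaffold_reduced_pitch_nm = obs$centerline$reduced_pitch_P,
      observed_tube_radius_nm = r_exp,
      polar_multiplicity = b$polar_multiplicity,
      monomer_arc_nm = b$monomer_arc,
      kappa_kBT = m$kappa),
    result = bound))
  path <- write_report(report, out_dir, "model1_bound.json")
  message(sprintf(
    "model-1 bound: mu >= %.4g k_BT per monomer (%s regime)",
    bound$mu_per_monomer, bound$regime))
  invisible(c(report, list(path = path)))
}

#' Deformable-filament inference from the measured geometries
#'
#' Runs the full model-2 inference on the built-in measurement table:
#' the feasible range of the bending persistence length ([infer_lp_min()]),
#' the binding-energy infimum ([infer_mu_bound()]), the stationarity
#' solution at the configured fixed `lp` ([infer_lt_mu_at_fixed_lp()]),
#' a one-at-a-time sensitivity table over +/- 1 SD of every measured input,
#' and a sweep of the fixed-`lp` solution over membrane stiffness. Writes
#' `model2_inference.json` and `model2_sensitivity.csv`.
#'
#' If the solution at `lp_fixed` is infeasible (a sign constraint is
#' violated), the exact algebraic solution is still reported with
#' `feasible = FALSE`; set `config$model2$require_feasible = TRUE` to turn
#' that into a classed error (`escrtube_infeasible`).
#'
#' @inheritParams run_phase_diagram
#' @return Invisibly, the report list.
#' @export
run_filament_inference <- function(config = load_config(), out_dir = ".") {
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  table <- reference_measurements()
  m <- membrane_params(config$membrane$kappa, config$membrane$sigma)
  b <- reference_bundle_model(
    lp = 250, lt = 0,
    polar_count = config$model2$polar_count,
    equatorial_count = config$model2$equatorial_count)
  obs <- reference_tube_geometry(table)

  lp_min <- infer_lp_min(obs, b, m, lp_upper = config$model2$lp_upper)
  mu_bound <- infer_mu_bound(obs, b, m, lp_upper = config$model2$lp_upper)
  # infeasibility surfaces through the report (and, on request, the classed
  # error below), not as a loose warning
  at_fixed <- withCallingHandlers(
    infer_lt_mu_at_fixed_lp(config$model2$lp_fixed, obs, b, m),
    escrtube_infeasible = function(w) invokeRestart("muffleWarning"))
  if (isTRUE(config$model2$require_feasible) && !at_fixed$feasible)
    stop_escrtube(sprintf(
      "lp_fixed = %g nm is outside the feasible interval [%.4g, %.4g] nm",
      config$model2$lp_fixed,
      lp_min$feasible_interval[["lo"]], lp_min$feasible_interval[["hi"]]),
      "escrtube_infeasible")

  # one-at-a-time sensitivity: +/- 1 SD on each measured input quantity
  used <- table$object_class %in%
    c("helical_tube", "zigzag_ribbon", "sinusoidal_ribbon") &
    table$quantity %in% c("outer_diameter", "axial_pitch", "tube_diameter",
                          "ribbon_diameter")
  sens <- do.call(rbind, lapply(which(used), function(i) {
    do.call(rbind, lapply(c(-1, 1), function(s) {
      tab <- table
      tab$mean_nm[i] <- tab$mean_nm[i] + s * tab$sd_nm[i]
      obs_i <- reference_tube_geometry(tab)
      b_i <- b
      rests <- reference_rest_helices(tab)
      b_i$polar <- filament_params(250, 0, rests$polar)
      b_i$equatorial <- filament_params(250, 0, rests$equatorial)
      sol <- solve_stationarity(config$model2$lp_fixed, obs_i, b_i, m)
      data.frame(object_class = table$object_class[i],
                 quantity = table$quantity[i],
                 shift_sd = s,
                 lt = sol$lt,
                 mu_per_monomer = sol$mu_per_monomer,
                 sigma = sol$sigma,
                 feasible = sol$feasible)
    }))
  }))
  sens_path <- file.path(out_dir, "model2_sensitivity.csv")
  write.csv(sens, sens_path, row.names = FALSE)

  kappa_sweep <- do.call(rbind, lapply(config$model2$kappa_sweep, function(k) {
    sol <- solve_stationarity(config$model2$lp_fixed, obs, b,
                              membrane_params(k, config$membrane$sigma))
    data.frame(kappa = k, sigma = sol$sigma, lt = sol$lt,
               mu_per_monomer = sol$mu_per_monomer, feasible = sol$feasible)
  }))

  report <- c(report_header(config, "model2-infer"), list(
    lp_min = lp_min,
    mu_bound = mu_bound,
    at_fixed_lp = at_fixed,
    kappa_sweep = kappa_sweep,
    sensitivity_csv = sens_path))
  path <- write_report(report, out_dir, "model2_inference.json")
  message(sprintf(
    paste0("model-2: feasible lp in [%.4g, %.4g] nm; inf mu = %.4g k_BT/monomer; ",
           "at lp = %g nm: lt = %.4g nm, mu = %.4g k_BT/monomer (feasible: %s)"),
    lp_min$feasible_interval[["lo"]], lp_min$feasible_interval[["hi"]],
    mu_bound$mu_per_monomer, config$model2$lp_fixed, at_fixed$lt,
    at_fixed$mu_per_monomer, at_fixed$feasible))
  invisible(c(report, list(path = path)))
}

#' Closed-loop parameter-recovery study
#'
#' Forward-simulates noisy measurement tables from known mechanical
#' parameters ([forward_observations()]), re-infers `(lt, mu)` at the true
#' `lp` with bootstrap intervals on every replicate, and reports the
#' noiseless recovery error and the fraction of replicates whose intervals
#' cover the truth. Writes `recovery_replicates.csv` and `recovery.json`.
#'
#' @inheritParams run_phase_diagram
#' @return Invisibly, the report list.
#' @export
run_recovery_study <- function(config = load_config(), out_dir = ".") {
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- config$simulate
  m <- membrane_params(config$membrane$kappa, sim$sigma_true)
  b <- reference_bundle_model(
    lp = sim$lp_true, lt = sim$lt_true,
    mu_per_length = sim$mu_per_monomer_true / default_monomer_arc(),
    polar_count = config$model2$polar_count,
    equatorial_count = config$model2$equatorial_count)
  noise_sd <- unlist(sim$noise_sd)

  # noiseless closure: summaries with sd = 0, inference must return truth
  noiseless <- forward_observations(b, m, noise_sd = 0 * noise_sd,
                                    n = sim$n_measurements, seed = config$seed)
  obs0 <- tube_from_measurements(
    noiseless$truth_quantities[["outer_diameter"]],
    noiseless$truth_quantities[["axial_pitch"]],
    noiseless$truth_quantities[["tube_diameter"]])
  sol0 <- solve_stationarity(sim$lp_true, obs0, b, m)
  closure <- c(lt_rel_error = abs(sol0$lt - sim$lt_true) / sim$lt_true,
               mu_rel_error = abs(sol0$mu_per_monomer -
                                    sim$mu_per_monomer_true) /
                 sim$mu_per_monomer_true)

  reps <- do.call(rbind, lapply(seq_len(sim$n_replicates), function(i) {
    seed_i <- config$seed + i
    fwd <- forward_observations(b, m, noise_sd = noise_sd,
                                n = sim$n_measurements, seed = seed_i)
    bi <- bootstrap_inference(fwd$table, b, m, lp_fixed = sim$lp_true,
                              n_boot = sim$n_boot, seed = seed_i + 10000L)
    covered <- function(method, par, truth) {
      iv <- bi$intervals[bi$intervals$method == method &
                           bi$intervals$parameter == par, ]
      iv$lower <= truth && truth <= iv$upper
    }
    stud <- function(par, col) {
      iv <- bi$intervals[bi$intervals$method == "student" &
                           bi$intervals$parameter == par, ]
      iv[[col]]
    }
    covered_lt <- covered("student", "lt", sim$lt_true)
    covered_mu <- covered("student", "mu_per_monomer",
                          sim$mu_per_monomer_true)
    data.frame(replicate = i, seed = seed_i,
               lt_hat = bi$point[["lt"]],
               mu_hat = bi$point[["mu_per_monomer"]],
               lt_lower = stud("lt", "lower"),
               lt_upper = stud("lt", "upper"),
               mu_lower = stud("mu_per_monomer", "lower"),
               mu_upper = stud("mu_per_monomer", "upper"),
               covered_lt = covered_lt, covered_mu = covered_mu,
               covered_both = covered_lt && covered_mu,
               covered_lt_perc = covered("percentile", "lt", sim$lt_true),
               covered_mu_perc = covered("percentile", "mu_per_monomer",
                                         sim$mu_per_monomer_true))
  }))
  reps_path <- file.path(out_dir, "recovery_replicates.csv")
  write.csv(reps, reps_path, row.names = FALSE)

  report <- c(report_header(config, "simulate"), list(
    truth = list(lp = sim$lp_true, lt = sim$lt_true,
                 mu_per_monomer = sim$mu_per_monomer_true,
                 sigma = sim$sigma_true,
                 equilibrium = as.list(noiseless$truth)),
    noiseless_closure = as.list(closure),
    coverage = list(lt = mean(reps$covered_lt),
                    mu = mean(reps$covered_mu),
                    joint = mean(reps$covered_both),
                    lt_percentile = mean(reps$covered_lt_perc),
                    mu_percentile = mean(reps$covered_mu_perc)),
    n_replicates = sim$n_replicates,
    n_boot = sim$n_boot,
    replicates_csv = reps_path))
  path <- write_report(report, out_dir, "recovery.json")
  message(sprintf(
    "recovery: noiseless rel. errors (lt, mu) = (%.2g, %.2g); joint coverage %.2f",
    closure[["lt_rel_error"]], closure[["mu_rel_error"]],
    mean(reps$covered_both)))
  invisible(c(report, list(path = path)))
}
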