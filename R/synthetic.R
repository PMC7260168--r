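# Synthetic-data generators. These stand in for the study's measurements:
# Gaussian replicates around stated mean/SD summaries (what a set of
# per-object geometry measurements looks like), and forward-simulated
# equilibrium geometries from known mechanical parameters with measurement
# noise, enabling closed-loop parameter-recovery experiments. Every
# operation with randomness takes an explicit seed and restores the caller's
# RNG state.

#' Draw synthetic per-object measurements around a summary
#'
#' `n` independent Gaussian draws around the summary's mean with its SD,
#' truncated at zero by redrawing (lengths cannot be negative). The noise
#' model is independent Gaussians per quantity: only means and SDs are
#' published, no covariances.
#'
#' @param s A one-row `measurement_table` (see [measurement_summary()]).
#' @param n Number of draws, at least 1.
#' @param seed Integer seed; fixed seed gives an identical sequence.
#' @return Numeric vector of `n` positive lengths (nm).
#' @examples
#' s <- measurement_summary("helical_tube", "axial_pitch", 53.1, 7.6)
#' sample_geometries(s, 5, seed = 1)
#' @export
sample_geometries <- function(s, n, seed) {
  s <- validate_measurement_table(as.data.frame(s), "s")
  if (nrow(s) != 1)
    stop_escrtube("`s` must be a single measurement summary row",
                  "escrtube_invalid_input")
  check_number(n, "n", lower = 1)
  check_number(seed, "seed")
  withr::with_seed(as.integer(seed), {
    draw_truncated_normal(n, s$mean_nm, s$sd_nm)
  })
}

# truncated-at-zero normal by redraw; assumes RNG state is managed by caller
draw_truncated_normal <- function(n, mean, sd, max_tries = 1000) {
  x <- rnorm(n, mean, sd)
  tries <- 0
  while (any(bad <- x <= 0)) {
    tries <- tries + 1
    if (tries > max_tries)
      stop_escrtube("truncated-normal redraw did not terminate (mean << 0?)",
                    "escrtube_no_convergence")
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  x
}

#' Forward-simulate noisy measurements of the equilibrium geometry
#'
#' Computes the noiseless mechanical equilibrium `(R, P, r)` of a
#' filament-membrane system via [equilibrium_shape()], converts it to the
#' measured quantities (superhelix outer diameter `2(R + r)`, axial pitch
#' `2 pi P`, tube diameter `2 r`), draws `n` noisy replicates of each with
#' the given per-quantity Gaussian noise (truncated at zero), and summarizes
#' them as a `measurement_table`.
#'
#' @param b A [bundle_model()] (the true mechanical parameters).
#' @param m A [membrane_params()] (true stiffness and tension).
#' @param noise_sd Named numeric vector with entries `outer_diameter`,
#'   `axial_pitch`, `tube_diameter` (nm); defaults to the SDs of the
#'   published tube measurements. Zero noise gives summaries equal to the
#'   noiseless forward values with SD 0.
#' @param n Measurements per quantity (at least 2 so an SD exists).
#' @param seed Integer seed.
#' @return A list with `truth` (named vector `R`, `P`, `r`),
#'   `truth_quantities` (named vector of the three noiseless observables),
#'   `table` (the synthetic `measurement_table`, `object_class`
#'   `"helical_tube"`, `source` `"synthetic"`), and `equilibrium` (the full
#'   [equilibrium_shape()] result).
#' @export
forward_observations <- function(b, m,
                                 noise_sd = c(outer_diameter = 6.1,
                                              axial_pitch = 7.6,
                                              tube_diameter = 3.7),
                                 n = 30, seed = 1) {
  b <- as_bundle_model(b)
  m <- as_membrane_params(m)
  check_number(n, "n", lower = 2)
  stopifnot(all(c("outer_diameter", "axial_pitch", "tube_diameter") %in%
                  names(noise_sd)))
  eq <- equilibrium_shape(b, m)
  truth_q <- c(outer_diameter = 2 * (eq$R + eq$r),
               axial_pitch = 2 * pi * eq$P,
               tube_diameter = 2 * eq$r)
  rows <- withr::with_seed(as.integer(seed), {
    lapply(names(truth_q), function(q) {
      draws <- if (noise_sd[[q]] > 0)
        draw_truncated_normal(n, truth_q[[q]], noise_sd[[q]])
      else rep(truth_q[[q]], n)
      s <- summarize_samples(draws)
      measurement_summary("helical_tube", q, s[["mean"]], s[["sd"]], n = n,
                          source = "synthetic")
    })
  })
  table <- validate_measurement_table(do.call(rbind, rows))
  list(truth = c(R = eq$R, P = eq$P, r = eq$r),
       truth_quantities = truth_q,
       table = table,
       equilibrium = eq)
}

#' Bootstrap uncertainty propagation for the filament inference
#'
#' Parametric bootstrap over the sampling distribution of the measured
#' geometry means: each replicate redraws every mean in the table from a
#' Gaussian with standard error `sd/sqrt(n)` (rows without `n` use the SD
#' itself), rebuilds the observed tube geometry (and, when ribbon rows are
#' present, the rest helices), re-runs the stationarity inference, and
#' collects `lt`, `mu` per monomer (at `lp_fixed`) and the lower end of the
#' feasible `lp` interval. Percentile intervals are returned. The
#' stationarity solve is a linear system, so replicates never fail to
#' produce a solution; replicates whose redrawn geometry is invalid (e.g.
#' outer diameter below tube diameter) are redrawn, and an error is raised
#' if more than 5 percent of replicates need more than `max_tries` redraws.
#'
#' @param table A `measurement_table` containing at least the three
#'   `helical_tube` rows; `zigzag_ribbon`/`sinusoidal_ribbon` rows, if
#'   present, are resampled too, otherwise the rest shapes of `b` are used
#'   as-is.
#' @param b A [bundle_model()] template (rest shapes, counts, monomer arc).
#' @param m A [membrane_params()].
#' @param lp_fixed Bending persistence length at which `(lt, mu)` are
#'   solved (nm).
#' @param n_boot Number of bootstrap replicates, at least 100.
#' @param seed Integer seed; fixed seed gives identical intervals.
#' @param level Interval coverage (default 0.95).
#' @return A list with `intervals` (data frame: parameter, method, lower,
#'   point, upper; `method` is `"percentile"` or `"student"`), `samples`
#'   (data frame of replicate draws) and `point` (the inference at the
#'   table's means). The student rows are `point +/- t * sd(boot)` with the
#'   t quantile at the measurement degrees of freedom; they are better
#'   calibrated than raw percentiles at moderate `n_boot`.
#' @export
bootstrap_inference <- function(table, b, m, lp_fixed = 250, n_boot = 200,
                                seed = 1, level = 0.95) {
  table <- validate_measurement_table(as.data.frame(table), "table")
  b <- as_bundle_model(b)
  m <- as_membrane_params(m)
  check_number(n_boot, "n_boot", lower = 100)
  alpha <- (1 - level) / 2
  se <- ifelse(is.na(table$n), table$sd_nm, table$sd_nm / sqrt(table$n))

  build_inputs <- function(means) {
    tab <- table
    tab$mean_nm <- means
    obs <- tube_from_measurements(
      measurement_lookup(tab, "helical_tube", "outer_diameter"),
      measurement_lookup(tab, "helical_tube", "axial_pitch"),
      measurement_lookup(tab, "helical_tube", "tube_diameter"))
    bb <- b
    if (any(tab$object_class == "zigzag_ribbon"))
      bb$polar <- filament_params(b$polar$lp, b$polar$lt, helix_spec(
        measurement_lookup(tab, "zigzag_ribbon", "ribbon_diameter") / 2,
        measurement_lookup(tab, "zigzag_ribbon", "axial_pitch") / (2 * pi)))
    if (any(tab$object_class == "sinusoidal_ribbon"))
      bb$equatorial <- filament_params(
        b$equatorial$lp, b$equatorial$lt, helix_spec(
          measurement_lookup(tab, "sinusoidal_ribbon", "ribbon_diameter") / 2,
          measurement_lookup(tab, "sinusoidal_ribbon", "axial_pitch") / (2 * pi)))
    list(obs = obs, b = bb)
  }

  infer_one <- function(means) {
    inp <- build_inputs(means)
    sol <- solve_stationarity(lp_fixed, inp$obs, inp$b, m)
    lo <- feasible_lp_interval(inp$obs, inp$b, m)
    c(lt = sol$lt, mu_per_monomer = sol$mu_per_monomer,
      lp_min = if (is.null(lo)) NA_real_ else unname(lo[["lo"]]))
  }

  point <- infer_one(table$mean_nm)
  max_tries <- 50
  hard_replicates <- 0
  samples <- withr::with_seed(as.integer(seed), {
    out <- matrix(NA_real_, n_boot, 3)
    colnames(out) <- c("lt", "mu_per_monomer", "lp_min")
    for (i in seq_len(n_boot)) {
      tries <- 0
      repeat {
        tries <- tries + 1
        means <- table$mean_nm + rnorm(nrow(table), 0, se)
        res <- tryCatch(infer_one(means), escrtube_error = function(e) NULL)
        if (!is.null(res) && all(means > 0)) break
        if (tries > max_tries) { hard_replicates <- hard_replicates + 1; break }
      }
      if (tries <= max_tries) out[i, ] <- res
    }
    out
  })
  if (hard_replicates > 0.05 * n_boot)
    stop_escrtube(sprintf(
      "bootstrap: %d of %d replicates failed to produce a valid geometry",
      hard_replicates, n_boot), "escrtube_no_convergence")
  samples <- as.data.frame(samples[stats::complete.cases(samples[, 1:2]), ,
                                   drop = FALSE])
  # percentile intervals (the primary output) plus student-type intervals
  # (point +/- t * bootstrap sd, with the t quantile at the measurement
  # degrees of freedom), which are better calibrated at moderate n_boot for
  # smooth nonlinear functionals like these
  df_t <- suppressWarnings(max(2, min(table$n, na.rm = TRUE) - 1))
  if (!is.finite(df_t)) df_t <- Inf
  tmult <- stats::qt(1 - alpha, df_t)
  perc <- data.frame(
    parameter = colnames(samples),
    method = "percentile",
    lower = vapply(samples, quantile, numeric(1), probs = alpha, na.rm = TRUE),
    point = unname(point[colnames(samples)]),
    upper = vapply(samples, quantile, numeric(1), probs = 1 - alpha,
                   na.rm = TRUE),
    row.names = NULL
  )
  boot_sd <- vapply(samples, sd, numeric(1), na.rm = TRUE)
  stud <- data.frame(
    parameter = colnames(samples),
    method = "student",
    lower = unname(point[colnames(samples)]) - tmult * boot_sd,
    point = unname(point[colnames(samples)]),
    upper = unname(point[colnames(samples)]) + tmult * boot_sd,
    row.names = NULL
  )
  list(intervals = rbind(perc, stud), samples = samples, point = point)
}
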