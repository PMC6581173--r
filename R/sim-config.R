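#' Simulation configuration for synthetic culture experiments
#'
#' Bundles the ground-truth parameters from which every synthetic data stream
#' is generated: per-substrate logistic growth parameters, per-cell carbon
#' flux rates for the radiotracer incubations, the cellular phosphorus quota,
#' per-cell formate levels, macromolecular fractionation proportions and the
#' plate-assay calibration line.  Defaults describe an axenic
#' *Prochlorococcus* MIT9301 batch culture grown on one of four phosphorus
#' sources (phosphate, phosphite, methylphosphonate, hydroxymethylphosphonate)
#' under a 12 h:12 h light-dark cycle.
#'
#' @param growth Data frame with columns `substrate`, `mu` (specific growth
#'   rate, per day), `K` (carrying capacity, cells/ml) and `N0` (inoculum
#'   density, cells/ml).  The default uses maximum growth rates of 0.42
#'   (phosphate), 0.18 (phosphite), 0.35 (MPn) and 0.39 (HMPn) per day, a
#'   6e8 cells/ml yield for phosphate-, MPn- and HMPn-grown cultures and half
#'   that for phosphite.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise applied to simulated cell densities (dimensionless; 0 disables
#'   noise).  Default 0.05, consistent with triplicate-culture growth-rate
#'   standard deviations near 0.01-0.03 per day.
#' @param true_cell_rate_light,true_cell_rate_dark Per-cell MPn carbon
#'   assimilation rates in the light and the dark (zmol C/cell/h); defaults
#'   250 and 89.
#' @param true_cell_rate_co2 Per-cell MPn carbon oxidation rate to CO2
#'   (zmol C/cell/h); default 3.75, i.e. 0.09 amol C/cell over a 24-h day.
#' @param quota_P Cellular phosphorus quota (amol P/cell); default 20.
#' @param formate_per_cell Named numeric vector of per-cell formate production
#'   by substrate (amol/cell); defaults 27 for phosphate- and phosphite-grown
#'   cultures and 48 for MPn and HMPn.
#' @param fractionation Named numeric simplex over the five macromolecular
#'   fractions plus a `residual` term, giving the expected share of cell
#'   pellet radiolabel recovered in each of metabolite, lipid, RNA, DNA and
#'   protein fractions.  The default normalises the MPn-tracer shares
#'   42/1.5/41/19/0.5 (percent of pellet) onto the simplex.
#' @param calib_slope,calib_intercept Linear plate-assay calibration
#'   (absorbance per nmol formate in the well, and blank absorbance).
#' @param assay_noise_sd Gaussian absorbance noise of the plate reader
#'   (default 0.001, consistent with replicate spreads of a few percent on
#'   culture-supernatant formate determinations).
#' @param photoperiod_h Light hours per 24-h day; default 12.
#' @param well_ul Assay well volume in microlitres of supernatant; default 50.
#' @param seed Integer seed; every generator derives a per-stream sub-seed
#'   from it so runs are reproducible end to end.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$growth
#' @export
sim_config <- function(growth = default_growth_params(),
                       noise_cv = 0.05,
                       true_cell_rate_light = 250,
                       true_cell_rate_dark = 89,
                       true_cell_rate_co2 = 3.75,
                       quota_P = 20,
                       formate_per_cell = c(
                         phosphate = 27, phosphite = 27,
                         MPn = 48, HMPn = 48
                       ),
                       fractionation = default_fraction_props(),
                       calib_slope = 0.05,
                       calib_intercept = 0.01,
                       assay_noise_sd = 0.001,
                       photoperiod_h = 12,
                       well_ul = 50,
                       seed = 1L) {
  growth <- as_tibble(growth)
  need <- c("substrate", "mu", "K", "N0")
  if (!all(need %in% names(growth))) {
    abort("`growth` needs columns substrate, mu, K and N0.")
  }
  if (any(growth$mu < 0)) abort("growth rates `mu` must be >= 0.")
  if (any(growth$N0 <= 0) || any(growth$K <= growth$N0)) {
    abort("`growth` must satisfy K > N0 > 0 for every substrate.")
  }
  check_nonneg(noise_cv, "noise_cv")
  check_nonneg(true_cell_rate_light, "true_cell_rate_light")
  check_nonneg(true_cell_rate_dark, "true_cell_rate_dark")
  check_nonneg(true_cell_rate_co2, "true_cell_rate_co2")
  check_positive(quota_P, "quota_P")
  if (any(formate_per_cell < 0) || is.null(names(formate_per_cell))) {
    abort("`formate_per_cell` must be a named, non-negative vector.")
  }
  frac_names <- c("metabolite", "lipid", "RNA", "DNA", "protein", "residual")
  if (!identical(sort(names(fractionation)), sort(frac_names))) {
    abort(paste(
      "`fractionation` must be named over",
      paste(frac_names, collapse = ", ")
    ))
  }
  if (any(fractionation < 0) || abs(sum(fractionation) - 1) > 1e-12) {
    abort("`fractionation` must be a simplex (non-negative, summing to 1).")
  }
  if (calib_slope <= 0) abort("`calib_slope` must be positive for inversion.")
  check_nonneg(assay_noise_sd, "assay_noise_sd")
  check_number(photoperiod_h, "photoperiod_h", min = 0)
  if (photoperiod_h > 24) abort("`photoperiod_h` cannot exceed 24.")
  check_positive(well_ul, "well_ul")
  check_number(seed, "seed")

  structure(
    list(
      growth = growth,
      noise_cv = noise_cv,
      true_cell_rate_light = true_cell_rate_light,
      true_cell_rate_dark = true_cell_rate_dark,
      true_cell_rate_co2 = true_cell_rate_co2,
      quota_P = quota_P,
      formate_per_cell = formate_per_cell,
      fractionation = fractionation[frac_names],
      calib_slope = calib_slope,
      calib_intercept = calib_intercept,
      assay_noise_sd = assay_noise_sd,
      photoperiod_h = photoperiod_h,
      well_ul = well_ul,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @rdname sim_config
#' @export
default_growth_params <- function() {
  tibble(
    substrate = c("phosphate", "phosphite", "MPn", "HMPn"),
    mu = c(0.42, 0.18, 0.35, 0.39),
    K = c(6e8, 3e8, 6e8, 6e8),
    N0 = rep(1e6, 4)
  )
}

#' @rdname sim_config
#' @export
default_fraction_props <- function() {
  pct <- c(
    metabolite = 42, lipid = 1.5, RNA = 41, DNA = 19,
    protein = 0.5, residual = 0
  )
  pct / sum(pct)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed", x$seed, "\n")
  cat("growth truths (per substrate):\n")
  print(x$growth)
  cat(sprintf(
    "tracer rates: %g (light) / %g (dark) / %g (CO2) zmol C/cell/h\n",
    x$true_cell_rate_light, x$true_cell_rate_dark, x$true_cell_rate_co2
  ))
  cat(sprintf(
    "quota %g amol P/cell; density noise CV %g; photoperiod %g h\n",
    x$quota_P, x$noise_cv, x$photoperiod_h
  ))
  invisible(x)
}
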