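#' Radiotracer unit conversions
#'
#' Helpers for 14C incubation arithmetic.  `tracer_molarity()` converts a
#' volumetric radiotracer addition into the substrate concentration it
#' contributes; `effective_specific_activity()` dilutes the stock specific
#' activity by any unlabelled carrier substrate, giving radioactivity per
#' mole of total (labelled plus unlabelled) substrate; `dpm_to_mol()`
#' converts disintegrations per minute to moles at a given specific activity
#' using the definitional 1 Ci = 2.22e12 dpm.
#'
#' @param activity Radiotracer addition (uCi per ml of culture).
#' @param sa,sa_stock Specific activity (Ci per mol).
#' @param carrier_uM Unlabelled carrier substrate concentration (uM).
#' @param dpm Disintegrations per minute.
#' @return `tracer_molarity()`: concentration in uM.
#'   `effective_specific_activity()`: Ci per mol of total substrate; always
#'   at most `sa_stock`, with equality exactly when `carrier_uM = 0`.
#'   `dpm_to_mol()`: moles.
#' @examples
#' tracer_molarity(0.1, 59) # ~1.7 uM
#' effective_specific_activity(0.25, 59, carrier_uM = 50)
#' dpm_to_mol(2.22e12, sa = 1) # 1 mol
#' @export
tracer_molarity <- function(activity, sa) {
  stopifnot(all(activity >= 0), all(sa > 0))
  # uCi/ml -> Ci/L is *1e-3; dividing by Ci/mol gives mol/L, *1e6 -> uM
  activity / sa * 1e3
}

#' @rdname tracer_molarity
#' @export
effective_specific_activity <- function(activity, sa_stock, carrier_uM = 0) {
  stopifnot(all(activity >= 0), all(sa_stock > 0))
  if (any(carrier_uM < 0)) abort("`carrier_uM` must be >= 0.")
  total_uM <- tracer_molarity(activity, sa_stock) + carrier_uM
  ifelse(total_uM == 0, sa_stock, activity * 1e3 / total_uM)
}

#' @rdname tracer_molarity
#' @export
dpm_to_mol <- function(dpm, sa) {
  stopifnot(all(dpm >= 0), all(sa > 0))
  dpm / (sa * DPM_PER_CI)
}

#' @rdname tracer_molarity
#' @param mol Moles of substrate.
#' @export
mol_to_dpm <- function(mol, sa) {
  stopifnot(all(mol >= 0), all(sa > 0))
  mol * sa * DPM_PER_CI
}

#' Per-cell carbon flux from scintillation counts
#'
#' Converts background-corrected dpm from tracer incubations into cell-
#' specific rates: sample radioactivity is divided by the effective specific
#' activity (isotope dilution by carrier included), by the incubation period
#' and by the cell inventory (density x volume).  CO2-trap incubations are
#' handled identically — the trapped dpm are the numerator.
#'
#' @param data Incubation table with columns `condition`, `dpm`,
#'   `activity_uCi_ml`, `sa_Ci_mol`, `carrier_uM`, `volume_ml`,
#'   `cells_per_ml`, `duration_h` (one row per incubation; extra columns such
#'   as `replicate` pass through).
#' @return The input tibble with appended columns `sa_eff_Ci_mol`,
#'   `rate_zmol_per_cell_h` and `rate_amol_per_cell_day` (1 amol =
#'   1000 zmol; the daily figure is the hourly rate times 24).
#' @examples
#' inc <- simulate_tracer_incubations(sim_config(seed = 1),
#'   cell_density = 1e8, noise = FALSE
#' )
#' cell_specific_rate(inc)
#' @export
cell_specific_rate <- function(data) {
  need <- c(
    "condition", "dpm", "activity_uCi_ml", "sa_Ci_mol", "carrier_uM",
    "volume_ml", "cells_per_ml", "duration_h"
  )
  if (!all(need %in% names(data))) {
    abort(paste("`data` needs columns:", paste(need, collapse = ", ")))
  }
  if (any(data$cells_per_ml <= 0)) abort("`cells_per_ml` must be > 0.")
  if (any(data$duration_h <= 0)) abort("`duration_h` must be > 0.")
  if (any(data$dpm < 0)) abort("`dpm` must be >= 0 (background-corrected).")
  as_tibble(data) %>%
    mutate(
      sa_eff_Ci_mol = effective_specific_activity(
        .data$activity_uCi_ml, .data$sa_Ci_mol, .data$carrier_uM
      ),
      rate_zmol_per_cell_h = dpm_to_mol(.data$dpm, .data$sa_eff_Ci_mol) /
        (.data$cells_per_ml * .data$volume_ml) / .data$duration_h * 1e21,
      rate_amol_per_cell_day = .data$rate_zmol_per_cell_h * 24 / 1e3
    )
}

#' Compose light and dark hourly rates into a daily rate
#'
#' @param light,dark Per-cell rates (zmol/cell/h) under light and darkness.
#' @param light_h Light hours per 24-h day (default 12).
#' @return Daily per-cell rate in amol/cell/day:
#'   `(light * light_h + dark * (24 - light_h)) / 1000`.
#' @examples
#' daily_rate(250, 89) # 4.068 amol/cell/day
#' @export
daily_rate <- function(light, dark, light_h = 12) {
  stopifnot(all(light >= 0), all(dark >= 0))
  if (any(light_h < 0 | light_h > 24)) abort("`light_h` must lie in [0, 24].")
  (light * light_h + dark * (24 - light_h)) / 1e3
}
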