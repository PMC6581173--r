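#' Radiolabel share per macromolecular fraction
#'
#' Expresses the radioactivity recovered in each macromolecular fraction
#' (acid-soluble metabolites, lipids, RNA, DNA, protein) as a percentage of
#' the total radioactivity of the intact cell pellet, per replicate.
#' Recovery — the summed fraction dpm over the pellet total — is reported,
#' not forced to 100%: extraction losses leave it below 1, carrier and
#' counting artefacts can push it above.
#'
#' @param data Fractionation table with columns `replicate`, `fraction`,
#'   `dpm` (>= 0) and `pellet_total_dpm` (> 0, constant within replicate).
#' @return The input tibble with appended `pct` (percent of pellet total)
#'   and `recovery` (fraction of pellet dpm recovered, repeated within
#'   replicate).
#' @examples
#' prof <- tibble::tibble(
#'   replicate = 1,
#'   fraction = c("metabolite", "lipid", "RNA", "DNA", "protein"),
#'   dpm = c(4200, 150, 4100, 1900, 50),
#'   pellet_total_dpm = 10000
#' )
#' fraction_percentages(prof)
#' @export
fraction_percentages <- function(data) {
  need <- c("replicate", "fraction", "dpm", "pellet_total_dpm")
  if (!all(need %in% names(data))) {
    abort(paste("`data` needs columns:", paste(need, collapse = ", ")))
  }
  if (any(data$dpm < 0)) abort("fraction dpm must be >= 0.")
  if (any(data$pellet_total_dpm <= 0)) abort("`pellet_total_dpm` must be > 0.")
  as_tibble(data) %>%
    group_by(.data$replicate) %>%
    mutate(
      pct = .data$dpm / .data$pellet_total_dpm * 100,
      recovery = sum(.data$dpm) / .data$pellet_total_dpm[1]
    ) %>%
    ungroup()
}

#' Brucite coprecipitation share
#'
#' Fraction of acid-soluble radiolabel scavenged by authigenic Mg(OH)2
#' (which quantitatively precipitates phosphate and nucleotides) versus the
#' label remaining in the supernatant.
#'
#' @param ppt_dpm Radioactivity in the dissolved precipitate (dpm).
#' @param supernatant_dpm Radioactivity left in the supernatant (dpm).
#' @return `ppt_dpm / (ppt_dpm + supernatant_dpm)`, a fraction in \[0, 1\].
#' @examples
#' brucite_fraction(75, 25)
#' @export
brucite_fraction <- function(ppt_dpm, supernatant_dpm) {
  stopifnot(all(ppt_dpm >= 0), all(supernatant_dpm >= 0))
  tot <- ppt_dpm + supernatant_dpm
  if (any(tot == 0)) abort("precipitate and supernatant dpm cannot both be zero.")
  ppt_dpm / tot
}

#' Assign 2-D TLC spots to compound standards
#'
#' Matches each radioassayed chromatogram spot to the nearest compound
#' standard in Euclidean retention-factor space (one Rf per solvent
#' dimension).  Distance ties are broken by the lexicographically smaller
#' compound name and flagged; spots farther than `cutoff` from every
#' standard stay unassigned (`NA` compound).
#'
#' @param spots Data frame with columns `spot_id`, `rf1`, `rf2` (in
#'   \[0, 1\]) and `dpm`.
#' @param standards Data frame with columns `compound`, `rf1`, `rf2`.
#' @param cutoff Maximum assignment distance in Rf units (default 0.1,
#'   about a 1-cm spot on a 10-cm sheet).
#' @return The `spots` tibble with appended `compound`, `distance` and
#'   `tied` columns.
#' @examples
#' std <- tibble::tibble(
#'   compound = c("AMP", "GMP"), rf1 = c(0.2, 0.5), rf2 = c(0.6, 0.3)
#' )
#' sp <- tibble::tibble(spot_id = 1, rf1 = 0.21, rf2 = 0.61, dpm = 900)
#' assign_tlc_spots(sp, std)
#' @export
assign_tlc_spots <- function(spots, standards, cutoff = 0.1) {
  for (nm in c("rf1", "rf2")) {
    if (any(spots[[nm]] < 0 | spots[[nm]] > 1) ||
      any(standards[[nm]] < 0 | standards[[nm]] > 1)) {
      abort("retention factors must lie in [0, 1].")
    }
  }
  if (any(spots$dpm < 0)) abort("spot dpm must be >= 0.")
  if (nrow(standards) == 0) abort("at least one standard is required.")
  std <- arrange(as_tibble(standards), .data$compound)
  assigned <- purrr::pmap_dfr(
    as_tibble(spots)[, c("rf1", "rf2")],
    function(rf1, rf2) {
      d <- sqrt((std$rf1 - rf1)^2 + (std$rf2 - rf2)^2)
      # ties (to rounding) go to the lexicographically smaller compound:
      # std is name-sorted, so the first index within tolerance wins
      near <- d <= min(d) + 1e-12
      i <- which(near)[1]
      tied <- sum(near) > 1
      if (d[i] > cutoff) {
        tibble(compound = NA_character_, distance = d[i], tied = FALSE)
      } else {
        tibble(compound = std$compound[i], distance = d[i], tied = tied)
      }
    }
  )
  dplyr::bind_cols(as_tibble(spots), assigned)
}

#' Summarise assigned TLC radioactivity per compound
#'
#' @param assigned Output of [assign_tlc_spots()].
#' @return A tibble of total `dpm` per `compound` (unassigned spots grouped
#'   under `NA`).
#' @export
tlc_dpm_by_compound <- function(assigned) {
  if (!all(c("compound", "dpm") %in% names(assigned))) {
    abort("`assigned` must come from assign_tlc_spots().")
  }
  assigned %>%
    group_by(.data$compound) %>%
    summarise(dpm = sum(.data$dpm), .groups = "drop")
}

#' Purine share of assigned TLC radioactivity
#'
#' Fraction of compound-assigned label residing in purine species — for
#' hydrolysed RNA the ribonucleotides AMP and GMP, for digested DNA the
#' deoxynucleosides dA and dG.
#'
#' @param assigned Output of [assign_tlc_spots()] (or any table with
#'   `compound` and `dpm` columns).
#' @param purines Compound names counted as purines.
#' @return Purine dpm over total assigned dpm, a fraction.
#' @export
purine_label_fraction <- function(assigned,
                                  purines = c("AMP", "GMP", "dA", "dG")) {
  by_comp <- tlc_dpm_by_compound(assigned) %>% filter(!is.na(.data$compound))
  tot <- sum(by_comp$dpm)
  if (tot == 0) abort("no assigned radioactivity to apportion.")
  sum(by_comp$dpm[by_comp$compound %in% purines]) / tot
}

#' Linear assay calibration
#'
#' Ordinary least-squares standard curve for colorimetric assays (signal
#' against amount), with inversion of sample signals back to amounts.
#' Covers both the formate plate assay (absorbance vs nmol formate per
#' well) and molybdenum-blue phosphate determination (absorbance vs nmol
#' P); the wet chemistry differs, the calibration algebra does not.
#'
#' @param data Data frame of standards.
#' @param amount,signal Names of the amount and signal columns (defaults
#'   `"amount_nmol"`, `"absorbance"`).
#' @return A `calibration_curve` object with `slope`, `intercept`, `r2`
#'   and `n`.
#' @examples
#' std <- tibble::tibble(amount_nmol = 0:5, absorbance = 0.01 + 0.05 * (0:5))
#' cal <- calibrate_linear(std)
#' invert_calibration(cal, 0.26) # 5 nmol
#' @export
calibrate_linear <- function(data, amount = "amount_nmol", signal = "absorbance") {
  if (!all(c(amount, signal) %in% names(data))) {
    abort(sprintf("`data` needs columns `%s` and `%s`.", amount, signal))
  }
  x <- data[[amount]]
  y <- data[[signal]]
  keep <- is.finite(x) & is.finite(y)
  if (sum(keep) < 3) abort("at least 3 standards are required.")
  if (stats::sd(y[keep]) == 0) {
    abort("degenerate calibration: zero slope cannot be inverted.")
  }
  f <- lm(y[keep] ~ x[keep])
  slope <- unname(coef(f)[2])
  if (!is.finite(slope) || slope == 0) {
    abort("degenerate calibration: zero slope cannot be inverted.")
  }
  r2 <- 1 - sum(stats::resid(f)^2) / sum((y[keep] - mean(y[keep]))^2)
  structure(
    list(
      slope = slope, intercept = unname(coef(f)[1]),
      r2 = r2, n = sum(keep)
    ),
    class = "calibration_curve"
  )
}

#' @rdname calibrate_linear
#' @param curve A `calibration_curve`.
#' @param x Signal values to invert.
#' @return `invert_calibration()`: amounts in the standards' unit; negative
#'   inversions are floored at 0 with a warning.
#' @export
invert_calibration <- function(curve, x) {
  stopifnot(inherits(curve, "calibration_curve"))
  amount <- (x - curve$intercept) / curve$slope
  if (any(amount < 0)) {
    warn("signal below the blank: inverted amount floored at 0.")
    amount <- pmax(amount, 0)
  }
  amount
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> signal = %.4g + %.4g x amount (r2 = %.4f, n = %d)\n",
    x$intercept, x$slope, x$r2, x$n
  ))
  invisible(x)
}

#' Per-cell formate from an assay plate
#'
#' Fits the calibration series of a formate plate, inverts the sample
#' absorbances to nmol per well, converts through the well volume to a
#' supernatant concentration and normalises by the culture cell yield.
#'
#' @param plate Plate table as produced by [simulate_formate_assay()]
#'   (`type`, `substrate`, `replicate`, `amount_nmol`, `absorbance`).
#' @param cell_yields Named vector of culture cell densities (cells/ml) by
#'   substrate.
#' @param well_ul Assayed supernatant volume per well (ul).
#' @return A tibble per substrate x replicate with `formate_nmol_well`,
#'   `formate_uM` and `formate_amol_cell`.
#' @export
formate_assay_analysis <- function(plate, cell_yields, well_ul = 50) {
  cal <- calibrate_linear(filter(plate, .data$type == "standard"))
  smp <- filter(plate, .data$type == "sample")
  if (!all(smp$substrate %in% names(cell_yields))) {
    abort("`cell_yields` must name every sample substrate.")
  }
  smp %>%
    mutate(
      formate_nmol_well = invert_calibration(cal, .data$absorbance),
      formate_uM = .data$formate_nmol_well / (well_ul * 1e-3),
      formate_amol_cell = formate_per_cell(
        .data$formate_uM, unname(cell_yields[.data$substrate])
      )
    ) %>%
    select(
      "substrate", "replicate", "formate_nmol_well",
      "formate_uM", "formate_amol_cell"
    )
}

#' Plot macromolecular fraction percentages
#'
#' @param data Output of [fraction_percentages()].
#' @return A ggplot bar chart of mean percent of pellet label per fraction
#'   with replicate points overlaid.
#' @export
plot_fraction_percentages <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$fraction, y = .data$pct)) +
    ggplot2::stat_summary(fun = mean, geom = "col", alpha = 0.7) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = NULL, y = "Radiolabel (% of cell pellet)",
      title = "Macromolecular distribution of radiolabel"
    ) +
    ggplot2::theme_minimal()
}
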