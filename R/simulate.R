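#' Simulate batch-culture growth curves
#'
#' Draws cell-density time series for every substrate in the configuration
#' from the three-parameter logistic
#' \deqn{N(t) = \frac{K N_0 e^{\mu t}}{K + N_0 (e^{\mu t} - 1)}}
#' with multiplicative lognormal noise of the configured coefficient of
#' variation.  The noise multiplier has mean exactly 1, so ensemble means
#' converge to the noiseless curve.
#'
#' @param cfg A [sim_config()].
#' @param n_rep Number of replicate cultures per substrate (>= 1).
#' @param sampling Strictly increasing vector of sampling times in days;
#'   the four-week default lets fast-growing cultures reach carrying
#'   capacity.
#' @return A tibble with columns `substrate`, `replicate`, `time_d`,
#'   `cells_per_ml`, carrying the generating parameters in the `"truth"`
#'   attribute.  Deterministic for a fixed config seed.
#' @examples
#' curves <- simulate_growth_curves(sim_config(noise_cv = 0, seed = 1))
#' dplyr::filter(curves, substrate == "phosphate", time_d == 21)
#' @export
simulate_growth_curves <- function(cfg, n_rep = 3, sampling = 0:28) {
  stopifnot(inherits(cfg, "sim_config"))
  if (n_rep < 1) abort("`n_rep` must be >= 1.")
  if (length(sampling) < 2 || any(diff(sampling) <= 0) || any(sampling < 0)) {
    abort("`sampling` must be non-negative and strictly increasing.")
  }
  sdlog <- sqrt(log(1 + cfg$noise_cv^2))
  out <- withr::with_seed(stream_seed(cfg$seed, "growth"), {
    purrr::pmap_dfr(cfg$growth, function(substrate, mu, K, N0) {
      mean_n <- logistic_density(sampling, mu, K, N0)
      purrr::map_dfr(seq_len(n_rep), function(r) {
        noise <- if (cfg$noise_cv > 0) {
          rlnorm(length(sampling), meanlog = -sdlog^2 / 2, sdlog = sdlog)
        } else {
          rep(1, length(sampling))
        }
        tibble(
          substrate = substrate, replicate = r,
          time_d = sampling, cells_per_ml = mean_n * noise
        )
      })
    })
  })
  attr(out, "truth") <- list(growth = cfg$growth, noise_cv = cfg$noise_cv)
  out
}

# noiseless logistic curve; mu = 0 degenerates to constant N0
logistic_density <- function(t, mu, K, N0) {
  e <- exp(mu * t)
  K * N0 * e / (K + N0 * (e - 1))
}

#' Simulate radiotracer incubations
#'
#' Forward-simulates liquid-scintillation counts for incubations of cultures
#' with a 14C-labelled substrate.  The expected disintegrations per minute are
#' the forward product of the true per-cell rate, the cell inventory
#' (density x volume), the incubation period and the effective specific
#' activity after isotope dilution by unlabelled carrier; realised counts are
#' Poisson draws around that expectation (radioactive counting statistics),
#' or exact when `noise = FALSE`.
#'
#' Conditions `"light"` and `"dark"` apply the corresponding configured rate
#' for the whole incubation; `"co2_trap"` applies the CO2 production rate
#' (its dpm are what a phenethylamine trap would collect); `"full_day"`
#' weights the light and dark rates by the configured photoperiod, for
#' incubations spanning whole light-dark cycles.
#'
#' @param cfg A [sim_config()].
#' @param cell_density Cell density during the incubation (cells/ml, > 0).
#' @param activity_added Radiotracer addition (uCi/ml).
#' @param sa_stock Stock specific activity (Ci/mol).
#' @param carrier_uM Unlabelled carrier substrate concentration (uM).
#' @param duration_h Incubation period (h, > 0).
#' @param volume_ml Incubation volume (ml).
#' @param conditions Character vector drawn from
#'   `c("light", "dark", "co2_trap", "full_day")`.
#' @param n_rep Replicates per condition.
#' @param noise Poisson counting noise on dpm (`TRUE`) or exact expected dpm.
#' @return A tibble in the incubation CSV schema (`condition`, `replicate`,
#'   `dpm`, `activity_uCi_ml`, `sa_Ci_mol`, `carrier_uM`, `volume_ml`,
#'   `cells_per_ml`, `duration_h`) with the true rates in the `"truth"`
#'   attribute.
#' @examples
#' inc <- simulate_tracer_incubations(sim_config(seed = 1),
#'   cell_density = 1e8, noise = FALSE
#' )
#' cell_specific_rate(inc)
#' @export
simulate_tracer_incubations <- function(cfg, cell_density,
                                        activity_added = 0.1,
                                        sa_stock = 59,
                                        carrier_uM = 0,
                                        duration_h = 12,
                                        volume_ml = 30,
                                        conditions = c("light", "dark", "co2_trap"),
                                        n_rep = 3,
                                        noise = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  check_positive(duration_h, "duration_h")
  check_nonneg(activity_added, "activity_added")
  check_nonneg(carrier_uM, "carrier_uM")
  rates <- c(
    light = cfg$true_cell_rate_light,
    dark = cfg$true_cell_rate_dark,
    co2_trap = cfg$true_cell_rate_co2,
    full_day = (cfg$true_cell_rate_light * cfg$photoperiod_h +
      cfg$true_cell_rate_dark * (24 - cfg$photoperiod_h)) / 24
  )
  conditions <- match.arg(conditions, names(rates), several.ok = TRUE)
  if (cell_density <= 0 && any(rates[conditions] > 0)) {
    abort("`cell_density` must be > 0 when true rates are non-zero.")
  }
  sa_eff <- effective_specific_activity(activity_added, sa_stock, carrier_uM)
  out <- withr::with_seed(stream_seed(cfg$seed, "tracer"), {
    purrr::map_dfr(conditions, function(cond) {
      # zmol/cell/h -> mol over the incubation -> dpm at the effective SA
      expected_mol <- rates[[cond]] * 1e-21 * cell_density * volume_ml * duration_h
      expected_dpm <- expected_mol * sa_eff * DPM_PER_CI
      dpm <- if (noise) rpois(n_rep, expected_dpm) else rep(expected_dpm, n_rep)
      tibble(
        condition = cond, replicate = seq_len(n_rep), dpm = as.numeric(dpm),
        activity_uCi_ml = activity_added, sa_Ci_mol = sa_stock,
        carrier_uM = carrier_uM, volume_ml = volume_ml,
        cells_per_ml = cell_density, duration_h = duration_h
      )
    })
  })
  attr(out, "truth") <- list(rates_zmol_cell_h = rates[conditions], sa_eff = sa_eff)
  out
}

#' Simulate a macromolecular fractionation experiment
#'
#' Distributes the radiolabel of each replicate cell pellet over the
#' metabolite, lipid, RNA, DNA and protein fractions by a multinomial draw
#' from the configured proportions; the residual share of the simplex is
#' label lost during the extraction sequence and appears in no fraction.
#'
#' @param cfg A [sim_config()].
#' @param total_dpm Radioactivity of the intact cell pellet (dpm, > 0).
#' @param n_rep Number of replicate pellets.
#' @return A tibble with columns `replicate`, `fraction`, `dpm`,
#'   `pellet_total_dpm`.
#' @examples
#' simulate_fractionation_profile(sim_config(seed = 1), total_dpm = 1e4)
#' @export
simulate_fractionation_profile <- function(cfg, total_dpm = 1e4, n_rep = 3) {
  stopifnot(inherits(cfg, "sim_config"))
  check_positive(total_dpm, "total_dpm")
  props <- cfg$fractionation
  fr <- setdiff(names(props), "residual")
  out <- withr::with_seed(stream_seed(cfg$seed, "fractionation"), {
    counts <- rmultinom(n_rep, size = round(total_dpm), prob = props)
    purrr::map_dfr(seq_len(n_rep), function(r) {
      tibble(
        replicate = r, fraction = fr, dpm = as.numeric(counts[fr, r]),
        pellet_total_dpm = total_dpm
      )
    })
  })
  attr(out, "truth") <- list(proportions = props)
  out
}

#' Simulate a colorimetric formate assay plate
#'
#' Generates a calibration series (formate standards spanning 0 to 10 nmol
#' per well) and culture-supernatant sample wells.  Sample absorbance follows
#' the configured linear calibration applied to the nmol of formate in the
#' well, which is the per-cell formate level times the culture cell yield
#' converted through the well volume; Gaussian plate-reader noise is added to
#' every well.
#'
#' @param cfg A [sim_config()].
#' @param cell_yields Named vector of culture cell yields by substrate
#'   (cells/ml).  Defaults to the configured carrying capacities.
#' @param n_rep Replicate cultures per substrate.
#' @param standards_nmol Amounts of the calibration series (nmol per well).
#' @return A tibble with columns `type` (`"standard"`/`"sample"`),
#'   `substrate`, `replicate`, `amount_nmol` (`NA` for samples) and
#'   `absorbance`; true per-cell formate levels sit in the `"truth"`
#'   attribute.
#' @examples
#' plate <- simulate_formate_assay(sim_config(assay_noise_sd = 0, seed = 1))
#' dplyr::filter(plate, type == "sample")
#' @export
simulate_formate_assay <- function(cfg,
                                   cell_yields = setNames(cfg$growth$K, cfg$growth$substrate),
                                   n_rep = 3,
                                   standards_nmol = c(0, 2, 4, 6, 8, 10)) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(names(cell_yields)) || any(cell_yields <= 0)) {
    abort("`cell_yields` must be a named vector of positive densities.")
  }
  missing_sub <- setdiff(names(cell_yields), names(cfg$formate_per_cell))
  if (length(missing_sub)) {
    abort(paste("no formate truth configured for:", paste(missing_sub, collapse = ", ")))
  }
  out <- withr::with_seed(stream_seed(cfg$seed, "assay"), {
    std <- tibble(
      type = "standard", substrate = NA_character_, replicate = 1L,
      amount_nmol = standards_nmol,
      absorbance = cfg$calib_intercept + cfg$calib_slope * standards_nmol +
        rnorm(length(standards_nmol), sd = cfg$assay_noise_sd)
    )
    smp <- purrr::map_dfr(names(cell_yields), function(sub) {
      conc_uM <- formate_well_concentration(cfg$formate_per_cell[[sub]], cell_yields[[sub]])
      nmol <- conc_uM * cfg$well_ul * 1e-3 # uM over well_ul ul -> nmol
      tibble(
        type = "sample", substrate = sub, replicate = seq_len(n_rep),
        amount_nmol = NA_real_,
        absorbance = cfg$calib_intercept + cfg$calib_slope * nmol +
          rnorm(n_rep, sd = cfg$assay_noise_sd)
      )
    })
    bind_rows(std, smp)
  })
  attr(out, "truth") <- list(
    formate_per_cell = cfg$formate_per_cell[names(cell_yields)],
    cell_yields = cell_yields, well_ul = cfg$well_ul,
    slope = cfg$calib_slope, intercept = cfg$calib_intercept
  )
  out
}

# per-cell amol x cells/ml -> supernatant concentration in uM
formate_well_concentration <- function(amol_per_cell, cells_per_ml) {
  amol_per_cell * cells_per_ml * 1e-9
}

#' Simulate a genome survey with alignment output
#'
#' Generates genome metadata and a 12-column tabular protein-alignment table
#' for a presence/absence survey of a two-gene pathway across ocean basins.
#' Genomes carrying the pathway yield high-identity alignments to both
#' reference proteins; genomes lacking it yield either no alignment rows or
#' sub-threshold identities.
#'
#' @param n_by_ocean Named integer vector: genomes surveyed per ocean.
#' @param presence_prob_by_ocean Named vector of carriage probabilities,
#'   names matching `n_by_ocean`.
#' @param identity_present Mean percent identity of both proteins in carrier
#'   genomes (should exceed the screening threshold).
#' @param identity_absent Mean percent identity of spurious hits in
#'   non-carrier genomes (capped below 97).
#' @param p_no_hit Probability that a non-carrier genome produces no
#'   alignment row at all.
#' @param seed Integer seed.
#' @return A list with elements `metadata` (a tibble of survey records) and
#'   `alignments` (a tibble in the 12-column tabular alignment dialect), plus
#'   a `"truth"` attribute recording the drawn presence flags.
#' @examples
#' sv <- simulate_survey(
#'   n_by_ocean = c(NAO = 20, NPO = 20),
#'   presence_prob_by_ocean = c(NAO = 0.5, NPO = 0.05), seed = 1
#' )
#' head(sv$alignments)
#' @export
simulate_survey <- function(n_by_ocean,
                            presence_prob_by_ocean,
                            identity_present = 98.5,
                            identity_absent = 55,
                            p_no_hit = 0.5,
                            seed = 1L) {
  if (is.null(names(n_by_ocean)) ||
    !all(names(n_by_ocean) %in% names(presence_prob_by_ocean))) {
    abort("`n_by_ocean` and `presence_prob_by_ocean` must share ocean names.")
  }
  if (any(presence_prob_by_ocean < 0 | presence_prob_by_ocean > 1)) {
    abort("presence probabilities must lie in [0, 1].")
  }
  withr::with_seed(stream_seed(seed, "survey"), {
    meta <- purrr::map_dfr(names(n_by_ocean), function(oc) {
      n <- n_by_ocean[[oc]]
      tibble(
        genome_id = sprintf("%s_g%04d", oc, seq_len(n)),
        clade = NA_character_,
        depth_m = round(stats::runif(n, 5, 150)),
        latitude = NA_real_, longitude = NA_real_,
        ocean = oc,
        carrier = stats::runif(n) < presence_prob_by_ocean[[oc]]
      )
    })
    aln <- purrr::pmap_dfr(meta, function(genome_id, carrier, ...) {
      if (carrier) {
        ident <- pmin(100, identity_present + stats::rnorm(2, sd = 0.3))
      } else {
        if (stats::runif(1) < p_no_hit) {
          return(tibble())
        }
        ident <- pmin(96.9, identity_absent + stats::rnorm(2, sd = 5))
      }
      tibble(
        qseqid = c("PhnY_ref", "PhnZ_ref"),
        sseqid = paste0(genome_id, "|", c("p1", "p2")),
        pident = round(pmax(ident, 0), 1),
        length = c(190L, 180L), mismatch = 0L, gapopen = 0L,
        qstart = 1L, qend = c(190L, 180L), sstart = 1L, send = c(190L, 180L),
        evalue = 1e-80, bitscore = round(2 * ident)
      )
    })
    out <- list(
      metadata = select(meta, -"carrier"),
      alignments = aln
    )
    attr(out, "truth") <- list(carrier = setNames(meta$carrier, meta$genome_id))
    out
  })
}

#' Write a full synthetic dataset to disk
#'
#' Generates every input stream the analysis modules read (growth curves,
#' tracer incubations, fractionation profiles, the formate assay plate and
#' the genome survey) and writes them as CSV/TSV files together with a
#' ground-truth JSON sidecar.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if missing).
#' @param cell_density Cell density for the tracer incubations (cells/ml).
#' @return Invisibly, the named list of generated objects.
#' @export
write_simulation <- function(cfg, dir, cell_density = 1e8) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  curves <- simulate_growth_curves(cfg)
  incs <- simulate_tracer_incubations(cfg, cell_density = cell_density)
  frac <- simulate_fractionation_profile(cfg)
  plate <- simulate_formate_assay(cfg)
  survey <- simulate_survey(
    n_by_ocean = c(NAO = 219, NPO = 187),
    presence_prob_by_ocean = c(NAO = 14 / 219, NPO = 1 / 187),
    seed = cfg$seed
  )
  readr::write_csv(curves, file.path(dir, "growth_curves.csv"))
  readr::write_csv(incs, file.path(dir, "incubations.csv"))
  readr::write_csv(frac, file.path(dir, "fractionation.csv"))
  readr::write_csv(plate, file.path(dir, "formate_assay.csv"))
  readr::write_csv(survey$metadata, file.path(dir, "genomes.csv"))
  readr::write_tsv(survey$alignments, file.path(dir, "alignments.tsv"),
    col_names = FALSE
  )
  truth <- list(
    growth = attr(curves, "truth"),
    tracer = attr(incs, "truth"),
    fractionation = attr(frac, "truth"),
    assay = attr(plate, "truth"),
    survey = list(n_carriers = sum(attr(survey, "truth")$carrier)),
    seed = cfg$seed
  )
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(list(
    growth = curves, incubations = incs, fractionation = frac,
    assay = plate, survey = survey
  ))
}
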