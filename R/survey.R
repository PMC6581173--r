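#' Screen genomes for pathway presence from alignment tables
#'
#' Reduces a 12-column tabular protein-alignment table (best hits of two
#' reference proteins against many genomes) to a per-genome presence call.
#' For each genome and reference protein the best hit is the row with the
#' maximum bitscore, ties broken by the higher percent identity; the genome
#' is called present when the best-hit identity for *both* proteins clears
#' the threshold.  The comparison is strict (`> threshold`) by default,
#' matching a ">97% identity" screening rule.  Genomes listed as reference
#' strains (the sources of the query proteins) are flagged separately so
#' enumeration can exclude them.
#'
#' @param alignments Alignment tibble with at least `qseqid`, `sseqid`,
#'   `pident`, `bitscore` (see [read_alignments()]).
#' @param metadata Genome metadata with columns `genome_id` and `ocean`
#'   (plus any others, passed through).
#' @param id_threshold Percent-identity threshold (default 97).
#' @param require_both Demand both proteins above threshold (default) or
#'   either.
#' @param strict Use `>` (default) rather than `>=` against the threshold.
#' @param reference_ids Genome ids to flag as reference strains.
#' @param genome_from_subject Function mapping subject sequence ids to
#'   genome ids; default takes everything before the first `|`.
#' @param protein_from_query Function mapping query ids to a reference
#'   protein label; default takes everything before the first `_` or `|`,
#'   so queries `PhnY_MIT9301` and `PhnY_MIT9303` both screen the protein
#'   `PhnY`.
#' @return The metadata tibble with one appended identity column per
#'   reference protein (`identity_<protein>`, `NA` when the genome has no
#'   hit) plus `present` and `is_reference`.  Order-independent in the
#'   alignment rows and idempotent.
#' @examples
#' sv <- simulate_survey(c(NAO = 10), c(NAO = 0.5), seed = 1)
#' screen_presence(sv$alignments, sv$metadata)
#' @export
screen_presence <- function(alignments, metadata,
                            id_threshold = 97,
                            require_both = TRUE,
                            strict = TRUE,
                            reference_ids = character(),
                            genome_from_subject = function(s) sub("\\|.*$", "", s),
                            protein_from_query = function(q) sub("[_|].*$", "", q)) {
  if (!all(c("genome_id", "ocean") %in% names(metadata))) {
    abort("`metadata` needs columns `genome_id` and `ocean`.")
  }
  clears <- function(ident) {
    !is.na(ident) & if (strict) ident > id_threshold else ident >= id_threshold
  }
  meta <- as_tibble(metadata)
  if (nrow(alignments) == 0) {
    best_wide <- tibble(genome_id = character())
    proteins <- character()
  } else {
    need <- c("qseqid", "sseqid", "pident", "bitscore")
    if (!all(need %in% names(alignments))) {
      abort(paste("`alignments` needs columns:", paste(need, collapse = ", ")))
    }
    best <- as_tibble(alignments) %>%
      mutate(
        genome_id = genome_from_subject(.data$sseqid),
        protein = protein_from_query(.data$qseqid)
      ) %>%
      group_by(.data$genome_id, .data$protein) %>%
      arrange(dplyr::desc(.data$bitscore), dplyr::desc(.data$pident)) %>%
      dplyr::slice(1) %>%
      ungroup()
    proteins <- sort(unique(best$protein))
    best_wide <- best %>%
      select("genome_id", "protein", "pident") %>%
      tidyr::pivot_wider(
        names_from = "protein", values_from = "pident",
        names_prefix = "identity_"
      )
  }
  out <- left_join(meta, best_wide, by = "genome_id")
  id_cols <- paste0("identity_", proteins)
  for (col in id_cols) {
    if (!col %in% names(out)) out[[col]] <- NA_real_
  }
  hit_mat <- if (length(id_cols)) {
    vapply(out[id_cols], clears, logical(nrow(out)))
  } else {
    matrix(FALSE, nrow(out), 0)
  }
  if (is.null(dim(hit_mat))) hit_mat <- matrix(hit_mat, nrow = nrow(out))
  out$present <- if (ncol(hit_mat) == 0) {
    rep(FALSE, nrow(out))
  } else if (require_both) {
    rowSums(hit_mat) == ncol(hit_mat)
  } else {
    rowSums(hit_mat) > 0
  }
  out$is_reference <- out$genome_id %in% reference_ids
  out
}

#' Count pathway-positive genomes per ocean
#'
#' @param records Output of [screen_presence()].
#' @param include_reference Count flagged reference strains too (default
#'   `FALSE`).
#' @return A tibble of `ocean`, `n_present` and `n_screened` (screened =
#'   records in the table for that ocean, references excluded unless
#'   requested).
#' @export
count_by_ocean <- function(records, include_reference = FALSE) {
  need <- c("ocean", "present", "is_reference")
  if (!all(need %in% names(records))) {
    abort("`records` must come from screen_presence().")
  }
  r <- if (include_reference) records else filter(records, !.data$is_reference)
  r %>%
    group_by(.data$ocean) %>%
    summarise(
      n_present = sum(.data$present), n_screened = n(), .groups = "drop"
    )
}

#' Biogeographic enrichment of pathway presence
#'
#' Computes the pathway-presence proportion per ocean basin against the
#' total number of genomes surveyed there, and tests whether the proportion
#' differs between two named basins with a Yates-corrected two-proportion
#' test ([two_proportion_test()]).  Reference strains count toward the
#' numerator by default: they are surveyed genomes that carry the pathway.
#'
#' @param records Output of [screen_presence()].
#' @param totals_by_ocean Named vector: total genomes surveyed per ocean
#'   (the denominator; presence records alone do not determine it).
#' @param oceans Length-2 character vector of basins to test (first vs
#'   second).
#' @param alternative Passed to [two_proportion_test()]; default
#'   `"greater"` (first basin enriched).
#' @param include_reference Include reference strains in presence counts
#'   (default `TRUE`).
#' @return A list with `proportions` (tibble of ocean, n_present, n_total,
#'   proportion) and `test` (a `prop_test_result`).
#' @examples
#' sv <- simulate_survey(
#'   n_by_ocean = c(NAO = 219, NPO = 187),
#'   presence_prob_by_ocean = c(NAO = 14 / 219, NPO = 1 / 187), seed = 42
#' )
#' rec <- screen_presence(sv$alignments, sv$metadata)
#' ocean_enrichment(rec, c(NAO = 219, NPO = 187))
#' @export
ocean_enrichment <- function(records, totals_by_ocean,
                             oceans = c("NAO", "NPO"),
                             alternative = "greater",
                             include_reference = TRUE) {
  if (is.null(names(totals_by_ocean))) {
    abort("`totals_by_ocean` must be named by ocean.")
  }
  if (length(oceans) != 2 || !all(oceans %in% names(totals_by_ocean))) {
    abort("`oceans` must name two basins present in `totals_by_ocean`.")
  }
  counts <- count_by_ocean(records, include_reference = include_reference)
  props <- tibble(
    ocean = names(totals_by_ocean),
    n_total = unname(totals_by_ocean)
  ) %>%
    left_join(select(counts, "ocean", "n_present"), by = "ocean") %>%
    mutate(
      n_present = dplyr::coalesce(.data$n_present, 0L),
      proportion = .data$n_present / .data$n_total
    )
  a <- filter(props, .data$ocean == oceans[1])
  b <- filter(props, .data$ocean == oceans[2])
  test <- two_proportion_test(
    a$n_present, a$n_total, b$n_present, b$n_total,
    alternative = alternative, continuity = TRUE
  )
  list(proportions = props, test = test)
}

#' Reference genome-survey fixture
#'
#' The reported survey of 18 *Prochlorococcus* genomes carrying the
#' PhnY-PhnZ phosphonate oxidation pathway (two of them the reference
#' strains MIT9301 and MIT9303 that supplied the query proteins), with
#' clade, sampling depth, coordinates and ocean basin, plus a matching
#' synthetic alignment table.  Per-genome alignment identities other than
#' the low-light genome's 99.6/100 match to the MIT9303 proteins and the
#' 48.0/49.4 identity between the two reference strains' proteins are not
#' reported; carriers are given a representative synthetic identity of
#' 98.5 so only the presence calls, not the identity values, are meaningful.
#'
#' @return A list with `metadata` (18 survey records with `is_reference`)
#'   and `alignments` (12-column alignment tibble of the four query
#'   proteins against all 18 genomes).
#' @examples
#' ref <- phn_survey_reference()
#' rec <- screen_presence(ref$alignments, ref$metadata,
#'   reference_ids = c("MIT9301", "MIT9303")
#' )
#' count_by_ocean(rec)
#' @export
phn_survey_reference <- function() {
  metadata <- tibble(
    genome_id = c(
      "MIT9301", "MIT9302", "MIT9303",
      "AG-355-M18", "AG-355-N22", "AG-355-P11", "AG-363-B18",
      "AG-388-E21", "AG-388-I18",
      "AG-412-C21", "AG-412-F02", "AG-412-L10",
      "AG-424-J22", "AG-424-P23", "AG-670-M15",
      "RS01", "RS04", "RS50"
    ),
    img_id = c(
      "640069322", "2606217691", "640069323",
      "2667527302", "2667527306", "2667527349", "2667527363",
      "2716884367", "2716884369",
      "2716884755", "2716884756", "2716884761",
      "2716884773", "2716884420", "2716884478",
      "2765235964", "2765235965", "2765235963"
    ),
    clade = c(
      "HLII", "HLII", "LLIV",
      "HLII", "HLII", "HLII", "HLVI",
      "HLI", "HLI",
      "HLII", "HLVI", "LLIV",
      "HLII", "HLII", "HLII",
      NA, NA, NA
    ),
    depth_m = c(
      90, 100, 100, 10, 10, 10, 100, 8, 8,
      119, 119, 119, 90.8, 90.8, 5, 10, 10, 10
    ),
    latitude = c(
      34.75, 34.75, 34.75, 31.67, 31.67, 31.67, 31.67, 36.20, 36.20,
      24.71, 24.71, 24.71, 38.32, 38.32, 28.14, 22.05, 22.05, 22.05
    ),
    longitude = c(
      -66.18, -66.19, -66.18, -64.17, -64.17, -64.17, -64.17, -53.31, -53.31,
      -67.07, -67.07, -67.07, -68.87, -68.87, -158.00, 37.93, 37.93, 37.93
    ),
    ocean = c(
      rep("NAO", 14), "NPO", rep("RS", 3)
    ),
    is_reference = c(TRUE, FALSE, TRUE, rep(FALSE, 15))
  )
  # identity of each genome's best hit against the PhnY/PhnZ queries of the
  # two reference strains; 98.5 is a synthetic stand-in above the 97% screen
  hi <- 98.5
  lo_y <- 48.0 # reported PhnY identity between the two reference strains
  lo_z <- 49.4 # reported PhnZ identity between the two reference strains
  ident <- function(genome) {
    switch(genome,
      "MIT9301" = c(100, 100, lo_y, lo_z),
      "MIT9303" = c(lo_y, lo_z, 100, 100),
      "AG-412-L10" = c(lo_y, lo_z, 99.6, 100),
      c(hi, hi, lo_y, lo_z)
    )
  }
  queries <- c("PhnY_MIT9301", "PhnZ_MIT9301", "PhnY_MIT9303", "PhnZ_MIT9303")
  alignments <- purrr::map_dfr(metadata$genome_id, function(g) {
    id <- ident(g)
    tibble(
      qseqid = queries,
      sseqid = paste0(g, "|", c("phnY", "phnZ", "phnY", "phnZ")),
      pident = id,
      length = c(190L, 180L, 190L, 180L),
      mismatch = as.integer(round((100 - id) / 100 * c(190, 180, 190, 180))),
      gapopen = 0L, qstart = 1L, qend = c(190L, 180L, 190L, 180L),
      sstart = 1L, send = c(190L, 180L, 190L, 180L),
      evalue = ifelse(id > 90, 1e-100, 1e-30),
      bitscore = round(id * 2)
    )
  })
  list(metadata = metadata, alignments = alignments)
}

#' Plot pathway presence proportions by ocean
#'
#' @param enrichment Output of [ocean_enrichment()].
#' @return A ggplot bar chart of presence proportion per basin.
#' @export
plot_ocean_enrichment <- function(enrichment) {
  ggplot2::ggplot(
    enrichment$proportions,
    ggplot2::aes(x = .data$ocean, y = .data$proportion * 100)
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "Ocean basin", y = "Genomes with pathway (%)",
      title = "Biogeography of the phosphonate oxidation pathway"
    ) +
    ggplot2::theme_minimal()
}
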