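#' Read and write the analysis CSV/TSV schemas
#'
#' Thin readr wrappers fixing the column schemas the analysis functions
#' expect, so files written by [write_simulation()] (or by hand) round-trip
#' cleanly.
#'
#' @param path File path.
#' @return A tibble in the corresponding schema:
#' \describe{
#'   \item{`read_growth_curves()`}{`substrate`, `replicate`, `time_d`,
#'     `cells_per_ml`.}
#'   \item{`read_incubations()`}{`condition`, `replicate`, `dpm`,
#'     `activity_uCi_ml`, `sa_Ci_mol`, `carrier_uM`, `volume_ml`,
#'     `cells_per_ml`, `duration_h`.}
#'   \item{`read_fractionation()`}{`replicate`, `fraction`, `dpm`,
#'     `pellet_total_dpm`.}
#'   \item{`read_genome_metadata()`}{`genome_id`, `ocean` and any further
#'     columns.}
#'   \item{`read_alignments()`}{the 12-column tabular alignment dialect
#'     (`qseqid`, `sseqid`, `pident`, `length`, `mismatch`, `gapopen`,
#'     `qstart`, `qend`, `sstart`, `send`, `evalue`, `bitscore`), headerless
#'     TSV.}
#' }
#' @name io
NULL

#' @rdname io
#' @export
read_growth_curves <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("substrate", "replicate", "time_d", "cells_per_ml")
  if (!all(need %in% names(d))) {
    abort(paste("growth-curve file needs columns:", paste(need, collapse = ", ")))
  }
  d
}

#' @rdname io
#' @export
read_incubations <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  need <- c(
    "condition", "dpm", "activity_uCi_ml", "sa_Ci_mol", "carrier_uM",
    "volume_ml", "cells_per_ml", "duration_h"
  )
  if (!all(need %in% names(d))) {
    abort(paste("incubation file needs columns:", paste(need, collapse = ", ")))
  }
  d
}

#' @rdname io
#' @export
read_fractionation <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("replicate", "fraction", "dpm", "pellet_total_dpm")
  if (!all(need %in% names(d))) {
    abort(paste("fractionation file needs columns:", paste(need, collapse = ", ")))
  }
  d
}

#' @rdname io
#' @export
read_genome_metadata <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("genome_id", "ocean") %in% names(d))) {
    abort("genome metadata needs columns `genome_id` and `ocean`.")
  }
  d
}

alignment_cols <- c(
  "qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
  "qstart", "qend", "sstart", "send", "evalue", "bitscore"
)

#' @rdname io
#' @export
read_alignments <- function(path) {
  d <- readr::read_tsv(path,
    col_names = alignment_cols, show_col_types = FALSE,
    col_types = readr::cols(
      qseqid = "c", sseqid = "c", pident = "d", length = "i", mismatch = "i",
      gapopen = "i", qstart = "i", qend = "i", sstart = "i", send = "i",
      evalue = "d", bitscore = "d"
    )
  )
  d
}
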