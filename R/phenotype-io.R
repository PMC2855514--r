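#' Construct and validate a phenotype table
#'
#' A phenotype table is one row per sample with the clinical and outcome
#' fields the analyses use: `sample_id`, `outcome` (lethal / indolent /
#' excluded), `death_from_cancer` (logical, `NA` = unknown), `followup_years`,
#' `age_at_diagnosis`, `gleason_category` (G4_6 / G7 / G8_10 / unknown) and
#' `erg_status` (rearranged / negative / unknown). The lethal class is by
#' definition death from the cancer during follow-up, so `outcome == "lethal"`
#' forces `death_from_cancer == TRUE`.
#'
#' @param df A data frame with at least `sample_id`, `outcome`,
#'   `death_from_cancer` and `followup_years`; missing optional columns are
#'   added as unknown.
#' @return A tibble satisfying the phenotype contract.
#' @export
phenotype_table <- function(df) {
  df <- tibble::as_tibble(df)
  mandatory <- c("sample_id", "outcome", "death_from_cancer", "followup_years")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols)) {
    abort(sprintf("phenotype schema error: missing mandatory column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    abort(sprintf("phenotype schema error: duplicate sample_id: %s",
                  df$sample_id[duplicated(df$sample_id)][[1L]]))
  }
  out <- as.character(df$outcome)
  if (!all(out %in% outcome_levels)) {
    abort(sprintf("unknown outcome level(s): %s",
                  paste(unique(setdiff(out, outcome_levels)), collapse = ", ")))
  }
  df$outcome <- factor(out, levels = outcome_levels)
  df$death_from_cancer <- as.logical(df$death_from_cancer)
  df$followup_years <- as.numeric(df$followup_years)
  if (any(is.na(df$followup_years)) || any(df$followup_years < 0)) {
    abort("followup_years must be non-negative")
  }
  bad <- df$outcome == "lethal" & !(df$death_from_cancer %in% TRUE)
  if (any(bad)) {
    abort(sprintf(
      "outcome 'lethal' requires death_from_cancer = TRUE (violated by %s)",
      df$sample_id[bad][[1L]]))
  }
  if (!"age_at_diagnosis" %in% names(df)) df$age_at_diagnosis <- NA_real_
  df$age_at_diagnosis <- as.numeric(df$age_at_diagnosis)
  gl <- if ("gleason_category" %in% names(df)) df$gleason_category else
    rep(NA_character_, nrow(df))
  df$gleason_category <- parse_gleason(gl)
  df$erg_status <- parse_erg(if ("erg_status" %in% names(df)) df$erg_status else
    rep(NA_character_, nrow(df)))
  df
}

# Gleason scores are grouped 4-6 / 7 / 8-10; numeric scores and range
# strings both map onto the three bands. Unparsable values become the
# explicit unknown level (callers count the warnings).
parse_gleason <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("unknown", length(x))
  out[x %in% c("g4_6", "4-6", "4_6", "2", "3", "4", "5", "6")] <- "G4_6"
  out[x %in% c("g7", "7")] <- "G7"
  out[x %in% c("g8_10", "8-10", "8_10", "8", "9", "10")] <- "G8_10"
  unparsable <- !(x %in% c("", "na", "unknown")) & out == "unknown" & !is.na(x)
  if (any(unparsable)) {
    warn(sprintf("%d unparsable gleason_category value(s) set to unknown",
                 sum(unparsable)))
  }
  factor(out, levels = gleason_levels)
}

parse_erg <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("unknown", length(x))
  out[x %in% c("rearranged", "positive", "fusion", "erg+", "1", "true", "yes")] <- "rearranged"
  out[x %in% c("negative", "erg-", "0", "false", "no")] <- "negative"
  unparsable <- !(x %in% c("", "na", "unknown")) & out == "unknown" & !is.na(x)
  if (any(unparsable)) {
    warn(sprintf("%d unparsable erg_status value(s) set to unknown",
                 sum(unparsable)))
  }
  factor(out, levels = erg_levels)
}

#' Read a phenotype table from TSV
#'
#' Expects a header naming the phenotype fields (see [phenotype_table()]).
#' Mandatory columns are `sample_id`, `outcome`, `death_from_cancer` and
#' `followup_years`; optional clinical fields that are absent or unparsable
#' become the explicit `unknown` level with a warning.
#'
#' @param path Path to a TSV file.
#' @return A phenotype tibble.
#' @export
read_phenotype <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE, na.strings = c("NA", ""))
  phenotype_table(df)
}

#' Write a phenotype table to TSV
#'
#' @param phenotype A phenotype tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotype <- function(phenotype, path) {
  readr::write_tsv(phenotype, path)
  invisible(path)
}
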