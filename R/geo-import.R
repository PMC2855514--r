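#' Default mapping from GEO characteristic keys to phenotype fields
#'
#' GEO series-matrix files carry per-sample annotations as
#' `!Sample_characteristics_ch1` lines of the form `"key: value"`. The key
#' labels are curator-chosen and not standardised, so the importer takes an
#' editable mapping from phenotype field to the characteristic key(s) that
#' hold it. The defaults are guesses suitable for prostate watchful-waiting
#' deposits such as GSE16560 and should be checked against the live record
#' before a real-data run.
#'
#' @return Named list: phenotype field -> character vector of candidate
#'   characteristic keys (matched case-insensitively).
#' @export
geo_default_mapping <- function() {
  list(
    outcome = c("outcome", "status", "disease status", "lethal"),
    death_from_cancer = c("death_from_cancer", "died of cancer", "cancer death"),
    followup_years = c("followup_years", "followup", "follow-up", "fup", "fup.year"),
    age_at_diagnosis = c("age_at_diagnosis", "age", "age at diagnosis"),
    gleason_category = c("gleason_category", "gleason", "gleason score"),
    erg_status = c("erg_status", "erg", "erg rearrangement", "erg fusion")
  )
}

#' Import a GEO series-matrix file as a cohort
#'
#' Parses the `!`-prefixed metadata lines and the expression table between
#' `!series_matrix_table_begin` and `!series_matrix_table_end`. Sample
#' characteristics are translated into phenotype fields through `mapping`
#' (see [geo_default_mapping()]); characteristic keys with no mapping are kept
#' as extra annotation columns. Samples without a mapped outcome get
#' `outcome = "excluded"`. Gzipped files are read transparently.
#'
#' @param path Path to a series-matrix text file (optionally `.gz`).
#' @param mapping Field-to-key mapping; see [geo_default_mapping()].
#' @return A `"cohort"` object.
#' @export
import_geo_series_matrix <- function(path, mapping = geo_default_mapping()) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)

  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L) {
    abort("format error: missing !series_matrix_table_begin/end delimiters")
  }
  expr <- parse_delim_matrix(lines[(begin + 1L):(end - 1L)], id_cols = 1L,
                             path = path)$values
  expr <- validate_expression_matrix(expr)

  meta <- lines[startsWith(lines, "!Sample_")]
  meta_cells <- lapply(strsplit(meta, "\t", fixed = TRUE), unquote_field)
  keys <- vapply(meta_cells, `[[`, character(1L), 1L)
  n_samp <- ncol(expr)

  # characteristics lines: one line per characteristic slot, one cell per
  # sample, each "key: value"
  char_rows <- meta_cells[keys == "!Sample_characteristics_ch1"]
  annot <- list()
  for (row in char_rows) {
    vals <- row[-1L]
    length(vals) <- n_samp
    kv <- regmatches(vals, regexpr(":", vals), invert = TRUE)
    k <- tolower(trimws(vapply(kv, function(p) if (length(p) == 2L) p[[1L]] else "", character(1L))))
    v <- trimws(vapply(kv, function(p) if (length(p) == 2L) p[[2L]] else NA_character_, character(1L)))
    for (key in unique(k[nzchar(k)])) {
      col <- rep(NA_character_, n_samp)
      col[k == key] <- v[k == key]
      if (is.null(annot[[key]])) annot[[key]] <- col
      else annot[[key]] <- ifelse(is.na(annot[[key]]), col, annot[[key]])
    }
  }
  if (!length(annot)) warn("no sample characteristics found; all outcomes set to excluded")

  pick <- function(field) {
    for (key in tolower(mapping[[field]])) if (!is.null(annot[[key]])) return(annot[[key]])
    rep(NA_character_, n_samp)
  }
  outcome <- tolower(pick("outcome"))
  outcome[!outcome %in% c("lethal", "indolent")] <- "excluded"
  n_unmapped <- sum(outcome == "excluded")
  if (n_unmapped > 0L) {
    inform(sprintf("import_geo_series_matrix: %d sample(s) without a mapped outcome set to excluded", n_unmapped))
  }
  dfc <- suppressWarnings(as.numeric(pick("death_from_cancer")))
  death <- ifelse(outcome == "lethal", TRUE,
                  ifelse(is.na(dfc), outcome == "lethal", dfc > 0))
  fup <- suppressWarnings(as.numeric(pick("followup_years")))
  fup[is.na(fup) | fup < 0] <- 0
  ph <- tibble::tibble(
    sample_id = colnames(expr),
    outcome = outcome,
    death_from_cancer = death,
    followup_years = fup,
    age_at_diagnosis = suppressWarnings(as.numeric(pick("age_at_diagnosis"))),
    gleason_category = pick("gleason_category"),
    erg_status = pick("erg_status")
  )
  # unmapped characteristic keys ride along as opaque annotation columns
  mapped_keys <- tolower(unlist(mapping))
  for (key in setdiff(names(annot), mapped_keys)) {
    ph[[paste0("geo_", gsub("[^a-z0-9]+", "_", key))]] <- annot[[key]]
  }
  cohort(expr, phenotype_table(ph))
}
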