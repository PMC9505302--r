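#' Clonotype tables
#'
#' A clonotype table is an ordinary tibble with one row per clonotype and at
#' least the columns `cdr3_nt`, `count` and `freq`; the full column set used
#' throughout the package is `sample_id`, `subject_id`, `subset`, `timepoint`,
#' `v_call`, `d_call`, `j_call`, `cdr3_nt`, `cdr3_aa`, `count`, `freq`.
#' Frequencies are always recomputed from counts (per sample), so that
#' `sum(freq) == 1` for every sample with reads; any frequency column found in
#' an input file is advisory only.
#'
#' @param df A data frame with at least a `count` column and clonotype
#'   identity columns (`v_call`, `j_call`, `cdr3_nt`, optionally `cdr3_aa`).
#' @param sample_id,subject_id,subset,timepoint Sample metadata attached to
#'   every row when not already present. `subset` is typically `"treg"` or
#'   `"tcon"`; `timepoint` is in days relative to the DLI.
#' @return A validated tibble with recomputed `freq`.
#' @examples
#' as_clonotype_tbl(
#'   data.frame(v_call = "TRBV9", j_call = "TRBJ1-1",
#'              cdr3_nt = c("TGTGCC", "TGTGCT"), count = c(30, 10)),
#'   sample_id = "s1"
#' )
#' @export
as_clonotype_tbl <- function(df, sample_id = NULL, subject_id = NULL,
                             subset = NULL, timepoint = NULL) {
  df <- as_tibble(df)
  meta <- list(sample_id = sample_id, subject_id = subject_id,
               subset = subset, timepoint = timepoint)
  for (nm in names(meta)) {
    if (!is.null(meta[[nm]])) df[[nm]] <- meta[[nm]]
    if (is.null(df[[nm]])) {
      df[[nm]] <- if (nm == "timepoint") NA_integer_ else NA_character_
    }
  }
  for (nm in c("v_call", "d_call", "j_call", "cdr3_nt", "cdr3_aa")) {
    if (is.null(df[[nm]])) df[[nm]] <- NA_character_
  }
  validate_clonotypes(df)
  recompute_freq(df)
}

validate_clonotypes <- function(df, call = rlang::caller_env()) {
  if (!"count" %in% names(df)) {
    abort("Clonotype table lacks a `count` column.", call = call)
  }
  if (nrow(df) == 0) {
    abort("Empty clonotype table: no records.",
          class = "repgvhd_empty_sample_error", call = call)
  }
  bad <- which(!is.finite(df$count) | df$count < 0)
  if (length(bad) > 0) {
    abort(sprintf("Negative or non-finite count at row(s) %s.",
                  paste(head(bad, 5), collapse = ", ")),
          class = "repgvhd_validation_error", call = call)
  }
  if (any(df$count != round(df$count))) {
    abort("Counts must be integers (read/UMI counts).",
          class = "repgvhd_validation_error", call = call)
  }
  totals <- tapply(df$count, sample_key(df), sum)
  if (any(totals == 0)) {
    abort(sprintf("Sample(s) with zero total count: %s.",
                  paste(names(totals)[totals == 0], collapse = ", ")),
          class = "repgvhd_empty_sample_error", call = call)
  }
  invisible(df)
}

sample_key <- function(df) {
  if ("sample_id" %in% names(df)) as.character(df$sample_id) else
    rep("<sample>", nrow(df))
}

recompute_freq <- function(df) {
  key <- sample_key(df)
  totals <- tapply(df$count, key, sum)
  df$freq <- df$count / as.numeric(totals[key])
  df
}

#' Read a clonotype table in VDJtools or AIRR dialect
#'
#' Reads one sample's clonotype table from a tab-separated file. Two dialects
#' are supported: `"vdjtools"` (columns `count`, `freq`, `cdr3nt`, `cdr3aa`,
#' `v`, `d`, `j`) and `"airr"` (AIRR Rearrangement schema columns
#' `duplicate_count`, `junction`, `junction_aa`, `v_call`, `j_call`, and
#' optionally `d_call`). Frequencies are recomputed from counts; if a
#' file-provided `freq` column disagrees with the recomputed values a warning
#' is emitted. Input row order is preserved.
#'
#' @param path Path to a TSV file.
#' @param dialect `"vdjtools"` or `"airr"`.
#' @inheritParams as_clonotype_tbl
#' @return A clonotype tibble (see [as_clonotype_tbl()]).
#' @examples
#' path <- system.file("extdata", "example_airr.tsv", package = "repgvhd")
#' read_clonotype_table(path, "airr", sample_id = "example")
#' @export
read_clonotype_table <- function(path, dialect = c("vdjtools", "airr"),
                                 sample_id = NULL, subject_id = NULL,
                                 subset = NULL, timepoint = NULL) {
  dialect <- rlang::arg_match(dialect)
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "repgvhd_io_error")
  }
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  cols <- dialect_columns(dialect)
  missing <- setdiff(cols$required, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("%s file %s is missing mandatory column(s): %s.",
                  dialect, path, paste(missing, collapse = ", ")),
          class = "repgvhd_format_error")
  }
  df <- tibble(
    v_call  = as.character(raw[[cols$map[["v_call"]]]] %||% NA_character_),
    d_call  = if (cols$map[["d_call"]] %in% names(raw))
      as.character(raw[[cols$map[["d_call"]]]]) else NA_character_,
    j_call  = as.character(raw[[cols$map[["j_call"]]]]),
    cdr3_nt = as.character(raw[[cols$map[["cdr3_nt"]]]]),
    cdr3_aa = if (cols$map[["cdr3_aa"]] %in% names(raw))
      as.character(raw[[cols$map[["cdr3_aa"]]]]) else NA_character_,
    count   = as.numeric(raw[[cols$map[["count"]]]])
  )
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  out <- as_clonotype_tbl(df, sample_id = sample_id, subject_id = subject_id,
                          subset = subset, timepoint = timepoint)
  if ("freq" %in% names(raw)) {
    file_freq <- as.numeric(raw$freq)
    if (any(abs(file_freq - out$freq) > 1e-6, na.rm = TRUE)) {
      warn(sprintf(
        "freq column in %s disagrees with counts; frequencies recomputed.",
        path))
    }
  }
  out
}

dialect_columns <- function(dialect) {
  if (dialect == "vdjtools") {
    list(
      required = c("count", "cdr3nt", "v", "j"),
      map = c(count = "count", cdr3_nt = "cdr3nt", cdr3_aa = "cdr3aa",
              v_call = "v", d_call = "d", j_call = "j")
    )
  } else {
    list(
      required = c("duplicate_count", "junction", "v_call", "j_call"),
      map = c(count = "duplicate_count", cdr3_nt = "junction",
              cdr3_aa = "junction_aa", v_call = "v_call", d_call = "d_call",
              j_call = "j_call")
    )
  }
}

#' Write a clonotype table in VDJtools or AIRR dialect
#'
#' Inverse of [read_clonotype_table()]: a read-write-read round trip
#' reproduces counts and clonotype keys exactly.
#'
#' @param df A clonotype tibble.
#' @param path Output TSV path.
#' @param dialect `"vdjtools"` or `"airr"`.
#' @return `path`, invisibly.
#' @export
write_clonotype_table <- function(df, path, dialect = c("vdjtools", "airr")) {
  dialect <- rlang::arg_match(dialect)
  validate_clonotypes(df)
  df <- recompute_freq(df)
  out <- if (dialect == "vdjtools") {
    tibble(count = df$count, freq = df$freq, cdr3nt = df$cdr3_nt,
           cdr3aa = df$cdr3_aa, v = df$v_call, d = df$d_call, j = df$j_call)
  } else {
    tibble(duplicate_count = df$count, junction = df$cdr3_nt,
           junction_aa = df$cdr3_aa, v_call = df$v_call, d_call = df$d_call,
           j_call = df$j_call)
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Clonotype identity keys
#'
#' The default clonotype identity is the composite (V call, J call, CDR3
#' nucleotide sequence); at the amino-acid level the CDR3 amino-acid sequence
#' replaces the nucleotide sequence.
#'
#' @param df A clonotype tibble.
#' @param level `"nt"` (default) or `"aa"`.
#' @return A character vector of keys, one per row.
#' @export
clonotype_key <- function(df, level = c("nt", "aa")) {
  level <- rlang::arg_match(level)
  cdr3 <- if (level == "nt") df$cdr3_nt else df$cdr3_aa
  paste(df$v_call, df$j_call, cdr3, sep = "|")
}

#' Merge clonotypes sharing an identity key
#'
#' Rows with the same clonotype key (within a sample) are merged by summing
#' counts; frequencies are renormalized. Non-key columns keep the value of
#' the most abundant merged row. After aggregation keys are unique within
#' each sample.
#'
#' @inheritParams clonotype_key
#' @return A clonotype tibble with unique keys per sample.
#' @export
aggregate_clonotypes <- function(df, level = c("nt", "aa")) {
  level <- rlang::arg_match(level)
  validate_clonotypes(df)
  df$.key <- clonotype_key(df, level)
  df$.sample <- sample_key(df)
  out <- df |>
    arrange(.data$.sample, .data$.key, desc(.data$count)) |>
    group_by(.data$.sample, .data$.key) |>
    mutate(count = sum(.data$count)) |>
    slice(1) |>
    ungroup() |>
    select(-".key", -".sample")
  recompute_freq(out)
}
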