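#' Inverse Simpson diversity (1/D)
#'
#' The inverse Simpson index \eqn{1/D = 1 / \sum_i p_i^2}, where \eqn{p_i}
#' are the clonotype frequencies. It is the effective number of equally
#' abundant clonotypes: it equals the number of unique clonotypes when all
#' frequencies are equal and 1 when a single clonotype occupies the whole
#' repertoire. Lower values indicate clonal expansion.
#'
#' @param x A single-sample clonotype tibble, or a bare numeric vector of
#'   counts (or frequencies).
#' @return A length-1 numeric.
#' @examples
#' inverse_simpson(c(80, 20))  # 1 / (0.8^2 + 0.2^2)
#' @export
inverse_simpson <- function(x) {
  p <- metric_freqs(x)
  1 / sum(p^2)
}

#' Clonal-space occupancy
#'
#' Sorts the unique clonotypes by decreasing abundance and reports, for each
#' threshold t (default 25%, 50%, 75% and 100% of the repertoire), the
#' minimal number of clonotypes whose summed frequency reaches at least t.
#' Few clonotypes covering a large share of the repertoire indicates strong
#' clonal expansion. Ties in frequency are broken deterministically
#' (descending count, then lexicographic clonotype key), which cannot change
#' the reported counts but fixes which clones are deemed to occupy the space.
#'
#' @inheritParams inverse_simpson
#' @param thresholds Fractions in (0, 1].
#' @return A tibble with columns `threshold` and `n_clones`.
#' @examples
#' clonal_space_occupancy(c(50, 30, 20))
#' @export
clonal_space_occupancy <- function(x, thresholds = c(0.25, 0.5, 0.75, 1)) {
  if (any(!is.finite(thresholds) | thresholds <= 0 | thresholds > 1)) {
    abort("`thresholds` must lie in (0, 1].",
          class = "repgvhd_validation_error")
  }
  p <- sort(metric_freqs(x), decreasing = TRUE)
  cum <- cumsum(p)
  n <- vapply(thresholds,
              function(t) which(cum >= t - 1e-9)[1],
              integer(1))
  tibble(threshold = thresholds, n_clones = as.integer(n))
}

#' Top-N clonal proportion
#'
#' The summed repertoire fraction of the `n` most abundant clonotypes
#' (default the top 20 clones). Values near 1 indicate that a handful of
#' clones dominate the repertoire.
#'
#' @inheritParams inverse_simpson
#' @param n Number of top clones (default 20).
#' @return A length-1 numeric in (0, 1].
#' @examples
#' top_n_proportion(c(50, 30, 20), n = 2)  # 0.8
#' @export
top_n_proportion <- function(x, n = 20) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    abort("`n` must be a single integer >= 1.",
          class = "repgvhd_validation_error")
  }
  p <- sort(metric_freqs(x), decreasing = TRUE)
  sum(p[seq_len(min(n, length(p)))])
}

#' Per-sample repertoire metrics
#'
#' Computes the three repertoire statistics — inverse Simpson diversity,
#' clonal-space occupancy at the configured thresholds, and top-N clonal
#' proportion — for every sample in a clonotype tibble, together with the
#' number of unique clonotypes and the total read count.
#'
#' Metrics are meant to be computed on depth-normalized tables (see
#' [downsample_reads()]); nothing enforces this, but comparisons across
#' depths are biased.
#'
#' @param df A clonotype tibble with one or more samples.
#' @param top_n Number of top clones for the clonal-proportion statistic.
#' @param thresholds Clonal-space thresholds, fractions in (0, 1].
#' @return A tibble with one row per sample: metadata columns, `n_unique`,
#'   `total_reads`, `inv_simpson`, one `cs<percent>` column per threshold
#'   (clone counts) and `top<top_n>` (proportion).
#' @examples
#' tbl <- as_clonotype_tbl(
#'   data.frame(v_call = "TRBV9", j_call = "TRBJ1-1",
#'              cdr3_nt = c("AAA", "CCC", "GGG"), count = c(50, 30, 20)),
#'   sample_id = "s1"
#' )
#' repertoire_metrics(tbl)
#' @export
repertoire_metrics <- function(df, top_n = 20,
                               thresholds = c(0.25, 0.5, 0.75, 1)) {
  validate_clonotypes(df)
  df <- recompute_freq(df)
  key <- sample_key(df)
  ids <- unique(key)
  cs_names <- paste0("cs", round(thresholds * 100))
  rows <- lapply(ids, function(id) {
    sub <- df[key == id, , drop = FALSE]
    cs <- clonal_space_occupancy(sub, thresholds)
    out <- tibble(
      sample_id = id,
      subject_id = first_or_na(sub$subject_id),
      subset = first_or_na(sub$subset),
      timepoint = if (is.null(sub$timepoint)) NA_integer_ else
        sub$timepoint[1],
      n_unique = nrow(sub),
      total_reads = sum(sub$count),
      inv_simpson = inverse_simpson(sub)
    )
    out[cs_names] <- as.list(cs$n_clones)
    out[[paste0("top", top_n)]] <- top_n_proportion(sub, top_n)
    out
  })
  bind_rows(rows)
}

first_or_na <- function(x) if (is.null(x)) NA_character_ else x[1]

metric_freqs <- function(x) {
  if (is.data.frame(x)) {
    validate_clonotypes(x)
    if (length(unique(sample_key(x))) > 1) {
      abort(paste("Metric functions take one sample at a time;",
                  "use repertoire_metrics() for multi-sample tables."),
            class = "repgvhd_validation_error")
    }
    x <- x$count
  }
  if (!is.numeric(x) || length(x) == 0) {
    abort("Empty sample: no clonotypes to compute metrics on.",
          class = "repgvhd_empty_sample_error")
  }
  if (any(!is.finite(x) | x < 0) || sum(x) == 0) {
    abort("Counts must be non-negative with a positive total.",
          class = "repgvhd_validation_error")
  }
  x <- x[x > 0]
  x / sum(x)
}
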