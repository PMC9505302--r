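# Shared fixtures and independent brute-force oracles.

# quick clonotype table from a count vector
make_ct <- function(counts, sample_id = "s1", subject_id = "p1",
                    subset = "treg", timepoint = 0L,
                    cdr3 = sprintf("TGT%03dTTT", seq_along(counts))) {
  as_clonotype_tbl(
    data.frame(v_call = "TRBV9", j_call = "TRBJ1-1", cdr3_nt = cdr3,
               cdr3_aa = substr(cdr3, 1, 5), count = counts),
    sample_id = sample_id, subject_id = subject_id, subset = subset,
    timepoint = timepoint
  )
}

write_vdjtools_fixture <- function(counts, path = tempfile(fileext = ".txt"),
                                   freq = counts / sum(counts)) {
  df <- data.frame(count = counts, freq = freq,
                   cdr3nt = sprintf("TGT%03dTTT", seq_along(counts)),
                   cdr3aa = sprintf("CA%dF", seq_along(counts)),
                   v = "TRBV9", d = "TRBD1", j = "TRBJ1-1")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_airr_fixture <- function(counts, path = tempfile(fileext = ".tsv"),
                               drop = NULL) {
  df <- data.frame(duplicate_count = counts,
                   junction = sprintf("TGT%03dTTT", seq_along(counts)),
                   junction_aa = sprintf("CA%dF", seq_along(counts)),
                   v_call = "TRBV9", d_call = "TRBD1", j_call = "TRBJ1-1")
  if (!is.null(drop)) df <- df[, setdiff(names(df), drop), drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# ---- independent oracles (deliberately naive) -------------------------------

oracle_inv_simpson <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  s <- 0
  for (pi in p) s <- s + pi * pi
  1 / s
}

oracle_clonal_space <- function(counts, threshold) {
  p <- sort(counts[counts > 0] / sum(counts), decreasing = TRUE)
  tot <- 0
  for (k in seq_along(p)) {
    tot <- tot + p[k]
    if (tot >= threshold - 1e-9) return(k)
  }
  length(p)
}

oracle_top_n <- function(counts, n) {
  p <- sort(counts[counts > 0] / sum(counts), decreasing = TRUE)
  sum(p[seq_len(min(n, length(p)))])
}

# random small count vector for property tests
random_counts <- function() {
  n <- sample(1:30, 1)
  sample(1:100, n, replace = TRUE)
}

# small event-table toy used across survival tests
toy_events <- function() {
  tibble::tibble(
    subject_id = sprintf("T%02d", 1:8),
    group = rep(c("a", "b"), each = 4),
    time = c(2, 5, 8, 30, 3, 11, 20, 36),
    event = c("gvhd", "relapse", "gvhd", "censored",
              "gvhd", "gvhd", "relapse", "censored")
  )
}
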