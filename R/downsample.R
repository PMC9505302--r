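#' Depth-normalize clonotype tables by random downsampling
#'
#' Randomly subsamples each sample's reads to a common depth (default 20,000
#' reads) so that diversity and clonality statistics are comparable across
#' samples sequenced at different depths. Reads are drawn uniformly without
#' replacement from the read-level expansion of the clonotype counts, i.e.
#' the per-clonotype downsampled counts follow a multivariate hypergeometric
#' distribution; clonotypes drawn to count zero are dropped and no new
#' clonotypes can appear. A multinomial (with-replacement) scheme is
#' available for sensitivity checks.
#'
#' The draw is deterministic for a fixed `(df, target_reads, seed)`: the
#' caller-supplied seed is applied locally and the session RNG state is left
#' untouched.
#'
#' Samples whose total read count is below `target_reads` cannot be
#' downsampled; `short_policy` decides their fate: `"skip"` (default)
#' excludes them from the output with a flag in the manifest, `"error"`
#' raises, `"keep"` passes them through unchanged with a flag.
#'
#' @param df A clonotype tibble (one or more samples, keyed by `sample_id`).
#' @param target_reads Target depth; default 20,000 reads.
#' @param seed Integer seed; mandatory so that runs are reproducible.
#' @param short_policy One of `"skip"`, `"error"`, `"keep"`.
#' @param method `"hypergeometric"` (without replacement, default) or
#'   `"multinomial"` (with replacement, sensitivity analysis only).
#' @return A clonotype tibble with recomputed frequencies; the per-sample
#'   bookkeeping (input reads, output reads, flag) is attached as the
#'   `"manifest"` attribute and is retrievable with [downsample_manifest()].
#' @examples
#' tbl <- as_clonotype_tbl(
#'   data.frame(v_call = "TRBV9", j_call = "TRBJ1-1",
#'              cdr3_nt = c("AAA", "CCC", "GGG"), count = c(500, 300, 200)),
#'   sample_id = "s1"
#' )
#' downsample_reads(tbl, target_reads = 100, seed = 1)
#' @export
downsample_reads <- function(df, target_reads = 20000, seed,
                             short_policy = c("skip", "error", "keep"),
                             method = c("hypergeometric", "multinomial")) {
  short_policy <- rlang::arg_match(short_policy)
  method <- rlang::arg_match(method)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 ||
      !is.finite(seed)) {
    abort("`seed` is mandatory and must be a single integer.",
          class = "repgvhd_validation_error")
  }
  if (!is.numeric(target_reads) || length(target_reads) != 1 ||
      target_reads <= 0 || target_reads != round(target_reads)) {
    abort("`target_reads` must be a single positive integer.",
          class = "repgvhd_validation_error")
  }
  validate_clonotypes(df)
  ids <- unique(sample_key(df))
  key <- sample_key(df)

  pieces <- vector("list", length(ids))
  manifest <- vector("list", length(ids))
  withr::with_seed(as.integer(seed), {
    for (i in seq_along(ids)) {
      sub <- df[key == ids[i], , drop = FALSE]
      total <- sum(sub$count)
      if (total < target_reads) {
        if (short_policy == "error") {
          abort(sprintf(
            "Sample %s has %d reads, below the %d-read target.",
            ids[i], total, target_reads), class = "repgvhd_depth_error")
        }
        flag <- if (short_policy == "skip") "under_depth_skipped"
                else "under_depth_kept"
        manifest[[i]] <- tibble(sample_id = ids[i], input_reads = total,
                                output_reads = if (flag == "under_depth_kept")
                                  total else 0L,
                                flag = flag)
        if (short_policy == "keep") pieces[[i]] <- sub
        next
      }
      if (total == target_reads) {
        new_counts <- sub$count
      } else if (method == "hypergeometric") {
        new_counts <- rmvhyper(sub$count, target_reads)
      } else {
        new_counts <- as.numeric(
          rmultinom(1, target_reads, sub$count / total))
      }
      keep <- new_counts > 0
      out <- sub[keep, , drop = FALSE]
      out$count <- new_counts[keep]
      pieces[[i]] <- out
      manifest[[i]] <- tibble(sample_id = ids[i], input_reads = total,
                              output_reads = as.integer(sum(out$count)),
                              flag = "ok")
    }
  })
  res <- bind_rows(pieces)
  if (nrow(res) > 0) res <- recompute_freq(res)
  attr(res, "manifest") <- bind_rows(manifest)
  res
}

#' Retrieve the downsampling manifest
#'
#' @param df The result of [downsample_reads()].
#' @return A tibble with columns `sample_id`, `input_reads`, `output_reads`,
#'   `flag` (`ok`, `under_depth_skipped`, or `under_depth_kept`).
#' @export
downsample_manifest <- function(df) {
  m <- attr(df, "manifest")
  if (is.null(m)) {
    abort("No downsampling manifest attached; was `downsample_reads()` run?")
  }
  m
}

# Multivariate hypergeometric draw: `n` reads taken uniformly without
# replacement from a pool with `counts[i]` reads of clonotype i.
rmvhyper <- function(counts, n) {
  total <- sum(counts)
  if (total <= 5e6) {
    pool <- rep.int(seq_along(counts), counts)
    as.numeric(tabulate(pool[sample.int(total, n)], nbins = length(counts)))
  } else {
    # sequential conditional draws avoid materializing the read pool
    out <- numeric(length(counts))
    remaining_total <- total
    remaining_draw <- n
    for (i in seq_along(counts)) {
      if (remaining_draw == 0) break
      out[i] <- rhyper(1, counts[i], remaining_total - counts[i],
                       remaining_draw)
      remaining_total <- remaining_total - counts[i]
      remaining_draw <- remaining_draw - out[i]
    }
    out
  }
}
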