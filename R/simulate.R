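TRBV_SEGMENTS <- paste0("TRBV", c(2:7, 9:16, 18:20, 24:25, 27:30))
TRBJ_SEGMENTS <- c(paste0("TRBJ1-", 1:6), paste0("TRBJ2-", 1:7))

# one-or-two synonymous codons per amino acid, so nucleotide-level
# degeneracy of amino-acid clonotypes exists in simulated data
CODONS <- list(
  A = c("GCT", "GCC"), R = c("CGT", "CGC"), N = c("AAT", "AAC"),
  D = c("GAT", "GAC"), C = "TGT", Q = c("CAA", "CAG"),
  E = c("GAA", "GAG"), G = c("GGT", "GGC"), H = c("CAT", "CAC"),
  I = c("ATT", "ATC"), L = c("CTT", "CTG"), K = c("AAA", "AAG"),
  M = "ATG", F = c("TTT", "TTC"), P = c("CCT", "CCC"),
  S = c("TCT", "TCC"), T = c("ACT", "ACC"), W = "TGG",
  Y = c("TAT", "TAC"), V = c("GTT", "GTC")
)

# flat codon lookup used by the vectorized generator
CODON1 <- vapply(CODONS, `[`, character(1), 1)
CODON2 <- vapply(CODONS, function(x) x[min(2, length(x))], character(1))

# random in-frame CDR3s: canonical C...F motif, 9-17 amino acids
# (27-51 nt); returns a tibble of unique (cdr3_nt, cdr3_aa) pairs
random_cdr3 <- function(n) {
  aa_pool <- names(CODONS)
  gen <- function(m) {
    lens <- sample(9:17, m, replace = TRUE)
    aa <- character(m)
    nt <- character(m)
    for (L in unique(lens)) {
      rows <- lens == L
      k <- sum(rows)
      mid <- matrix(sample(aa_pool, k * (L - 2), replace = TRUE), nrow = k)
      # random synonymous codon per position
      cods <- CODON1[mid]
      alt <- runif(length(mid)) < 0.5
      cods[alt] <- CODON2[mid[alt]]
      dim(cods) <- dim(mid)
      cols <- function(mat) lapply(seq_len(ncol(mat)),
                                   function(j) mat[, j])
      aa[rows] <- do.call(paste0, cols(mid))
      nt[rows] <- do.call(paste0, cols(cods))
    }
    tibble(cdr3_nt = paste0("TGT", nt, "TTT"),
           cdr3_aa = paste0("C", aa, "F"))
  }
  out <- gen(n)
  dup <- which(duplicated(out$cdr3_nt))
  while (length(dup) > 0) {
    out[dup, ] <- gen(length(dup))
    dup <- which(duplicated(out$cdr3_nt))
  }
  out
}

draw_clone_masses <- function(n_clones, clone_law, alpha, meanlog, sdlog) {
  if (clone_law == "power_law") {
    if (!is.finite(alpha) || alpha <= 1) {
      abort("Power-law exponent `alpha` must be > 1.",
            class = "repgvhd_validation_error")
    }
    runif(n_clones)^(-1 / (alpha - 1))  # Pareto(1, alpha - 1) masses
  } else {
    if (!is.finite(sdlog) || sdlog <= 0) {
      abort("`sdlog` must be > 0.", class = "repgvhd_validation_error")
    }
    rlnorm(n_clones, meanlog, sdlog)
  }
}

check_sim_args <- function(n_clones, expansion_factor, n_expanded,
                           total_reads) {
  if (n_clones < 1 || total_reads < 1 || expansion_factor < 1 ||
      n_expanded > n_clones || n_expanded < 0) {
    abort(paste("Need n_clones >= 1, total_reads >= 1,",
                "expansion_factor >= 1 and 0 <= n_expanded <= n_clones."),
          class = "repgvhd_validation_error")
  }
}

#' Simulate a TRB clonotype repertoire
#'
#' Draws clone masses from a skewed clone-size law (power law with exponent
#' `alpha`, default 2, or log-normal), multiplies the top `n_expanded`
#' masses by `expansion_factor` to emulate GVHD-associated clonal expansion,
#' normalizes to probabilities and draws read counts multinomially. Random
#' in-frame CDR3 sequences and V/J segment calls are attached. The default
#' depth of 100,000 reads leaves room for the 20,000-read downsampling step.
#' Deterministic for a fixed `seed`; the session RNG is untouched.
#'
#' @param n_clones Number of distinct clones in the underlying pool.
#' @param clone_law `"power_law"` or `"log_normal"`.
#' @param alpha Power-law exponent (> 1); default 2.
#' @param meanlog,sdlog Log-normal parameters.
#' @param expansion_factor Multiplier (>= 1) applied to the `n_expanded`
#'   largest clone masses; 1 = healthy-like, large values emulate expansion.
#' @param n_expanded Number of top clones expanded (default 5).
#' @param total_reads Reads drawn (default 100,000).
#' @param seed Integer seed (mandatory).
#' @param sample_id,subject_id,subset,timepoint Metadata for the table.
#' @return A clonotype tibble; clones drawn to count zero are absent.
#' @export
simulate_repertoire <- function(n_clones = 1000,
                                clone_law = c("power_law", "log_normal"),
                                alpha = 2, meanlog = 0, sdlog = 1,
                                expansion_factor = 1, n_expanded = 5,
                                total_reads = 100000, seed,
                                sample_id = "sim", subject_id = NA,
                                subset = "treg", timepoint = 0L) {
  clone_law <- rlang::arg_match(clone_law)
  check_sim_args(n_clones, expansion_factor, n_expanded, total_reads)
  withr::with_seed(as.integer(seed), {
    masses <- draw_clone_masses(n_clones, clone_law, alpha, meanlog, sdlog)
    pool <- clone_pool(n_clones)
    counts <- draw_counts(masses, expansion_factor, n_expanded, total_reads)
    assemble_repertoire(pool, counts, sample_id, subject_id, subset,
                        timepoint)
  })
}

clone_pool <- function(n_clones) {
  cdr3 <- random_cdr3(n_clones)
  tibble(
    v_call = sample(TRBV_SEGMENTS, n_clones, replace = TRUE),
    d_call = sample(c("TRBD1", "TRBD2"), n_clones, replace = TRUE),
    j_call = sample(TRBJ_SEGMENTS, n_clones, replace = TRUE),
    cdr3_nt = cdr3$cdr3_nt,
    cdr3_aa = cdr3$cdr3_aa
  )
}

draw_counts <- function(masses, expansion_factor, n_expanded, total_reads) {
  if (n_expanded > 0 && expansion_factor > 1) {
    top <- order(masses, decreasing = TRUE)[seq_len(n_expanded)]
    masses[top] <- masses[top] * expansion_factor
  }
  as.numeric(rmultinom(1, total_reads, masses / sum(masses)))
}

assemble_repertoire <- function(pool, counts, sample_id, subject_id, subset,
                                timepoint) {
  keep <- counts > 0
  out <- pool[keep, , drop = FALSE]
  out$count <- counts[keep]
  out$sample_id <- sample_id
  out$subject_id <- as.character(subject_id)
  out$subset <- subset
  out$timepoint <- as.integer(timepoint)
  recompute_freq(out[, c("sample_id", "subject_id", "subset", "timepoint",
                         "v_call", "d_call", "j_call", "cdr3_nt", "cdr3_aa",
                         "count")])
}

#' Simulate a pre/post longitudinal repertoire pair
#'
#' Generates two repertoires from a shared clone pool: the `pre` table uses
#' the base expansion factor and the `post` table re-weights the top
#' `n_expanded` clones by `post_expansion`, emulating clonal expansion at
#' GVHD onset (`post_expansion` > 1 pushes diversity down) or a null change
#' (`post_expansion = 1`). Clonotype keys overlap between the timepoints by
#' construction.
#'
#' @inheritParams simulate_repertoire
#' @param post_expansion Expansion factor applied at the post timepoint.
#' @param pre_timepoint,post_timepoint Days relative to the clinical anchor.
#' @return A list with clonotype tibbles `pre` and `post`.
#' @export
simulate_longitudinal_patient <- function(post_expansion, seed,
                                          n_clones = 1000,
                                          clone_law = c("power_law",
                                                        "log_normal"),
                                          alpha = 2, meanlog = 0, sdlog = 1,
                                          expansion_factor = 1,
                                          n_expanded = 5,
                                          total_reads = 100000,
                                          subject_id = "p1", subset = "treg",
                                          pre_timepoint = -66L,
                                          post_timepoint = 9L) {
  clone_law <- rlang::arg_match(clone_law)
  check_sim_args(n_clones, expansion_factor, n_expanded, total_reads)
  if (post_expansion < 1) {
    abort("`post_expansion` must be >= 1.",
          class = "repgvhd_validation_error")
  }
  withr::with_seed(as.integer(seed), {
    masses <- draw_clone_masses(n_clones, clone_law, alpha, meanlog, sdlog)
    pool <- clone_pool(n_clones)
    pre_counts <- draw_counts(masses, expansion_factor, n_expanded,
                              total_reads)
    post_counts <- draw_counts(masses, post_expansion, n_expanded,
                               total_reads)
    # same-subject samples share their detectable clones: every clone
    # observed pre persists post (one read reallocated from the top clone)
    lost <- which(pre_counts > 0 & post_counts == 0)
    if (length(lost) > 0) {
      top <- which.max(post_counts)
      move <- min(length(lost), post_counts[top] - 1)
      post_counts[lost[seq_len(move)]] <- 1
      post_counts[top] <- post_counts[top] - move
    }
    list(
      pre = assemble_repertoire(pool, pre_counts,
                                paste0(subject_id, "_pre"), subject_id,
                                subset, pre_timepoint),
      post = assemble_repertoire(pool, post_counts,
                                 paste0(subject_id, "_post"), subject_id,
                                 subset, post_timepoint)
    )
  })
}

#' Simulate a DLI cohort with competing risks
#'
#' Generates a cohort of subjects in two groups (`expanded`, with
#' repertoire expansion factor `expansion_factors["expanded"]` and an
#' endpoint hazard multiplied by `hazard_multiplier_expanded`; and
#' `healthy_like`). Per subject, cause-specific event times for the
#' endpoint (GVHD), relapse and non-relapse mortality are drawn from
#' exponential distributions with the stated monthly hazards; the first
#' event wins and follow-up is administratively censored at
#' `followup_months`. Baseline repertoires (default: day 14 post DLI) are
#' generated with each subject's expansion factor, linking repertoire
#' clonality to GVHD risk.
#'
#' Default hazards (GVHD 0.03/month in the healthy-like group with a 2.5x
#' multiplier when expanded; relapse 0.03/month; NRM 0.01/month) give
#' 36-month incidences in the range reported for DLI cohorts (GVHD in
#' roughly half the patients, relapse in over half).
#'
#' @param n_expanded_subjects,n_healthy_like Group sizes.
#' @param expansion_factors Named numeric, expansion factor per group.
#' @param hazard_gvhd Baseline endpoint hazard (events/month).
#' @param hazard_multiplier_expanded Endpoint hazard multiplier for the
#'   expanded group (the repertoire-risk linkage; default 2.5).
#' @param hazard_relapse,hazard_nrm Competing-event hazards (events/month).
#' @param followup_months Administrative censoring horizon (default 36).
#' @param seed Integer seed (mandatory).
#' @param simulate_repertoires Also generate baseline repertoires? (Set to
#'   `FALSE` for event-table-only simulations.)
#' @param n_clones,total_reads,n_expanded Repertoire generator settings.
#' @param baseline_timepoint Day of the baseline sample (default 14).
#' @return A list with `subjects` (per-subject metadata), `events` (an
#'   event table, see [event-tables]) and `repertoires` (a clonotype tibble
#'   or `NULL`).
#' @export
simulate_cohort <- function(n_expanded_subjects = 9, n_healthy_like = 12,
                            expansion_factors = c(expanded = 20,
                                                  healthy_like = 1),
                            hazard_gvhd = 0.03,
                            hazard_multiplier_expanded = 2.5,
                            hazard_relapse = 0.03, hazard_nrm = 0.01,
                            followup_months = 36, seed,
                            simulate_repertoires = TRUE, n_clones = 1000,
                            total_reads = 100000, n_expanded = 5,
                            baseline_timepoint = 14L) {
  hazards <- c(hazard_gvhd, hazard_relapse, hazard_nrm)
  if (any(!is.finite(hazards) | hazards < 0) ||
      hazard_multiplier_expanded < 0) {
    abort("Hazards must be finite and >= 0.",
          class = "repgvhd_validation_error")
  }
  if (all(hazards == 0) && !is.finite(followup_months)) {
    abort("All hazards zero with no censoring horizon.",
          class = "repgvhd_validation_error")
  }
  if (n_expanded_subjects < 1 || n_healthy_like < 1) {
    abort("Group sizes must be >= 1.", class = "repgvhd_validation_error")
  }
  n <- n_expanded_subjects + n_healthy_like
  group <- rep(c("expanded", "healthy_like"),
               c(n_expanded_subjects, n_healthy_like))
  withr::with_seed(as.integer(seed), {
    subjects <- tibble(
      subject_id = sprintf("S%03d", seq_len(n)),
      group = group,
      expansion_factor = unname(expansion_factors[group]),
      hazard_endpoint = hazard_gvhd *
        ifelse(group == "expanded", hazard_multiplier_expanded, 1)
    )
    t_gvhd <- rexp_or_inf(n, subjects$hazard_endpoint)
    t_rel <- rexp_or_inf(n, rep(hazard_relapse, n))
    t_nrm <- rexp_or_inf(n, rep(hazard_nrm, n))
    tmin <- pmin(t_gvhd, t_rel, t_nrm)
    cause <- c("gvhd", "relapse", "nrm")[
      max.col(-cbind(t_gvhd, t_rel, t_nrm))]
    events <- tibble(
      subject_id = subjects$subject_id,
      group = subjects$group,
      time = pmin(tmin, followup_months),
      event = ifelse(tmin <= followup_months, cause, "censored")
    )
    repertoires <- NULL
    if (simulate_repertoires) {
      reps <- lapply(seq_len(n), function(i) {
        masses <- draw_clone_masses(n_clones, "power_law", 2, 0, 1)
        pool <- clone_pool(n_clones)
        counts <- draw_counts(masses, subjects$expansion_factor[i],
                              n_expanded, total_reads)
        assemble_repertoire(pool, counts,
                            paste0(subjects$subject_id[i], "_d14"),
                            subjects$subject_id[i], "treg",
                            baseline_timepoint)
      })
      repertoires <- bind_rows(reps)
    }
    list(subjects = subjects, events = events, repertoires = repertoires)
  })
}

rexp_or_inf <- function(n, rate) {
  out <- rep(Inf, n)
  pos <- rate > 0
  # draw in subject order so the stream is stable
  for (i in which(pos)) out[i] <- rexp(1, rate[i])
  out
}
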