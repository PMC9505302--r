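new_rep_test <- function(test, statistic, p_value, estimate = NA_real_,
                         conf_low = NA_real_, conf_high = NA_real_,
                         note = NA_character_, ...) {
  structure(
    c(list(test = test, statistic = as.numeric(statistic),
           p_value = as.numeric(p_value), estimate = estimate,
           conf_low = conf_low, conf_high = conf_high, note = note),
      list(...)),
    class = "rep_test"
  )
}

#' @export
print.rep_test <- function(x, ...) {
  cat(sprintf("<rep_test> %s\n  statistic = %.4g, p = %.4g\n",
              x$test, x$statistic, x$p_value))
  if (is.finite(x$estimate)) {
    cat(sprintf("  estimate = %.4g (95%% CI %.4g-%.4g)\n",
                x$estimate, x$conf_low, x$conf_high))
  }
  if (!is.na(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' @method tidy rep_test
#' @export
tidy.rep_test <- function(x, ...) {
  tibble(test = x$test, statistic = x$statistic, p_value = x$p_value,
         estimate = x$estimate, conf_low = x$conf_low,
         conf_high = x$conf_high,
         normality_gate = x$normality_gate %||% NA_character_,
         note = x$note)
}

#' @method glance rep_test
#' @export
glance.rep_test <- function(x, ...) tidy(x, ...)

#' Normality-gated two-group comparison
#'
#' Dispatches the two-group test the way the study's statistics were run:
#' each group (or, for paired data, the within-pair differences) is checked
#' for normality with the Shapiro-Wilk test at gate level `alpha`; if
#' normality is not rejected anywhere, a two-tailed Student's t-test is used
#' (paired or unpaired), otherwise the two-tailed exact Mann-Whitney test
#' (unpaired) or Wilcoxon matched-pairs signed-rank test (paired). The exact
#' Mann-Whitney distribution is used for groups of up to 25 observations
#' without ties; larger or tied samples use the tie-corrected normal
#' approximation.
#'
#' @param x,y Numeric vectors, each with at least 3 observations (equal
#'   lengths when `paired = TRUE`).
#' @param paired Paired comparison?
#' @param alpha Shapiro-Wilk gate level (default 0.05).
#' @param choose `"auto"` (gate decides), `"parametric"` or
#'   `"nonparametric"` to force a branch.
#' @return An object of class `rep_test`; `tidy()` returns a one-row tibble.
#'   The field `normality_gate` records the gate outcome.
#' @examples
#' dispatch_two_group_test(c(1, 2, 3, 4), c(5, 6, 7, 8),
#'                         choose = "nonparametric")
#' @export
dispatch_two_group_test <- function(x, y, paired = FALSE, alpha = 0.05,
                                    choose = c("auto", "parametric",
                                               "nonparametric")) {
  choose <- rlang::arg_match(choose)
  if (length(x) < 3 || length(y) < 3) {
    abort("Each group needs at least 3 observations.",
          class = "repgvhd_sample_size_error")
  }
  if (paired && length(x) != length(y)) {
    abort("Paired comparison requires equal-length vectors.",
          class = "repgvhd_validation_error")
  }

  shapiro_p <- function(v) {
    if (sd(v) == 0) return(0)  # degenerate: treat as non-normal
    shapiro.test(v)$p.value
  }
  gate_ps <- if (paired) shapiro_p(y - x) else c(shapiro_p(x), shapiro_p(y))
  normal <- all(gate_ps >= alpha)
  gate <- sprintf("shapiro_p=%s; %s",
                  paste(signif(gate_ps, 3), collapse = ","),
                  if (normal) "normal" else "non-normal")
  use_parametric <- switch(choose, auto = normal,
                           parametric = TRUE, nonparametric = FALSE)

  if (use_parametric) {
    tt <- t.test(x, y, paired = paired, alternative = "two.sided")
    res <- new_rep_test(test = "t", statistic = unname(tt$statistic),
                        p_value = tt$p.value,
                        estimate = unname(if (paired) tt$estimate
                                          else diff(rev(tt$estimate))),
                        conf_low = tt$conf.int[1], conf_high = tt$conf.int[2])
  } else if (paired) {
    d <- y - x
    if (all(d == 0)) {
      res <- new_rep_test(test = "wilcoxon_signed_rank", statistic = 0,
                          p_value = 1,
                          note = "all paired differences are zero")
    } else {
      wt <- suppressWarnings(
        wilcox.test(x, y, paired = TRUE, alternative = "two.sided"))
      res <- new_rep_test(test = "wilcoxon_signed_rank",
                          statistic = unname(wt$statistic),
                          p_value = wt$p.value)
    }
  } else {
    exact <- max(length(x), length(y)) <= 25 &&
      !any(duplicated(c(x, y)))
    wt <- suppressWarnings(
      wilcox.test(x, y, exact = exact, correct = !exact,
                  alternative = "two.sided"))
    res <- new_rep_test(test = "mann_whitney",
                        statistic = unname(wt$statistic),
                        p_value = wt$p.value)
  }
  res$normality_gate <- gate
  res
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-tailed exact test for association in a 2x2 contingency table of
#' non-negative integer counts: the p-value sums the hypergeometric
#' probabilities of all tables (at the observed margins) no more probable
#' than the observed one. Wraps [stats::fisher.test()].
#'
#' @param tab A 2x2 matrix (or something coercible to one) of non-negative
#'   integer counts.
#' @return An object of class `rep_test` with the odds-ratio estimate, its
#'   95% CI and the two-tailed p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2))
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) {
    abort("`tab` must be a 2x2 table.", class = "repgvhd_validation_error")
  }
  if (any(!is.finite(tab) | tab < 0 | tab != round(tab))) {
    abort("Cells must be non-negative integers.",
          class = "repgvhd_validation_error")
  }
  if (sum(tab) == 0) {
    abort("Degenerate table: all cells are zero.",
          class = "repgvhd_degenerate_table_error")
  }
  ft <- fisher.test(tab, alternative = "two.sided")
  new_rep_test(test = "fisher_exact", statistic = NA_real_,
               p_value = ft$p.value, estimate = unname(ft$estimate),
               conf_low = ft$conf.int[1], conf_high = ft$conf.int[2])
}
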