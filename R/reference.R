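#' Build a healthy-control reference band
#'
#' Healthy individuals are sampled repeatedly, so the reference distribution
#' is built in one of two modes: `"per_individual"` (default) first averages
#' each individual's repeated samples and takes percentiles over those
#' means — matching the use of each healthy individual's average diversity
#' as the control value — or `"all_samples"`, which pools every
#' healthy-control sample. The 25th and 75th percentiles (linear
#' interpolation between order statistics, `stats::quantile()` type 7) form
#' the interquartile band used for plotting and the 25th percentile is the
#' expansion-classification threshold.
#'
#' @param df A data frame of healthy-control values with columns
#'   `individual_id` and the metric column named by `value`.
#' @param value Name of the metric column (default `"inv_simpson"`).
#' @param mode `"per_individual"` or `"all_samples"`.
#' @return An object of class `hc_reference`: a list with `individual_means`
#'   (tibble), `p25`, `p75`, `mode`, `value`, `n_individuals`. Has [tidy()]
#'   and [glance()] methods.
#' @examples
#' hc <- tibble::tibble(individual_id = rep(letters[1:3], each = 2),
#'                      inv_simpson = c(100, 200, 300, 300, 500, 700))
#' build_hc_reference(hc)
#' @export
build_hc_reference <- function(df, value = "inv_simpson",
                               mode = c("per_individual", "all_samples")) {
  mode <- rlang::arg_match(mode)
  if (!all(c("individual_id", value) %in% names(df))) {
    abort(sprintf("`df` needs columns `individual_id` and `%s`.", value),
          class = "repgvhd_validation_error")
  }
  vals <- df[[value]]
  if (any(!is.finite(vals))) {
    abort("Non-finite metric values in the healthy-control table.",
          class = "repgvhd_validation_error")
  }
  ids <- as.character(df$individual_id)
  if (length(unique(ids)) < 2) {
    abort("A reference band needs at least 2 healthy individuals.",
          class = "repgvhd_reference_error")
  }
  means <- tibble(
    individual_id = names(tapply(vals, ids, mean)),
    mean_value = as.numeric(tapply(vals, ids, mean)),
    n_samples = as.integer(table(ids)[names(tapply(vals, ids, mean))])
  )
  pooled <- if (mode == "per_individual") means$mean_value else vals
  structure(
    list(
      individual_means = means,
      p25 = unname(quantile(pooled, 0.25, type = 7)),
      p75 = unname(quantile(pooled, 0.75, type = 7)),
      mode = mode,
      value = value,
      n_individuals = nrow(means),
      n_samples = length(vals)
    ),
    class = "hc_reference"
  )
}

#' @export
print.hc_reference <- function(x, ...) {
  cat(sprintf(
    "<hc_reference> %s, mode = %s\n  %d individuals, %d samples\n  p25 = %.4g, p75 = %.4g\n",
    x$value, x$mode, x$n_individuals, x$n_samples, x$p25, x$p75))
  invisible(x)
}

#' @method tidy hc_reference
#' @export
tidy.hc_reference <- function(x, ...) x$individual_means

#' @method glance hc_reference
#' @export
glance.hc_reference <- function(x, ...) {
  tibble(value = x$value, mode = x$mode, p25 = x$p25, p75 = x$p75,
         n_individuals = x$n_individuals, n_samples = x$n_samples)
}

#' Classify samples as expanded vs healthy-like
#'
#' A sample is `expanded` when its diversity lies strictly below the 25th
#' percentile of the healthy-control reference, and `healthy_like` when its
#' diversity is at or above that percentile (a value exactly at the
#' threshold is healthy-like).
#'
#' @param df A data frame with the metric column named by `value` (e.g. the
#'   output of [repertoire_metrics()]).
#' @param reference An [hc_reference][build_hc_reference()] object.
#' @param value Metric column name; defaults to the reference's metric.
#' @return `df` with added columns `threshold` and `label`
#'   (`"expanded"` / `"healthy_like"`).
#' @export
classify_samples <- function(df, reference, value = reference$value) {
  stopifnot(inherits(reference, "hc_reference"))
  if (!value %in% names(df)) {
    abort(sprintf("`df` has no `%s` column.", value),
          class = "repgvhd_validation_error")
  }
  v <- df[[value]]
  if (any(!is.finite(v))) {
    abort("Non-finite metric values cannot be classified.",
          class = "repgvhd_validation_error")
  }
  df$threshold <- reference$p25
  df$label <- ifelse(v < reference$p25, "expanded", "healthy_like")
  as_tibble(df)
}

#' Percent change between paired measurements
#'
#' `100 * (post - pre) / pre`, the convention used for longitudinal
#' repertoire changes (e.g. a drop from 100 to 43.73 is -56.27%).
#'
#' @param pre,post Numeric vectors (recycled to common length).
#' @return Numeric vector of percent changes.
#' @export
percent_change <- function(pre, post) {
  if (any(!is.finite(pre)) || any(!is.finite(post))) {
    abort("`pre` and `post` must be finite.",
          class = "repgvhd_validation_error")
  }
  if (any(pre == 0)) {
    abort("Percent change is undefined for pre == 0.",
          class = "repgvhd_undefined_change_error")
  }
  100 * (post - pre) / pre
}

#' Pair longitudinal samples around a clinical anchor
#'
#' For subjects with an anchor (e.g. the day GVHD was diagnosed), the pair is
#' the last sample strictly before the anchor (`pre`) and the first sample at
#' or after it (`post`). Control subjects without an anchor are matched for
#' timing: among their consecutive sample pairs, the one minimizing the
#' summed absolute distance to the target pre/post days is chosen (target
#' defaults to the median pre/post sampling days of the anchored subjects);
#' ties go to the earlier pair.
#'
#' @param df A data frame with columns `subject_id`, `timepoint` (days) and
#'   the metric column named by `value`.
#' @param anchors A data frame with columns `subject_id` and `anchor` (day);
#'   subjects present here are treated as event subjects, all others as
#'   controls. An optional `group` column is carried through.
#' @param value Metric column name (default `"inv_simpson"`).
#' @param control_targets Optional length-2 numeric `c(pre_day, post_day)`
#'   overriding the matching target for controls.
#' @return A tibble with one row per paired subject: `subject_id`, `group`,
#'   `pre_timepoint`, `pre_value`, `post_timepoint`, `post_value`,
#'   `percent_change`.
#' @export
pair_longitudinal <- function(df, anchors, value = "inv_simpson",
                              control_targets = NULL) {
  needed <- c("subject_id", "timepoint", value)
  if (!all(needed %in% names(df))) {
    abort(sprintf("`df` needs columns %s.", paste(needed, collapse = ", ")),
          class = "repgvhd_validation_error")
  }
  if (!all(c("subject_id", "anchor") %in% names(anchors))) {
    abort("`anchors` needs columns `subject_id` and `anchor`.",
          class = "repgvhd_validation_error")
  }
  df <- df |>
    arrange(.data$subject_id, .data$timepoint)
  anchored <- anchors[!is.na(anchors$anchor), , drop = FALSE]

  event_rows <- lapply(seq_len(nrow(anchored)), function(i) {
    sid <- anchored$subject_id[i]
    a <- anchored$anchor[i]
    sub <- df[df$subject_id == sid, , drop = FALSE]
    pre <- sub[sub$timepoint < a, , drop = FALSE]
    post <- sub[sub$timepoint >= a, , drop = FALSE]
    if (nrow(pre) == 0 || nrow(post) == 0) {
      abort(sprintf(
        "Subject %s has no sample %s the anchor; cannot pair.",
        sid, if (nrow(pre) == 0) "before" else "at/after"),
        class = "repgvhd_pairing_error")
    }
    tibble(
      subject_id = as.character(sid),
      group = if ("group" %in% names(anchored)) anchored$group[i]
              else "event",
      pre_timepoint = max(pre$timepoint),
      pre_value = pre[[value]][which.max(pre$timepoint)],
      post_timepoint = min(post$timepoint),
      post_value = post[[value]][which.min(post$timepoint)]
    )
  })
  event_pairs <- bind_rows(event_rows)

  control_ids <- setdiff(unique(df$subject_id), anchored$subject_id)
  control_pairs <- NULL
  if (length(control_ids) > 0) {
    if (is.null(control_targets)) {
      if (nrow(event_pairs) == 0) {
        abort("No anchored subjects and no `control_targets`; cannot match controls for timing.",
              class = "repgvhd_pairing_error")
      }
      control_targets <- c(median(event_pairs$pre_timepoint),
                           median(event_pairs$post_timepoint))
    }
    control_rows <- lapply(control_ids, function(sid) {
      sub <- df[df$subject_id == sid, , drop = FALSE]
      if (nrow(sub) < 2) {
        abort(sprintf("Control subject %s has fewer than 2 timepoints.", sid),
              class = "repgvhd_pairing_error")
      }
      dist <- abs(sub$timepoint[-nrow(sub)] - control_targets[1]) +
        abs(sub$timepoint[-1] - control_targets[2])
      k <- which.min(dist)  # which.min takes the earliest tie
      tibble(
        subject_id = as.character(sid),
        group = "control",
        pre_timepoint = sub$timepoint[k],
        pre_value = sub[[value]][k],
        post_timepoint = sub$timepoint[k + 1],
        post_value = sub[[value]][k + 1]
      )
    })
    control_pairs <- bind_rows(control_rows)
  }

  out <- bind_rows(event_pairs, control_pairs)
  out$percent_change <- percent_change(out$pre_value, out$post_value)
  out
}
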