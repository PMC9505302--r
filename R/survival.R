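#' Event tables
#'
#' Competing-risk analyses consume an event table: one row per subject with
#' columns `subject_id`, `group`, `time` (months since DLI, > 0) and `event`
#' (a character code; `"censored"` marks censoring, the value passed as
#' `endpoint` marks the event of interest, and any other value is a
#' competing event). Follow-up is administratively capped (36 months in the
#' study design); [simulate_cohort()] produces tables in this shape.
#'
#' @name event-tables
#' @keywords internal
NULL

validate_events <- function(df, endpoint, call = rlang::caller_env()) {
  needed <- c("time", "event")
  if (!all(needed %in% names(df))) {
    abort("Event table needs columns `time` and `event`.",
          class = "repgvhd_validation_error", call = call)
  }
  if (nrow(df) == 0) {
    abort("Empty cohort: no event records.",
          class = "repgvhd_empty_cohort_error", call = call)
  }
  if (any(!is.finite(df$time) | df$time <= 0)) {
    abort("Event times must be finite and > 0.",
          class = "repgvhd_validation_error", call = call)
  }
  invisible(df)
}

#' Aalen-Johansen cumulative incidence under competing risks
#'
#' Estimates the cumulative incidence function (CIF) of one endpoint in the
#' presence of competing events: \eqn{CIF(t) = \sum_{t_i \le t} S(t_i-)
#' d_i/n_i}, where \eqn{S} is the all-cause Kaplan-Meier survival, \eqn{d_i}
#' the number of endpoint events at \eqn{t_i} and \eqn{n_i} the number at
#' risk. Competing events remove subjects from the risk set without
#' contributing to this endpoint's CIF. Computed with the multi-state
#' Aalen-Johansen estimator of [survival::survfit()].
#'
#' @param df An event table (see [event-tables]); a `group` column, when
#'   present and `by_group = TRUE`, yields one curve per group.
#' @param endpoint The `event` code of interest (e.g. `"gvhd"`).
#' @param by_group Estimate per-group curves when a `group` column exists.
#' @return A tibble of class `cif_tbl` with columns `group`, `time`,
#'   `n_risk`, `n_event`, `n_censor`, `estimate` (the CIF) and `std_err`.
#' @examples
#' ev <- tibble::tibble(subject_id = 1:3, group = "all",
#'                      time = c(1, 2, 3),
#'                      event = c("gvhd", "relapse", "gvhd"))
#' cumulative_incidence(ev, "gvhd")
#' @export
cumulative_incidence <- function(df, endpoint, by_group = TRUE) {
  validate_events(df, endpoint)
  codes <- unique(df$event)
  states <- c("censored", endpoint, sort(setdiff(codes,
                                                 c("censored", endpoint))))
  ev <- factor(df$event, levels = states)
  grp <- if (by_group && "group" %in% names(df)) factor(df$group)
         else factor(rep("all", nrow(df)))
  if (all(df$event == "censored")) {
    # no transitions at all: the curve never leaves zero
    out <- tibble(group = as.character(grp), time = df$time) |>
      arrange(.data$group, .data$time) |>
      group_by(.data$group) |>
      mutate(n_risk = rev(seq_len(n())), n_event = 0L, n_censor = 1L,
             estimate = 0, std_err = 0) |>
      ungroup()
    attr(out, "endpoint") <- endpoint
    class(out) <- c("cif_tbl", class(out))
    return(out)
  }
  fit <- survival::survfit(survival::Surv(df$time, ev) ~ grp)
  state_col <- match(endpoint, fit$states)
  strata <- if (is.null(fit$strata)) {
    rep(levels(grp)[1], length(fit$time))
  } else {
    rep(sub("^grp=", "", names(fit$strata)), fit$strata)
  }
  out <- tibble(
    group = strata,
    time = fit$time,
    n_risk = as.integer(fit$n.risk[, 1]),
    n_event = as.integer(fit$n.event[, state_col]),
    n_censor = as.integer(if (is.matrix(fit$n.censor))
      rowSums(fit$n.censor) else fit$n.censor),
    estimate = fit$pstate[, state_col],
    std_err = fit$std.err[, state_col]
  )
  attr(out, "endpoint") <- endpoint
  class(out) <- c("cif_tbl", class(out))
  out
}

#' Mantel-Haenszel hazard ratio for cumulative incidence curves
#'
#' At each distinct endpoint-event time a 2x2 at-risk/event table is formed;
#' with observed and expected event totals \eqn{O_j, E_j} summed over those
#' tables, the hazard ratio is \eqn{(O_1/E_1)/(O_2/E_2)} and the 95% CI is
#' \eqn{\exp(\log HR \pm 1.96/\sqrt{V})} with \eqn{V} the summed
#' hypergeometric variance. Competing events are treated as censored at
#' their time for this endpoint (the usual convention when hazard ratios
#' accompany cumulative-incidence curves; it targets the cause-specific
#' hazard, which can differ from a subdistribution contrast). Group 1 is the
#' first factor level of `group` (or `reference` when given).
#'
#' @inheritParams cumulative_incidence
#' @param reference Optional group label to use as group 1 (numerator).
#' @return An object of class `rep_test` with fields `estimate` (HR),
#'   `conf_low`/`conf_high`, `statistic` (log-rank chi-square), `p_value`.
#' @export
mantel_haenszel_hr <- function(df, endpoint, reference = NULL) {
  validate_events(df, endpoint)
  if (!"group" %in% names(df)) {
    abort("Event table needs a `group` column.",
          class = "repgvhd_validation_error")
  }
  grp <- factor(df$group)
  if (nlevels(grp) != 2) {
    abort("mantel_haenszel_hr() compares exactly two groups.",
          class = "repgvhd_validation_error")
  }
  if (!is.null(reference)) {
    grp <- stats::relevel(grp, ref = as.character(reference))
  }
  status <- as.integer(df$event == endpoint)  # competing -> censored here
  if (sum(status) == 0) {
    abort("No endpoint events in either group: hazard ratio undefined.",
          class = "repgvhd_undefined_hr_error")
  }
  sd <- survival::survdiff(survival::Surv(df$time, status) ~ grp)
  O <- sd$obs; E <- sd$exp; V <- sd$var[1, 1]
  note <- NA_character_
  if (O[1] == 0 || O[2] == 0) {
    hr <- if (O[1] == 0) 0 else Inf
    ci <- if (O[1] == 0) c(0, NA_real_) else c(NA_real_, Inf)
    note <- "zero endpoint events in one group; one-sided CI"
  } else {
    hr <- (O[1] / E[1]) / (O[2] / E[2])
    ci <- exp(log(hr) + c(-1, 1) * 1.96 / sqrt(V))
  }
  new_rep_test(
    test = "mantel_haenszel",
    statistic = unname(sd$chisq),
    p_value = unname(1 - pchisq(sd$chisq, df = 1)),
    estimate = hr, conf_low = ci[1], conf_high = ci[2],
    note = note,
    groups = levels(grp), obs = unname(O), exp = unname(E), var = V
  )
}

#' Gray's test for equality of cumulative incidence functions
#'
#' Two-group comparison of the subdistribution hazards of one endpoint under
#' competing risks (Gray 1988, rho = 0). The score accumulates, over the
#' pooled endpoint-event times, the difference between group 1's observed
#' endpoint events and its expectation under the null, using modified risk
#' sets \eqn{R_j(t) = y_j(t)\,(1 - \hat F_{1j}(t-)) / \hat S_j(t-)} that keep
#' subjects with prior competing events "at risk" for the subdistribution;
#' the statistic is score\eqn{^2/V} with the hypergeometric variance over
#' the modified risk sets, referred to a chi-square with 1 df. With this
#' variance convention the test reduces exactly to the log-rank test when
#' no competing events are present.
#'
#' For small cohorts the chi-square reference is coarse; with
#' `p_method = "permutation"` the p-value is instead taken from the
#' group-label permutation distribution of the statistic (enumerated
#' exactly when there are at most `max_enum` distinct label assignments,
#' otherwise `n_perm` seeded random permutations).
#'
#' @inheritParams cumulative_incidence
#' @param p_method `"asymptotic"` (chi-square, default) or
#'   `"permutation"`.
#' @param n_perm Random permutations when exact enumeration is infeasible.
#' @param perm_seed Seed for sampled permutations (mandatory when used).
#' @param max_enum Enumeration limit on `choose(n, n1)`.
#' @return An object of class `rep_test` with `statistic`, `p_value`, and
#'   the score and variance as `score`/`var`.
#' @export
grays_test <- function(df, endpoint,
                       p_method = c("asymptotic", "permutation"),
                       n_perm = 10000, perm_seed = NULL,
                       max_enum = 20000) {
  p_method <- rlang::arg_match(p_method)
  validate_events(df, endpoint)
  if (!"group" %in% names(df)) {
    abort("Event table needs a `group` column.",
          class = "repgvhd_validation_error")
  }
  grp <- factor(df$group)
  if (nlevels(grp) != 2) {
    abort("grays_test() compares exactly two groups.",
          class = "repgvhd_validation_error")
  }
  if (sum(df$event == endpoint) == 0) {
    abort("No endpoint events: Gray's test is degenerate.",
          class = "repgvhd_degenerate_test_error")
  }
  gs <- grays_score(df$time, df$event, grp, endpoint)
  stat <- if (gs$var > 0) gs$score^2 / gs$var else 0
  if (p_method == "asymptotic") {
    p <- unname(1 - pchisq(stat, df = 1))
  } else {
    p <- grays_perm_p(df, grp, endpoint, stat, n_perm, perm_seed, max_enum)
  }
  new_rep_test(
    test = "grays",
    statistic = stat,
    p_value = p,
    p_method = p_method,
    score = gs$score, var = gs$var, groups = levels(grp)
  )
}

grays_perm_p <- function(df, grp, endpoint, stat, n_perm, perm_seed,
                         max_enum) {
  n <- length(grp)
  n1 <- sum(grp == levels(grp)[1])
  stat_for <- function(sel) {
    g <- rep(levels(grp)[2], n)
    g[sel] <- levels(grp)[1]
    gs <- grays_score(df$time, df$event,
                      factor(g, levels = levels(grp)), endpoint)
    if (gs$var > 0) gs$score^2 / gs$var else 0
  }
  if (choose(n, n1) <= max_enum) {
    stats <- apply(utils::combn(n, n1), 2, stat_for)
  } else {
    if (is.null(perm_seed)) {
      abort("`perm_seed` is required for sampled permutations.",
            class = "repgvhd_validation_error")
    }
    stats <- withr::with_seed(as.integer(perm_seed), {
      replicate(n_perm, stat_for(sample.int(n, n1)))
    })
  }
  mean(stats >= stat - 1e-12)
}

# Score and hypergeometric variance of the rho = 0 subdistribution log-rank
# contrast for the first factor level.
grays_score <- function(time, event, grp, endpoint) {
  event_times <- sort(unique(time[event == endpoint]))
  lv <- levels(grp)
  # per-group left-limit step functions for all-cause KM survival S(t-) and
  # the endpoint CIF F1(t-)
  gf <- lapply(lv, function(g) {
    sel <- grp == g
    group_steps(time[sel], event[sel], endpoint)
  })
  names(gf) <- lv
  score <- 0
  vsum <- 0
  for (t in event_times) {
    R <- numeric(2)
    d1 <- numeric(2)
    for (j in 1:2) {
      sel <- grp == lv[j]
      y <- sum(time[sel] >= t)
      st <- step_left(gf[[j]], t)
      R[j] <- if (st$S > 0) y * (1 - st$F1) / st$S else 0
      d1[j] <- sum(sel & time == t & event == endpoint)
    }
    Rtot <- sum(R)
    dtot <- sum(d1)
    if (Rtot <= 0) next
    score <- score + d1[1] - dtot * R[1] / Rtot
    if (Rtot > 1) {
      vsum <- vsum + dtot * (R[1] / Rtot) * (1 - R[1] / Rtot) *
        (Rtot - dtot) / (Rtot - 1)
    }
  }
  list(score = score, var = vsum)
}

# Stepwise all-cause KM survival and endpoint CIF for one group: values just
# after each of the group's distinct event times.
group_steps <- function(time, event, endpoint) {
  ts <- sort(unique(time[event != "censored"]))
  S <- numeric(length(ts)); F1 <- numeric(length(ts))
  s_cur <- 1; f_cur <- 0
  for (k in seq_along(ts)) {
    y <- sum(time >= ts[k])
    d_all <- sum(time == ts[k] & event != "censored")
    d1 <- sum(time == ts[k] & event == endpoint)
    f_cur <- f_cur + s_cur * d1 / y
    s_cur <- s_cur * (1 - d_all / y)
    S[k] <- s_cur; F1[k] <- f_cur
  }
  list(times = ts, S = S, F1 = F1)
}

# Left limits S(t-), F1(t-) from a group_steps() object.
step_left <- function(gs, t) {
  k <- sum(gs$times < t)
  if (k == 0) list(S = 1, F1 = 0) else list(S = gs$S[k], F1 = gs$F1[k])
}
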