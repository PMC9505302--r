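test_that("normality gate dispatches between t-test and rank tests", {
  withr::with_seed(21, {
    heavy_x <- exp(rnorm(15, 0, 2))
    heavy_y <- exp(rnorm(15, 1, 2))
  })
  res <- dispatch_two_group_test(heavy_x, heavy_y)
  expect_equal(res$test, "mann_whitney")
  expect_match(res$normality_gate, "non-normal")

  withr::with_seed(22, {
    norm_x <- rnorm(20); norm_y <- rnorm(20, 0.5)
  })
  res2 <- dispatch_two_group_test(norm_x, norm_y)
  expect_equal(res2$test, "t")

  paired0 <- dispatch_two_group_test(c(1, 2, 3, 4), c(1, 2, 3, 4),
                                     paired = TRUE)
  expect_equal(paired0$test, "wilcoxon_signed_rank")
  expect_equal(paired0$p_value, 1)
  expect_match(paired0$note, "zero")

  expect_error(dispatch_two_group_test(c(1, 2), c(1, 2, 3)),
               class = "repgvhd_sample_size_error")
  expect_error(dispatch_two_group_test(1:4, 1:5, paired = TRUE),
               class = "repgvhd_validation_error")
})

test_that("exact Mann-Whitney p matches full rank-assignment enumeration", {
  # all choose(8,4) = 70 assignments of ranks: only the two extreme
  # orderings give |U| as extreme, so two-tailed p = 2/70
  res <- dispatch_two_group_test(c(1, 2, 3, 4), c(5, 6, 7, 8),
                                 choose = "nonparametric")
  expect_equal(res$test, "mann_whitney")
  expect_equal(res$p_value, 2 / 70, tolerance = 1e-12)
})

test_that("fisher's exact test matches hypergeometric enumeration", {
  res <- fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2))
  expect_equal(res$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(3, 2, 2))$p_value, 1)

  # independent enumeration oracle on random tables
  enum_fisher <- function(tab) {
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
    support <- max(0, k - n):min(k, m)
    probs <- dhyper(support, m, n, k)
    obs <- dhyper(tab[1, 1], m, n, k)
    sum(probs[probs <= obs * (1 + 1e-7)])
  }
  withr::with_seed(12, {
    for (i in 1:20) {
      tab <- matrix(rpois(4, 5), 2)
      if (sum(tab) == 0) next
      expect_equal(fisher_exact_2x2(tab)$p_value, enum_fisher(tab),
                   tolerance = 1e-9)
    }
  })

  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)),
               class = "repgvhd_validation_error")
  expect_error(fisher_exact_2x2(matrix(0, 2, 2)),
               class = "repgvhd_degenerate_table_error")
})

test_that("Aalen-Johansen CIF matches hand-worked competing-risk examples", {
  # 3 subjects: event at 1, competing at 2, event at 3
  ev <- tibble::tibble(subject_id = 1:3, time = 1:3,
                       event = c("gvhd", "relapse", "gvhd"))
  cif <- cumulative_incidence(ev, "gvhd")
  expect_equal(cif$estimate, c(1 / 3, 1 / 3, 2 / 3))

  # no competing events, no censoring: CIF is the empirical CDF
  ev2 <- tibble::tibble(subject_id = 1:4, time = c(2, 4, 6, 8),
                        event = "gvhd")
  cif2 <- cumulative_incidence(ev2, "gvhd")
  expect_equal(cif2$estimate, c(0.25, 0.5, 0.75, 1))

  # everyone censored: the curve never leaves zero
  ev3 <- tibble::tibble(subject_id = 1:4, time = 1:4, event = "censored")
  expect_true(all(cumulative_incidence(ev3, "gvhd")$estimate == 0))

  expect_error(cumulative_incidence(ev[0, ], "gvhd"),
               class = "repgvhd_empty_cohort_error")
  expect_error(
    cumulative_incidence(tibble::tibble(time = -1, event = "gvhd"), "gvhd"),
    class = "repgvhd_validation_error")
})

test_that("CIFs of all causes and overall survival sum to one without censoring", {
  withr::with_seed(31, {
    ev <- tibble::tibble(
      subject_id = 1:30,
      time = round(rexp(30, 0.1) + 0.1, 3),
      event = sample(c("gvhd", "relapse", "nrm"), 30, replace = TRUE)
    )
  })
  cifs <- lapply(c("gvhd", "relapse", "nrm"),
                 function(e) cumulative_incidence(ev, e))
  km <- survival::survfit(survival::Surv(ev$time, rep(1, 30)) ~ 1)
  total_at_end <- sum(vapply(cifs, function(x) dplyr::last(x$estimate),
                             numeric(1))) +
    dplyr::last(km$surv)
  expect_equal(total_at_end, 1, tolerance = 1e-12)
  for (x in cifs) expect_true(all(diff(x$estimate) >= -1e-12))
})

test_that("Mantel-Haenszel HR matches a hand-built risk-table worksheet", {
  # group a: events at 1, 2 (n=2); group b: events at 3, 4 (n=2)
  ev <- tibble::tibble(subject_id = 1:4, group = c("a", "a", "b", "b"),
                       time = 1:4, event = "gvhd")
  # risk sets: t=1 y=(2,2); t=2 y=(1,2); t=3 y=(0,2); t=4 y=(0,1)
  Ea <- 2 / 4 + 1 / 3
  Eb <- 2 / 4 + 2 / 3 + 1 + 1
  hr <- mantel_haenszel_hr(ev, "gvhd")
  expect_equal(hr$estimate, (2 / Ea) / (2 / Eb), tolerance = 1e-12)
  expect_true(hr$conf_low <= hr$estimate & hr$estimate <= hr$conf_high)

  # identical event histories -> HR exactly 1
  same <- tibble::tibble(subject_id = 1:6,
                         group = rep(c("a", "b"), each = 3),
                         time = rep(c(1, 2, 3), 2), event = "gvhd")
  expect_equal(mantel_haenszel_hr(same, "gvhd")$estimate, 1)

  # swapping group labels inverts the HR exactly
  hr_ba <- mantel_haenszel_hr(ev, "gvhd", reference = "b")
  expect_equal(hr_ba$estimate, 1 / hr$estimate, tolerance = 1e-12)

  none <- tibble::tibble(subject_id = 1:4, group = c("a", "a", "b", "b"),
                         time = 1:4, event = "censored")
  expect_error(mantel_haenszel_hr(none, "gvhd"),
               class = "repgvhd_undefined_hr_error")

  one_sided <- tibble::tibble(
    subject_id = 1:6, group = rep(c("a", "b"), each = 3),
    time = c(1, 2, 3, 4, 5, 6),
    event = c("censored", "censored", "censored", "gvhd", "gvhd", "gvhd"))
  res <- mantel_haenszel_hr(one_sided, "gvhd")
  expect_equal(res$estimate, 0)
  expect_match(res$note, "one-sided")
})

test_that("Gray's test is symmetric, detects nothing on identical groups", {
  base <- toy_events()
  dup <- dplyr::bind_rows(
    dplyr::mutate(base, group = "g1", subject_id = paste0(subject_id, "x")),
    dplyr::mutate(base, group = "g2", subject_id = paste0(subject_id, "y")))
  res <- grays_test(dup, "gvhd")
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)

  swapped <- dplyr::mutate(toy_events(),
                           group = ifelse(group == "a", "b", "a"))
  expect_equal(grays_test(toy_events(), "gvhd")$statistic,
               grays_test(swapped, "gvhd")$statistic, tolerance = 1e-12)

  no_events <- dplyr::mutate(toy_events(), event = "censored")
  expect_error(grays_test(no_events, "gvhd"),
               class = "repgvhd_degenerate_test_error")
})

test_that("without competing events Gray's test collapses to the log-rank test", {
  withr::with_seed(41, {
    ev <- tibble::tibble(
      subject_id = 1:40, group = rep(c("a", "b"), each = 20),
      time = c(rexp(20, 0.08), rexp(20, 0.15)),
      event = "gvhd")
  })
  g <- grays_test(ev, "gvhd")
  sd <- survival::survdiff(survival::Surv(ev$time, rep(1, 40)) ~ ev$group)
  expect_equal(g$statistic, sd$chisq, tolerance = 1e-9)
  expect_equal(g$p_value, 1 - pchisq(sd$chisq, 1), tolerance = 1e-9)
})

test_that("Gray's statistic asymptotically tracks the cmprsk implementation", {
  skip_if_not_installed("cmprsk")
  stats_pair <- sapply(1:40, function(i) {
    ev <- simulate_cohort(n_expanded_subjects = 50, n_healthy_like = 50,
                          seed = 500 + i, simulate_repertoires = FALSE)$events
    code <- ifelse(ev$event == "gvhd", 1,
                   ifelse(ev$event == "censored", 0, 2))
    c(mine = grays_test(ev, "gvhd")$statistic,
      ref = unname(cmprsk::cuminc(ev$time, code, ev$group)$Tests[1, "stat"]))
  })
  expect_gt(cor(stats_pair["mine", ], stats_pair["ref", ]), 0.98)
})
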