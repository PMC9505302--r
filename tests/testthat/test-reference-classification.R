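test_that("reference band averages individuals before taking percentiles", {
  hc <- tibble::tibble(
    individual_id = c("a", "a", rep(letters[2:9], each = 1)),
    inv_simpson = c(100, 200, 10 * 2:9)
  )
  ref <- build_hc_reference(hc)
  expect_equal(tidy(ref)$mean_value[tidy(ref)$individual_id == "a"], 150)

  # 9 individual means 10..90: the 25th percentile interpolates onto the
  # 3rd order statistic
  hc9 <- tibble::tibble(individual_id = letters[1:9],
                        inv_simpson = seq(10, 90, by = 10))
  ref9 <- build_hc_reference(hc9)
  expect_equal(ref9$p25, 30)
  expect_equal(ref9$p75, 70)

  same <- tibble::tibble(individual_id = rep(c("a", "b"), 3),
                         inv_simpson = 55)
  ref_same <- build_hc_reference(same, mode = "all_samples")
  expect_equal(ref_same$p25, 55)
  expect_equal(ref_same$p75, 55)

  expect_error(build_hc_reference(
    tibble::tibble(individual_id = "a", inv_simpson = 1)),
    class = "repgvhd_reference_error")
})

test_that("per-individual band is unchanged by duplicating an individual's samples", {
  hc <- tibble::tibble(individual_id = rep(letters[1:5], each = 3),
                       inv_simpson = withr::with_seed(5, rnorm(15, 300, 50)))
  ref <- build_hc_reference(hc)
  dup <- dplyr::bind_rows(hc, hc[hc$individual_id == "c", ])
  ref_dup <- build_hc_reference(dup)
  expect_equal(ref_dup$p25, ref$p25)
  expect_equal(ref_dup$p75, ref$p75)
})

test_that("expansion classification uses a strict < at the 25th percentile", {
  hc9 <- tibble::tibble(individual_id = letters[1:9],
                        inv_simpson = seq(10, 90, by = 10))
  ref9 <- build_hc_reference(hc9)  # p25 = 30
  df <- tibble::tibble(sample_id = c("lo", "edge", "hi"),
                       inv_simpson = c(29.9, 30, 1e9))
  cls <- classify_samples(df, ref9)
  expect_equal(cls$label, c("expanded", "healthy_like", "healthy_like"))
  expect_true(all(cls$threshold == 30))

  # monotone: lowering a value can never flip expanded -> healthy_like
  withr::with_seed(3, {
    v <- runif(50, 0, 100)
    lab1 <- classify_samples(tibble::tibble(inv_simpson = v), ref9)$label
    lab2 <- classify_samples(tibble::tibble(inv_simpson = v - runif(50, 0, 20)),
                             ref9)$label
    expect_false(any(lab1 == "expanded" & lab2 == "healthy_like"))
  })
  expect_error(classify_samples(tibble::tibble(inv_simpson = NaN), ref9),
               class = "repgvhd_validation_error")
})

test_that("percent change follows 100 * (post - pre) / pre", {
  expect_equal(percent_change(200, 200), 0)
  expect_equal(percent_change(100, 43.73), -56.27)
  expect_equal(percent_change(100, 227.02), 127.02)
  expect_error(percent_change(0, 10),
               class = "repgvhd_undefined_change_error")

  # antisymmetry holds only through the exact nonlinear relation
  withr::with_seed(8, {
    a <- runif(50, 1, 500); b <- runif(50, 1, 500)
    pc_ab <- percent_change(a, b)
    pc_ba <- percent_change(b, a)
    expect_equal(pc_ab, -100 * pc_ba / (100 + pc_ba), tolerance = 1e-10)
  })
})

test_that("longitudinal pairing picks last-before and first-after the anchor", {
  df <- tibble::tibble(
    subject_id = rep(c("p1", "p2"), c(4, 3)),
    timepoint = c(-120, -66, 9, 50, 10, 40, 80),
    inv_simpson = c(200, 180, 80, 90, 100, 120, 110)
  )
  anchors <- tibble::tibble(subject_id = "p1", anchor = 0,
                            group = "aGVHD")
  pairs <- pair_longitudinal(df, anchors, control_targets = c(15, 45))
  p1 <- pairs[pairs$subject_id == "p1", ]
  expect_equal(p1$pre_timepoint, -66)
  expect_equal(p1$post_timepoint, 9)
  expect_equal(p1$percent_change, 100 * (80 - 180) / 180)
  expect_equal(p1$group, "aGVHD")

  # control matched for timing against targets (15, 45) -> pair (10, 40)
  p2 <- pairs[pairs$subject_id == "p2", ]
  expect_equal(c(p2$pre_timepoint, p2$post_timepoint), c(10, 40))

  only_after <- tibble::tibble(subject_id = "p3", timepoint = c(5, 9),
                               inv_simpson = c(1, 2))
  expect_error(
    pair_longitudinal(only_after,
                      tibble::tibble(subject_id = "p3", anchor = 0)),
    "p3", class = "repgvhd_pairing_error")
})
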