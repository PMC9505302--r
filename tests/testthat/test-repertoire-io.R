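test_that("vdjtools tables are read with frequencies recomputed from counts", {
  path <- write_vdjtools_fixture(c(10, 30, 60))
  tbl <- read_clonotype_table(path, "vdjtools", sample_id = "s1")
  expect_equal(sum(tbl$count), 100)
  expect_equal(tbl$freq, c(0.10, 0.30, 0.60))
  expect_equal(tbl$cdr3_nt, sprintf("TGT%03dTTT", 1:3))  # row order kept

  # a lying freq column is overridden with a warning
  bad <- write_vdjtools_fixture(c(10, 30, 60), freq = c(0.5, 0.25, 0.25))
  expect_warning(tbl2 <- read_clonotype_table(bad, "vdjtools"),
                 "recomputed")
  expect_equal(tbl2$freq, c(0.10, 0.30, 0.60))
})

test_that("airr tables are read and missing mandatory columns are named", {
  path <- write_airr_fixture(c(5, 15))
  tbl <- read_clonotype_table(path, "airr", sample_id = "a1")
  expect_equal(tbl$count, c(5, 15))
  expect_equal(tbl$freq, c(0.25, 0.75))

  nocount <- write_airr_fixture(c(5, 15), drop = "duplicate_count")
  expect_error(read_clonotype_table(nocount, "airr"),
               "duplicate_count", class = "repgvhd_format_error")
})

test_that("invalid counts are rejected with informative errors", {
  neg <- data.frame(v_call = "V", j_call = "J", cdr3_nt = c("A", "B"),
                    count = c(5, -1))
  expect_error(as_clonotype_tbl(neg, sample_id = "s"),
               "row", class = "repgvhd_validation_error")
  zero <- data.frame(v_call = "V", j_call = "J", cdr3_nt = "A", count = 0)
  expect_error(as_clonotype_tbl(zero, sample_id = "s"),
               class = "repgvhd_empty_sample_error")
})

test_that("read-write-read round trips preserve counts and keys exactly", {
  tbl <- make_ct(c(7, 3, 90, 11))
  for (dialect in c("vdjtools", "airr")) {
    path <- tempfile(fileext = ".tsv")
    write_clonotype_table(tbl, path, dialect)
    back <- read_clonotype_table(path, dialect, sample_id = "s1")
    expect_equal(back$count, tbl$count)
    expect_equal(clonotype_key(back), clonotype_key(tbl))
  }
})

test_that("aggregation merges identical keys at the requested level", {
  df <- data.frame(
    v_call = "TRBV9", j_call = "TRBJ1-1",
    cdr3_nt = c("TGTGCTTTT", "TGTGCTTTT", "TGTGCCTTT"),
    cdr3_aa = c("CAF", "CAF", "CAF"),
    count = c(5, 15, 10)
  )
  tbl <- as_clonotype_tbl(df, sample_id = "s1")
  nt <- aggregate_clonotypes(tbl, "nt")
  expect_equal(nrow(nt), 2)
  expect_equal(sort(nt$count), c(10, 20))
  aa <- aggregate_clonotypes(tbl, "aa")
  expect_equal(nrow(aa), 1)
  expect_equal(aa$count, 30)
  expect_equal(aa$freq, 1)

  distinct_tbl <- make_ct(c(1, 2, 3))
  again <- aggregate_clonotypes(distinct_tbl, "nt")
  expect_equal(sort(again$count), sort(distinct_tbl$count))
  expect_false(any(duplicated(clonotype_key(again))))
})

test_that("downsampling hits the target exactly and is seed-deterministic", {
  tbl <- make_ct(c(20000, 15000, 10000, 5000))  # 50,000 reads
  out <- downsample_reads(tbl, 20000, seed = 11)
  expect_equal(sum(out$count), 20000)
  a <- downsample_reads(tbl, 20000, seed = 42)
  b <- downsample_reads(tbl, 20000, seed = 42)
  expect_identical(a$count, b$count)
  expect_identical(a$cdr3_nt, b$cdr3_nt)

  # table already at target passes through unchanged
  at <- make_ct(c(15000, 5000))
  expect_equal(downsample_reads(at, 20000, seed = 1)$count, at$count)
})

test_that("downsampling never inflates clones nor invents keys", {
  for (s in 1:15) {
    counts <- sample(1:500, 20, replace = TRUE)
    tbl <- make_ct(counts)
    out <- downsample_reads(tbl, floor(sum(counts) / 3), seed = s)
    m <- match(clonotype_key(out), clonotype_key(tbl))
    expect_false(any(is.na(m)))
    expect_true(all(out$count <= tbl$count[m]))
  }
})

test_that("under-depth samples follow the short policy and are flagged", {
  shallow <- make_ct(c(50, 30), sample_id = "shallow")
  deep <- make_ct(c(4000, 3000, 3000), sample_id = "deep")
  both <- dplyr::bind_rows(shallow, deep)

  skip_res <- downsample_reads(both, 5000, seed = 1, short_policy = "skip")
  expect_false("shallow" %in% skip_res$sample_id)
  man <- downsample_manifest(skip_res)
  expect_equal(man$flag[man$sample_id == "shallow"], "under_depth_skipped")
  expect_equal(man$flag[man$sample_id == "deep"], "ok")

  expect_error(downsample_reads(both, 5000, seed = 1,
                                short_policy = "error"),
               class = "repgvhd_depth_error")

  keep_res <- downsample_reads(both, 5000, seed = 1, short_policy = "keep")
  expect_equal(sum(keep_res$count[keep_res$sample_id == "shallow"]), 80)

  expect_error(downsample_reads(deep, -5, seed = 1),
               class = "repgvhd_validation_error")
  expect_error(downsample_reads(deep, 100),  # missing seed
               class = "repgvhd_validation_error")
})

test_that("downsampled frequencies are unbiased on a 5-clone toy", {
  counts <- c(400, 250, 200, 100, 50)
  tbl <- make_ct(counts)
  n <- 250
  target <- 200
  draws <- sapply(seq_len(n), function(s) {
    out <- downsample_reads(tbl, target, seed = s)
    full <- numeric(5)
    full[match(clonotype_key(out), clonotype_key(tbl))] <- out$count
    full
  })
  p <- counts / sum(counts)
  expected <- target * p
  # exact hypergeometric variance of each clone's downsampled count
  v <- target * p * (1 - p) * (sum(counts) - target) / (sum(counts) - 1)
  se_mean <- sqrt(v / n)
  expect_true(all(abs(rowMeans(draws) - expected) <= 3 * se_mean))
})
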