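pair_fixture <- function(r_target = -1) {
  pairs <- tibble::tibble(mirna_id = "m1", transcript_id = "t1",
                          start = 10L, end = 31L, E = 0,
                          n_mismatch = 0L, n_gu = 0L, n_gap = 0L,
                          mode = "cleavage", states = strrep(":", 21))
  mm <- tibble::tibble(mirna_id = "m1", rpkm_mean_18 = 1,
                       rpkm_mean_23 = 2, rpkm_mean_28 = 3)
  list(pairs = pairs, mirna_means = mm)
}

test_that("pair retention follows the strict r < -0.6 rule", {
  fx <- pair_fixture()
  run_case <- function(y) {
    mrna <- tibble::tibble(transcript_id = "t1", mean_18 = y[1],
                           mean_23 = y[2], mean_28 = y[3])
    correlate_pairs(fx$pairs, fx$mirna_means, mrna, dems = "m1",
                    degs = "t1")
  }
  expect_true(run_case(c(3, 2, 1))$retained)          # r = -1
  expect_false(run_case(c(1, 2, 3))$retained)         # r = +1
  # r exactly -0.6: not retained ("below -0.6" is strict)
  y <- local({
    x <- c(1, 2, 3); xs <- (x - mean(x)) / sd(x)
    w <- c(1, -2, 1) / sd(c(1, -2, 1))
    5 + (-0.6 * xs + sqrt(1 - 0.36) * w)
  })
  case <- run_case(y)
  expect_equal(case$r, -0.6, tolerance = 1e-12)
  expect_false(case$retained)
  # r = -0.5: not retained; r = -0.7: retained
  mk <- function(rho) {
    x <- c(1, 2, 3); xs <- (x - mean(x)) / sd(x)
    w <- c(1, -2, 1) / sd(c(1, -2, 1))
    5 + (rho * xs + sqrt(1 - rho^2) * w)
  }
  expect_false(run_case(mk(-0.5))$retained)
  expect_true(run_case(mk(-0.7))$retained)
  # degenerate (flat) target profile: r undefined, flagged, never retained
  dg <- run_case(c(2, 2, 2))
  expect_true(dg$degenerate)
  expect_true(is.na(dg$r))
  expect_false(dg$retained)
})

test_that("retention requires DEM and DEG membership", {
  fx <- pair_fixture()
  mrna <- tibble::tibble(transcript_id = "t1", mean_18 = 3, mean_23 = 2,
                         mean_28 = 1)
  expect_false(correlate_pairs(fx$pairs, fx$mirna_means, mrna,
                               dems = character(), degs = "t1")$retained)
  expect_false(correlate_pairs(fx$pairs, fx$mirna_means, mrna,
                               dems = "m1", degs = character())$retained)
  # missing expression: pair skipped with a warning, not an error
  expect_warning(
    out <- correlate_pairs(fx$pairs, fx$mirna_means[0, ], mrna,
                           dems = "m1", degs = "t1"),
    "skipped")
  expect_equal(nrow(out), 0)
})

test_that("tightening the correlation threshold never adds pairs", {
  withr::with_seed(21, {
    n <- 30
    pairs <- tibble::tibble(mirna_id = sprintf("m%02d", 1:n),
                            transcript_id = sprintf("t%02d", 1:n),
                            start = 0L, end = 21L, E = 0, n_mismatch = 0L,
                            n_gu = 0L, n_gap = 0L, mode = "cleavage",
                            states = "")
    mm <- tibble::tibble(mirna_id = pairs$mirna_id,
                         rpkm_mean_18 = runif(n, 1, 10),
                         rpkm_mean_23 = runif(n, 1, 10),
                         rpkm_mean_28 = runif(n, 1, 10))
    mrna <- tibble::tibble(transcript_id = pairs$transcript_id,
                           mean_18 = runif(n, 1, 10),
                           mean_23 = runif(n, 1, 10),
                           mean_28 = runif(n, 1, 10))
    r1 <- correlate_pairs(pairs, mm, mrna, dems = pairs$mirna_id,
                          degs = pairs$transcript_id, threshold = -0.6)
    r2 <- correlate_pairs(pairs, mm, mrna, dems = pairs$mirna_id,
                          degs = pairs$transcript_id, threshold = -0.9)
    expect_true(all(r2$mirna_id[r2$retained] %in% r1$mirna_id[r1$retained]))
    # never a NaN correlation in retained output
    expect_false(any(is.na(r1$r[r1$retained])))
  })
})

test_that("regulator classification validates categories and attaches them", {
  fx <- pair_fixture()
  mrna <- tibble::tibble(transcript_id = "t1", mean_18 = 3, mean_23 = 2,
                         mean_28 = 1)
  pr <- correlate_pairs(fx$pairs, fx$mirna_means, mrna, dems = "m1",
                        degs = "t1")
  ann <- tibble::tibble(transcript_id = c("t1", "t2"),
                        category = c("Histone methylation", NA))
  out <- classify_regulators(pr, ann)
  expect_equal(out$category, "Histone methylation")
  out2 <- classify_regulators(pr, tibble::tibble(transcript_id = "t9",
                                                 category = "sRNA pathways"))
  expect_true(is.na(out2$category))
  expect_error(
    classify_regulators(pr, tibble::tibble(transcript_id = "t1",
                                           category = "Histone juggling")),
    "unknown regulator categories")
})

test_that("summary tables mirror the category/family schemas", {
  # empty pair set: all-zero tables, valid report
  empty <- tibble::tibble(mirna_id = character(), transcript_id = character(),
                          retained = logical(), category = character())
  s0 <- summarize_pairs(empty)
  expect_equal(nrow(s0$category_table), 8)
  expect_true(all(s0$category_table$n_mirnas == 0))
  expect_equal(s0$report$n_pairs_retained, 0)
  # 2 miRNAs sharing 1 target in one category
  pr <- tibble::tibble(mirna_id = c("m1", "m2"), transcript_id = "t1",
                       retained = TRUE, category = "Chromatin remodeling")
  s1 <- summarize_pairs(pr, annotation = tibble::tibble(
    transcript_id = "t1", category = "Chromatin remodeling",
    domain_family = "SNF2"))
  row <- s1$category_table[s1$category_table$category == "Chromatin remodeling", ]
  expect_equal(row$n_mirnas, 2L)
  expect_equal(row$n_targets, 1L)
  expect_equal(s1$family_table$n_mirnas[s1$family_table$domain_family == "SNF2"],
               2L)
})
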