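make_es <- function(counts_mat, lens = NULL, lib_sizes = NULL,
                    temps = rep(c(18L, 23L, 28L), each = 2)) {
  n_lib <- ncol(counts_mat)
  libs <- sprintf("L%02d", seq_len(n_lib))
  colnames(counts_mat) <- libs
  md <- tibble::tibble(library = libs, genotype = "A2C", stage = 1L,
                       temperature = temps)
  if (is.null(lens)) lens <- rep(21L, nrow(counts_mat))
  counts <- dplyr::bind_cols(
    tibble::tibble(mirna_id = sprintf("m%03d", seq_len(nrow(counts_mat))),
                   sequence = vapply(lens, function(l) strrep("A", l), "")),
    tibble::as_tibble(counts_mat))
  quantify_mirnas(counts, md, lib_sizes)
}

test_that("RPKM follows the count / (depth x length) formula", {
  es <- make_es(matrix(rep(100L, 6), 1), lens = 21L,
                lib_sizes = setNames(rep(1e6, 6), sprintf("L%02d", 1:6)))
  expect_equal(unname(as.matrix(es$rpkm[1, -1])[1, 1]),
               100 / (1 * 0.021), tolerance = 1e-9)
  # count 0 -> RPKM 0
  es0 <- make_es(matrix(0L, 1, 6),
                 lib_sizes = setNames(rep(1e6, 6), sprintf("L%02d", 1:6)))
  expect_true(all(as.matrix(es0$rpkm[, -1]) == 0))
  # doubling counts and library sizes leaves RPKM unchanged
  m <- matrix(as.integer(c(10, 20, 30, 40, 50, 60)), 1)
  s1 <- setNames(rep(2e5, 6), sprintf("L%02d", 1:6))
  e1 <- make_es(m, lib_sizes = s1)
  e2 <- make_es(2L * m, lib_sizes = 2 * s1)
  expect_equal(as.matrix(e1$rpkm[, -1]), as.matrix(e2$rpkm[, -1]))
  # zero-size library errors with its name
  expect_error(make_es(m, lib_sizes = setNames(c(0, rep(1e6, 5)),
                                               sprintf("L%02d", 1:6))),
               "L01")
})

test_that("expressed filter keys on per-condition means", {
  m <- rbind(c(12L, 12L, 0L, 0L, 0L, 0L),   # mean 12 at 18C -> kept
             c(9L, 9L, 9L, 9L, 9L, 9L))     # means (9,9,9) -> dropped
  es <- make_es(m)
  kept <- filter_expressed(es, 10)
  expect_equal(kept$counts$mirna_id, "m001")
  expect_equal(nrow(filter_expressed(es, 0)$counts), 2)
})

test_that("Kal's test matches arithmetic and an exact binomial oracle", {
  # second low-count row keeps the zero-guard pseudo-value small
  es <- make_es(rbind(c(40L, 40L, 10L, 10L, 0L, 0L),
                      c(1L, 1L, 1L, 1L, 1L, 1L)),
                lib_sizes = setNames(rep(1e6, 6), sprintf("L%02d", 1:6)))
  de <- de_test(es, contrast = "18v23")
  expect_equal(de$log2_ratio[1], 2, tolerance = 0.03)
  expect_true(de$significant[1])
  # identical pooled proportions: p = 1, not significant
  es_eq <- make_es(rbind(c(25L, 25L, 25L, 25L, 0L, 0L)),
                   lib_sizes = setNames(rep(1e6, 6), sprintf("L%02d", 1:6)))
  de_eq <- de_test(es_eq, contrast = "18v23")
  expect_equal(de_eq$p_value, 1)
  expect_false(de_eq$significant)
  # both conditions zero: defined, silent
  es_z <- make_es(rbind(c(0L, 0L, 0L, 0L, 5L, 5L)),
                  lib_sizes = setNames(rep(1e6, 6), sprintf("L%02d", 1:6)))
  de_z <- de_test(es_z, contrast = "18v23")
  expect_equal(de_z$log2_ratio, 0)
  expect_equal(de_z$p_value, 1)
  # moderate counts: Z-test p tracks the exact conditional binomial to
  # normal-approximation accuracy
  es_b <- make_es(rbind(c(30L, 0L, 16L, 0L, 0L, 0L)),
                  lib_sizes = setNames(rep(1e6, 6), sprintf("L%02d", 1:6)))
  de_b <- de_test(es_b, contrast = "18v23")
  exact <- stats::binom.test(30, 46, 0.5)$p.value
  expect_equal(de_b$p_value, exact, tolerance = 0.35)
  # high-separation case: both p-values essentially zero
  es_c <- make_es(rbind(c(150L, 0L, 50L, 0L, 0L, 0L)),
                  lib_sizes = setNames(rep(1e6, 6), sprintf("L%02d", 1:6)))
  de_c <- de_test(es_c, contrast = "18v23")
  exact_c <- stats::binom.test(150, 200, 0.5)$p.value
  expect_equal(de_c$p_value, exact_c, tolerance = 1e-3)
})

test_that("DEM calling uses strict thresholds", {
  # engineer log2 ratio exactly 1 with a large, highly significant Z
  es <- make_es(rbind(c(200L, 200L, 100L, 100L, 0L, 0L)),
                lib_sizes = setNames(rep(1e6, 6), sprintf("L%02d", 1:6)))
  de <- de_test(es, contrast = "18v23")
  # pseudo-count keeps the ratio a hair under 2x here; force the boundary
  de$log2_ratio <- 1
  de$significant <- abs(de$log2_ratio) > 1 & de$p_value < 0.05
  expect_false(de$significant)   # "more than 1" is strict
  dems <- call_dems(dplyr::bind_rows(
    de, dplyr::mutate(de, contrast = "18v28"),
    dplyr::mutate(de, contrast = "23v28")))
  expect_false(dems$is_dem)
  # clearly significant case
  es2 <- make_es(rbind(c(500L, 500L, 100L, 100L, 0L, 0L)),
                 lib_sizes = setNames(rep(1e6, 6), sprintf("L%02d", 1:6)))
  de2 <- de_test(es2)
  expect_true(any(de2$significant))
  expect_true(call_dems(de2)$is_dem)
})

test_that("DEM calls are invariant to library order within conditions", {
  withr::with_seed(10, {
    m <- matrix(as.integer(rpois(60, lambda = rep(c(200, 60, 30), each = 20))),
                nrow = 10)
    es1 <- make_es(m)
    perm <- c(2, 1, 4, 3, 6, 5)   # swap libraries within each condition
    es2 <- make_es(m[, perm])
    d1 <- call_dems(de_test(es1))
    d2 <- call_dems(de_test(es2))
    expect_equal(d1$is_dem, d2$is_dem)
  })
})

test_that("the sign-triple space has exactly 12 non-flat consistent classes", {
  space <- profile_cluster_space()
  expect_equal(nrow(space), 12)
  expect_equal(anyDuplicated(space[, c("s_18v23", "s_23v28", "s_18v28")]), 0)
  # enumerate all 27 sign triples: 13 consistent (12 non-flat + flat)
  grid <- expand.grid(a = -1:1, b = -1:1, c = -1:1)
  key <- paste(grid$a, grid$b, grid$c)
  space_key <- paste(space$s_18v23, space$s_23v28, space$s_18v28)
  consistent <- key %in% c(space_key, "0 0 0")
  expect_equal(sum(consistent), 13)
  expect_equal(sum(!consistent), 14)
  # every consistent triple is realised by some real-valued means vector
  for (i in seq_len(nrow(space))) {
    r <- unlist(space[i, c("rank_18", "rank_23", "rank_28")])
    expect_equal(sign(r[[1]] - r[[2]]), space$s_18v23[i])
    expect_equal(sign(r[[2]] - r[[3]]), space$s_23v28[i])
    expect_equal(sign(r[[1]] - r[[3]]), space$s_18v28[i])
  }
})

test_that("profile clustering labels match the described patterns", {
  # means (10, 10, 100): only 28-contrasts significant -> high at 28 only
  de <- tibble::tibble(
    mirna_id = "m1", contrast = c("18v23", "18v28", "23v28"),
    log2_ratio = c(0, -3.3, -3.3), p_value = c(0.9, 1e-6, 1e-6),
    significant = c(FALSE, TRUE, TRUE))
  cm <- tibble::tibble(mirna_id = "m1", rpkm_mean_18 = 10,
                       rpkm_mean_23 = 10, rpkm_mean_28 = 100)
  cl <- cluster_profiles(de, cm)
  expect_equal(cl$label, "28 > 18 = 23")
  expect_false(cl$resigned)
  # means (100, 50, 10), all contrasts significant downward with temperature
  de2 <- tibble::tibble(
    mirna_id = "m2", contrast = c("18v23", "18v28", "23v28"),
    log2_ratio = c(1.1, 3.3, 2.2), p_value = 1e-6, significant = TRUE)
  cm2 <- tibble::tibble(mirna_id = "m2", rpkm_mean_18 = 100,
                        rpkm_mean_23 = 50, rpkm_mean_28 = 10)
  cl2 <- cluster_profiles(de2, cm2)
  expect_equal(cl2$label, "18 > 23 > 28")
  # inconsistent triple gets re-signed from the means and flagged
  de3 <- tibble::tibble(
    mirna_id = "m3", contrast = c("18v23", "18v28", "23v28"),
    log2_ratio = c(1.5, 0.2, 1.4), p_value = c(1e-4, 0.5, 1e-4),
    significant = c(TRUE, FALSE, TRUE))
  cm3 <- tibble::tibble(mirna_id = "m3", rpkm_mean_18 = 90,
                        rpkm_mean_23 = 30, rpkm_mean_28 = 80)
  cl3 <- suppressMessages(cluster_profiles(de3, cm3))
  expect_true(cl3$resigned)
  expect_equal(cl3$label, "18 > 28 > 23")
})

test_that("the null DEM rate is conservative", {
  null <- simulate_null_dem_rate(n_mirnas = 200, n_reps = 20, seed = 5)
  expect_lte(null$dem_rate, 0.07)
})
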