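test_that("the generator is deterministic under a fixed seed", {
  cfg <- tiny_cfg(seed = 3)
  s1 <- simulate_srna_experiment(cfg)
  s2 <- simulate_srna_experiment(cfg)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$transcripts, s2$transcripts)
  expect_identical(s1$loci, s2$loci)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$mrna, s2$mrna)
  # byte-identical files too
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(s1, d1)
  write_simulation(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("transcript loci are non-overlapping and sized as requested", {
  cfg <- sim_config(seed = 5, genome_length = 200000, n_mir_loci = 40,
                    n_transcripts = 300)
  g <- generate_genome(cfg)
  tx <- g$transcripts[order(g$transcripts$start), ]
  expect_equal(nrow(tx), 300)
  # brute-force interval scan
  expect_true(all(tx$start[-1] >= tx$end[-nrow(tx)]))
  expect_true(all(tx$end <= cfg$genome_length))
  expect_equal(nchar(g$genome), cfg$genome_length)
})

test_that("degenerate and failing genome configurations behave", {
  cfg0 <- sim_config(seed = 1, genome_length = 5000, n_mir_loci = 0,
                     n_transcripts = 0, n_regulator_transcripts = 0)
  g0 <- generate_genome(cfg0)
  expect_equal(nrow(g0$transcripts), 0)
  p <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(g0, p)
  expect_true(file.exists(p))
  cfg_small <- sim_config(seed = 1, genome_length = 2000, n_mir_loci = 0,
                          n_transcripts = 10, n_regulator_transcripts = 0)
  expect_error(generate_genome(cfg_small), "genome too short")
})

test_that("planted loci have designed hairpin geometry and unique ids", {
  sim <- plant_mir_loci(generate_genome(tiny_cfg(seed = 9)))
  lo <- sim$loci
  expect_equal(nrow(lo), 6)
  expect_false(anyDuplicated(lo$locus_id) > 0)
  # a locus with 0 designed mismatches has an exact reverse-complement arm
  zero <- lo[lo$n_designed_mismatches == 0, ]
  for (i in seq_len(nrow(zero))) {
    expect_identical(zero$star_seq[i], revcomp(zero$guide_seq[i]))
  }
  # every guide is embedded verbatim in the rewritten genome
  for (i in seq_len(nrow(lo))) {
    hp <- substr(sim$genome, lo$genome_start[i] + 1, lo$genome_end[i])
    expect_identical(hp, paste0(lo$arm5p[i], lo$loop_seq[i], lo$arm3p[i]))
  }
})

test_that("planted hairpin windows fold into validating duplexes", {
  sim <- plant_target_links(plant_mir_loci(generate_genome(tiny_cfg(seed = 21))))
  lo <- sim$loci
  for (i in seq_len(nrow(lo))) {
    g_start <- if (lo$guide_arm[i] == "5p") lo$genome_start[i] else
      lo$arm3p_start[i]
    g_end <- g_start + nchar(lo$guide_seq[i])
    w <- extract_window(sim$genome, g_start, g_end, 80)
    hp <- fold_hairpin(w$seq)
    v <- validate_duplex(hp, g_start - w$start, g_end - w$start)
    expect_true(v$pass, info = lo$locus_id[i])
    expect_equal(v$arm, lo$guide_arm[i])
  }
})

test_that("truth counts are conserved and pure-signal reads are exact", {
  cfg <- tiny_cfg(seed = 13,
                  isomir_rates = c(substitution = 0, trim5 = 0, trim3 = 0,
                                   ext3_templated = 0, tail3_U = 0,
                                   tail3_A = 0),
                  seq_error_rate = 0)
  sim <- simulate_srna_experiment(cfg)
  tc <- sim$truth_counts |>
    dplyr::group_by(library) |>
    dplyr::summarise(n = sum(count))
  expect_true(all(tc$n == cfg$reads_per_library))
  planted <- c(sim$loci$guide_seq, sim$loci$star_seq)
  lib1 <- cfg$library_design$library[1]
  n_mirna <- sum(sim$truth_counts$count[sim$truth_counts$library == lib1 &
                                          sim$truth_counts$source != "background"])
  # miRNA-derived reads are exactly the planted guide/star sequences
  reads <- sim$reads[[lib1]]
  expect_equal(sum(reads %in% planted) >= n_mirna, TRUE)
})

test_that("read lengths follow the configured mixture (chi-square GOF)", {
  cfg <- sim_config(seed = 17, genome_length = 50000, n_mir_loci = 0,
                    n_transcripts = 20, n_regulator_transcripts = 0,
                    reads_per_library = 30000, frac_mirna_reads = 0,
                    library_design = default_library_design()[1, ])
  sim <- simulate_srna_experiment(cfg)
  lens <- nchar(sim$reads[[1]])
  pmf <- sporomir:::length_mixture_pmf(cfg$length_mixture)
  obs <- table(factor(lens, levels = names(pmf)))
  gof <- suppressWarnings(stats::chisq.test(obs, p = pmf))
  expect_gt(gof$p.value, 0.01)
  # modal classes detected on the pre-filter profile
  prof <- length_distribution(list(lib = sim$reads[[1]]))
  expect_true(all(c(24, 31) %in% prof$modes))
  expect_true(any(c(21, 22) %in% prof$modes))
})

test_that("temperature-responsive miRNAs have rank-ordered empirical counts", {
  cfg <- tiny_cfg(seed = 29, reads_per_library = 8000)
  sim <- simulate_srna_experiment(cfg)
  em <- sim$expression_model
  de <- em[em$de, ]
  ld <- cfg$library_design
  counts_of <- function(locus, temp) {
    libs <- ld$library[ld$temperature == temp]
    src <- paste0(locus, ":guide")
    sum(sim$truth_counts$count[sim$truth_counts$library %in% libs &
                                 sim$truth_counts$source == src])
  }
  for (i in seq_len(nrow(de))) {
    mult <- unlist(de[i, c("mult_18", "mult_23", "mult_28")])
    cnt <- c(counts_of(de$locus_id[i], 18), counts_of(de$locus_id[i], 23),
             counts_of(de$locus_id[i], 28))
    hi <- which.max(mult); lo <- which.min(mult)
    expect_gt(cnt[hi], cnt[lo])
  }
})

test_that("mRNA table has planted anti-correlation and unbiased background", {
  cfg <- tiny_cfg(seed = 31)
  sim <- simulate_srna_experiment(cfg)
  expect_equal(dim(sim$mrna), c(cfg$n_transcripts, 4))
  em <- sim$expression_model
  for (k in seq_len(nrow(sim$target_links))) {
    li <- match(sim$target_links$locus_id[k], em$locus_id)
    x <- em$base_abundance[li] * unlist(em[li, c("mult_18", "mult_23",
                                                 "mult_28")])
    y <- unlist(sim$mrna[match(sim$target_links$transcript_id[k],
                               sim$mrna$transcript_id),
                         c("mean_18", "mean_23", "mean_28")])
    expect_equal(cor(x, y), cfg$anticorrelation_strength, tolerance = 1e-8)
  }
  # exact negatives at strength -1
  cfg2 <- tiny_cfg(seed = 31, anticorrelation_strength = -1)
  sim2 <- simulate_srna_experiment(cfg2)
  em2 <- sim2$expression_model
  k <- 1
  li <- match(sim2$target_links$locus_id[k], em2$locus_id)
  x <- em2$base_abundance[li] * unlist(em2[li, c("mult_18", "mult_23",
                                                 "mult_28")])
  y <- unlist(sim2$mrna[match(sim2$target_links$transcript_id[k],
                              sim2$mrna$transcript_id),
                        c("mean_18", "mean_23", "mean_28")])
  expect_equal(cor(x, y), -1, tolerance = 1e-8)
  # unlinked transcripts show no systematic correlation sign
  unlinked <- setdiff(sim$mrna$transcript_id, sim$target_links$transcript_id)
  de_loci <- em[em$de, ]
  rs <- c()
  for (id in unlinked) {
    y <- unlist(sim$mrna[match(id, sim$mrna$transcript_id),
                         c("mean_18", "mean_23", "mean_28")])
    for (i in seq_len(min(5, nrow(de_loci)))) {
      x <- unlist(de_loci[i, c("mult_18", "mult_23", "mult_28")])
      rs <- c(rs, suppressWarnings(cor(x, y)))
    }
  }
  expect_lt(abs(mean(rs, na.rm = TRUE)), 0.1)
})

test_that("conserved guides enter the reference set and novels do not", {
  sim <- simulate_srna_experiment(tiny_cfg(seed = 37))
  cons <- sim$loci[sim$loci$conserved, ]
  nov <- sim$loci[!sim$loci$conserved, ]
  expect_true(all(cons$guide_seq %in% sim$reference$sequence))
  expect_false(any(nov$guide_seq %in% sim$reference$sequence))
})
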