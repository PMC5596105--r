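#' Simulation configuration for the planted-truth sRNA experiment
#'
#' Bundles every tunable of the synthetic-data generator: a toy genome with
#' planted MIR hairpin loci, 18 small-RNA libraries (2 genotypes x 3
#' developmental stages x 3 epitype-inducing temperatures 18/23/28 degrees C),
#' and a matched mRNA condition-mean table with known anti-correlated
#' miRNA-target links.
#'
#' @param seed Integer seed; every simulated output is deterministic given it.
#' @param genome_length Genome size in nt.
#' @param n_mir_loci Number of planted MIR hairpin loci.
#' @param n_transcripts Number of transcript (gene-model) loci; must be at
#'   least `n_mir_loci` because each hairpin is planted inside a host
#'   transcript.
#' @param n_regulator_transcripts Number of transcripts annotated as
#'   epigenetic regulators (drawn from the eight-category schema).
#' @param library_design Tibble with columns `library`, `genotype`
#'   (`"A2C"`/`"B10W"`), `stage` (1:3) and `temperature` (18/23/28); defaults
#'   to the full 18-library factorial.
#' @param reads_per_library Reads simulated per library.
#' @param length_mixture Named numeric weights over the modal background read
#'   lengths `"21"`, `"22"`, `"24"`, `"31"` plus `"uniform"` (spread evenly
#'   over 15-35 nt). Must sum to 1.
#' @param frac_mirna_reads Fraction of each library drawn from planted
#'   guide/star arms (the rest are background genome fragments).
#' @param isomir_rates Named probabilities for the isomiR modification classes
#'   `substitution`, `trim5`, `trim3`, `ext3_templated`, `tail3_U`, `tail3_A`
#'   (mutually exclusive per read; the remainder is canonical).
#' @param seq_error_rate Per-base sequencing error probability.
#' @param frac_de_mirnas Fraction of planted miRNAs given temperature-dependent
#'   (4-fold) expression profiles.
#' @param frac_conserved Fraction of planted miRNAs flagged conserved and
#'   copied into the emitted reference mature set.
#' @param fold_change Fold difference between high and low expression levels of
#'   a temperature-responsive planted miRNA.
#' @param anticorrelation_strength Pearson correlation (over the three
#'   temperature condition means) constructed between a planted miRNA and its
#'   linked target transcript.
#' @return A `sim_config` list, validated.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, genome_length = 30000, n_mir_loci = 6,
#'                   n_transcripts = 30, reads_per_library = 2000)
#' cfg$n_mir_loci
sim_config <- function(seed = 1L,
                       genome_length = 200000L,
                       n_mir_loci = 40L,
                       n_transcripts = 300L,
                       n_regulator_transcripts = 60L,
                       library_design = default_library_design(),
                       reads_per_library = 100000L,
                       length_mixture = c("21" = 0.14, "22" = 0.11,
                                          "24" = 0.28, "31" = 0.07,
                                          uniform = 0.40),
                       frac_mirna_reads = 0.6,
                       isomir_rates = c(substitution = 0.03, trim5 = 0.04,
                                        trim3 = 0.07, ext3_templated = 0.05,
                                        tail3_U = 0.04, tail3_A = 0.02),
                       seq_error_rate = 0.002,
                       frac_de_mirnas = 0.6,
                       frac_conserved = 0.5,
                       fold_change = 4,
                       anticorrelation_strength = -0.9) {
  cfg <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
              n_mir_loci = as.integer(n_mir_loci),
              n_transcripts = as.integer(n_transcripts),
              n_regulator_transcripts = as.integer(n_regulator_transcripts),
              library_design = as_tibble(library_design),
              reads_per_library = as.integer(reads_per_library),
              length_mixture = length_mixture,
              frac_mirna_reads = frac_mirna_reads,
              isomir_rates = isomir_rates,
              seq_error_rate = seq_error_rate,
              frac_de_mirnas = frac_de_mirnas,
              frac_conserved = frac_conserved,
              fold_change = fold_change,
              anticorrelation_strength = anticorrelation_strength)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Default 18-library factorial design
#'
#' Two genotypes x three maturation stages x three epitype-inducing
#' temperatures (18, 23, 28 degrees C).
#'
#' @return Tibble with columns `library`, `genotype`, `stage`, `temperature`.
#' @export
default_library_design <- function() {
  d <- expand.grid(genotype = c("A2C", "B10W"), stage = 1:3,
                   temperature = c(18L, 23L, 28L),
                   stringsAsFactors = FALSE)
  d <- d[order(d$temperature, d$genotype, d$stage), ]
  tibble(library = sprintf("%s_S%d_T%d", d$genotype, d$stage, d$temperature),
         genotype = d$genotype, stage = d$stage, temperature = d$temperature)
}

validate_sim_config <- function(cfg) {
  assert_that(length(cfg$seed) == 1 && !is.na(cfg$seed), "seed must be a single integer")
  for (fld in c("genome_length", "n_mir_loci", "n_transcripts",
                "n_regulator_transcripts", "reads_per_library")) {
    assert_that(cfg[[fld]] >= 0, paste0(fld, " must be non-negative"))
  }
  assert_that(cfg$n_mir_loci == 0 || cfg$n_transcripts >= cfg$n_mir_loci,
              "n_transcripts must be >= n_mir_loci (hairpins are planted inside transcripts)")
  assert_that(cfg$n_regulator_transcripts <= cfg$n_transcripts,
              "n_regulator_transcripts must be <= n_transcripts")
  ld <- cfg$library_design
  assert_that(all(c("library", "genotype", "stage", "temperature") %in% names(ld)),
              "library_design needs columns library, genotype, stage, temperature")
  assert_that(all(ld$temperature %in% c(18L, 23L, 28L)),
              "temperatures must be drawn from {18, 23, 28}")
  assert_that(!anyDuplicated(ld$library), "library ids must be unique")
  lm <- cfg$length_mixture
  assert_that(setequal(names(lm), c("21", "22", "24", "31", "uniform")),
              "length_mixture needs weights for 21, 22, 24, 31 and uniform")
  assert_that(abs(sum(lm) - 1) < 1e-8, "length_mixture weights must sum to 1")
  assert_that(all(lm >= 0), "length_mixture weights must be non-negative")
  assert_that(all(cfg$isomir_rates >= 0) && sum(cfg$isomir_rates) <= 1,
              "isomir_rates must be non-negative and sum to at most 1")
  assert_that(cfg$seq_error_rate >= 0 && cfg$seq_error_rate < 1,
              "seq_error_rate must be in [0, 1)")
  assert_that(cfg$frac_mirna_reads >= 0 && cfg$frac_mirna_reads <= 1,
              "frac_mirna_reads must be in [0, 1]")
  assert_that(cfg$frac_de_mirnas >= 0 && cfg$frac_de_mirnas <= 1,
              "frac_de_mirnas must be in [0, 1]")
  assert_that(cfg$anticorrelation_strength >= -1 && cfg$anticorrelation_strength <= 0,
              "anticorrelation_strength must be in [-1, 0]")
  assert_that(cfg$fold_change >= 1, "fold_change must be >= 1")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genome %d nt, %d MIR loci, %d transcripts (%d regulators)\n",
              x$genome_length, x$n_mir_loci, x$n_transcripts,
              x$n_regulator_transcripts))
  cat(sprintf("  %d libraries x %d reads, miRNA fraction %.2f, seq error %.4f\n",
              nrow(x$library_design), x$reads_per_library, x$frac_mirna_reads,
              x$seq_error_rate))
  cat(sprintf("  %.0f%% DE miRNAs at %.1f-fold, planted target r = %.2f, seed %d\n",
              100 * x$frac_de_mirnas, x$fold_change, x$anticorrelation_strength,
              x$seed))
  invisible(x)
}
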