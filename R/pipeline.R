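#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Run the full discovery-to-integration pipeline on a simulated experiment
#'
#' Chains every stage: read collapsing and filtering (19-27 nt, singleton
#' removal), conserved annotation against the emitted reference, novel miRNA
#' discovery (mapping, stack calling at `min_locus_reads`, folding, duplex
#' validation, guide/star assignment), RPKM quantification and expressed-set
#' filtering, pairwise temperature DE with Kal's Z-test, profile clustering,
#' target scanning at `cutoff`, and anti-correlation pair refinement at
#' `corr_threshold` with regulator classification.
#'
#' Every distinct surviving tag that matches the reference is a conserved
#' miRNA (isomiRs included, named `Pab-{family}.{serial}`); novel miRNAs are
#' deduplicated discovery guides named `Pab-miRn{serial}_{arm}`.
#'
#' @param cfg A [sim_config()] (used to simulate when `sim` is `NULL`).
#' @param sim Optional pre-built `sporomir_sim`.
#' @param min_locus_reads,cutoff,corr_threshold,min_mean Stage thresholds.
#' @param verbose Print stage progress.
#' @return A `sporomir_run` list with all intermediate tables, summary
#'   tables, the stage-count report, and `truth_recovery` metrics (see
#'   [evaluate_truth_recovery()]).
#' @export
run_pipeline <- function(cfg = sim_config(), sim = NULL,
                         min_locus_reads = 100, cutoff = 3.0,
                         corr_threshold = -0.6, min_mean = 10,
                         verbose = TRUE) {
  say <- function(...) if (verbose) inform(paste0("[sporomir] ", ...))
  if (is.null(sim)) {
    say("simulating experiment (seed ", cfg$seed, ")")
    sim <- simulate_srna_experiment(cfg)
  }
  cfg <- sim$cfg
  say("collapsing ", length(sim$reads), " libraries")
  tags0 <- collapse_reads(sim$reads)
  profile <- length_distribution(tags0)
  tags1 <- length_filter(tags0)
  tags <- drop_singletons(tags1)
  report <- c(reads_in = attr(tags0, "reads_in"),
              reads_with_n = attr(tags0, "reads_with_n"),
              reads_length_removed = sum(tags0$total) - sum(tags1$total),
              reads_singleton_removed = sum(tags1$total) - sum(tags$total),
              reads_surviving = sum(tags$total))
  say(nrow(tags), " tags survive filtering")

  conserved_hits <- match_conserved(tags, sim$reference)
  say(nrow(conserved_hits), " tags match the reference mature set")

  loci_seqs <- setNames(sim$transcripts$sequence,
                        sim$transcripts$transcript_id)
  say("discovering novel miRNA loci")
  candidates <- discover_mirnas(tags, loci_seqs,
                                min_locus_reads = min_locus_reads)
  named <- dedupe_and_name(candidates, conserved_hits)
  say(nrow(candidates), " validated candidates; ", nrow(named$novel),
      " novel miRNAs")

  # expression set: every conserved tag is a miRNA; novel guides likewise
  libs <- cfg$library_design$library
  cons_tags <- conserved_hits |>
    arrange(.data$family, .data$ref_id, .data$sequence) |>
    group_by(.data$family) |>
    mutate(mirna_id = sprintf("Pab-%s.%d", .data$family, row_number())) |>
    ungroup() |>
    select("mirna_id", "sequence") |>
    mutate(class = "conserved")
  nov_tags <- tibble(mirna_id = named$novel$mirna_id,
                     sequence = named$novel$sequence, class = "novel")
  mirnas <- bind_rows(cons_tags, nov_tags) |>
    distinct(.data$sequence, .keep_all = TRUE)
  counts <- inner_join(mirnas, tags[, c("sequence", libs)], by = "sequence")
  say(nrow(counts), " miRNAs quantified (",
      sum(counts$class == "conserved"), " conserved, ",
      sum(counts$class == "novel"), " novel)")
  lib_sizes <- colSums(as.matrix(tags[, libs, drop = FALSE]))
  es <- quantify_mirnas(counts, cfg$library_design, lib_sizes)
  es <- filter_expressed(es, min_mean = min_mean)
  say(nrow(es$condition_means), " miRNAs expressed (mean count >= ",
      min_mean, " in some condition)")

  de <- de_test(es)
  dems <- call_dems(de)
  clusters <- cluster_profiles(de, es$condition_means, dems)
  say(sum(dems$is_dem), " DEMs")

  dem_tbl <- es$counts[es$counts$mirna_id %in% dems$mirna_id[dems$is_dem],
                       c("mirna_id", "sequence")]
  say("scanning targets for ", nrow(dem_tbl), " DEMs")
  sites <- scan_targets(dem_tbl, loci_seqs, cutoff = cutoff)
  tt <- target_table(sites)

  degs <- call_degs(sim$mrna)
  pairs <- correlate_pairs(tt$pairs, es$condition_means, sim$mrna,
                           dems, degs, threshold = corr_threshold)
  pairs <- classify_regulators(pairs, sim$annotation)
  say(sum(pairs$retained), " retained anti-correlated pairs")

  stage_counts <- c(as.list(report),
                    list(n_tags = nrow(tags),
                         n_conserved_mirnas = sum(counts$class == "conserved"),
                         n_novel_mirnas = sum(counts$class == "novel"),
                         n_candidates = nrow(candidates),
                         n_expressed = nrow(es$condition_means),
                         n_dems = sum(dems$is_dem),
                         n_degs = sum(degs$is_deg)))
  summ <- summarize_pairs(pairs, sim$annotation, stage_counts)
  out <- list(cfg = cfg, sim = sim, tags = tags, profile = profile,
              conserved_hits = conserved_hits, candidates = candidates,
              novel = named$novel,
              conserved_candidates = named$conserved_candidates,
              expression = es, de = de, dems = dems, clusters = clusters,
              sites = sites, target_pairs = tt$pairs, pairs = pairs,
              degs = degs, category_table = summ$category_table,
              family_table = summ$family_table, report = summ$report)
  class(out) <- "sporomir_run"
  out$truth_recovery <- evaluate_truth_recovery(out, sim)
  out
}

#' Planted-truth recovery metrics for a pipeline run
#'
#' Compares a `sporomir_run` against the simulation's answer key: guide
#' recovery (planted guide found as a validated candidate with the correct
#' arm), star recovery among recovered candidates, DEM sensitivity over
#' planted temperature-responsive miRNAs, retained-pair recovery over
#' planted regulator links (with the correct category), and the spurious
#' candidate rate.
#'
#' @param run A `sporomir_run`.
#' @param sim The `sporomir_sim` it was run on.
#' @return Named list of rates (0-1) and supporting counts.
#' @export
evaluate_truth_recovery <- function(run, sim) {
  loci <- sim$loci
  cand <- run$candidates
  rec <- map_int(seq_len(nrow(loci)), function(i) {
    hit <- cand$guide_seq == loci$guide_seq[i] &
      cand$guide_arm == loci$guide_arm[i]
    as.integer(any(hit))
  })
  star_ok <- map_int(which(rec == 1L), function(i) {
    hit <- cand[cand$guide_seq == loci$guide_seq[i], , drop = FALSE]
    as.integer(any(hit$star_seq == loci$star_seq[i]))
  })
  # DEM sensitivity over planted temperature-responsive guides
  em <- sim$expression_model
  de_loci <- loci[em$de[match(loci$locus_id, em$locus_id)], , drop = FALSE]
  dem_ids <- run$dems$mirna_id[run$dems$is_dem]
  dem_seqs <- run$expression$counts$sequence[
    run$expression$counts$mirna_id %in% dem_ids]
  dem_hit <- de_loci$guide_seq %in% dem_seqs
  # planted regulator links recovered as retained, correctly categorised pairs
  links <- sim$target_links
  reg_links <- links[!is.na(links$category), , drop = FALSE]
  pr <- run$pairs[run$pairs$retained, , drop = FALSE]
  pr_seq <- run$expression$counts$sequence[
    match(pr$mirna_id, run$expression$counts$mirna_id)]
  link_hit <- map_int(seq_len(nrow(reg_links)), function(i) {
    ok <- pr_seq == reg_links$guide_seq[i] &
      pr$transcript_id == reg_links$transcript_id[i] &
      !is.na(pr$category) & pr$category == reg_links$category[i]
    as.integer(any(ok))
  })
  spurious <- !(cand$locus_id %in% loci$transcript_id & cand$strand == "+")
  list(guide_recovery = mean(rec),
       n_loci = nrow(loci), n_guides_recovered = sum(rec),
       star_recovery = if (length(star_ok)) mean(star_ok) else NA_real_,
       dem_recovery = if (nrow(de_loci)) mean(dem_hit) else NA_real_,
       n_de_planted = nrow(de_loci), n_dem_recovered = sum(dem_hit),
       pair_recovery = if (nrow(reg_links)) mean(link_hit) else NA_real_,
       n_regulator_links = nrow(reg_links),
       n_pairs_recovered = sum(link_hit),
       spurious_candidates = sum(spurious),
       spurious_rate = if (nrow(cand)) mean(spurious) else 0)
}

#' @export
print.sporomir_run <- function(x, ...) {
  r <- x$report
  cat("<sporomir_run>\n")
  cat(sprintf("  reads in %s -> surviving %s; %d tags\n",
              format(r$reads_in, big.mark = ","),
              format(r$reads_surviving, big.mark = ","), r$n_tags))
  cat(sprintf("  miRNAs: %d conserved + %d novel; %d expressed; %d DEMs\n",
              r$n_conserved_mirnas, r$n_novel_mirnas, r$n_expressed,
              r$n_dems))
  cat(sprintf("  pairs: %d tested, %d retained (r < threshold)\n",
              r$n_pairs_tested, r$n_pairs_retained))
  tr <- x$truth_recovery
  if (!is.null(tr)) {
    cat(sprintf("  truth: guide %.0f%%, DEM %.0f%%, pair %.0f%% recovery\n",
                100 * tr$guide_recovery, 100 * tr$dem_recovery,
                100 * tr$pair_recovery))
  }
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `sporomir_run`.
#' @param ... Unused.
#' @export
glance.sporomir_run <- function(x, ...) {
  r <- x$report
  as_tibble(r[c("reads_in", "reads_surviving", "n_tags",
                "n_conserved_mirnas", "n_novel_mirnas", "n_candidates",
                "n_expressed", "n_dems", "n_degs", "n_pairs_tested",
                "n_pairs_retained")])
}

#' @rdname run_pipeline
#' @export
tidy.sporomir_run <- function(x, ...) {
  x$pairs |>
    filter(.data$retained) |>
    select("mirna_id", "transcript_id", "E", "mode", "r", "category") |>
    arrange(.data$r)
}
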