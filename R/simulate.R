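MIR_FAMILY_POOL <- c("miR156", "miR159", "miR166", "miR171", "miR319", "miR390",
                     "miR396", "miR397", "miR482", "miR946", "miR950", "miR951",
                     "miR1311", "miR1312", "miR1316", "miR3701", "miR3710",
                     "miR3712")

DOMAIN_FAMILY_POOL <- c("LRR", "Protein kinase", "NB-ARC", "PPR", "TIR", "AAA",
                        "TPR", "Clathrin/VPS", "Multicopper oxidase", "Myb-like",
                        "AP2", "F-box", "SET domain", "SNF2", "WD40", "unknown")

#' Generate a toy genome with non-overlapping transcript loci
#'
#' Draws a uniform-random genome and places `n_transcripts` non-overlapping
#' gene-model loci on the forward strand. The first `n_mir_loci` transcripts
#' are sized to host a planted hairpin at least 300 nt from either edge.
#'
#' @param cfg A [sim_config()].
#' @return A list (class `sporomir_genome`) with `genome` (character scalar),
#'   `transcripts` (tibble: `transcript_id`, `start`, `end`, `length`,
#'   `strand`, `is_mir_host`; coordinates 0-based half-open) and the `cfg`.
#' @export
generate_genome <- function(cfg) {
  validate_sim_config(cfg)
  withr::with_seed(derive_seed(cfg$seed, 1L), {
    genome <- random_dna(cfg$genome_length)
    n <- cfg$n_transcripts
    if (n == 0) {
      tx <- tibble(transcript_id = character(), start = integer(),
                   end = integer(), length = integer(), strand = character(),
                   is_mir_host = logical())
      out <- list(genome = genome, transcripts = tx, cfg = cfg)
      class(out) <- "sporomir_genome"
      return(out)
    }
    n_host <- cfg$n_mir_loci
    lens <- c(if (n_host > 0) sample(750:900, n_host, replace = TRUE),
              if (n > n_host) sample(300:600, n - n_host, replace = TRUE))
    is_host <- c(rep(TRUE, n_host), rep(FALSE, n - n_host))
    slack <- cfg$genome_length - sum(lens)
    if (slack < n + 1) {
      abort(sprintf(paste0("genome too short: %d transcripts need %d nt plus ",
                           "spacing but genome_length is %d (short by %d nt)"),
                    n, sum(lens), cfg$genome_length,
                    sum(lens) + n + 1 - cfg$genome_length))
    }
    # shuffle genomic order, then distribute the slack as random gaps
    ord <- sample.int(n)
    lens <- lens[ord]; is_host <- is_host[ord]
    gaps <- as.vector(rmultinom(1, slack - (n + 1), rep(1 / (n + 1), n + 1))) + 1L
    starts <- if (n == 1) gaps[1] else
      cumsum(c(gaps[1], lens[-n] + gaps[2:n]))
    tx <- tibble(transcript_id = sprintf("tx%04d", seq_len(n)),
                 start = as.integer(starts), end = as.integer(starts + lens),
                 length = as.integer(lens), strand = "+", is_mir_host = is_host)
    out <- list(genome = genome, transcripts = tx, cfg = cfg)
    class(out) <- "sporomir_genome"
    out
  })
}

# substitute the 3'-arm base opposite a designed mismatch so it cannot pair
# (neither Watson-Crick nor G:U) with the guide base
non_pairing_base <- function(b) {
  partners <- list(A = "T", C = "G", G = c("C", "T"), T = c("A", "G"))
  sample(setdiff(DNA_BASES, partners[[b]]), 1)
}

#' Plant MIR hairpin loci into host transcripts
#'
#' Each hairpin is mature arm + loop + near-reverse-complement arm with 0-3
#' designed mismatches, overwritten into the host transcript at least 300 nt
#' from its edges. A configured fraction of guides is flagged conserved and
#' will be emitted in the reference mature set.
#'
#' @param sim A `sporomir_genome` from [generate_genome()].
#' @param cfg A [sim_config()]; defaults to the one stored in `sim`.
#' @return `sim` with the genome rewritten and a `loci` tibble added: one row
#'   per planted locus with arm sequences, genomic coordinates (0-based
#'   half-open), designated guide arm, family label and conserved flag.
#' @export
plant_mir_loci <- function(sim, cfg = sim$cfg) {
  withr::with_seed(derive_seed(cfg$seed, 2L), {
    hosts <- sim$transcripts[sim$transcripts$is_mir_host, ]
    n <- cfg$n_mir_loci
    assert_that(nrow(hosts) == n, "host transcript count mismatch")
    if (n == 0) {
      sim$loci <- tibble(
        locus_id = character(), transcript_id = character(),
        genome_start = integer(), genome_end = integer(),
        tx_offset = integer(), arm5p = character(), arm3p = character(),
        loop_seq = character(), guide_arm = character(),
        guide_seq = character(), star_seq = character(),
        n_designed_mismatches = integer(), family = character(),
        conserved = logical(), arm5p_start = integer(),
        arm3p_start = integer())
      return(sim)
    }
    genome <- sim$genome
    n_cons <- round(cfg$frac_conserved * n)
    conserved <- sample(c(rep(TRUE, n_cons), rep(FALSE, n - n_cons)))
    fam_cons <- rep_len(MIR_FAMILY_POOL, max(n_cons, 1L))
    rows <- vector("list", n)
    i_cons <- 0L; i_nov <- 0L
    for (i in seq_len(n)) {
      m_len <- sample(20:22, 1)
      loop_len <- sample(8:20, 1)
      n_mm <- sample(0:3, 1)
      guide_arm <- sample(c("5p", "3p"), 1)
      guide <- random_dna(m_len)
      opp <- revcomp(guide)
      mm_pos <- if (n_mm > 0) sort(sample(3:(m_len - 2), n_mm)) else integer()
      if (n_mm > 0) {
        och <- strsplit(opp, "")[[1]]
        # opp position j pairs guide position m_len + 1 - j
        for (j in (m_len + 1 - mm_pos)) {
          och[j] <- non_pairing_base(substr(guide, m_len + 1 - j + 0, m_len + 1 - j))
        }
        opp <- paste(och, collapse = "")
      }
      loop_seq <- random_dna(loop_len)
      if (guide_arm == "5p") {
        arm5 <- guide; arm3 <- opp
      } else {
        arm5 <- opp; arm3 <- guide
      }
      hairpin <- paste0(arm5, loop_seq, arm3)
      h_len <- nchar(hairpin)
      host <- hosts[i, ]
      off_max <- host$length - 300L - h_len
      assert_that(off_max >= 300L, "host transcript too short for hairpin placement")
      off <- sample(300:off_max, 1)
      g_start <- host$start + off                     # 0-based genomic
      substr(genome, g_start + 1, g_start + h_len) <- hairpin
      arm5_start <- g_start
      arm3_start <- g_start + nchar(arm5) + loop_len
      if (conserved[i]) {
        i_cons <- i_cons + 1L
        fam <- fam_cons[i_cons]
      } else {
        i_nov <- i_nov + 1L
        fam <- sprintf("novel-fam%02d", i_nov)
      }
      rows[[i]] <- tibble(
        locus_id = sprintf("MIR%03d", i), transcript_id = host$transcript_id,
        genome_start = g_start, genome_end = g_start + h_len,
        tx_offset = off, arm5p = arm5, arm3p = arm3, loop_seq = loop_seq,
        guide_arm = guide_arm, guide_seq = guide, star_seq = opp,
        n_designed_mismatches = n_mm, family = fam, conserved = conserved[i],
        arm5p_start = arm5_start, arm3p_start = arm3_start)
    }
    sim$genome <- genome
    sim$loci <- bind_rows(rows)
    sim
  })
}

# standardized profile orthogonal to x (3 points), unit sample sd, random sign
orth_profile <- function(x) {
  xs <- x - mean(x)
  u <- c(1, 0, -1)
  if (sd(xs) < 1e-12) {
    w <- u
  } else {
    xn <- xs / sqrt(sum(xs^2))
    w <- u - sum(u * xn) * xn
    if (sqrt(sum(w^2)) < 1e-8) w <- c(1, -2, 1) - sum(c(1, -2, 1) * xn) * xn
  }
  w <- w / sd(w)
  w * sample(c(-1, 1), 1)
}

#' Assign expression models, target links and regulator annotations
#'
#' A configured fraction of planted miRNAs receives a temperature-dependent
#' profile (one of the 12 non-flat weak orderings of the three conditions,
#' spanning `fold_change` between low and high); the rest are flat. Each
#' temperature-responsive miRNA gets one planted target site (the reverse
#' complement of its guide, optionally with mismatches outside the seed)
#' overwritten into a distinct non-host transcript; most links point at
#' transcripts annotated with one of the eight epigenetic-regulator
#' categories.
#'
#' @param sim A `sporomir_genome` after [plant_mir_loci()].
#' @param cfg A [sim_config()].
#' @return `sim` extended with `expression_model`, `target_links`,
#'   `annotation` and a genome carrying the planted sites.
#' @export
plant_target_links <- function(sim, cfg = sim$cfg) {
  withr::with_seed(derive_seed(cfg$seed, 3L), {
    loci <- sim$loci
    n <- nrow(loci)
    n_de <- round(cfg$frac_de_mirnas * n)
    de <- sample(c(rep(TRUE, n_de), rep(FALSE, n - n_de)))
    space <- profile_cluster_space()
    fc <- cfg$fold_change
    mult <- matrix(1, nrow = n, ncol = 3,
                   dimnames = list(NULL, c("18", "23", "28")))
    prof <- rep("flat", n)
    for (i in which(de)) {
      row <- space[sample.int(nrow(space), 1), ]
      ranks <- unlist(row[c("rank_18", "rank_23", "rank_28")])
      rmax <- max(ranks)
      mult[i, ] <- fc^((ranks - 1) / (rmax - 1))
      prof[i] <- row$label
    }
    base <- rlnorm(n, meanlog = 0, sdlog = 0.6)
    star_ratio <- runif(n, 5, 20)
    sim$expression_model <- tibble(
      locus_id = loci$locus_id, base_abundance = base,
      star_ratio = star_ratio, de = de, profile = prof,
      mult_18 = mult[, 1], mult_23 = mult[, 2], mult_28 = mult[, 3])

    # regulator annotation over non-host transcripts
    non_host <- sim$transcripts$transcript_id[!sim$transcripts$is_mir_host]
    n_reg <- min(cfg$n_regulator_transcripts, length(non_host))
    reg_tx <- sample(non_host, n_reg)
    cat_w <- c("DNA methylation" = 0.05, "Histone methylation" = 0.20,
               "Histone acetylation" = 0.10,
               "Histone (protein) phosphorylation" = 0.30,
               "Histone ubiquitination (sumoylation)" = 0.10,
               "Chromatin remodeling" = 0.10, "sRNA pathways" = 0.10,
               "Thermosensing" = 0.05)
    sim$annotation <- tibble(
      transcript_id = sim$transcripts$transcript_id,
      domain_family = sample(DOMAIN_FAMILY_POOL,
                             nrow(sim$transcripts), replace = TRUE),
      category = NA_character_)
    sim$annotation$category[match(reg_tx, sim$annotation$transcript_id)] <-
      sample(names(cat_w), n_reg, replace = TRUE, prob = cat_w)

    # one planted target per temperature-responsive miRNA
    genome <- sim$genome
    de_idx <- which(de)
    n_links <- length(de_idx)
    links <- NULL
    if (n_links > 0) {
      n_reg_links <- min(round(0.7 * n_links), length(reg_tx))
      other_tx <- setdiff(non_host, reg_tx)
      assert_that(n_links - n_reg_links <= length(other_tx),
                  "not enough non-host transcripts to place planted target sites")
      pool_reg <- sample(reg_tx, n_reg_links)
      pool_other <- sample(other_tx, n_links - n_reg_links)
      targets <- sample(c(pool_reg, pool_other))
      score_class <- sample(c("strong", "medium"), n_links, replace = TRUE,
                            prob = c(0.7, 0.3))
      rows <- vector("list", n_links)
      for (k in seq_len(n_links)) {
        li <- de_idx[k]
        guide <- loci$guide_seq[li]
        site <- revcomp(guide)
        L <- nchar(site)
        if (score_class[k] == "medium") {
          # 1-2 mismatches outside the seed (site position j pairs miRNA L+1-j)
          n_mm <- sample(1:2, 1)
          mir_pos <- sample(c(1L, 14:L), n_mm)
          site <- substitute_bases(site, L + 1L - mir_pos)
        }
        tx <- sim$transcripts[sim$transcripts$transcript_id == targets[k], ]
        off <- sample(30:(tx$length - 30L - L), 1)
        substr(genome, tx$start + off + 1, tx$start + off + L) <- site
        rows[[k]] <- tibble(locus_id = loci$locus_id[li], guide_seq = guide,
                            transcript_id = targets[k], site_start = off,
                            site_end = off + L, score_class = score_class[k])
      }
      links <- bind_rows(rows)
      links <- left_join(links,
                         select(sim$annotation, "transcript_id", "category"),
                         by = "transcript_id")
    } else {
      links <- tibble(locus_id = character(), guide_seq = character(),
                      transcript_id = character(), site_start = integer(),
                      site_end = integer(), score_class = character(),
                      category = character())
    }
    sim$genome <- genome
    sim$target_links <- links
    sim
  })
}

#' Simulate the matched mRNA condition-mean expression table
#'
#' Linked target transcripts get profiles constructed to have Pearson
#' correlation exactly `anticorrelation_strength` with their miRNA's expected
#' condition means (the residual direction is the orthogonal complement in the
#' centered 3-point space, so the correlation is exact rather than noisy);
#' unlinked transcripts get independent profiles of random amplitude.
#'
#' @param sim A `sporomir_genome` after [plant_target_links()].
#' @param cfg A [sim_config()].
#' @return Tibble `transcript_id`, `mean_18`, `mean_23`, `mean_28`.
#' @export
simulate_mrna_expression <- function(sim, cfg = sim$cfg) {
  withr::with_seed(derive_seed(cfg$seed, 4L), {
    tx_ids <- sim$transcripts$transcript_id
    nt <- length(tx_ids)
    out <- matrix(NA_real_, nrow = nt, ncol = 3)
    em <- sim$expression_model
    rho <- cfg$anticorrelation_strength
    linked <- sim$target_links
    mu <- rlnorm(nt, meanlog = 3, sdlog = 0.5)
    for (i in seq_len(nt)) {
      id <- tx_ids[i]
      k <- match(id, linked$transcript_id)
      if (!is.na(k)) {
        li <- match(linked$locus_id[k], em$locus_id)
        x <- em$base_abundance[li] *
          c(em$mult_18[li], em$mult_23[li], em$mult_28[li])
        xs <- (x - mean(x)) / sd(x)
        w <- orth_profile(x)
        z <- rho * xs + sqrt(max(0, 1 - rho^2)) * w
        out[i, ] <- mu[i] * (1 + 0.5 * z)
      } else {
        z <- rnorm(3)
        z <- (z - mean(z)) / sd(z)
        amp <- runif(1, 0.05, 0.5)
        out[i, ] <- mu[i] * (1 + amp * z)
      }
    }
    tibble(transcript_id = tx_ids, mean_18 = out[, 1], mean_23 = out[, 2],
           mean_28 = out[, 3])
  })
}

# background read-length distribution implied by the mixture config: point
# masses at the modal lengths plus a uniform component over 15-35 nt
length_mixture_pmf <- function(length_mixture) {
  lens <- 15:35
  p <- rep(length_mixture[["uniform"]] / length(lens), length(lens))
  names(p) <- lens
  for (m in c("21", "22", "24", "31")) p[m] <- p[m] + length_mixture[[m]]
  p
}

# apply one isomiR modification class to a batch of identical source reads
apply_isomir <- function(seqs, class, downstream) {
  n <- length(seqs)
  if (n == 0) return(character())
  L <- nchar(seqs)
  switch(class,
    canonical = seqs,
    substitution = {
      pos <- sapply(L, function(l) sample.int(l, 1))
      old <- substr(seqs, pos, pos)
      new <- vapply(old, function(b) sample(setdiff(DNA_BASES, b), 1), "")
      substr(seqs, pos, pos) <- new
      seqs
    },
    trim5 = substr(seqs, 1 + sample(1:2, n, replace = TRUE), L),
    trim3 = substr(seqs, 1, L - sample(1:2, n, replace = TRUE)),
    ext3_templated = paste0(seqs, substr(downstream, 1,
                                         sample(1:2, n, replace = TRUE))),
    tail3_U = paste0(seqs, strrep("T", sample(1:2, n, replace = TRUE))),
    tail3_A = paste0(seqs, strrep("A", sample(1:2, n, replace = TRUE))),
    abort(paste("unknown isomiR class", class)))
}

#' Simulate the small-RNA libraries
#'
#' Every read in a library is drawn by one multinomial over the planted
#' guide/star arms (abundance = base x temperature multiplier, star arm at
#' 1/5-1/20 of the guide) and a background class of genome fragments at the
#' configured length mixture. miRNA-derived reads are modified with one
#' isomiR class at the configured rates; per-base sequencing errors are
#' applied to all reads.
#'
#' @param sim A `sporomir_genome` after [plant_target_links()].
#' @param cfg A [sim_config()].
#' @return List with `reads` (named list, one character vector of read
#'   sequences per library, in library-design order) and `truth_counts`
#'   (tibble `library`, `source` = locus arm or `"background"`, `count`;
#'   counts per library sum to `reads_per_library`).
#' @export
simulate_libraries <- function(sim, cfg = sim$cfg) {
  withr::with_seed(derive_seed(cfg$seed, 5L), {
    loci <- sim$loci
    em <- sim$expression_model
    genome <- sim$genome
    n <- nrow(loci)
    # per-arm source table with genomic downstream context for templated tails
    src <- NULL
    if (n > 0) {
      arm_ctx <- function(start, len) {
        substring(genome, start + len + 1, start + len + 4)
      }
      g_is5 <- loci$guide_arm == "5p"
      g_start <- ifelse(g_is5, loci$arm5p_start, loci$arm3p_start)
      s_start <- ifelse(g_is5, loci$arm3p_start, loci$arm5p_start)
      src <- tibble(
        source = c(paste0(loci$locus_id, ":guide"),
                   paste0(loci$locus_id, ":star")),
        seq = c(loci$guide_seq, loci$star_seq),
        downstream = c(arm_ctx(g_start, nchar(loci$guide_seq)),
                       arm_ctx(s_start, nchar(loci$star_seq))),
        weight = c(em$base_abundance, em$base_abundance / em$star_ratio),
        mult_18 = rep(em$mult_18, 2), mult_23 = rep(em$mult_23, 2),
        mult_28 = rep(em$mult_28, 2))
    }
    iso <- cfg$isomir_rates
    iso_p <- c(canonical = 1 - sum(iso), iso)
    len_pmf <- length_mixture_pmf(cfg$length_mixture)
    lens <- as.integer(names(len_pmf))
    ld <- cfg$library_design
    reads <- vector("list", nrow(ld))
    names(reads) <- ld$library
    tc <- vector("list", nrow(ld))
    for (b in seq_len(nrow(ld))) {
      tcol <- paste0("mult_", ld$temperature[b])
      if (!is.null(src) && cfg$frac_mirna_reads > 0 && sum(src$weight) > 0) {
        w <- src$weight * src[[tcol]]
        p <- c(w / sum(w) * cfg$frac_mirna_reads, 1 - cfg$frac_mirna_reads)
      } else {
        p <- 1
      }
      cnt <- as.vector(rmultinom(1, cfg$reads_per_library, p))
      n_src <- length(p) - 1L
      lib_reads <- vector("list", n_src + 1L)
      if (n_src > 0) {
        for (s in seq_len(n_src)) {
          if (cnt[s] == 0) next
          cls_cnt <- as.vector(rmultinom(1, cnt[s], iso_p))
          pieces <- map2(names(iso_p), cls_cnt, function(cl, k) {
            apply_isomir(rep(src$seq[s], k), cl, src$downstream[s])
          })
          lib_reads[[s]] <- unlist(pieces)
        }
      }
      n_bg <- cnt[length(cnt)]
      if (n_bg > 0) {
        bl <- sample(lens, n_bg, replace = TRUE, prob = len_pmf)
        pos <- floor(runif(n_bg) * (cfg$genome_length - bl))
        frag <- substring(genome, pos + 1, pos + bl)
        neg <- runif(n_bg) < 0.5
        frag[neg] <- revcomp(frag[neg])
        lib_reads[[n_src + 1L]] <- frag
      }
      out <- unlist(lib_reads)
      # per-base sequencing errors (one substitution per affected draw)
      if (cfg$seq_error_rate > 0 && length(out) > 0) {
        k <- rbinom(length(out), nchar(out), cfg$seq_error_rate)
        while (any(k > 0)) {
          idx <- which(k > 0)
          pos <- 1 + floor(runif(length(idx)) * nchar(out[idx]))
          old <- substr(out[idx], pos, pos)
          new <- vapply(old, function(b) sample(setdiff(DNA_BASES, b), 1), "")
          substr(out[idx], pos, pos) <- new
          k[idx] <- k[idx] - 1L
        }
      }
      reads[[b]] <- sample(out)
      tc[[b]] <- tibble(library = ld$library[b],
                        source = c(if (n_src > 0) src$source, "background"),
                        count = c(if (n_src > 0) cnt[seq_len(n_src)],
                                  cnt[length(cnt)]))
    }
    list(reads = reads, truth_counts = bind_rows(tc))
  })
}

#' Run the whole synthetic-data generator
#'
#' Chains [generate_genome()], [plant_mir_loci()], [plant_target_links()],
#' [simulate_mrna_expression()] and [simulate_libraries()] and attaches the
#' emitted reference mature set (conserved planted guides only).
#'
#' @param cfg A [sim_config()].
#' @return A `sporomir_sim` list: `genome`, `transcripts` (with sequences),
#'   `loci`, `expression_model`, `target_links`, `annotation`, `mrna`,
#'   `reference` (tibble `id`, `family`, `sequence`), `reads`, `truth_counts`
#'   and `cfg`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 7, genome_length = 40000, n_mir_loci = 4,
#'                   n_transcripts = 30, n_regulator_transcripts = 10,
#'                   reads_per_library = 2000)
#' sim <- simulate_srna_experiment(cfg)
#' nrow(sim$loci)
simulate_srna_experiment <- function(cfg) {
  sim <- generate_genome(cfg)
  sim <- plant_mir_loci(sim, cfg)
  sim <- plant_target_links(sim, cfg)
  sim$mrna <- simulate_mrna_expression(sim, cfg)
  libs <- simulate_libraries(sim, cfg)
  sim$reads <- libs$reads
  sim$truth_counts <- libs$truth_counts
  cons <- sim$loci[sim$loci$conserved, ]
  sim$reference <- tibble(
    id = if (nrow(cons)) sprintf("%s-%s", cons$family, tolower(cons$locus_id))
         else character(),
    family = cons$family, sequence = cons$guide_seq)
  sim$transcripts$sequence <- substring(sim$genome,
                                        sim$transcripts$start + 1,
                                        sim$transcripts$end)
  class(sim) <- c("sporomir_sim", class(sim))
  sim
}
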