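# Independent brute-force oracles used to verify the fast implementations.

pair_weight_r <- function(a, b) {
  if ((a == "G" && b == "C") || (a == "C" && b == "G")) return(3)
  if ((a == "A" && b == "T") || (a == "T" && b == "A")) return(2)
  if ((a == "G" && b == "T") || (a == "T" && b == "G")) return(1)
  0
}

# exhaustive maximum over all nested pairings (min hairpin loop 3);
# recursion: position i unpaired, or i paired with any admissible k
brute_fold_score <- function(seq, min_loop = 3) {
  ch <- strsplit(toupper(seq), "")[[1]]
  rec <- function(i, j) {
    if (i >= j) return(0)
    best <- rec(i + 1, j)
    ks <- i + min_loop + seq_len(max(0, j - i - min_loop))
    for (k in ks) {
      w <- pair_weight_r(ch[i], ch[k])
      if (w > 0) best <- max(best, w + rec(i + 1, k - 1) + rec(k + 1, j))
    }
    best
  }
  rec(1, length(ch))
}

# all-alignment scan of one tag over a reference set; same contract as
# match_conserved but by direct enumeration
brute_match_best <- function(tag, reference, max_sub = 2, max_offset = 4,
                             min_overlap = 17) {
  ref <- reference[order(reference$id), , drop = FALSE]
  Lt <- nchar(tag)
  best <- NULL
  for (r in seq_len(nrow(ref))) {
    rs <- ref$sequence[r]
    Lr <- nchar(rs)
    for (s in -max_offset:max_offset) {
      off5 <- -s
      off3 <- (s + Lt) - Lr
      if (abs(off3) > max_offset) next
      lo <- max(0, -s)
      hi <- min(Lt, Lr - s)
      ov <- hi - lo
      if (ov < min_overlap) next
      tt <- substr(tag, lo + 1, hi)
      rr <- substr(rs, s + lo + 1, s + hi)
      sub <- sum(strsplit(tt, "")[[1]] != strsplit(rr, "")[[1]])
      if (sub > max_sub) next
      cand <- list(ref_id = ref$id[r], n_sub = sub,
                   osum = abs(off5) + abs(off3), off5 = off5, off3 = off3,
                   ref_rank = r, s = s)
      if (is.null(best) ||
          cand$n_sub < best$n_sub ||
          (cand$n_sub == best$n_sub && cand$osum < best$osum) ||
          (cand$n_sub == best$n_sub && cand$osum == best$osum &&
             cand$ref_rank < best$ref_rank) ||
          (cand$n_sub == best$n_sub && cand$osum == best$osum &&
             cand$ref_rank == best$ref_rank && cand$s < best$s)) {
        best <- cand
      }
    }
  }
  best
}

# all-position Hamming scan of a tag over loci, both strands
brute_map <- function(tag, loci, max_mm = 2) {
  out <- NULL
  for (ln in names(loci)) {
    S <- loci[[ln]]
    for (q in c("+", "-")) {
      qs <- if (q == "+") tag else sporomir::revcomp(tag)
      L <- nchar(qs)
      n <- nchar(S)
      if (L > n) next
      qch <- strsplit(qs, "")[[1]]
      for (s in 0:(n - L)) {
        mm <- sum(qch != strsplit(substr(S, s + 1, s + L), "")[[1]])
        if (mm <= max_mm) {
          out <- rbind(out, data.frame(locus_id = ln, start = s, strand = q,
                                       n_mismatches = mm))
        }
      }
    }
  }
  out
}

# minimum expectation score of a miRNA against one site window, enumerating
# every <=1-gap alignment through the R duplex scorer
brute_min_E <- function(mirna, transcript, max_gaps = 1) {
  L <- nchar(mirna)
  n <- nchar(transcript)
  best <- Inf
  for (t in 0:n) {
    for (len in (L - max_gaps):(L + max_gaps)) {
      if (len < 1 || t + len > n) next
      site <- substr(transcript, t + 1, t + len)
      gaps <- list()
      if (len == L) gaps <- list(NULL)
      if (len == L + 1 && max_gaps >= 1) {
        gaps <- lapply(1:(L - 1), function(g) list(kind = "target", after = g))
      }
      if (len == L - 1 && max_gaps >= 1) {
        gaps <- lapply(2:(L - 1), function(g) list(kind = "mirna", at = g))
      }
      for (gp in gaps) {
        E <- sporomir::score_duplex(mirna, site, gp)$E
        best <- min(best, E)
      }
    }
  }
  best
}

# small deterministic sim config for fast tests
tiny_cfg <- function(seed = 11, ...) {
  args <- utils::modifyList(
    list(seed = seed, genome_length = 60000, n_mir_loci = 6,
         n_transcripts = 40, n_regulator_transcripts = 12,
         reads_per_library = 4000),
    list(...))
  do.call(sim_config, args)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# build a clean designed hairpin window: guide + loop + near-revcomp arm,
# embedded in unpairable poly-A flanks so the designed stem dominates
make_hairpin_window <- function(guide, n_mm = 0, loop = "CTCTCTCT",
                                flank = 10) {
  opp <- sporomir::revcomp(guide)
  if (n_mm > 0) {
    m <- nchar(guide)
    pos <- seq(3, m - 2, length.out = n_mm)
    och <- strsplit(opp, "")[[1]]
    gch <- strsplit(guide, "")[[1]]
    partners <- list(A = "T", C = "G", G = c("C", "T"), T = c("A", "G"))
    for (p in round(pos)) {
      j <- m + 1 - p
      och[j] <- setdiff(c("A", "C", "G", "T"),
                        c(partners[[gch[p]]], och[j]))[1]
    }
    opp <- paste(och, collapse = "")
  }
  pad <- strrep("A", flank)
  list(seq = paste0(pad, guide, loop, opp, pad),
       guide_start = flank, guide_end = flank + nchar(guide),
       star = opp,
       star_start = flank + nchar(guide) + nchar(loop),
       star_end = flank + nchar(guide) + nchar(loop) + nchar(opp))
}
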