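#' Map tags to locus (gene-model) sequences
#'
#' Reports every ungapped placement of each tag, on both strands, with at
#' most `max_mm` mismatches (seed-indexed, equivalent to a full Hamming scan
#' of all positions). Multi-mapping tags are down-weighted: a tag with `k`
#' placements contributes `total / k` fractional reads to each.
#'
#' @param tags Tag tibble from [collapse_reads()] (or character vector; then
#'   all totals are 1).
#' @param loci Named character vector of locus sequences (names = locus ids).
#' @param max_mm Maximum mismatches per placement.
#' @return Tibble `sequence`, `locus_id`, `start` (0-based), `end`
#'   (half-open), `strand`, `n_mismatches`, `total`, `n_placements`,
#'   `frac_count`.
#' @export
map_tags <- function(tags, loci, max_mm = 2) {
  if (is.character(tags)) tags <- tibble(sequence = tags, total = 1L)
  assert_that(!is.null(names(loci)) && !anyDuplicated(names(loci)),
              "loci must be a uniquely named character vector")
  if (nrow(tags) == 0 || length(loci) == 0) {
    return(tibble(sequence = character(), locus_id = character(),
                  start = integer(), end = integer(), strand = character(),
                  n_mismatches = integer(), total = integer(),
                  n_placements = integer(), frac_count = double()))
  }
  m <- map_tags_cpp(tags$sequence, unname(loci), max_mm)
  out <- tibble(sequence = tags$sequence[m$tag_idx],
                locus_id = names(loci)[m$locus_idx],
                start = m$start,
                end = m$start + nchar(tags$sequence[m$tag_idx]),
                strand = m$strand,
                n_mismatches = m$n_mismatches,
                total = tags$total[m$tag_idx])
  out <- out |>
    group_by(.data$sequence) |>
    mutate(n_placements = n()) |>
    ungroup() |>
    mutate(frac_count = .data$total / .data$n_placements)
  out
}

#' Call candidate miRNA gene loci from mapped tag stacks
#'
#' Overlapping placements on one locus strand are merged into stacks; a
#' stack whose fractional read total reaches `min_reads` becomes a candidate
#' locus.
#'
#' @param mappings Mapping tibble from [map_tags()].
#' @param min_reads Minimum (fractional) mapped reads per stack.
#' @return Tibble of accepted stacks: `locus_id`, `strand`, `stack_start`,
#'   `stack_end`, `total_reads`, `n_distinct_tags` and list-column
#'   `placements` (the member placements).
#' @export
call_loci <- function(mappings, min_reads = 100) {
  empty <- tibble(locus_id = character(), strand = character(),
                  stack_start = integer(), stack_end = integer(),
                  total_reads = double(), n_distinct_tags = integer(),
                  placements = list())
  if (nrow(mappings) == 0) return(empty)
  groups <- mappings |>
    group_by(.data$locus_id, .data$strand) |>
    dplyr::group_split()
  rows <- map(groups, function(g) {
    ir <- IRanges::IRanges(start = g$start + 1L, end = g$end)
    red <- IRanges::reduce(ir, with.revmap = TRUE)
    rv <- S4Vectors::mcols(red)$revmap
    map(seq_along(red), function(i) {
      idx <- rv[[i]]
      pl <- g[idx, , drop = FALSE]
      tibble(locus_id = g$locus_id[1], strand = g$strand[1],
             stack_start = as.integer(IRanges::start(red)[i] - 1L),
             stack_end = as.integer(IRanges::end(red)[i]),
             total_reads = sum(pl$frac_count),
             n_distinct_tags = length(unique(pl$sequence)),
             placements = list(pl))
    }) |> bind_rows()
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) return(empty)
  out <- out[out$total_reads >= min_reads, , drop = FALSE]
  arrange(out, .data$locus_id, .data$strand, .data$stack_start)
}

#' Extract a folding window around a candidate tag
#'
#' Window = `flank` nt on each side of the tag, truncated (and flagged) at
#' the locus bounds.
#'
#' @param locus_seq Locus sequence (character scalar).
#' @param tag_start,tag_end Tag coordinates on the locus (0-based half-open).
#' @param flank Flank width (nt) per side.
#' @return List `start`, `end` (window on the locus, 0-based half-open),
#'   `seq`, `truncated`.
#' @export
extract_window <- function(locus_seq, tag_start, tag_end, flank) {
  n <- nchar(locus_seq)
  ws <- tag_start - flank
  we <- tag_end + flank
  truncated <- ws < 0 || we > n
  ws <- max(0L, ws)
  we <- min(n, we)
  list(start = as.integer(ws), end = as.integer(we),
       seq = substr(locus_seq, ws + 1, we), truncated = truncated)
}

# flank growth schedule: flank_min..flank_max in `step` nt increments, then
# coarser steps until the window reaches extended_max nt
window_schedule <- function(tag_len, flank_min = 80, flank_max = 300,
                            extended_max = 1000, step = 20) {
  fl <- seq(flank_min, flank_max, by = step)
  flank_cap <- floor((extended_max - tag_len) / 2)
  if (flank_cap > flank_max) {
    fl <- c(fl, seq(flank_max + 50, flank_cap, by = 50))
    if (fl[length(fl)] < flank_cap) fl <- c(fl, flank_cap)
  }
  unique(fl[2 * fl + tag_len <= extended_max])
}

#' Fold a window into its maximum-weight hairpin structure
#'
#' Maximum-weight nested base pairing (weighted Nussinov dynamic programme;
#' pair weights GC = 3, AU = 2, GU = 1, minimum hairpin loop 3 nt) with a
#' deterministic traceback.
#'
#' @param seq Window sequence, 1-1000 nt.
#' @param min_loop Minimum hairpin loop (unpaired nt between a pair).
#' @return A `hairpin`: list with `seq`, `structure` (dot-bracket), `score`,
#'   `pairs` (two-column 1-based matrix) and `partner` (integer vector,
#'   `NA` = unpaired).
#' @export
#' @examples
#' fold_hairpin("GGGAAACCC")$structure
fold_hairpin <- function(seq, min_loop = 3) {
  assert_that(nchar(seq) <= 1000, "fold window must be at most 1000 nt")
  r <- nussinov_fold_cpp(toupper(seq), as.integer(min_loop))
  partner <- rep(NA_integer_, nchar(seq))
  if (nrow(r$pairs) > 0) {
    partner[r$pairs[, 1]] <- r$pairs[, 2]
    partner[r$pairs[, 2]] <- r$pairs[, 1]
  }
  out <- list(seq = toupper(seq), structure = r$structure, score = r$score,
              pairs = r$pairs, partner = partner)
  class(out) <- "hairpin"
  out
}

#' @export
print.hairpin <- function(x, ...) {
  cat("<hairpin>", nchar(x$seq), "nt, score", x$score, "\n")
  cat(x$seq, "\n", x$structure, "\n", sep = "")
  invisible(x)
}

#' Validate the miRNA/miRNA* duplex of a guide on a folded window
#'
#' The guide must pair into a single stem arm: at least `min_paired` of its
#' positions paired to the dominant opposite arm, at most `max_unpaired`
#' positions not part of that duplex (unpaired, or stray pairings away from
#' the duplex arm, at most 2 of which are tolerated), at most `max_bulged`
#' asymmetric-bulge nucleotides (interior unpaired guide bases in excess of
#' the opposite strand's gap; symmetric internal loops such as simple
#' mismatches do not count as bulges), and it must not span a terminal loop
#' (no base pair with both ends inside the guide).
#'
#' @param hairpin A `hairpin` from [fold_hairpin()].
#' @param guide_start,guide_end Guide coordinates on the window (0-based
#'   half-open).
#' @param max_unpaired,max_bulged,min_paired Duplex limits.
#' @return List `pass`, `reason`, `n_paired`, `n_unpaired`, `n_bulged`,
#'   `arm` (`"5p"`/`"3p"`), `star_span` (0-based half-open span of the
#'   duplex partners, before the 2-nt overhang shift) or `NULL`s on failure.
#' @export
validate_duplex <- function(hairpin, guide_start, guide_end,
                            max_unpaired = 5, max_bulged = 3,
                            min_paired = 14) {
  n <- nchar(hairpin$seq)
  assert_that(guide_start >= 0 && guide_end <= n && guide_start < guide_end,
              "guide must lie within the window")
  idx <- (guide_start + 1):guide_end           # 1-based guide positions
  p <- hairpin$partner[idx]
  inside <- !is.na(p) & p >= guide_start + 1 & p <= guide_end
  fail <- function(reason) list(pass = FALSE, reason = reason,
                                n_paired = sum(!is.na(p) & !inside),
                                n_unpaired = sum(is.na(p)),
                                n_bulged = NA_integer_, arm = NA_character_,
                                star_span = NULL)
  if (any(inside)) return(fail("spans loop"))
  is_left <- !is.na(p) & p < guide_start + 1
  is_right <- !is.na(p) & p > guide_end
  right <- sum(is_right) >= sum(is_left)
  duplex <- if (right) is_right else is_left
  stray <- sum(is_left) + sum(is_right) - sum(duplex)
  if (stray > 2) return(fail("partners on both sides"))
  n_paired <- sum(duplex)
  n_unpaired <- length(p) - n_paired     # unpaired or stray-paired
  if (n_paired < min_paired) return(fail("too few paired positions"))
  if (n_unpaired > max_unpaired) return(fail("too many unpaired positions"))
  # asymmetric bulges: interior unpaired guide runs in excess of the
  # opposite strand's corresponding gap
  di <- which(duplex)
  bulged <- 0L
  if (length(di) > 1) {
    for (k in seq_len(length(di) - 1)) {
      run_len <- di[k + 1] - di[k] - 1L
      if (run_len > 0) {
        opp_gap <- abs(p[di[k]] - p[di[k + 1]]) - 1L
        bulged <- bulged + max(0L, run_len - opp_gap)
      }
    }
  }
  if (bulged > max_bulged) return(fail("too many bulged nucleotides"))
  partners <- p[duplex]
  arm <- if (right) "5p" else "3p"
  list(pass = TRUE, reason = "ok", n_paired = n_paired,
       n_unpaired = n_unpaired, n_bulged = bulged, arm = arm,
       star_span = c(min(partners) - 1L, max(partners)))
}

# theoretical star span with the canonical 2-nt 3' overhangs: partners of the
# guide shifted rigidly +2 (guide on 5' arm) or -2 (guide on 3' arm)
expected_star_span <- function(validation) {
  sh <- if (validation$arm == "5p") 2L else -2L
  validation$star_span + sh
}

#' Assign guide and star strands on a validated hairpin
#'
#' The guide is the highest-count stack tag (given); the star is the
#' highest-count tag on the opposite arm whose placement lies within
#' `star_shift` nt (rigid displacement, max of the two end offsets) of the
#' theoretical star span (guide duplex partner with 2-nt 3' overhangs). When
#' no mapped tag qualifies, the theoretical star sequence is emitted with
#' count 0.
#'
#' @param placements Tibble of window-coordinate placements (`sequence`,
#'   `wstart`, `wend`, `total`): the stack members inside the window.
#' @param hairpin A `hairpin` from [fold_hairpin()].
#' @param validation Result of [validate_duplex()] (must pass).
#' @param guide_start,guide_end Guide window coordinates (0-based half-open).
#' @param star_shift Maximum displacement (nt) from the theoretical star.
#' @return List `star_seq`, `star_count`, `star_start`, `star_end`,
#'   `star_shift_used`.
#' @export
assign_guide_star <- function(placements, hairpin, validation,
                              guide_start, guide_end, star_shift = 6) {
  assert_that(isTRUE(validation$pass), "duplex must be validated")
  span <- expected_star_span(validation)
  exp_s <- max(0L, span[1])
  exp_e <- min(nchar(hairpin$seq), span[2])
  cand <- placements[placements$wstart >= 0 &
                       placements$wend <= nchar(hairpin$seq), , drop = FALSE]
  if (nrow(cand) > 0) {
    d <- pmax(abs(cand$wstart - exp_s), abs(cand$wend - exp_e))
    # must sit on the opposite arm, not overlap the guide
    opp <- cand$wend <= guide_start | cand$wstart >= guide_end
    cand <- cand[opp & d <= star_shift, , drop = FALSE]
  }
  if (nrow(cand) > 0) {
    ord <- order(-cand$total, -nchar(cand$sequence), cand$sequence)
    best <- cand[ord[1], ]
    d_best <- max(abs(best$wstart - exp_s), abs(best$wend - exp_e))
    list(star_seq = best$sequence, star_count = best$total,
         star_start = best$wstart, star_end = best$wend,
         star_shift_used = as.integer(d_best))
  } else {
    list(star_seq = substr(hairpin$seq, exp_s + 1, exp_e), star_count = 0,
         star_start = exp_s, star_end = exp_e, star_shift_used = NA_integer_)
  }
}

#' Discover miRNA candidates from tags and locus sequences
#'
#' The full discovery chain: map tags to gene models, call read stacks with
#' at least `min_locus_reads` fractional reads, grow a folding window around
#' the modal tag (from `flank_min` to `flank_max` nt per side in `step` nt
#' increments, then coarser up to a `extended_max` nt window), fold it,
#' validate the miRNA/miRNA* duplex and assign guide and star.
#'
#' @param tags Tag tibble from [collapse_reads()].
#' @param loci Named character vector of locus sequences.
#' @param min_locus_reads Stack read threshold.
#' @param flank_min,flank_max,extended_max,step Window growth schedule (nt).
#' @param star_shift Maximum star displacement (nt).
#' @param max_mm Maximum mapping mismatches.
#' @param max_unpaired,max_bulged,min_paired Duplex limits
#'   (see [validate_duplex()]).
#' @return Tibble of validated candidates, one row per accepted stack:
#'   locus, strand, window and stack coordinates (stack-strand 0-based
#'   half-open window given by `window_start`/`window_end` on the forward
#'   locus), guide/star sequences, counts, arm labels, duplex stats,
#'   precursor sequence and dot-bracket structure.
#' @export
discover_mirnas <- function(tags, loci, min_locus_reads = 100,
                            flank_min = 80, flank_max = 300,
                            extended_max = 1000, step = 20, star_shift = 6,
                            max_mm = 2, max_unpaired = 5, max_bulged = 3,
                            min_paired = 14) {
  mappings <- map_tags(tags, loci, max_mm)
  stacks <- call_loci(mappings, min_locus_reads)
  map_groups <- split(mappings, paste(mappings$locus_id, mappings$strand))
  empty <- tibble(locus_id = character(), strand = character(),
                  stack_start = integer(), stack_end = integer(),
                  total_reads = double(), n_distinct_tags = integer(),
                  window_start = integer(), window_end = integer(),
                  flank = integer(), truncated = logical(),
                  guide_seq = character(), guide_arm = character(),
                  guide_count = integer(), star_seq = character(),
                  star_count = double(), star_shift_used = integer(),
                  n_paired = integer(), n_unpaired = integer(),
                  n_bulged = integer(), precursor_seq = character(),
                  structure = character(), score = integer())
  if (nrow(stacks) == 0) return(empty)
  rows <- vector("list", nrow(stacks))
  for (i in seq_len(nrow(stacks))) {
    st <- stacks[i, ]
    lseq <- loci[[st$locus_id]]
    Ln <- nchar(lseq)
    pl <- st$placements[[1]]
    # all placements on this locus strand (star tags sit outside the stack)
    pl_all <- map_groups[[paste(st$locus_id, st$strand)]]
    if (st$strand == "-") {
      sseq <- revcomp(lseq)
      new_start <- Ln - pl$end
      pl$end <- Ln - pl$start
      pl$start <- new_start
      new_start_all <- Ln - pl_all$end
      pl_all$end <- Ln - pl_all$start
      pl_all$start <- new_start_all
    } else {
      sseq <- lseq
    }
    # modal tag: highest pooled count, ties to the longer then smaller sequence
    ord <- order(-pl$total, -nchar(pl$sequence), pl$sequence)
    modal <- pl[ord[1], ]
    sched <- window_schedule(nchar(modal$sequence), flank_min, flank_max,
                             extended_max, step)
    found <- NULL
    for (fl in sched) {
      w <- extract_window(sseq, modal$start, modal$end, fl)
      hp <- fold_hairpin(w$seq)
      gs <- modal$start - w$start
      ge <- modal$end - w$start
      v <- validate_duplex(hp, gs, ge, max_unpaired, max_bulged, min_paired)
      if (!v$pass) next
      wp <- tibble(sequence = pl_all$sequence,
                   wstart = pl_all$start - w$start,
                   wend = pl_all$end - w$start,
                   total = pl_all$total)
      star <- assign_guide_star(wp, hp, v, gs, ge, star_shift)
      ws_fwd <- if (st$strand == "-") Ln - w$end else w$start
      we_fwd <- if (st$strand == "-") Ln - w$start else w$end
      found <- tibble(
        locus_id = st$locus_id, strand = st$strand,
        stack_start = st$stack_start, stack_end = st$stack_end,
        total_reads = st$total_reads, n_distinct_tags = st$n_distinct_tags,
        window_start = as.integer(ws_fwd), window_end = as.integer(we_fwd),
        flank = as.integer(fl), truncated = w$truncated,
        guide_seq = modal$sequence, guide_arm = v$arm,
        guide_count = as.integer(modal$total),
        star_seq = star$star_seq, star_count = as.double(star$star_count),
        star_shift_used = star$star_shift_used,
        n_paired = as.integer(v$n_paired),
        n_unpaired = as.integer(v$n_unpaired),
        n_bulged = as.integer(v$n_bulged),
        precursor_seq = w$seq, structure = hp$structure,
        score = as.integer(hp$score))
      break
    }
    rows[[i]] <- found
  }
  out <- bind_rows(rows[!vapply(rows, is.null, TRUE)])
  if (nrow(out) == 0) empty else out
}

#' Partition candidates into conserved and novel sets and name the novels
#'
#' Candidates whose guide has a conserved hit are routed to the conserved
#' set (precursor attached); the remaining guides become novel miRNAs named
#' `Pab-miRn{serial}_{arm}`, with identical guide sequences from multiple
#' precursors collapsed into one miRNA carrying a precursor list.
#'
#' @param candidates Candidate tibble from [discover_mirnas()].
#' @param conserved_hits Hit tibble from [match_conserved()].
#' @return List with `novel` (tibble `mirna_id`, `sequence`, `arm`,
#'   `guide_count`, `n_precursors`, list-column `precursors`) and
#'   `conserved_candidates` (candidate rows routed conserved, with `ref_id`
#'   and `family`).
#' @export
dedupe_and_name <- function(candidates, conserved_hits) {
  is_cons <- candidates$guide_seq %in% conserved_hits$sequence
  cons <- candidates[is_cons, , drop = FALSE]
  if (nrow(cons) > 0) {
    cons <- left_join(cons,
                      distinct(conserved_hits, .data$sequence, .data$ref_id,
                               .data$family),
                      by = c(guide_seq = "sequence"))
  } else {
    cons$ref_id <- character()
    cons$family <- character()
  }
  nov <- candidates[!is_cons, , drop = FALSE]
  if (nrow(nov) == 0) {
    novel <- tibble(mirna_id = character(), sequence = character(),
                    arm = character(), guide_count = integer(),
                    n_precursors = integer(), precursors = list())
  } else {
    novel <- nov |>
      group_by(.data$guide_seq) |>
      summarise(arm = .data$guide_arm[which.max(.data$guide_count)],
                guide_count = max(.data$guide_count),
                n_precursors = n(),
                precursors = list(dplyr::pick("locus_id", "strand",
                                              "window_start", "window_end",
                                              "precursor_seq", "structure")),
                .groups = "drop") |>
      arrange(desc(.data$guide_count), .data$guide_seq) |>
      mutate(mirna_id = sprintf("Pab-miRn%04d_%s", row_number(), .data$arm)) |>
      select("mirna_id", sequence = "guide_seq", "arm", "guide_count",
             "n_precursors", "precursors")
  }
  list(novel = novel, conserved_candidates = cons)
}
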