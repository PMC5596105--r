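#' Score a single miRNA-target duplex alignment
#'
#' Expectation-style additive penalty over the aligned miRNA positions:
#' match 0, G:U wobble 0.5, mismatch 1, gap 2, each doubled when the 1-based
#' miRNA position (from the 5' end) lies in the seed region 2-13.
#'
#' @param mirna miRNA sequence (5'->3', DNA alphabet).
#' @param site Target site sequence in transcript orientation (5'->3').
#' @param gap Optional single gap: `NULL` for an ungapped duplex, or
#'   `list(kind = "target", after = g)` for a bulged target base between
#'   miRNA positions g and g+1, or `list(kind = "mirna", at = g)` for an
#'   unpaired (bulged) miRNA position g.
#' @return List `E`, `n_mismatch`, `n_gu`, `n_gap`, `states` (one symbol per
#'   alignment column: `:` match, `.` G:U, `X` mismatch, `-` miRNA gap,
#'   `^` target bulge), `mode` (`"cleavage"` unless any miRNA position 9-11
#'   is not a Watson-Crick match, then `"translational"`).
#' @export
score_duplex <- function(mirna, site, gap = NULL) {
  L <- nchar(mirna)
  exp_len <- L + if (is.null(gap)) 0L else if (gap$kind == "target") 1L else -1L
  assert_that(nchar(site) == exp_len,
              "site length must match the miRNA length plus/minus the gap")
  m <- strsplit(toupper(mirna), "")[[1]]
  s3 <- rev(strsplit(toupper(site), "")[[1]])  # site indexed from its 3' end
  pen <- function(state, pos1) {
    p <- switch(state, match = 0, gu = 0.5, mismatch = 1, gap = 2)
    if (pos1 >= 2 && pos1 <= 13) p * 2 else p
  }
  pair_state <- function(mb, sb) {
    wc <- (mb == "A" && sb == "T") || (mb == "T" && sb == "A") ||
      (mb == "C" && sb == "G") || (mb == "G" && sb == "C")
    if (wc) return("match")
    if ((mb == "G" && sb == "T") || (mb == "T" && sb == "G")) return("gu")
    "mismatch"
  }
  E <- 0; n_mm <- 0L; n_gu <- 0L; n_gap <- 0L
  states <- character()
  central_bad <- FALSE
  j <- 1L
  for (i in seq_len(L)) {
    if (!is.null(gap) && gap$kind == "mirna" && i == gap$at) {
      E <- E + pen("gap", i); n_gap <- n_gap + 1L
      states <- c(states, "-")
      if (i >= 9 && i <= 11) central_bad <- TRUE
      next
    }
    if (!is.null(gap) && gap$kind == "target" && i == gap$after + 1 && j == i) {
      E <- E + pen("gap", i); n_gap <- n_gap + 1L
      states <- c(states, "^")
      j <- j + 1L
    }
    st <- pair_state(m[i], s3[j])
    E <- E + pen(st, i)
    if (st == "mismatch") n_mm <- n_mm + 1L
    if (st == "gu") n_gu <- n_gu + 1L
    if (st != "match" && i >= 9 && i <= 11) central_bad <- TRUE
    states <- c(states, switch(st, match = ":", gu = ".", mismatch = "X"))
    j <- j + 1L
  }
  list(E = E, n_mismatch = n_mm, n_gu = n_gu, n_gap = n_gap,
       states = paste(states, collapse = ""),
       mode = if (central_bad) "translational" else "cleavage")
}

#' Scan transcripts for miRNA target sites
#'
#' Every transcript window whose reverse-complement alignment to the miRNA
#' (allowing at most `max_gaps` gaps, 0 or 1) has expectation E <= `cutoff`
#' is reported; overlapping sites of the same miRNA-transcript pair are
#' resolved to the minimum-E site (ties: leftmost).
#'
#' @param mirnas Tibble with `mirna_id`, `sequence`, or a named character
#'   vector.
#' @param transcripts Named character vector of transcript sequences, or a
#'   tibble with `transcript_id`, `sequence`.
#' @param cutoff Maximum expectation score.
#' @param max_gaps Maximum gaps in the duplex (0 or 1).
#' @param dedupe_overlaps Collapse overlapping same-pair sites (default).
#' @return Tibble `mirna_id`, `transcript_id`, `start`, `end` (0-based
#'   half-open on the transcript), `E`, `n_mismatch`, `n_gu`, `n_gap`,
#'   `mode`, `states`.
#' @export
scan_targets <- function(mirnas, transcripts, cutoff = 3.0, max_gaps = 1,
                         dedupe_overlaps = TRUE) {
  assert_that(max_gaps %in% c(0L, 1L), "max_gaps must be 0 or 1")
  if (!is.data.frame(mirnas)) {
    mirnas <- tibble(mirna_id = names(mirnas), sequence = unname(mirnas))
  }
  if (is.data.frame(transcripts)) {
    transcripts <- setNames(transcripts$sequence, transcripts$transcript_id)
  }
  assert_that(length(transcripts) > 0, "transcript set must be non-empty")
  empty <- tibble(mirna_id = character(), transcript_id = character(),
                  start = integer(), end = integer(), E = double(),
                  n_mismatch = integer(), n_gu = integer(),
                  n_gap = integer(), mode = character(), states = character())
  if (nrow(mirnas) == 0) return(empty)
  hits <- scan_targets_cpp(mirnas$sequence, unname(transcripts),
                           cutoff, as.integer(max_gaps))
  if (nrow(hits) == 0) return(empty)
  out <- tibble(mirna_id = mirnas$mirna_id[hits$mirna_idx],
                transcript_id = names(transcripts)[hits$transcript_idx],
                start = hits$start, end = hits$end, E = hits$E,
                n_mismatch = hits$n_mismatch, n_gu = hits$n_gu,
                n_gap = hits$n_gap,
                mode = ifelse(hits$translational, "translational", "cleavage"),
                states = hits$states)
  if (dedupe_overlaps && nrow(out) > 1) {
    out <- out |>
      group_by(.data$mirna_id, .data$transcript_id) |>
      dplyr::group_modify(function(g, key) {
        g <- arrange(g, .data$start)
        keep <- rep(TRUE, nrow(g))
        i <- 1
        while (i <= nrow(g)) {
          j <- i
          while (j < nrow(g) && g$start[j + 1] < g$end[i]) j <- j + 1
          block <- i:j
          best <- block[order(g$E[block], g$start[block])][1]
          keep[setdiff(block, best)] <- FALSE
          i <- j + 1
        }
        g[keep, , drop = FALSE]
      }) |>
      ungroup()
  }
  arrange(out, .data$mirna_id, .data$transcript_id, .data$start)
}

#' Build the per-pair target table and census
#'
#' Keeps the best (minimum-E, ties leftmost) site per miRNA-transcript pair
#' and summarises targets per miRNA and miRNAs per target.
#'
#' @param sites Site tibble from [scan_targets()].
#' @return List `pairs` (best site per pair), `targets_per_mirna`
#'   (tibble `mirna_id`, `n_targets`), `mirnas_per_target`
#'   (tibble `transcript_id`, `n_mirnas`).
#' @export
target_table <- function(sites) {
  pairs <- sites |>
    group_by(.data$mirna_id, .data$transcript_id) |>
    arrange(.data$E, .data$start, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
  list(pairs = pairs,
       targets_per_mirna = count(pairs, .data$mirna_id, name = "n_targets"),
       mirnas_per_target = count(pairs, .data$transcript_id,
                                 name = "n_mirnas"))
}
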