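#' Match tags against a reference mature-miRNA set
#'
#' Sliding ungapped alignment of each tag over every reference, with end
#' offsets of up to `max_offset` nt at either end, at least `min_overlap` nt
#' of overlap and at most `max_sub` substitutions inside the overlap (the
#' classic "up to 2 mismatches" homology rule, relaxed at the ends to absorb
#' isomiR length variation). The best hit per tag minimises substitutions,
#' then total end offset, then reference id (lexicographic).
#'
#' @param tags Tag tibble from [collapse_reads()] or a character vector of
#'   tag sequences.
#' @param reference Tibble with `id`, `family`, `sequence` (see
#'   [simulate_srna_experiment()] for the emitted synthetic reference).
#' @param max_sub Maximum substitutions in the overlap.
#' @param max_offset Maximum absolute end offset (nt) at each end.
#' @param min_overlap Minimum aligned overlap (nt).
#' @return Tibble of hits: `sequence`, `ref_id`, `family`, `n_sub`,
#'   `offset_5p`, `offset_3p` (offsets signed, tag end minus reference end;
#'   negative = trimmed, positive = extended). Tags without a hit are absent.
#' @export
match_conserved <- function(tags, reference, max_sub = 2, max_offset = 4,
                            min_overlap = 17) {
  seqs <- if (is.data.frame(tags)) tags$sequence else tags
  if (length(seqs) == 0 || nrow(reference) == 0) {
    return(tibble(sequence = character(), ref_id = character(),
                  family = character(), n_sub = integer(),
                  offset_5p = integer(), offset_3p = integer()))
  }
  assert_that(!anyDuplicated(reference$id), "reference ids must be unique")
  ref <- reference[order(reference$id), , drop = FALSE]
  hits <- match_tags_cpp(seqs, ref$sequence, max_sub, max_offset, min_overlap)
  tibble(sequence = seqs[hits$tag_idx],
         ref_id = ref$id[hits$ref_idx],
         family = ref$family[hits$ref_idx],
         n_sub = hits$n_sub,
         offset_5p = hits$offset_5p,
         offset_3p = hits$offset_3p)
}

#' Classify the isomiR modification of a conserved hit
#'
#' Offsets below zero are trims; offsets above zero are extensions, split
#' into templated (the flanking genomic bases match the added bases) versus
#' nontemplated 3' tails (a uniform added run of `T` is 3' uridylation, of
#' `A` 3' adenylation, anything else `tail3_other`). Internal substitutions
#' add the `substitution` class. A tag equal to its reference over the full
#' length with no offsets is `canonical`.
#'
#' @param hits Hit tibble from [match_conserved()].
#' @param reference Reference tibble (`id`, `sequence`).
#' @param ref_context Optional tibble `ref_id`, `upstream`, `downstream`
#'   giving the genomic bases flanking each reference mature. Without it,
#'   extensions are reported with `detail = "template-unknown"` rather than
#'   erroring.
#' @return `hits` with list-column `isomir_classes` and character `detail`.
#' @export
classify_isomir <- function(hits, reference, ref_context = NULL) {
  if (nrow(hits) == 0) {
    hits$isomir_classes <- list()
    hits$detail <- character()
    return(hits)
  }
  ref_seq <- setNames(reference$sequence, reference$id)
  ctx_down <- ctx_up <- NULL
  if (!is.null(ref_context)) {
    ctx_down <- setNames(ref_context$downstream, ref_context$ref_id)
    ctx_up <- setNames(ref_context$upstream, ref_context$ref_id)
  }
  res <- pmap(list(hits$sequence, hits$ref_id, hits$offset_5p,
                   hits$offset_3p, hits$n_sub),
              function(tag, rid, off5, off3, nsub) {
    classes <- character()
    detail <- character()
    if (off5 < 0) { classes <- c(classes, "trim5")
                    detail <- c(detail, sprintf("5' trimmed %d nt", -off5)) }
    if (off3 < 0) { classes <- c(classes, "trim3")
                    detail <- c(detail, sprintf("3' trimmed %d nt", -off3)) }
    if (nsub > 0) { classes <- c(classes, "substitution")
                    detail <- c(detail, sprintf("%d substitution(s)", nsub)) }
    if (off5 > 0) {
      added <- substr(tag, 1, off5)
      templ <- if (!is.null(ctx_up) && !is.na(ctx_up[rid])) {
        up <- ctx_up[[rid]]
        identical(added, substr(up, nchar(up) - off5 + 1, nchar(up)))
      } else NA
      if (isTRUE(templ)) {
        classes <- c(classes, "ext5_templated")
        detail <- c(detail, sprintf("5' templated extension %s", added))
      } else {
        classes <- c(classes, "ext5")
        detail <- c(detail, if (is.na(templ)) "5' ext, template-unknown"
                            else sprintf("5' nontemplated extension %s", added))
      }
    }
    if (off3 > 0) {
      L <- nchar(tag)
      added <- substr(tag, L - off3 + 1, L)
      templ <- if (!is.null(ctx_down) && !is.na(ctx_down[rid])) {
        identical(added, substr(ctx_down[[rid]], 1, off3))
      } else NA
      if (is.na(templ)) {
        classes <- c(classes, "ext3")
        detail <- c(detail, "3' ext, template-unknown")
      } else if (templ) {
        classes <- c(classes, "ext3_templated")
        detail <- c(detail, sprintf("3' templated extension %s", added))
      } else if (added == strrep("T", off3)) {
        classes <- c(classes, "tail3_U")
        detail <- c(detail, sprintf("3' uridylation (%d nt)", off3))
      } else if (added == strrep("A", off3)) {
        classes <- c(classes, "tail3_A")
        detail <- c(detail, sprintf("3' adenylation (%d nt)", off3))
      } else {
        classes <- c(classes, "tail3_other")
        detail <- c(detail, sprintf("3' nontemplated tail %s", added))
      }
    }
    if (length(classes) == 0) {
      classes <- "canonical"
      detail <- "exact reference match"
    }
    list(classes = classes, detail = paste(detail, collapse = "; "))
  })
  hits$isomir_classes <- map(res, "classes")
  hits$detail <- map_chr(res, "detail")
  hits
}

#' Per-family isomiR census
#'
#' Number of distinct tag sequences whose best conserved hit falls in each
#' family (each tag counts for exactly one family).
#'
#' @param hits Hit tibble from [match_conserved()].
#' @return Tibble `family`, `n_isomirs`, sorted by decreasing count.
#' @export
family_census <- function(hits) {
  if (nrow(hits) == 0) {
    return(tibble(family = character(), n_isomirs = integer()))
  }
  hits |>
    distinct(.data$sequence, .data$family) |>
    count(.data$family, name = "n_isomirs") |>
    arrange(desc(.data$n_isomirs), .data$family)
}
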