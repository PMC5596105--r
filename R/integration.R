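#' The eight epigenetic-regulator categories
#'
#' @return Character vector of the closed category set.
#' @export
regulator_categories <- function() {
  c("DNA methylation", "Histone methylation", "Histone acetylation",
    "Histone (protein) phosphorylation",
    "Histone ubiquitination (sumoylation)", "Chromatin remodeling",
    "sRNA pathways", "Thermosensing")
}

#' Call differentially expressed genes from condition means
#'
#' With only the three temperature condition means available for mRNAs, a
#' transcript is a DEG iff some pairwise |log2 ratio| of its means exceeds
#' `min_abs_log2` (strict).
#'
#' @param mrna Tibble `transcript_id`, `mean_18`, `mean_23`, `mean_28`.
#' @param min_abs_log2 Fold-change threshold on log2 scale.
#' @return Tibble `transcript_id`, `max_abs_log2`, `is_deg`.
#' @export
call_degs <- function(mrna, min_abs_log2 = 1) {
  m <- as.matrix(mrna[, c("mean_18", "mean_23", "mean_28")])
  pseudo <- {
    nz <- m[m > 0]
    if (length(nz)) min(nz) / 2 else 0.5
  }
  lm_ <- log2(m + pseudo)
  mx <- pmax(abs(lm_[, 1] - lm_[, 2]), abs(lm_[, 2] - lm_[, 3]),
             abs(lm_[, 1] - lm_[, 3]))
  tibble(transcript_id = mrna$transcript_id, max_abs_log2 = mx,
         is_deg = mx > min_abs_log2)
}

#' Refine DEM-DEG pairs by expression anti-correlation
#'
#' Pearson correlation over the three temperature condition means of the
#' miRNA and its predicted target; a pair is retained iff r < `threshold`
#' (strict), the miRNA is a DEM and the transcript a DEG. Degenerate
#' profiles (zero variance on either side) give undefined r and are flagged,
#' never retained.
#'
#' @param pairs Best-site pair tibble (from [target_table()]`$pairs`).
#' @param mirna_means Tibble `mirna_id`, `rpkm_mean_18/23/28`.
#' @param mrna_means Tibble `transcript_id`, `mean_18`, `mean_23`, `mean_28`.
#' @param dems DEM tibble from [call_dems()] (or vector of DEM ids).
#' @param degs DEG tibble from [call_degs()] (or vector of DEG ids).
#' @param threshold Correlation threshold (strict "below").
#' @return Tibble: the pairs with `r`, `is_dem`, `is_deg`, `degenerate`,
#'   `retained`. Pairs lacking expression on either side are dropped with a
#'   warning.
#' @export
correlate_pairs <- function(pairs, mirna_means, mrna_means, dems, degs,
                            threshold = -0.6) {
  dem_ids <- if (is.data.frame(dems)) dems$mirna_id[dems$is_dem] else dems
  deg_ids <- if (is.data.frame(degs)) degs$transcript_id[degs$is_deg] else degs
  out <- pairs |>
    left_join(select(mirna_means, "mirna_id", "rpkm_mean_18", "rpkm_mean_23",
                     "rpkm_mean_28"), by = "mirna_id") |>
    left_join(select(mrna_means, "transcript_id", "mean_18", "mean_23",
                     "mean_28"), by = "transcript_id")
  missing <- is.na(out$rpkm_mean_18) | is.na(out$mean_18)
  if (any(missing)) {
    warn(sprintf("%d pair(s) skipped: missing expression for a member",
                 sum(missing)))
    out <- out[!missing, , drop = FALSE]
  }
  x <- as.matrix(out[, c("rpkm_mean_18", "rpkm_mean_23", "rpkm_mean_28")])
  y <- as.matrix(out[, c("mean_18", "mean_23", "mean_28")])
  sx <- apply(x, 1, sd); sy <- apply(y, 1, sd)
  degenerate <- sx == 0 | sy == 0
  r <- rep(NA_real_, nrow(out))
  ok <- !degenerate
  if (any(ok)) {
    r[ok] <- vapply(which(ok), function(i) cor(x[i, ], y[i, ]), 0)
  }
  out$r <- r
  out$degenerate <- degenerate
  out$is_dem <- out$mirna_id %in% dem_ids
  out$is_deg <- out$transcript_id %in% deg_ids
  out$retained <- !degenerate & !is.na(r) & r < threshold &
    out$is_dem & out$is_deg
  out
}

#' Attach epigenetic-regulator categories to pairs
#'
#' @param pairs Pair tibble (e.g. from [correlate_pairs()]).
#' @param annotation Tibble `transcript_id`, `category` (one of the eight
#'   regulator categories or `NA`).
#' @return `pairs` with a `category` column (`NA` where unannotated).
#' @export
classify_regulators <- function(pairs, annotation) {
  known <- annotation$category[!is.na(annotation$category)]
  bad <- setdiff(unique(known), regulator_categories())
  if (length(bad) > 0) {
    abort(paste0("unknown regulator categories: ",
                 paste(bad, collapse = ", "), "; allowed: ",
                 paste(regulator_categories(), collapse = ", ")))
  }
  left_join(pairs, distinct(annotation, .data$transcript_id, .data$category),
            by = "transcript_id")
}

#' Summary tables over retained pairs
#'
#' Builds (a) the per-category four-column census (miRNAs, target gene
#' models, DEMs, target DEGs), (b) a per-domain-family table of target genes
#' and miRNAs, and (c) a run report of stage counts.
#'
#' @param pairs Pair tibble after [correlate_pairs()] and
#'   [classify_regulators()].
#' @param annotation Optional annotation with `transcript_id`,
#'   `domain_family` for the family table.
#' @param stage_counts Optional named list/vector of pipeline stage counts to
#'   embed in the report.
#' @return List `category_table`, `family_table`, `report`.
#' @export
summarize_pairs <- function(pairs, annotation = NULL, stage_counts = NULL) {
  cats <- regulator_categories()
  has_cat <- "category" %in% names(pairs)
  category_table <- map(cats, function(ct) {
    sub <- if (has_cat) pairs[!is.na(pairs$category) & pairs$category == ct, ]
           else pairs[0, ]
    ret <- sub[sub$retained, , drop = FALSE]
    tibble(category = ct,
           n_mirnas = length(unique(sub$mirna_id)),
           n_targets = length(unique(sub$transcript_id)),
           n_dems = length(unique(ret$mirna_id)),
           n_target_degs = length(unique(ret$transcript_id)))
  }) |> bind_rows()
  family_table <- NULL
  if (!is.null(annotation) && "domain_family" %in% names(annotation)) {
    ret <- pairs[pairs$retained, , drop = FALSE]
    family_table <- ret |>
      left_join(distinct(annotation, .data$transcript_id,
                         .data$domain_family), by = "transcript_id") |>
      group_by(.data$domain_family) |>
      summarise(n_targets = length(unique(.data$transcript_id)),
                n_mirnas = length(unique(.data$mirna_id)),
                .groups = "drop") |>
      arrange(desc(.data$n_targets))
  }
  report <- c(as.list(stage_counts %||% list()),
              list(n_pairs_tested = nrow(pairs),
                   n_pairs_retained = sum(pairs$retained),
                   n_pair_mirnas = length(unique(pairs$mirna_id[pairs$retained])),
                   n_pair_targets = length(unique(pairs$transcript_id[pairs$retained]))))
  list(category_table = category_table, family_table = family_table,
       report = report)
}
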