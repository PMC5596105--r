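#' Quantify miRNA expression as RPKM with condition means
#'
#' RPKM = count / (library_size / 1e6 x length_kb). Condition means pool the
#' libraries of each temperature (genotypes and stages treated as
#' replicates).
#'
#' @param counts Tibble with `mirna_id`, `sequence` and one raw count column
#'   per library.
#' @param metadata Library metadata tibble (`library`, `temperature`, ...);
#'   see [default_library_design()].
#' @param library_sizes Named numeric vector of per-library read totals
#'   (defaults to the column sums of `counts`).
#' @return An `expression_set`: list with `counts`, `rpkm` (same shape),
#'   `metadata`, `library_sizes` and `condition_means` (tibble `mirna_id`,
#'   `count_mean_18/23/28`, `rpkm_mean_18/23/28`, `length`).
#' @export
quantify_mirnas <- function(counts, metadata, library_sizes = NULL) {
  libs <- metadata$library
  assert_that(all(libs %in% names(counts)),
              "counts must have one column per metadata library")
  cm <- as.matrix(counts[, libs, drop = FALSE])
  if (is.null(library_sizes)) library_sizes <- colSums(cm)
  assert_that(all(libs %in% names(library_sizes)),
              "library_sizes must cover every library")
  library_sizes <- library_sizes[libs]
  if (any(library_sizes <= 0)) {
    abort(paste("zero-size library:",
                paste(libs[library_sizes <= 0], collapse = ", ")))
  }
  len_kb <- nchar(counts$sequence) / 1000
  rpkm <- sweep(cm, 2, library_sizes / 1e6, "/") / len_kb
  temps <- c(18, 23, 28)
  cmeans <- sapply(temps, function(t) {
    rowMeans(cm[, libs[metadata$temperature == t], drop = FALSE])
  })
  rmeans <- sapply(temps, function(t) {
    rowMeans(rpkm[, libs[metadata$temperature == t], drop = FALSE])
  })
  if (nrow(counts) == 1) { cmeans <- matrix(cmeans, 1); rmeans <- matrix(rmeans, 1) }
  condition_means <- tibble(
    mirna_id = counts$mirna_id, sequence = counts$sequence,
    length = nchar(counts$sequence),
    count_mean_18 = cmeans[, 1], count_mean_23 = cmeans[, 2],
    count_mean_28 = cmeans[, 3],
    rpkm_mean_18 = rmeans[, 1], rpkm_mean_23 = rmeans[, 2],
    rpkm_mean_28 = rmeans[, 3])
  out <- list(counts = counts, rpkm = bind_cols(
                tibble(mirna_id = counts$mirna_id), as_tibble(rpkm)),
              metadata = metadata, library_sizes = library_sizes,
              condition_means = condition_means)
  class(out) <- "expression_set"
  out
}

#' @export
print.expression_set <- function(x, ...) {
  cat("<expression_set>", nrow(x$condition_means), "miRNAs x",
      length(x$library_sizes), "libraries\n")
  invisible(x)
}

#' Filter to expressed miRNAs
#'
#' Keeps miRNAs whose mean raw count within at least one temperature
#' condition reaches `min_mean` (default 10). Set `per_library = TRUE` for
#' the stricter per-single-library reading (max single-library count).
#'
#' @param es An `expression_set` from [quantify_mirnas()].
#' @param min_mean Minimum mean count.
#' @param per_library Use the maximum single-library count instead.
#' @return The filtered `expression_set`.
#' @export
filter_expressed <- function(es, min_mean = 10, per_library = FALSE) {
  if (per_library) {
    keep <- apply(as.matrix(es$counts[, es$metadata$library, drop = FALSE]),
                  1, max) >= min_mean
  } else {
    m <- es$condition_means
    keep <- pmax(m$count_mean_18, m$count_mean_23, m$count_mean_28) >= min_mean
  }
  es$counts <- es$counts[keep, , drop = FALSE]
  es$rpkm <- es$rpkm[keep, , drop = FALSE]
  es$condition_means <- es$condition_means[keep, , drop = FALSE]
  es
}

#' Pairwise differential-expression test between two temperatures
#'
#' Kal's Z-test on pooled proportions: within each condition, counts and
#' library sizes are pooled, and the two pooled proportions compared with a
#' two-sided Z statistic. The effect size is the log2 ratio of mean RPKM
#' with a pseudo-value (half the smallest nonzero RPKM in the matrix) to
#' guard zeros. Significance requires |log2 ratio| > 1 (strict) and
#' p < 0.05 (strict).
#'
#' @param es An `expression_set`.
#' @param contrast One of `"18v23"`, `"18v28"`, `"23v28"`, or `"all"` for
#'   the three pairwise contrasts stacked.
#' @param alpha P-value threshold.
#' @param min_abs_log2 Log2-ratio threshold (strict inequality).
#' @param method `"kal"` (default) or `"fisher"` (two-sided Fisher exact on
#'   the pooled counts).
#' @return Tibble `mirna_id`, `contrast`, `log2_ratio`, `p_value`,
#'   `significant`.
#' @export
de_test <- function(es, contrast = "all", alpha = 0.05, min_abs_log2 = 1,
                    method = c("kal", "fisher")) {
  method <- match.arg(method)
  contrasts <- if (identical(contrast, "all")) c("18v23", "18v28", "23v28")
               else contrast
  assert_that(all(contrasts %in% c("18v23", "18v28", "23v28")),
              "contrast must be 18v23, 18v28, 23v28 or all")
  cm <- as.matrix(es$counts[, es$metadata$library, drop = FALSE])
  rm_ <- as.matrix(es$rpkm[, es$metadata$library, drop = FALSE])
  nz <- rm_[rm_ > 0]
  pseudo <- if (length(nz)) min(nz) / 2 else 0.5
  out <- map(contrasts, function(ct) {
    t_a <- as.integer(substr(ct, 1, 2))
    t_b <- as.integer(substr(ct, 4, 5))
    la <- es$metadata$library[es$metadata$temperature == t_a]
    lb <- es$metadata$library[es$metadata$temperature == t_b]
    assert_that(length(la) >= 1 && length(lb) >= 1,
                "both conditions need at least one library")
    na <- rowSums(cm[, la, drop = FALSE]); Na <- sum(es$library_sizes[la])
    nb <- rowSums(cm[, lb, drop = FALSE]); Nb <- sum(es$library_sizes[lb])
    ra <- rowMeans(rm_[, la, drop = FALSE])
    rb <- rowMeans(rm_[, lb, drop = FALSE])
    log2_ratio <- log2((ra + pseudo) / (rb + pseudo))
    if (method == "kal") {
      pa <- na / Na; pb <- nb / Nb
      pbar <- (na + nb) / (Na + Nb)
      se <- sqrt(pbar * (1 - pbar) * (1 / Na + 1 / Nb))
      z <- ifelse(se > 0, (pa - pb) / se, 0)
      p <- 2 * pnorm(-abs(z))
    } else {
      p <- vapply(seq_along(na), function(i) {
        stats::fisher.test(matrix(c(na[i], Na - na[i], nb[i], Nb - nb[i]),
                                  2, 2))$p.value
      }, 0)
    }
    both_zero <- (na + nb) == 0
    log2_ratio[both_zero] <- 0
    p[both_zero] <- 1
    tibble(mirna_id = es$counts$mirna_id, contrast = ct,
           log2_ratio = log2_ratio, p_value = p,
           significant = abs(log2_ratio) > min_abs_log2 & p < alpha)
  })
  bind_rows(out)
}

#' Call differentially expressed miRNAs
#'
#' A miRNA is a DEM iff it is significant (|log2 RPKM ratio| > 1 and
#' p < 0.05, both strict) in at least one of the three pairwise temperature
#' contrasts.
#'
#' @param de_calls Tibble from [de_test()] over all three contrasts.
#' @return Tibble `mirna_id`, `n_significant_contrasts`, `is_dem`.
#' @export
call_dems <- function(de_calls) {
  de_calls |>
    group_by(.data$mirna_id) |>
    summarise(n_significant_contrasts = sum(.data$significant),
              .groups = "drop") |>
    mutate(is_dem = .data$n_significant_contrasts >= 1)
}

#' The 12-class profile-cluster label space
#'
#' Enumerates the 13 weak orderings of the three temperature conditions and
#' drops the flat one, leaving exactly 12 non-flat classes. Each class is a
#' sign triple over the contrasts (18v23, 23v28, 18v28), where + means the
#' first condition is higher.
#'
#' @return Tibble `cluster` (1-12), `label`, `s_18v23`, `s_23v28`,
#'   `s_18v28`, `rank_18`, `rank_23`, `rank_28` (1 = lowest expression).
#' @export
profile_cluster_space <- function() {
  ranks <- list(
    c(3, 2, 1), c(3, 1, 2), c(2, 3, 1), c(1, 3, 2), c(2, 1, 3), c(1, 2, 3),
    c(2, 2, 1), c(1, 1, 2), c(2, 1, 2), c(1, 2, 1), c(2, 1, 1), c(1, 2, 2))
  rows <- map(seq_along(ranks), function(i) {
    r <- ranks[[i]]
    parts <- split(c("18", "23", "28"), -r)
    lab <- paste(vapply(parts, paste, "", collapse = " = "), collapse = " > ")
    tibble(cluster = i, label = lab,
           s_18v23 = sign(r[1] - r[2]), s_23v28 = sign(r[2] - r[3]),
           s_18v28 = sign(r[1] - r[3]),
           rank_18 = r[1], rank_23 = r[2], rank_28 = r[3])
  })
  bind_rows(rows)
}

#' Assign each DEM a temperature-profile cluster
#'
#' Each contrast contributes a sign (+/-/0): the direction of its log2 ratio
#' if significant, else 0. Sign triples consistent with a non-flat weak
#' ordering of the three conditions map to one of the 12 cluster labels;
#' inconsistent triples (violating transitivity, e.g. significant 18>23 and
#' 23>28 but no significant 18v28) are resolved by re-signing from the
#' condition-mean ranks and flagged `resigned`.
#'
#' @param de_calls Tibble from [de_test()] over all three contrasts.
#' @param condition_means Tibble with `mirna_id`, `rpkm_mean_18/23/28` (from
#'   an `expression_set`).
#' @param dems Optional DEM call tibble from [call_dems()]; defaults to
#'   calling it on `de_calls`. Only DEMs are labelled.
#' @return Tibble `mirna_id`, `s_18v23`, `s_23v28`, `s_18v28`, `cluster`,
#'   `label`, `resigned`.
#' @export
cluster_profiles <- function(de_calls, condition_means, dems = NULL) {
  if (is.null(dems)) dems <- call_dems(de_calls)
  dem_ids <- dems$mirna_id[dems$is_dem]
  space <- profile_cluster_space()
  signs <- de_calls |>
    filter(.data$mirna_id %in% dem_ids) |>
    mutate(s = ifelse(.data$significant, sign(.data$log2_ratio), 0L)) |>
    select("mirna_id", "contrast", "s") |>
    pivot_wider(names_from = "contrast", values_from = "s",
                names_prefix = "s_")
  out <- left_join(signs,
                   select(condition_means, "mirna_id", "rpkm_mean_18",
                          "rpkm_mean_23", "rpkm_mean_28"),
                   by = "mirna_id")
  key <- function(a, b, c) paste(a, b, c)
  space_key <- key(space$s_18v23, space$s_23v28, space$s_18v28)
  k <- match(key(out$s_18v23, out$s_23v28, out$s_18v28), space_key)
  resigned <- is.na(k)
  if (any(resigned)) {
    m18 <- out$rpkm_mean_18[resigned]
    m23 <- out$rpkm_mean_23[resigned]
    m28 <- out$rpkm_mean_28[resigned]
    out$s_18v23[resigned] <- sign(m18 - m23)
    out$s_23v28[resigned] <- sign(m23 - m28)
    out$s_18v28[resigned] <- sign(m18 - m28)
    k <- match(key(out$s_18v23, out$s_23v28, out$s_18v28), space_key)
  }
  flat <- out$s_18v23 == 0 & out$s_23v28 == 0 & out$s_18v28 == 0
  out$cluster <- space$cluster[k]
  out$label <- space$label[k]
  out$label[flat] <- "flat"
  out$resigned <- resigned
  if (any(resigned)) {
    inform(sprintf("%d inconsistent sign triple(s) re-signed from condition-mean ranks",
                   sum(resigned)))
  }
  select(out, "mirna_id", "s_18v23", "s_23v28", "s_18v28", "cluster",
         "label", "resigned")
}

#' Plot mean expression profiles by cluster
#'
#' @param condition_means Condition-mean tibble from an `expression_set`.
#' @param clusters Cluster tibble from [cluster_profiles()].
#' @return A ggplot of per-miRNA scaled RPKM profiles facetted by cluster.
#' @export
plot_cluster_profiles <- function(condition_means, clusters) {
  df <- inner_join(condition_means, clusters, by = "mirna_id") |>
    select("mirna_id", "label", "rpkm_mean_18", "rpkm_mean_23",
           "rpkm_mean_28") |>
    pivot_longer(cols = dplyr::starts_with("rpkm_mean_"),
                 names_to = "temperature", values_to = "rpkm",
                 names_prefix = "rpkm_mean_") |>
    mutate(temperature = as.integer(.data$temperature)) |>
    group_by(.data$mirna_id) |>
    mutate(scaled = (.data$rpkm - mean(.data$rpkm)) /
             (sd(.data$rpkm) + 1e-12)) |>
    ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$temperature, y = .data$scaled,
                                   group = .data$mirna_id)) +
    ggplot2::geom_line(alpha = 0.3, colour = "darkred") +
    ggplot2::facet_wrap(~label) +
    ggplot2::labs(x = "EpI temperature (°C)", y = "scaled RPKM",
                  title = "DEM temperature profiles by cluster") +
    ggplot2::theme_minimal()
}

#' Empirical DEM rate under a null (no differential expression) simulation
#'
#' Simulates Poisson counts with equal expected proportions in two
#' temperature conditions and measures the fraction of miRNA tests called
#' significant at the joint threshold (|log2 RPKM ratio| > 1 and p < 0.05).
#' Used to check the calibration (conservativeness) of the DE caller.
#'
#' @param n_mirnas miRNAs per replicate.
#' @param n_reps Replicate simulations.
#' @param libs_per_condition Libraries per condition.
#' @param depth Library size (reads).
#' @param seed Random seed.
#' @return List `dem_rate` (pooled over replicates), `n_tests`.
#' @export
simulate_null_dem_rate <- function(n_mirnas = 500, n_reps = 200,
                                   libs_per_condition = 6, depth = 3e5,
                                   seed = 1) {
  withr::with_seed(seed, {
    n_lib <- 2 * libs_per_condition
    libs <- sprintf("lib%02d", seq_len(n_lib))
    metadata <- tibble(library = libs,
                       genotype = "A2C", stage = 1L,
                       temperature = rep(c(18L, 23L), each = libs_per_condition))
    n_sig <- 0L
    n_tests <- 0L
    for (rep_i in seq_len(n_reps)) {
      w <- rlnorm(n_mirnas, meanlog = log(50 / depth), sdlog = 1)
      lambda <- outer(w, rep(depth, n_lib))
      cm <- matrix(stats::rpois(length(lambda), lambda), nrow = n_mirnas)
      colnames(cm) <- libs
      counts <- bind_cols(tibble(mirna_id = sprintf("m%04d", seq_len(n_mirnas)),
                                 sequence = strrep("A", 21)),
                          as_tibble(cm))
      lib_sizes <- setNames(rep(depth, n_lib), libs)
      rpkm <- sweep(cm, 2, lib_sizes / 1e6, "/") / (21 / 1000)
      es <- list(counts = counts,
                 rpkm = bind_cols(tibble(mirna_id = counts$mirna_id),
                                  as_tibble(rpkm)),
                 metadata = metadata, library_sizes = lib_sizes)
      class(es) <- "expression_set"
      de <- de_test(es, contrast = "18v23")
      n_sig <- n_sig + sum(de$significant)
      n_tests <- n_tests + nrow(de)
    }
    list(dem_rate = n_sig / n_tests, n_tests = n_tests)
  })
}
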