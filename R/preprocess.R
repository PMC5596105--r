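#' Collapse reads into counted sequence tags
#'
#' Identical read sequences are collapsed into one tag with per-library
#' counts. `U` is normalised to `T` on input; reads containing any other
#' non-ACGT character (including `N`) are discarded and reported.
#'
#' @param reads Either a named list of character vectors (one per library) or
#'   a character vector of FASTQ paths (library names taken from file names).
#' @return Tibble with `sequence`, one integer count column per library (in
#'   input order), and `total`. Attributes `reads_in` and `reads_with_n`
#'   record the read-conservation bookkeeping; attribute `libraries` the
#'   library names.
#' @export
#' @examples
#' collapse_reads(list(a = c("ACGT", "ACGT", "TTTT"), b = "ACGT"))
collapse_reads <- function(reads) {
  if (is.character(reads)) {
    paths <- reads
    reads <- lapply(paths, read_fastq)
    names(reads) <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(paths))
  }
  assert_that(is.list(reads) && length(reads) > 0, "no read libraries given")
  if (is.null(names(reads)) || any(names(reads) == "")) {
    names(reads) <- sprintf("lib%d", seq_along(reads))
  }
  libs <- names(reads)
  reads <- lapply(reads, function(x) toupper(chartr("U", "T", x)))
  reads_in <- vapply(reads, length, 0L)
  keep <- lapply(reads, function(x) grepl("^[ACGT]*$", x) & nchar(x) > 0)
  reads_with_n <- reads_in - vapply(keep, sum, 0L)
  long <- tibble(
    library = rep(libs, vapply(keep, sum, 0L)),
    sequence = unlist(map2(reads, keep, function(x, k) x[k]), use.names = FALSE))
  if (nrow(long) == 0) {
    wide <- tibble(sequence = character())
  } else {
    wide <- long |>
      count(.data$sequence, .data$library) |>
      pivot_wider(names_from = "library", values_from = "n", values_fill = 0L)
  }
  for (l in libs) if (!l %in% names(wide)) wide[[l]] <- integer(nrow(wide))
  wide <- wide[order(wide$sequence), c("sequence", libs), drop = FALSE]
  wide$total <- as.integer(rowSums(wide[, libs, drop = FALSE]))
  out <- as_tibble(wide)
  attr(out, "reads_in") <- sum(reads_in)
  attr(out, "reads_with_n") <- sum(reads_with_n)
  attr(out, "libraries") <- libs
  out
}

tag_libraries <- function(tags) {
  libs <- attr(tags, "libraries")
  if (is.null(libs)) libs <- setdiff(names(tags), c("sequence", "total"))
  libs
}

keep_tag_attrs <- function(out, tags) {
  for (a in c("reads_in", "reads_with_n", "libraries")) {
    attr(out, a) <- attr(tags, a)
  }
  out
}

#' Filter tags by read length
#'
#' Retains tags with length between `min_len` and `max_len` nt, both bounds
#' inclusive (the canonical miRNA-range filter is 19-27 nt).
#'
#' @param tags Tag tibble from [collapse_reads()].
#' @param min_len,max_len Inclusive length bounds (15-35 nt allowed).
#' @return Filtered tag tibble.
#' @export
length_filter <- function(tags, min_len = 19, max_len = 27) {
  assert_that(min_len <= max_len, "min_len must be <= max_len")
  assert_that(min_len >= 15 && max_len <= 35,
              "length bounds must lie within 15-35 nt")
  len <- nchar(tags$sequence)
  keep_tag_attrs(tags[len >= min_len & len <= max_len, , drop = FALSE], tags)
}

#' Remove singleton tags
#'
#' Drops tags whose pooled total across all libraries is below `min_total`
#' (default 2, i.e. sequences seen exactly once anywhere are removed). Set
#' `per_library = TRUE` to instead require `min_total` reads within at least
#' one library.
#'
#' @param tags Tag tibble from [collapse_reads()].
#' @param min_total Minimum read support.
#' @param per_library Apply the threshold per library instead of pooled.
#' @return Filtered tag tibble.
#' @export
drop_singletons <- function(tags, min_total = 2, per_library = FALSE) {
  libs <- tag_libraries(tags)
  keep <- if (per_library) {
    apply(tags[, libs, drop = FALSE], 1, max) >= min_total
  } else {
    tags$total >= min_total
  }
  keep_tag_attrs(tags[keep, , drop = FALSE], tags)
}

#' Length distribution of tags or raw reads
#'
#' Exact per-library and pooled read-count histograms over 15-35 nt, plus the
#' modal length classes detected as local maxima of the pooled profile.
#'
#' @param x A tag tibble from [collapse_reads()] or a named list of raw read
#'   vectors.
#' @return A `length_profile`: list with `profile` (long tibble `library`,
#'   `length`, `reads`), `pooled` (tibble `length`, `reads`) and `modes`
#'   (integer vector of local maxima with non-zero support).
#' @export
length_distribution <- function(x) {
  if (!is.data.frame(x)) x <- collapse_reads(x)
  libs <- tag_libraries(x)
  len <- nchar(x$sequence)
  bins <- 15:35
  per_lib <- map(libs, function(l) {
    tibble(library = l, length = bins,
           reads = vapply(bins, function(b)
             sum(x[[l]][len == b]), 0L))
  })
  profile <- bind_rows(per_lib)
  pooled <- profile |>
    group_by(.data$length) |>
    summarise(reads = sum(.data$reads), .groups = "drop")
  r <- pooled$reads
  is_mode <- vapply(seq_along(r), function(i) {
    left <- if (i == 1) 0L else r[i - 1]
    right <- if (i == length(r)) 0L else r[i + 1]
    r[i] > 0 && r[i] >= left && r[i] > right
  }, TRUE)
  out <- list(profile = profile, pooled = pooled,
              modes = pooled$length[is_mode])
  class(out) <- "length_profile"
  out
}

#' @export
print.length_profile <- function(x, ...) {
  cat("<length_profile> modes at", paste(x$modes, collapse = ", "), "nt;",
      sum(x$pooled$reads), "reads\n")
  invisible(x)
}

#' Plot a read-length profile
#'
#' @param object A `length_profile` from [length_distribution()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.length_profile <- function(object, ...) {
  ggplot2::ggplot(object$pooled,
                  ggplot2::aes(x = .data$length, y = .data$reads)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "read length (nt)", y = "reads",
                  title = "sRNA length distribution (pooled)") +
    ggplot2::theme_minimal()
}

#' Run the standard preprocessing chain with read-count bookkeeping
#'
#' Collapse, length-filter (19-27 nt inclusive) and singleton removal, with a
#' conservation report: reads in = reads with N + reads removed by length +
#' singleton reads removed + reads surviving.
#'
#' @param reads As in [collapse_reads()].
#' @param min_len,max_len Length bounds, inclusive.
#' @param min_total Pooled singleton threshold.
#' @return List with `tags` (the surviving tag tibble) and `report` (named
#'   integer vector of the conservation identity terms).
#' @export
preprocess_reads <- function(reads, min_len = 19, max_len = 27,
                             min_total = 2) {
  tags0 <- collapse_reads(reads)
  tags1 <- length_filter(tags0, min_len, max_len)
  tags2 <- drop_singletons(tags1, min_total)
  report <- c(reads_in = attr(tags0, "reads_in"),
              reads_with_n = attr(tags0, "reads_with_n"),
              reads_length_removed = sum(tags0$total) - sum(tags1$total),
              reads_singleton_removed = sum(tags1$total) - sum(tags2$total),
              reads_surviving = sum(tags2$total))
  list(tags = tags2, report = report)
}
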