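DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character vectors (DNA alphabet,
#' `U` accepted on input and treated as `T`).
#'
#' @param x Character vector of DNA/RNA sequences.
#' @return Character vector of reverse complements (DNA alphabet).
#' @export
#' @examples
#' revcomp("ACGTT")
revcomp <- function(x) {
  x <- toupper(chartr("Uu", "Tt", x))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# substitute positions `pos` of `seq` with random different bases
substitute_bases <- function(seq, pos) {
  ch <- strsplit(seq, "")[[1]]
  for (p in pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1)
  paste(ch, collapse = "")
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

# deterministic sub-seed derivation, kept below 2^31
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1000003L * as.integer(offset)) %% 2147483629L
}
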