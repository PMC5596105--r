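#' Write sequences as FASTA
#'
#' @param seqs Named character vector of sequences (names become headers).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unname(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA file.
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write reads as FASTQ with constant quality
#'
#' Emits Sanger-encoded records at a constant Q30 (`?`), matching the
#' simulator's contract of pre-trimmed reads without per-base quality
#' structure.
#'
#' @param reads Character vector of read sequences.
#' @param path Output file.
#' @param ids Optional read ids; defaults to `read1 ... readN`.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, ids = NULL) {
  n <- length(reads)
  if (is.null(ids)) ids <- sprintf("read%d", seq_len(n))
  con <- file(path, "w")
  on.exit(close(con))
  if (n > 0) {
    rec <- paste0("@", ids, "\n", reads, "\n+\n",
                  strrep("?", nchar(reads)))
    writeLines(rec, con)
  }
  invisible(path)
}

#' Read one FASTQ file
#'
#' @param path FASTQ file.
#' @return Character vector of read sequences (U normalised to T, uppercase).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  toupper(chartr("U", "T", as.character(x)))
}

#' Write transcript and MIR locus annotations as GFF3
#'
#' Transcripts are emitted as `gene` features and planted hairpins as
#' `miRNA_primary_transcript` features, converting the internal 0-based
#' half-open coordinates to GFF3 1-based closed intervals.
#'
#' @param sim A `sporomir_sim` (or any list with `transcripts` and optionally
#'   `loci` tibbles).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(sim, path) {
  tx <- sim$transcripts
  gr <- GenomicRanges::GRanges(
    seqnames = rep("genome", nrow(tx)),
    ranges = IRanges::IRanges(start = tx$start + 1L, end = tx$end),
    strand = tx$strand, type = rep("gene", nrow(tx)),
    ID = tx$transcript_id)
  if (!is.null(sim$loci) && nrow(sim$loci) > 0) {
    lo <- sim$loci
    gr2 <- GenomicRanges::GRanges(
      seqnames = "genome",
      ranges = IRanges::IRanges(start = lo$genome_start + 1L,
                                end = lo$genome_end),
      strand = "+", type = "miRNA_primary_transcript", ID = lo$locus_id)
    gr <- c(gr, gr2)
  }
  if (length(gr) == 0) {
    writeLines("##gff-version 3", path)
  } else {
    rtracklayer::export(gr, path, format = "gff3")
  }
  invisible(path)
}

#' Write the simulated experiment to disk
#'
#' Emits the genome FASTA, transcript FASTA, GFF3 annotation, one FASTQ per
#' library, the reference mature FASTA + family TSV, the mRNA expression TSV,
#' the regulator annotation TSV, and a JSON ground-truth bundle.
#'
#' @param sim A `sporomir_sim` from [simulate_srna_experiment()].
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(c(genome = sim$genome), file.path(outdir, "genome.fa"))
  write_fasta(setNames(sim$transcripts$sequence, sim$transcripts$transcript_id),
              file.path(outdir, "transcripts.fa"))
  write_gff3(sim, file.path(outdir, "annotation.gff3"))
  for (lib in names(sim$reads)) {
    write_fastq(sim$reads[[lib]], file.path(outdir, paste0(lib, ".fastq")))
  }
  write_fasta(setNames(sim$reference$sequence, sim$reference$id),
              file.path(outdir, "reference_matures.fa"))
  utils::write.table(sim$reference[, c("id", "family")],
                     file.path(outdir, "reference_families.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$mrna, file.path(outdir, "mrna_expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$annotation, file.path(outdir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(loci = sim$loci, expression_model = sim$expression_model,
                target_links = sim$target_links,
                truth_counts = sim$truth_counts)
  jsonlite::write_json(truth, file.path(outdir, "ground_truth.json"),
                       dataframe = "columns", digits = NA)
  invisible(outdir)
}
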