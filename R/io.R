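# FASTA/FASTQ input and output.  File handling goes through Biostrings; in
# memory the package works with plain named character vectors (sequences)
# and data frames (reads), which keeps the per-base arithmetic of trimming
# and alignment simple.

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read paired FASTQ files into a read-pair table
#'
#' @param path1,path2 FASTQ files for mate 1 and mate 2 (Phred+33).
#' @return data frame with columns `read_id`, `mate1`, `qual1`, `mate2`,
#'   `qual2`.  Mate ids must match after stripping a trailing `/1` / `/2`.
#' @export
read_fastq_pairs <- function(path1, path2) {
  r1 <- read_fastq_single(path1)
  r2 <- read_fastq_single(path2)
  id1 <- sub("/[12]$", "", r1$read_id)
  id2 <- sub("/[12]$", "", r2$read_id)
  if (!identical(sort(id1), sort(id2)))
    config_error("mate files carry different read ids")
  r2 <- r2[match(id1, id2), ]
  data.frame(read_id = id1, mate1 = r1$seq, qual1 = r1$qual,
             mate2 = r2$seq, qual2 = r2$qual, stringsAsFactors = FALSE)
}

#' Read a single-end FASTQ file
#'
#' @param path FASTQ file (Phred+33).
#' @return data frame with columns `read_id`, `seq`, `qual`.
#' @export
read_fastq_single <- function(path) {
  x <- Biostrings::readQualityScaledDNAStringSet(path,
                                                 quality.scoring = "phred")
  data.frame(read_id = sub("\\s.*$", "", names(x)),
             seq = as.character(x),
             qual = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE)
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param ids,seqs,quals read names, sequences and quality strings.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_fastq <- function(ids, seqs, quals, path) {
  # the constructor warns when it drops the (empty) metadata columns that
  # readQualityScaledDNAStringSet attaches; nothing of value is lost
  withCallingHandlers(
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(setNames(seqs, ids)),
      Biostrings::PhredQuality(quals)),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Write a paired read table to two FASTQ files
#'
#' @param pairs data frame as returned by [read_fastq_pairs()] or
#'   [simulate_mixed_library()].
#' @param path1,path2 output FASTQ files for mates 1 and 2.
#' @return invisibly, `c(path1, path2)`.
#' @export
write_fastq_pairs <- function(pairs, path1, path2) {
  write_fastq(paste0(pairs$read_id, "/1"), pairs$mate1, pairs$qual1, path1)
  write_fastq(paste0(pairs$read_id, "/2"), pairs$mate2, pairs$qual2, path2)
  invisible(c(path1, path2))
}

# Phred+33 helpers
qual_to_int <- function(q) utf8ToInt(q) - 33L
int_to_qual <- function(v) intToUtf8(v + 33L)
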