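# Read-level simulator: paired-end interface library with a known host
# contamination fraction, per-position qualities and a per-read origin table.

# Sequencing errors and qualities for one mate.  With probability
# `low_quality_tail_prob` the read carries a low-quality 3' tail; bases in
# the tail get a proportionally elevated error rate.  With a zero base
# error rate no errors are introduced anywhere, so reads are exact
# substrings of their source.
apply_read_noise <- function(seq, config) {
  rl <- nchar(seq)
  qual <- rep(config$quality_high, rl)
  if (runif(1) < config$low_quality_tail_prob) {
    max_tail <- max(1L, floor(rl * config$max_tail_fraction))
    tail_len <- sample(max_tail, 1L)
    qual[(rl - tail_len + 1L):rl] <- config$quality_low
  }
  if (config$base_error_rate > 0) {
    perr <- ifelse(qual == config$quality_high, config$base_error_rate,
                   min(0.5, config$base_error_rate * 40))
    hit <- which(runif(rl) < perr)
    if (length(hit)) {
      ch <- strsplit(seq, "", fixed = TRUE)[[1]]
      ch[hit] <- vapply(ch[hit], function(b)
        sample(setdiff(DNA_BASES, b), 1L), character(1))
      seq <- paste(ch, collapse = "")
    }
  }
  list(seq = seq, qual = int_to_qual(qual))
}

#' Simulate a contaminated paired-end interface library
#'
#' Draws read pairs from the parasite assembly pool and, with probability
#' equal to the configured contamination fraction, from a host transcript
#' set.  Fragments have uniform insert sizes, mate 2 is the reverse
#' complement of the fragment end, and every pair is labeled with its true
#' origin.  Parasite transcripts are sampled proportionally to their
#' negative-binomial expression weights.
#'
#' @param config a [sim_config()].
#' @param refs result of [simulate_reference_sets()].
#' @param host which host set contaminates the library (`"hostA"` or
#'   `"hostB"`).
#' @param outdir optional directory; when given, writes `reads_1.fastq`,
#'   `reads_2.fastq` and `read_origins.tsv`.
#' @return a list with `pairs` (data frame `read_id`, `mate1`, `qual1`,
#'   `mate2`, `qual2`) and `origins` (data frame `read_id`, `origin`,
#'   `source_id`).
#' @export
simulate_mixed_library <- function(config, refs, host = c("hostA", "hostB"),
                                   outdir = NULL) {
  stopifnot(is(config, "sim_config"))
  host <- match.arg(host)
  set.seed(config$seed + 1L)
  pool <- refs$sets$parasite_assembly
  host_set <- refs$sets[[host]]
  if (config$read_length > min(nchar(c(pool, host_set))))
    config_error("read_length exceeds the shortest transcript length")

  n <- config$n_read_pairs
  f <- config$contamination_fraction
  rl <- config$read_length
  w_par <- refs$families$expr_weight
  is_host <- runif(n) < f
  src_par <- sample(length(pool), n, replace = TRUE, prob = w_par)
  src_host <- sample(length(host_set), n, replace = TRUE)

  pairs <- vector("list", n)
  origins <- data.frame(read_id = sprintf("R%06d", seq_len(n)),
                        origin = ifelse(is_host, host, "parasite"),
                        source_id = ifelse(is_host,
                                           names(host_set)[src_host],
                                           names(pool)[src_par]),
                        stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    tx <- if (is_host[i]) host_set[[src_host[i]]] else pool[[src_par[i]]]
    L <- nchar(tx)
    ins <- sample(seq(config$insert_size_range[1],
                      config$insert_size_range[2]), 1L)
    ins <- max(rl, min(ins, L))
    start <- sample(L - ins + 1L, 1L)
    m1 <- substr(tx, start, start + rl - 1L)
    m2 <- revcomp(substr(tx, start + ins - rl, start + ins - 1L))
    m1 <- apply_read_noise(m1, config)
    m2 <- apply_read_noise(m2, config)
    pairs[[i]] <- c(m1$seq, m1$qual, m2$seq, m2$qual)
  }
  mat <- do.call(rbind, pairs)
  pairs <- data.frame(read_id = origins$read_id,
                      mate1 = mat[, 1], qual1 = mat[, 2],
                      mate2 = mat[, 3], qual2 = mat[, 4],
                      stringsAsFactors = FALSE)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_fastq_pairs(pairs, file.path(outdir, "reads_1.fastq"),
                      file.path(outdir, "reads_2.fastq"))
    write.table(origins, file.path(outdir, "read_origins.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(pairs = pairs, origins = origins)
}
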