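# Quality trimming with the end-trim + half-length survival rule, pair
# reconstruction with orphan accounting, and read-level host screening.

#' Trimming policy
#'
#' @param quality_floor Phred score below which terminal bases are removed
#'   (default 20, i.e. the Q20 rule).
#' @param min_survival_fraction minimum surviving fraction of the original
#'   read length; shorter survivors are discarded (default 0.5, i.e. at
#'   least half the original length).
#' @return a list of class `trim_policy`.
#' @export
trim_policy <- function(quality_floor = 20L, min_survival_fraction = 0.5) {
  if (quality_floor < 0) config_error("quality_floor must be non-negative")
  if (min_survival_fraction <= 0 || min_survival_fraction > 1)
    config_error("min_survival_fraction must lie in (0, 1]")
  structure(list(quality_floor = as.integer(quality_floor),
                 min_survival_fraction = min_survival_fraction),
            class = "trim_policy")
}

#' Quality-trim reads from the ends
#'
#' Strips the maximal prefix and the maximal suffix of bases whose quality
#' is below the policy floor; interior low-quality bases are untouched.  A
#' read is discarded when the surviving fragment is shorter than
#' `min_survival_fraction` times the original length.
#'
#' @param seqs character vector of read sequences.
#' @param quals character vector of Phred+33 quality strings, same lengths
#'   as `seqs`.
#' @param policy a [trim_policy()].
#' @return data frame with columns `seq`, `qual` (trimmed; `NA` when
#'   discarded), `kept` (logical), `trim_start`, `trim_end` (1-based kept
#'   range in the original read; 0/−1-style empty range when discarded) and
#'   `original_length`.
#' @export
quality_trim <- function(seqs, quals, policy = trim_policy()) {
  if (length(seqs) != length(quals))
    config_error("seqs and quals differ in length")
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad))
    config_error("malformed quality string for record %d: %d bases vs %d quality values",
                 bad[1], nchar(seqs[bad[1]]), nchar(quals[bad[1]]))
  if (any(nchar(seqs) == 0)) config_error("empty read")
  n <- length(seqs)
  out <- data.frame(seq = rep(NA_character_, n), qual = rep(NA_character_, n),
                    kept = logical(n), trim_start = integer(n),
                    trim_end = integer(n), original_length = nchar(seqs),
                    stringsAsFactors = FALSE)
  floorq <- policy$quality_floor
  for (i in seq_len(n)) {
    q <- qual_to_int(quals[[i]])
    ok <- which(q >= floorq)
    L <- length(q)
    if (length(ok) == 0) {
      out$trim_start[i] <- 0L; out$trim_end[i] <- -1L
      next
    }
    a <- ok[1]; b <- ok[length(ok)]
    if ((b - a + 1) >= policy$min_survival_fraction * L) {
      out$seq[i] <- substr(seqs[[i]], a, b)
      out$qual[i] <- substr(quals[[i]], a, b)
      out$kept[i] <- TRUE
    }
    out$trim_start[i] <- a; out$trim_end[i] <- b
  }
  out
}

#' Reconstruct pairs and orphans after trimming
#'
#' @param trimmed1,trimmed2 [quality_trim()] results for mates 1 and 2 (rows
#'   aligned by position).
#' @param ids read-pair ids (no duplicates).
#' @return a list with `pairs` (data frame `read_id`, `mate1`, `qual1`,
#'   `mate2`, `qual2` where both mates survive), `orphans` (data frame
#'   `read_id`, `mate`, `seq`, `qual` where exactly one survives) and
#'   `accounting` (data frame of stage counts; 2*pairs + orphans +
#'   discarded = 2*input pairs).
#' @export
repair_pairs <- function(trimmed1, trimmed2, ids) {
  if (anyDuplicated(ids)) config_error("duplicate read id: %s",
                                       ids[duplicated(ids)][1])
  stopifnot(nrow(trimmed1) == length(ids), nrow(trimmed2) == length(ids))
  both <- trimmed1$kept & trimmed2$kept
  only1 <- trimmed1$kept & !trimmed2$kept
  only2 <- !trimmed1$kept & trimmed2$kept
  pairs <- data.frame(read_id = ids[both],
                      mate1 = trimmed1$seq[both], qual1 = trimmed1$qual[both],
                      mate2 = trimmed2$seq[both], qual2 = trimmed2$qual[both],
                      stringsAsFactors = FALSE)
  orphans <- data.frame(
    read_id = c(ids[only1], ids[only2]),
    mate = c(rep(1L, sum(only1)), rep(2L, sum(only2))),
    seq = c(trimmed1$seq[only1], trimmed2$seq[only2]),
    qual = c(trimmed1$qual[only1], trimmed2$qual[only2]),
    stringsAsFactors = FALSE)
  accounting <- data.frame(
    stage = c("input_reads", "surviving_paired_reads", "orphan_reads",
              "discarded_reads"),
    count = c(2L * length(ids), 2L * nrow(pairs), nrow(orphans),
              2L * length(ids) - 2L * nrow(pairs) - nrow(orphans)),
    stringsAsFactors = FALSE)
  list(pairs = pairs, orphans = orphans, accounting = accounting)
}

#' Screen host-origin reads by mapping
#'
#' Maps every read against the host reference under the mapping policy; a
#' read is host-assigned iff it maps (coverage and identity thresholds of
#' the policy; for screening, `min_similarity` is normally set from the
#' calibrated host-exclusion threshold).  For pairs where exactly one mate
#' maps to the host, both mates are removed (conservative against chimeric
#' carry-through) and counted as `half_host_pairs` in the accounting.
#'
#' @param pairs data frame of read pairs (`read_id`, `mate1`, `qual1`,
#'   `mate2`, `qual2`); may have zero rows.
#' @param orphans data frame of orphan reads (`read_id`, `mate`, `seq`,
#'   `qual`); may be `NULL`.
#' @param host_reference named character vector of host transcripts (or a
#'   prebuilt [build_index()]).
#' @param policy a [mapping_policy()].
#' @return a list with `retained_pairs`, `retained_orphans`, `host_pairs`,
#'   `host_orphans` (subsets of the inputs), `pair_flags` (per-pair mate
#'   host calls, the basis of pair-level contamination estimates) and
#'   `accounting` (stage counts, conserving every input read).
#' @export
screen_host_reads <- function(pairs, orphans = NULL, host_reference,
                              policy = mapping_policy()) {
  index <- if (is(host_reference, "seed_index")) host_reference
           else build_index(host_reference, policy$k)
  if (length(index$reference) == 0) config_error("empty host reference")
  if (is.null(orphans))
    orphans <- data.frame(read_id = character(0), mate = integer(0),
                          seq = character(0), qual = character(0),
                          stringsAsFactors = FALSE)
  maps_host <- function(seqs) {
    if (length(seqs) == 0) return(logical(0))
    res <- map_reads(setNames(seqs, sprintf("q%06d", seq_along(seqs))),
                     index, policy)
    sprintf("q%06d", seq_along(seqs)) %in% res$assignments$read_id
  }
  h1 <- maps_host(pairs$mate1)
  h2 <- maps_host(pairs$mate2)
  pair_host <- h1 | h2
  half <- xor(h1, h2)
  ho <- maps_host(orphans$seq)
  accounting <- data.frame(
    stage = c("input_reads", "host_assigned_reads", "half_host_pairs",
              "retained_reads"),
    count = c(2L * nrow(pairs) + nrow(orphans),
              2L * sum(pair_host) + sum(ho),
              sum(half),
              2L * sum(!pair_host) + sum(!ho)),
    stringsAsFactors = FALSE)
  list(retained_pairs = pairs[!pair_host, , drop = FALSE],
       retained_orphans = orphans[!ho, , drop = FALSE],
       host_pairs = pairs[pair_host, , drop = FALSE],
       host_orphans = orphans[ho, , drop = FALSE],
       pair_flags = data.frame(read_id = pairs$read_id,
                               mate1_host = h1, mate2_host = h2,
                               stringsAsFactors = FALSE),
       accounting = accounting)
}

#' Read-screen accounting from stage counts
#'
#' The arithmetic of the read-level screening ledger: given total reads and
#' host-assigned reads, the host-filtered (retained) count.
#'
#' @param total_reads total input reads.
#' @param host_reads reads removed as host.
#' @return data frame with `total_reads`, `host_reads`, `host_filtered`.
#' @export
read_screen_accounting <- function(total_reads, host_reads) {
  if (host_reads > total_reads)
    config_error("host_reads exceeds total_reads")
  data.frame(total_reads = total_reads, host_reads = host_reads,
             host_filtered = total_reads - host_reads)
}
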