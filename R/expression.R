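# RPKM quantification, cross-library correlation over shared orthogroups,
# and top-N expression ranking per Venn region.

#' RPKM from counts, lengths and library size
#'
#' RPKM = 10^9 * C / (N * L): reads per kilobase of transcript per million
#' mappable reads, where C is the mapped read count of the transcript, L
#' its length in bp and N the library's mapped-read total.
#'
#' @param counts named numeric vector of mapped read counts.
#' @param lengths named numeric vector of transcript lengths (bp), aligned
#'   with `counts` by name (or position when unnamed).
#' @param total_mapped mapped-read total N of the library; defaults to
#'   `sum(counts)`.
#' @return data frame with `unigene_id`, `count`, `length`, `rpkm`.
#' @export
compute_rpkm <- function(counts, lengths, total_mapped = sum(counts)) {
  if (any(lengths <= 0)) config_error("lengths must be positive")
  if (total_mapped <= 0) config_error("total_mapped must be positive")
  if (!is.null(names(counts)) && !is.null(names(lengths)))
    lengths <- lengths[names(counts)]
  if (length(counts) != length(lengths))
    config_error("counts and lengths differ in length")
  data.frame(unigene_id = if (is.null(names(counts)))
               as.character(seq_along(counts)) else names(counts),
             count = as.numeric(counts),
             length = as.numeric(lengths),
             rpkm = 1e9 * as.numeric(counts) /
               (total_mapped * as.numeric(lengths)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Expression correlation over shared orthogroups
#'
#' Pearson correlation of two libraries' expression over unigenes whose
#' orthogroups are shared, computed by default on log2(RPKM + 1) (recorded
#' in the output).
#'
#' @param exprA,exprB [compute_rpkm()] data frames.
#' @param shared_ids unigene ids to correlate (e.g. unigenes of shared
#'   orthogroups); must match `unigene_id` in both inputs.
#' @param log2_transform correlate on log2(RPKM + 1) (default) or raw RPKM.
#' @return a list with `r` (Pearson coefficient), `n` (points used) and
#'   `transform`.
#' @export
correlate_shared <- function(exprA, exprB, shared_ids,
                             log2_transform = TRUE) {
  a <- exprA$rpkm[match(shared_ids, exprA$unigene_id)]
  b <- exprB$rpkm[match(shared_ids, exprB$unigene_id)]
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 3) config_error("need at least 3 shared points")
  if (log2_transform) { a <- log2(a + 1); b <- log2(b + 1) }
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    config_error("zero variance in an expression vector")
  list(r = cor(a, b), n = length(a),
       transform = if (log2_transform) "log2(rpkm+1)" else "rpkm")
}

#' Top expressed unigenes within a Venn region
#'
#' The `n` highest-RPKM unigenes whose orthogroups fall in the requested
#' region, with deterministic id-ordered tie-breaking.
#'
#' @param expr a [compute_rpkm()] data frame.
#' @param og_assignment data frame with `unigene_id` and `orthogroup`.
#' @param partition a [venn_partition()].
#' @param region region name in the partition.
#' @param n list length (default 20).
#' @return `expr` rows of the region's top unigenes, ranked, with
#'   `orthogroup` and `rank` columns; empty (zero-row) when the region has
#'   no unigenes.
#' @export
top_expressed <- function(expr, og_assignment, partition, region, n = 20) {
  stopifnot(is(partition, "venn_partition"))
  if (!region %in% names(partition$regions))
    config_error("unknown region: %s", region)
  ogs <- partition$regions[[region]]
  og <- og_assignment$orthogroup[match(expr$unigene_id,
                                       og_assignment$unigene_id)]
  sub <- expr[!is.na(og) & og %in% ogs, , drop = FALSE]
  sub$orthogroup <- og[!is.na(og) & og %in% ogs]
  sub <- sub[order(-sub$rpkm, sub$unigene_id), , drop = FALSE]
  sub <- head(sub, n)
  if (nrow(sub)) sub$rank <- seq_len(nrow(sub))
  else sub$rank <- integer(0)
  rownames(sub) <- NULL
  sub
}
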