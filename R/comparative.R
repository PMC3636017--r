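# Orthogroup assignment, three-way Venn partitioning of transcriptomes,
# interface fractions, and GO Slim proportionality tests with residual
# flags.

#' Assign unigenes to orthogroups by best hit
#'
#' Each unigene with a significant best hit against the orthogroup-labeled
#' reference inherits the orthogroup of that hit; unigenes without a
#' significant hit stay unassigned.
#'
#' @param unigenes named character vector of sequences.
#' @param reference named character vector of labeled reference transcripts
#'   (or a prebuilt [build_index()]).
#' @param reference_labels data frame with columns `id` (reference record)
#'   and `orthogroup`; every reference record must be labeled.
#' @param policy a [mapping_policy()].
#' @return data frame with `unigene_id`, `orthogroup` (`NA` when
#'   unassigned), `best_subject`, `identity`, `score`.
#' @export
assign_orthogroups <- function(unigenes, reference, reference_labels,
                               policy = mapping_policy()) {
  index <- if (is(reference, "seed_index")) reference
           else build_index(reference, policy$k)
  missing <- setdiff(names(index$reference), reference_labels$id)
  if (length(missing))
    config_error("unlabeled reference record: %s", missing[1])
  hits <- search_hits(unigenes, index, policy, mode = "global")
  m <- match(names(unigenes), hits$query)
  og <- reference_labels$orthogroup[match(hits$subject[m],
                                          reference_labels$id)]
  data.frame(unigene_id = names(unigenes),
             orthogroup = og,
             best_subject = hits$subject[m],
             identity = hits$percent_identity[m],
             score = hits$score[m],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Three-way Venn partition of orthogroup sets
#'
#' Partitions the orthogroups observed in two interface transcriptomes (A,
#' B) and an above-ground reference into the seven disjoint Venn regions.
#'
#' @param setA,setB orthogroup ids observed in the interface transcriptome
#'   on host A / host B.
#' @param setRef orthogroup ids observed in the above-ground reference.
#' @return a list of class `venn_partition` with `regions` (named list of
#'   id vectors: `shared_all`, `interface_shared`, `A_interface_unique`,
#'   `B_interface_unique`, `A_above_shared`, `B_above_shared`,
#'   `above_unique`) and `counts` (named integer vector).
#' @export
venn_partition <- function(setA, setB, setRef) {
  setA <- unique(setA); setB <- unique(setB); setRef <- unique(setRef)
  regions <- list(
    shared_all = intersect(intersect(setA, setB), setRef),
    interface_shared = setdiff(intersect(setA, setB), setRef),
    A_interface_unique = setdiff(setdiff(setA, setB), setRef),
    B_interface_unique = setdiff(setdiff(setB, setA), setRef),
    A_above_shared = setdiff(intersect(setA, setRef), setB),
    B_above_shared = setdiff(intersect(setB, setRef), setA),
    above_unique = setdiff(setdiff(setRef, setA), setB))
  counts <- vapply(regions, length, integer(1))
  structure(list(regions = regions, counts = counts),
            class = "venn_partition")
}

#' Interface-only orthogroup fractions
#'
#' Percentages of the interface-only orthogroups (those absent from the
#' above-ground reference) that are shared between hosts or unique to one
#' host, rounded to the nearest percent.
#'
#' @param partition a [venn_partition()].
#' @return data frame with `region`, `count`, `percent` for
#'   `interface_shared`, `A_interface_unique`, `B_interface_unique`, plus
#'   the attribute `interface_only_total`.
#' @export
interface_fractions <- function(partition) {
  stopifnot(is(partition, "venn_partition"))
  cnt <- partition$counts[c("interface_shared", "A_interface_unique",
                            "B_interface_unique")]
  total <- sum(cnt)
  if (total == 0) config_error("no interface-only orthogroups")
  out <- data.frame(region = names(cnt), count = as.integer(unname(cnt)),
                    percent = unname(round(100 * cnt / total)),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "interface_only_total") <- total
  out
}

#' GO Slim proportionality test with residual flags
#'
#' Pearson chi-square test of a GO Slim category x Venn-region count table
#' (expected counts from the row/column margins, no continuity correction),
#' with per-cell Pearson residuals (O - E) / sqrt(E) and flags where the
#' residual exceeds `flag_bound` in magnitude.  Rows or columns with a zero
#' margin are dropped with a message; cells with expected count below 5 are
#' listed as caveats.
#'
#' @param table matrix (or table) of non-negative counts, GO Slim
#'   categories in rows (including an explicit "no_category" row where
#'   applicable) and Venn regions in columns.
#' @param flag_bound magnitude bound for flagging residuals (default 4).
#' @return a list of class `goslim_chisq`: `statistic`, `df`, `p_value`,
#'   `observed`, `expected`, `residuals`, `flags` (character matrix `"+"`,
#'   `"-"` or `""`), `low_expected` (data frame of cells with expected
#'   < 5), `dropped` (names of dropped rows/columns).
#' @export
goslim_chi_square <- function(table, flag_bound = 4) {
  m <- as.matrix(table)
  if (any(m < 0)) config_error("counts must be non-negative")
  dropped <- character(0)
  zr <- rowSums(m) == 0
  zc <- colSums(m) == 0
  if (any(zr) || any(zc)) {
    dropped <- c(rownames(m)[zr], colnames(m)[zc])
    message("dropping zero-margin rows/columns: ",
            paste(dropped, collapse = ", "))
    m <- m[!zr, !zc, drop = FALSE]
  }
  if (nrow(m) < 2 || ncol(m) < 2)
    config_error("table must have at least 2 rows and 2 columns after dropping zero margins")
  ct <- suppressWarnings(chisq.test(m, correct = FALSE))
  res <- ct$residuals            # Pearson residuals (O - E) / sqrt(E)
  flags <- matrix("", nrow(m), ncol(m), dimnames = dimnames(m))
  flags[res > flag_bound] <- "+"
  flags[res < -flag_bound] <- "-"
  low <- which(ct$expected < 5, arr.ind = TRUE)
  low_expected <- data.frame(
    row = rownames(m)[low[, 1]], column = colnames(m)[low[, 2]],
    expected = ct$expected[low], stringsAsFactors = FALSE)
  structure(list(statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = unname(ct$p.value),
                 observed = m, expected = ct$expected,
                 residuals = res, flags = flags,
                 low_expected = low_expected, dropped = dropped),
            class = "goslim_chisq")
}

#' Build a GO Slim x Venn-region contingency table from unigene labels
#'
#' Counts unigenes per (GO Slim category, Venn region of the unigene's
#' orthogroup) for one transcriptome.
#'
#' @param unigenes data frame with columns `goslim` and `region` (as in
#'   [simulate_comparative_labels()]'s `unigenes`).
#' @param regions which region columns to keep (default: all present).
#' @return count matrix (categories x regions).
#' @export
goslim_contingency <- function(unigenes, regions = NULL) {
  tab <- table(unigenes$goslim, unigenes$region)
  if (!is.null(regions)) tab <- tab[, intersect(regions, colnames(tab)),
                                    drop = FALSE]
  unclass(as.matrix(tab))
}
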