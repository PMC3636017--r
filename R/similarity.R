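# Self-contained nucleotide similarity engine: k-mer seeded, banded
# dynamic-programming alignment producing percent identity, best hits and
# read-to-transcript mapping.  It fills the role BLASTn / read mappers play
# at desk scale, with the alignment core in compiled code (src/align.cpp).

#' Alignment and mapping policy
#'
#' Scoring and acceptance parameters shared by all similarity operations.
#' The default costs follow the read-mapping parameterization the package
#' replays (mismatch cost 2, insertion cost 3, deletion cost 3, length
#' fraction 0.5, similarity 0.8); match reward is +1.  `min_score` is the
#' raw-score significance surrogate standing in for a BLAST e-value cutoff:
#' hits scoring below it are treated as no-hit.
#'
#' @param length_fraction minimum fraction of the query that must be aligned
#'   for a read to count as mapped.
#' @param min_similarity minimum identity (as a fraction) on the aligned
#'   part for a read to count as mapped.
#' @param match match reward (positive).
#' @param mismatch,insertion,deletion positive costs subtracted per
#'   mismatch, per query base aligned to a gap, and per subject base aligned
#'   to a gap.
#' @param k seed k-mer length (>= 4).
#' @param band half-width of the alignment band around the seed diagonal
#'   (global mode widens the corridor automatically to cover any length
#'   difference).
#' @param min_score minimum alignment score for a hit to be significant.
#' @param max_candidates number of top seed-sharing subjects evaluated per
#'   query and strand.
#' @return a list of class `mapping_policy`.
#' @export
mapping_policy <- function(length_fraction = 0.5, min_similarity = 0.8,
                           match = 1L, mismatch = 2L, insertion = 3L,
                           deletion = 3L, k = 11L, band = 32L,
                           min_score = 20L, max_candidates = 8L) {
  if (length_fraction <= 0 || length_fraction > 1 ||
      min_similarity <= 0 || min_similarity > 1)
    config_error("length_fraction and min_similarity must lie in (0, 1]")
  if (any(c(match, mismatch, insertion, deletion) <= 0))
    config_error("alignment costs must be positive")
  if (k < 4) config_error("seed length k must be at least 4")
  structure(list(length_fraction = length_fraction,
                 min_similarity = min_similarity,
                 match = as.integer(match), mismatch = as.integer(mismatch),
                 insertion = as.integer(insertion),
                 deletion = as.integer(deletion),
                 k = as.integer(k), band = as.integer(band),
                 min_score = as.integer(min_score),
                 max_candidates = as.integer(max_candidates)),
            class = "mapping_policy")
}

#' Build a k-mer seed index over reference sequences
#'
#' Every length-`k` substring of every reference (forward strand) is stored
#' with its subject and offset.  Queries are searched on both strands by
#' reverse-complementing the query, so the index itself is strand-naive.
#'
#' @param reference named character vector (or `DNAStringSet`) of reference
#'   sequences.
#' @param k seed length; must be at least 4 and no longer than the shortest
#'   reference.
#' @return a list of class `seed_index` with the postings environment, the
#'   reference sequences and `k`.
#' @export
build_index <- function(reference, k = 11L) {
  if (is(reference, "DNAStringSet"))
    reference <- setNames(as.character(reference), names(reference))
  if (length(reference) == 0) config_error("empty reference set")
  if (is.null(names(reference)) || anyDuplicated(names(reference)))
    config_error("reference sequences must carry unique names")
  k <- as.integer(k)
  if (k < 4) config_error("seed length k must be at least 4")
  if (min(nchar(reference)) < k)
    config_error("k exceeds the shortest reference length")
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (si in seq_along(reference)) {
    s <- reference[[si]]
    L <- nchar(s)
    kmers <- substring(s, seq_len(L - k + 1L), k:L)
    for (p in seq_along(kmers)) {
      km <- kmers[[p]]
      env[[km]] <- rbind(env[[km]], c(si, p))
    }
  }
  structure(list(postings = env, reference = reference, k = k),
            class = "seed_index")
}

#' Look up the postings of one k-mer
#'
#' @param index a [build_index()] result.
#' @param kmer character k-mer.
#' @return integer matrix with columns `subject` (index into the reference)
#'   and `pos` (1-based offset), or `NULL` when absent.
#' @export
index_postings <- function(index, kmer) {
  m <- index$postings[[kmer]]
  if (is.null(m)) return(NULL)
  colnames(m) <- c("subject", "pos")
  m
}

#' Global percent identity between two sequences
#'
#' Banded global (end-to-end) alignment under the policy's costs; identity
#' is matches over alignment columns, gap columns included, following the
#' usual BLAST-style reporting the package's thresholds assume.  The band
#' corridor always covers the length difference between the sequences, so a
#' connecting path exists for any input.
#'
#' @param query,subject sequences (character).
#' @param policy a [mapping_policy()].
#' @return one-row data frame: `query`, `subject`, `percent_identity`,
#'   `alignment_length`, `score`, `strand` (`"+"`; strand selection happens
#'   in [best_hit()]).
#' @export
align_identity <- function(query, subject, policy = mapping_policy()) {
  if (nchar(query) == 0 || nchar(subject) == 0)
    config_error("sequences must be nonempty")
  r <- nw_banded_cpp(query, subject, policy$match, policy$mismatch,
                     policy$insertion, policy$deletion, policy$band)
  data.frame(query = if (is.null(names(query))) NA_character_ else
               names(query),
             subject = if (is.null(names(subject))) NA_character_ else
               names(subject),
             percent_identity = 100 * r$matches / max(1L, r$columns),
             alignment_length = r$columns,
             score = r$score,
             strand = "+",
             stringsAsFactors = FALSE)
}

# Seed-derived candidate subjects for one query string against an index:
# for each subject, the modal seed diagonal and its support.
seed_candidates <- function(q, index) {
  k <- index$k
  L <- nchar(q)
  if (L < k) return(NULL)
  kmers <- substring(q, seq_len(L - k + 1L), k:L)
  hits <- lapply(seq_along(kmers), function(p) {
    m <- index$postings[[kmers[[p]]]]
    if (is.null(m)) return(NULL)
    cbind(m[, 1], m[, 2] - p)   # subject, diagonal (0-based offset)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits) || nrow(hits) == 0) return(NULL)
  out <- list()
  for (si in unique(hits[, 1])) {
    d <- hits[hits[, 1] == si, 2]
    tab <- table(d)
    best <- which.max(tab)
    out[[length(out) + 1L]] <- c(subject = si,
                                 diag = as.integer(names(tab)[best]),
                                 support = as.integer(tab[best]),
                                 total = length(d))
  }
  m <- do.call(rbind, out)
  m[order(-m[, "total"], m[, "subject"]), , drop = FALSE]
}

# Align one query against one subject in the requested mode; returns a hit
# row (list) or NULL.
align_candidate <- function(q, sname, s, strand, diag, policy, mode) {
  if (mode == "global") {
    r <- nw_banded_cpp(q, s, policy$match, policy$mismatch, policy$insertion,
                       policy$deletion, policy$band)
    qcov <- 1
  } else {
    r <- sw_banded_cpp(q, s, diag, policy$match, policy$mismatch,
                       policy$insertion, policy$deletion, policy$band)
    if (r$score <= 0) return(NULL)
    qcov <- (r$qend - r$qstart + 1) / nchar(q)
  }
  list(subject = sname,
       percent_identity = 100 * r$matches / max(1L, r$columns),
       alignment_length = r$columns, score = r$score, strand = strand,
       query_coverage = qcov)
}

#' Best hit of a query against an indexed reference
#'
#' Seeds on both strands, evaluates the top seed-sharing subjects with a
#' banded alignment, and returns the best hit under the declared tie-break:
#' score, then identity, then alignment length, then lexicographically
#' smallest subject id.  Returns no hit when no seed matches or the best
#' score falls below `policy$min_score`.
#'
#' @param query single sequence (character, optionally named).
#' @param index a [build_index()] result.
#' @param policy a [mapping_policy()].
#' @param mode `"global"` for end-to-end identity (unigene screening) or
#'   `"local"` for read mapping.
#' @return one-row data frame (`query`, `subject`, `percent_identity`,
#'   `alignment_length`, `score`, `strand`, `query_coverage`), or `NULL`
#'   for no hit.
#' @export
best_hit <- function(query, index, policy = mapping_policy(),
                     mode = c("global", "local")) {
  mode <- match.arg(mode)
  qname <- if (is.null(names(query))) NA_character_ else names(query)[1]
  q <- unname(query[[1]])
  hits <- list()
  for (strand in c("+", "-")) {
    qs <- if (strand == "+") q else revcomp(q)
    cand <- seed_candidates(qs, index)
    if (is.null(cand)) next
    n_eval <- min(nrow(cand), policy$max_candidates)
    for (ci in seq_len(n_eval)) {
      si <- cand[ci, "subject"]
      h <- align_candidate(qs, names(index$reference)[si],
                           index$reference[[si]], strand,
                           cand[ci, "diag"], policy, mode)
      if (!is.null(h)) hits[[length(hits) + 1L]] <- h
    }
  }
  if (length(hits) == 0) return(NULL)
  df <- do.call(rbind, lapply(hits, as.data.frame,
                              stringsAsFactors = FALSE))
  df <- df[order(-df$score, -df$percent_identity, -df$alignment_length,
                 df$subject), , drop = FALSE]
  best <- df[1, , drop = FALSE]
  if (best$score < policy$min_score) return(NULL)
  cbind(data.frame(query = qname, stringsAsFactors = FALSE), best,
        row.names = NULL)
}

#' All best hits of a query set against an indexed reference
#'
#' @param queries named character vector of query sequences.
#' @param index a [build_index()] result.
#' @param policy a [mapping_policy()].
#' @param mode alignment mode, see [best_hit()].
#' @return data frame of best-hit rows, one per query with a hit, in BLAST
#'   tabular column order (`query`, `subject`, `percent_identity`,
#'   `alignment_length`, `score`, `strand`, `query_coverage`).
#' @export
search_hits <- function(queries, index, policy = mapping_policy(),
                        mode = c("global", "local")) {
  mode <- match.arg(mode)
  rows <- lapply(seq_along(queries), function(i)
    best_hit(queries[i], index, policy, mode))
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(query = character(0), subject = character(0),
                      percent_identity = numeric(0),
                      alignment_length = integer(0), score = integer(0),
                      strand = character(0), query_coverage = numeric(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Map reads to a reference and count per-transcript reads
#'
#' A read counts toward a transcript iff its best local hit covers at least
#' `length_fraction` of the read and has identity at least `min_similarity`
#' on the aligned part; each mapped read is assigned to exactly one
#' transcript (its best hit).
#'
#' @param reads named character vector of read sequences.
#' @param reference named character vector of transcripts, or a prebuilt
#'   [build_index()].
#' @param policy a [mapping_policy()].
#' @return a list with `assignments` (data frame `read_id`, `subject`,
#'   `percent_identity`, `query_coverage`, `score` for mapped reads) and
#'   `counts` (named integer vector over all reference transcripts).
#' @export
map_reads <- function(reads, reference, policy = mapping_policy()) {
  index <- if (is(reference, "seed_index")) reference
           else build_index(reference, policy$k)
  hits <- search_hits(reads, index, policy, mode = "local")
  ok <- hits[hits$query_coverage >= policy$length_fraction &
             hits$percent_identity >= 100 * policy$min_similarity, ,
             drop = FALSE]
  counts <- setNames(integer(length(index$reference)),
                     names(index$reference))
  if (nrow(ok)) {
    tab <- table(ok$subject)
    counts[names(tab)] <- as.integer(tab)
  }
  list(assignments = data.frame(read_id = ok$query, subject = ok$subject,
                                percent_identity = ok$percent_identity,
                                query_coverage = ok$query_coverage,
                                score = ok$score,
                                stringsAsFactors = FALSE),
       counts = counts)
}
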