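# Independent oracles and small fixture builders shared across the suite.
# Every oracle is implemented independently of the code path it checks.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# Brute-force end-trimming oracle: peel single low-quality bases off either
# end until both ends are at/above the floor, then apply the survival rule.
oracle_trim <- function(seq, qual, floorq = 20L, min_frac = 0.5) {
  q <- utf8ToInt(qual) - 33L
  a <- 1L
  b <- length(q)
  while (a <= b && q[a] < floorq) a <- a + 1L
  while (b >= a && q[b] < floorq) b <- b - 1L
  if (a > b || (b - a + 1) < min_frac * length(q))
    return(NULL)
  list(seq = substr(seq, a, b), qual = substr(qual, a, b))
}

# Full (unbanded) dynamic-programming oracle via pairwise alignment with
# the same linear-gap scoring as the banded engine.
oracle_global <- function(a, b, match = 1, mismatch = 2, gap = 3) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = -mismatch,
                                                  baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(a, b, substitutionMatrix = mat,
                                      gapOpening = 0, gapExtension = gap,
                                      type = "global")
  list(score = Biostrings::score(pa),
       matches = Biostrings::nmatch(pa),
       columns = Biostrings::nchar(pa))
}

# Local-alignment oracle with the same scoring, both strands; returns the
# accepted best assignment of a read under the mapping rule, or NA.
oracle_read_assign <- function(read, reference, policy) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = policy$match,
                                                  mismatch = -policy$mismatch,
                                                  baseOnly = TRUE)
  best <- NULL
  for (strand in c("+", "-")) {
    q <- if (strand == "+") read else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
    for (sname in names(reference)) {
      pa <- Biostrings::pairwiseAlignment(q, reference[[sname]],
                                          substitutionMatrix = mat,
                                          gapOpening = 0,
                                          gapExtension = policy$insertion,
                                          type = "local")
      sc <- Biostrings::score(pa)
      if (sc <= 0) next
      idn <- 100 * Biostrings::nmatch(pa) / Biostrings::nchar(pa)
      qr <- Biostrings::pattern(pa)   # aligned query range in read coords
      cov <- (Biostrings::end(qr) - Biostrings::start(qr) + 1) / nchar(read)
      cand <- data.frame(subject = sname, score = sc, identity = idn,
                         columns = Biostrings::nchar(pa), coverage = cov,
                         stringsAsFactors = FALSE)
      best <- rbind(best, cand)
    }
  }
  if (is.null(best)) return(NA_character_)
  best <- best[order(-best$score, -best$identity, -best$columns,
                     best$subject), ]
  top <- best[1, ]
  if (top$score < policy$min_score || top$coverage < policy$length_fraction ||
      top$identity < 100 * policy$min_similarity)
    return(NA_character_)
  top$subject
}

# O(n^2) containment-deduplication oracle: a sequence is removed iff some
# other sequence that sorts earlier (longer, or same length with a smaller
# name) contains it on either strand.
oracle_dedup <- function(seqs) {
  rc <- function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  nm <- names(seqs)
  keep <- rep(TRUE, length(seqs))
  ord <- order(-nchar(seqs), nm)
  for (pos in seq_along(ord)) {
    i <- ord[pos]
    if (pos == 1) next
    for (pos2 in seq_len(pos - 1)) {
      j <- ord[pos2]
      if (!keep[j]) next
      if (grepl(seqs[[i]], seqs[[j]], fixed = TRUE) ||
          grepl(rc(seqs[[i]]), seqs[[j]], fixed = TRUE)) {
        keep[i] <- FALSE
        break
      }
    }
  }
  sort(nm[keep])
}

# Small-simulation configuration used by several suites: quick but with a
# wide (~18-point) host/parasite divergence gap.  Arguments in ... override
# the small-scale defaults.
small_sim <- function(seed, ...) {
  base <- list(n_parasite_transcripts = 30L, n_host_transcripts = 20L,
               n_microbial = 6L, microbial_contamination = 3L,
               transcript_length_range = c(300L, 500L),
               n_read_pairs = 400L)
  override <- list(...)
  base[names(override)] <- override
  do.call(sim_config, c(list(seed = seed), base))
}

# Build disjoint orthogroup-id pools realizing given Venn region counts,
# returning the three observed sets.
venn_fixture <- function(shared_all, interface_shared, A_unique, B_unique,
                         A_above, B_above, above_unique) {
  counts <- c(shared_all, interface_shared, A_unique, B_unique, A_above,
              B_above, above_unique)
  ids <- split(sprintf("OG%05d", seq_len(sum(counts))),
               factor(rep(seq_along(counts), counts),
                      levels = seq_along(counts)))
  list(A = c(ids[[1]], ids[[2]], ids[[3]], ids[[5]]),
       B = c(ids[[1]], ids[[2]], ids[[4]], ids[[6]]),
       Ref = c(ids[[1]], ids[[5]], ids[[6]], ids[[7]]))
}
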