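# Assembly post-processing and the staged classification cascade assigning
# every unigene to exactly one category with a complete accounting table.

#' Remove exact-duplicate and contained sequences
#'
#' Keeps the longest representative of any group of sequences where one is
#' identical to, or an exact substring of, another on either strand.
#'
#' @param unigenes named character vector of sequences.
#' @return a list with `retained` and `removed` (named character vectors)
#'   and `removed_reason` (data frame `unigene_id`, `container`).
#' @export
deduplicate <- function(unigenes) {
  if (length(unigenes) == 0)
    return(list(retained = unigenes, removed = unigenes[0],
                removed_reason = data.frame(unigene_id = character(0),
                                            container = character(0))))
  ord <- order(-nchar(unigenes), names(unigenes))
  retained_idx <- integer(0)
  removed <- character(0)
  container <- character(0)
  for (i in ord) {
    s <- unigenes[[i]]
    rc <- revcomp(s)
    hit <- NA_character_
    for (j in retained_idx) {
      big <- unigenes[[j]]
      if (grepl(s, big, fixed = TRUE) || grepl(rc, big, fixed = TRUE)) {
        hit <- names(unigenes)[j]
        break
      }
    }
    if (is.na(hit)) {
      retained_idx <- c(retained_idx, i)
    } else {
      removed <- c(removed, names(unigenes)[i])
      container <- c(container, hit)
    }
  }
  retained_idx <- sort(retained_idx)
  list(retained = unigenes[retained_idx],
       removed = unigenes[names(unigenes) %in% removed],
       removed_reason = data.frame(unigene_id = removed,
                                   container = container,
                                   stringsAsFactors = FALSE))
}

#' Translatability filter by longest open reading frame
#'
#' A lightweight stand-in for frame-shift screening: a unigene is kept iff
#' its longest stop-free stretch of codons, over all six reading frames,
#' spans at least `min_orf_fraction` of the sequence length.
#'
#' @param unigenes named character vector of sequences.
#' @param min_orf_fraction minimum longest-ORF length as a fraction of the
#'   sequence length.
#' @return data frame with `unigene_id`, `longest_orf` (nt), `orf_fraction`,
#'   `keep`, and `reason` for drops.
#' @export
translatability_filter <- function(unigenes, min_orf_fraction = 0.3) {
  if (min_orf_fraction < 0 || min_orf_fraction > 1)
    config_error("min_orf_fraction must lie in [0, 1]")
  longest_orf <- function(s) {
    L <- nchar(s)
    if (L < 3) return(0L)
    best <- 0L
    for (strand_seq in c(s, revcomp(s))) {
      for (off in 0:2) {
        n_codon <- (nchar(strand_seq) - off) %/% 3L
        if (n_codon == 0) next
        aa <- substring(strand_seq,
                        off + seq(1L, by = 3L, length.out = n_codon),
                        off + seq(3L, by = 3L, length.out = n_codon))
        stops <- c(0L, which(aa %in% c("TAA", "TAG", "TGA")), n_codon + 1L)
        run <- max(diff(stops)) - 1L
        best <- max(best, 3L * run)
      }
    }
    best
  }
  orf <- vapply(unigenes, longest_orf, integer(1))
  # denominator is the codon-aligned length, so a fully stop-free frame
  # scores fraction 1 regardless of trailing partial codons
  frac <- orf / pmax(3L, 3L * (nchar(unigenes) %/% 3L))
  keep <- nchar(unigenes) >= 3 & frac >= min_orf_fraction
  reason <- ifelse(nchar(unigenes) < 3, "shorter than one codon",
                   ifelse(keep, "", "longest ORF below fraction"))
  data.frame(unigene_id = names(unigenes), longest_orf = orf,
             orf_fraction = unname(frac), keep = unname(keep),
             reason = reason, row.names = NULL, stringsAsFactors = FALSE)
}

#' Staged unigene classification cascade
#'
#' Assigns every unigene to exactly one category by the declared stage
#' order: (1) host screen - best-hit identity to the host database at or
#' above `tau_host` makes it `host`; (2) parasite screen - identity to the
#' parasite reference at or above `tau_parasite` makes it `parasite`;
#' (3) labeled-reference screen - a significant hit against a
#' kingdom-labeled database makes it `other_plant` or `non_plant` by label;
#' otherwise `no_hit`.  Plant-labeled and no-hit unigenes are pooled with
#' the parasite-screen positives into the putative-parasite pool in the
#' accounting, mirroring the published count structure.  Unigenes at or
#' above both thresholds go to `host` (conservative against contamination);
#' they are reported in the `ambiguous` attribute as the order-sensitive
#' band.
#'
#' @param unigenes named character vector of sequences.
#' @param host_db,parasite_db named character vectors (or prebuilt
#'   [build_index()] objects).
#' @param labeled_db optional named character vector of labeled reference
#'   sequences for stage 3.
#' @param labels data frame labeling stage 3: either by reference record
#'   (`id`, `kingdom`) to be joined to `labeled_db` hits, or a precomputed
#'   per-unigene table (`unigene_id`, `kingdom`) used directly when
#'   `labeled_db` is `NULL`.  `kingdom` must be `"plant"` or `"non_plant"`.
#' @param tau_host,tau_parasite identity thresholds in percent (calibrate
#'   with [select_threshold()]; 95 replays the published choice).
#' @param policy a [mapping_policy()]; its `min_score` is the significance
#'   threshold of the stage-3 screen.
#' @return a list with `classified` (data frame `unigene_id`, `category`,
#'   `stage`, `best_subject`, `identity`, `score`), `accounting` (data
#'   frame of stage counts) and `ambiguous` (ids at/above both nucleotide
#'   thresholds).
#' @export
classify_cascade <- function(unigenes, host_db, parasite_db,
                             labeled_db = NULL, labels = NULL,
                             tau_host = 95, tau_parasite = 95,
                             policy = mapping_policy()) {
  if (length(unigenes) == 0) config_error("empty unigene set")
  host_index <- if (is(host_db, "seed_index")) host_db
                else build_index(host_db, policy$k)
  par_index <- if (is(parasite_db, "seed_index")) parasite_db
               else build_index(parasite_db, policy$k)
  host_hits <- search_hits(unigenes, host_index, policy, mode = "global")
  par_hits <- search_hits(unigenes, par_index, policy, mode = "global")
  hid <- setNames(rep(NA_real_, length(unigenes)), names(unigenes))
  hsub <- setNames(rep(NA_character_, length(unigenes)), names(unigenes))
  hsc <- hid
  hid[host_hits$query] <- host_hits$percent_identity
  hsub[host_hits$query] <- host_hits$subject
  hsc[host_hits$query] <- host_hits$score
  pid <- setNames(rep(NA_real_, length(unigenes)), names(unigenes))
  psub <- setNames(rep(NA_character_, length(unigenes)), names(unigenes))
  psc <- pid
  pid[par_hits$query] <- par_hits$percent_identity
  psub[par_hits$query] <- par_hits$subject
  psc[par_hits$query] <- par_hits$score

  is_host <- !is.na(hid) & hid >= tau_host
  is_par <- !is.na(pid) & pid >= tau_parasite
  ambiguous <- names(unigenes)[is_host & is_par]

  category <- rep(NA_character_, length(unigenes))
  stage <- rep("unresolved", length(unigenes))
  best_subject <- rep(NA_character_, length(unigenes))
  identity <- rep(NA_real_, length(unigenes))
  score <- rep(NA_real_, length(unigenes))

  category[is_host] <- "host"
  stage[is_host] <- "host_screen"
  best_subject[is_host] <- hsub[is_host]
  identity[is_host] <- hid[is_host]
  score[is_host] <- hsc[is_host]

  sel <- !is_host & is_par
  category[sel] <- "parasite"
  stage[sel] <- "parasite_screen"
  best_subject[sel] <- psub[sel]
  identity[sel] <- pid[sel]
  score[sel] <- psc[sel]

  rest <- which(is.na(category))
  if (length(rest)) {
    if (!is.null(labeled_db)) {
      if (is.null(labels) || !all(c("id", "kingdom") %in% names(labels)))
        config_error("labeled_db requires a labels table with columns id, kingdom")
      lab_index <- build_index(labeled_db, policy$k)
      lhits <- search_hits(unigenes[rest], lab_index, policy,
                           mode = "global")
      for (r in seq_len(nrow(lhits))) {
        kg <- labels$kingdom[match(lhits$subject[r], labels$id)]
        if (is.na(kg))
          config_error("no taxon label for reference record %s",
                       lhits$subject[r])
        i <- match(lhits$query[r], names(unigenes))
        category[i] <- if (kg == "plant") "other_plant" else "non_plant"
        stage[i] <- "protein_screen"
        best_subject[i] <- lhits$subject[r]
        identity[i] <- lhits$percent_identity[r]
        score[i] <- lhits$score[r]
      }
    } else if (!is.null(labels)) {
      if (!all(c("unigene_id", "kingdom") %in% names(labels)))
        config_error("per-unigene labels need columns unigene_id, kingdom")
      m <- match(names(unigenes)[rest], labels$unigene_id)
      hit <- !is.na(m)
      category[rest[hit]] <- ifelse(labels$kingdom[m[hit]] == "plant",
                                    "other_plant", "non_plant")
      stage[rest[hit]] <- "protein_screen"
    }
  }
  category[is.na(category)] <- "no_hit"
  classified <- data.frame(unigene_id = names(unigenes),
                           category = category, stage = stage,
                           best_subject = best_subject, identity = identity,
                           score = score, row.names = NULL,
                           stringsAsFactors = FALSE)
  n_cat <- function(x) sum(category == x)
  accounting <- cascade_accounting(total = length(unigenes),
                                   host = n_cat("host"),
                                   non_plant = n_cat("non_plant"),
                                   parasite_hits = n_cat("parasite"),
                                   other_plant = n_cat("other_plant"),
                                   no_hits = n_cat("no_hit"))
  list(classified = classified, accounting = accounting,
       ambiguous = ambiguous)
}

#' Cascade accounting table
#'
#' The count arithmetic of the classification cascade: host and non-plant
#' unigenes are removed, and the remainder (parasite-screen positives,
#' other-plant hits, and no-hits) forms the putative-parasite pool.  Errors
#' if the category counts do not conserve the total.
#'
#' @param total input unigene count.
#' @param host,non_plant,parasite_hits,other_plant,no_hits category counts.
#' @return data frame with one row per ledger line (`stage`, `count`),
#'   including the derived `putative_parasite_pool`.
#' @export
cascade_accounting <- function(total, host, non_plant, parasite_hits,
                               other_plant, no_hits) {
  pool <- total - host - non_plant
  if (pool != parasite_hits + other_plant + no_hits)
    config_error("category counts do not conserve the unigene total")
  data.frame(stage = c("unigenes_total", "host_unigenes",
                       "non_plant_unigenes", "putative_parasite_pool",
                       "parasite_hits", "other_plant_hits", "no_hits"),
             count = c(total, host, non_plant, pool, parasite_hits,
                       other_plant, no_hits),
             stringsAsFactors = FALSE)
}

#' Assembly summary statistics
#'
#' @param unigenes named character vector of sequences.
#' @param min_length optional subset floor (e.g. 500 for the >500 bp
#'   subset); statistics are computed on sequences at least this long.
#' @return data frame with `n`, `total_bp`, `min_length`, `max_length`,
#'   `n50`.
#' @export
assembly_stats <- function(unigenes, min_length = 0) {
  lens <- nchar(unigenes)
  lens <- lens[lens >= min_length]
  if (length(lens) == 0) config_error("no sequences of the requested length")
  data.frame(n = length(lens), total_bp = sum(lens),
             min_length = min(lens), max_length = max(lens),
             n50 = n50(lens))
}

#' N50 of a set of lengths
#'
#' Length of the shortest sequence in the smallest prefix of the
#' descending-length ordering whose cumulative length reaches half the
#' total.
#'
#' @param lengths integer vector of sequence lengths.
#' @return the N50 length.
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0) config_error("empty length set")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}
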