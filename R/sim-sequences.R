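# Sequence-level simulators: reference transcript sets with known homology
# structure, plus the mixed "assembly" of unigenes with ground-truth origins.

# Random mRNA-like transcript: short UTRs flanking a stop-free CDS built
# from the 61 non-stop codons, so ORF-based translatability filters behave
# as they would on real coding transcripts.
random_transcripts <- function(n, length_range) {
  codons <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1, paste,
                  collapse = "")
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  lens <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
  vapply(lens, function(L) {
    utr5 <- min(30L, max(0L, L - 60L))
    utr3 <- max(0L, L - utr5 - 3L * ((L - utr5 - 20L) %/% 3L))
    n_codon <- (L - utr5 - utr3) %/% 3L
    utr3 <- L - utr5 - 3L * n_codon
    paste0(paste(sample(DNA_BASES, utr5, replace = TRUE), collapse = ""),
           paste(sample(codons, n_codon, replace = TRUE), collapse = ""),
           paste(sample(DNA_BASES, utr3, replace = TRUE), collapse = ""))
  }, character(1))
}

# Independent per-site substitutions at rate d; each hit site changes to one
# of the three other bases.  Substitution-only by design: it keeps the
# expected pairwise identity analytic (~= 1 - d).
mutate_sequences <- function(seqs, d) {
  if (d == 0) return(seqs)
  vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- which(runif(length(ch)) < d)
    if (length(hit)) {
      ch[hit] <- vapply(ch[hit], function(b)
        sample(setdiff(DNA_BASES, b), 1L), character(1))
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate labeled reference transcript sets
#'
#' Generates every sequence collection the deconvolution pipeline consumes,
#' with known homology structure and ground truth: the parasite interface
#' assembly pool, a parasite reference library diverged from it at the
#' within-parasite rate, two host species (cDNA reference plus an EST-style
#' collection per host) diverged from the parasite at the parasite-host
#' rate, a non-parasitic control relative, a small microbial (non-plant)
#' set, and a mixed "interface assembly" of unigenes in which a known
#' fraction of host and microbial transcripts is planted.
#'
#' Each parasite gene family carries an orthogroup id, a Venn-region
#' assignment and a GO Slim category (with the configured enrichment planted
#' by region), so the downstream comparative analyses can be checked against
#' ground truth.
#'
#' @param config a [sim_config()].
#' @param outdir optional directory; when given, every set is written as
#'   FASTA and the label/ground-truth tables as TSV.
#' @return a list with elements `sets` (named list of named character
#'   vectors of sequences: `parasite_assembly`, `parasite_ref`, `hostA`,
#'   `hostA_est`, `hostB`, `hostB_est`, `control`, `microbial`,
#'   `mixed_unigenes`), `families` (per-family orthogroup/region/GO Slim
#'   table with expression weights), `unigene_truth` (per-unigene origin
#'   table for the mixed assembly) and `config`.
#' @export
simulate_reference_sets <- function(config, outdir = NULL) {
  stopifnot(is(config, "sim_config"))
  set.seed(config$seed)
  n_fam <- config$n_parasite_transcripts
  n_host <- config$n_host_transcripts

  pool <- random_transcripts(n_fam, config$transcript_length_range)
  names(pool) <- sprintf("TvInt_%04d", seq_len(n_fam))

  regions <- sample(names(config$region_weights), n_fam, replace = TRUE,
                    prob = config$region_weights)
  goslim <- draw_goslim(regions, config)
  families <- data.frame(family = seq_len(n_fam),
                         transcript_id = names(pool),
                         orthogroup = sprintf("OG%04d", seq_len(n_fam)),
                         region = regions,
                         goslim = goslim,
                         length = nchar(pool),
                         expr_weight = rnbinom(n_fam, mu = config$nb_mean,
                                               size = config$nb_size) + 1L,
                         stringsAsFactors = FALSE)

  parasite_ref <- mutate_sequences(pool, config$divergence_within_parasite)
  names(parasite_ref) <- sprintf("TvRef_%04d", seq_len(n_fam))

  make_host <- function(prefix) {
    n_hom <- round(config$host_homolog_fraction * n_host)
    n_hom <- min(n_hom, n_fam)
    fams <- sample(n_fam, n_hom)
    hom <- mutate_sequences(pool[fams], config$divergence_parasite_host)
    novel <- random_transcripts(n_host - n_hom, config$transcript_length_range)
    seqs <- c(hom, novel)
    names(seqs) <- sprintf("%s_%04d", prefix, seq_len(n_host))
    attr(seqs, "homolog_family") <- c(fams, rep(NA_integer_, n_host - n_hom))
    seqs
  }
  hostA <- make_host("HostA")
  hostB <- make_host("HostB")
  hostA_est <- mutate_sequences(hostA, config$divergence_within_host)
  names(hostA_est) <- sub("HostA", "HostAest", names(hostA))
  hostB_est <- mutate_sequences(hostB, config$divergence_within_host)
  names(hostB_est) <- sub("HostB", "HostBest", names(hostB))

  ctrl_fams <- sample(n_fam, min(n_fam, n_host))
  control <- mutate_sequences(pool[ctrl_fams], config$divergence_control)
  names(control) <- sprintf("Ctrl_%04d", seq_along(control))

  microbial <- random_transcripts(config$n_microbial,
                                  config$transcript_length_range)
  names(microbial) <- sprintf("Mic_%03d", seq_len(config$n_microbial))

  # Mixed interface "assembly": every parasite unigene plus planted host and
  # microbial contaminants (read-level screening leakage at the unigene
  # level), each with a ground-truth origin.
  n_host_uni <- round(config$unigene_contamination_fraction * n_fam)
  host_pick <- sample(n_host, min(n_host, n_host_uni))
  mic_pick <- seq_len(min(config$n_microbial, config$microbial_contamination))
  mixed <- c(unname(pool), unname(hostA[host_pick]),
             unname(microbial[mic_pick]))
  unigene_truth <- data.frame(
    unigene_id = sprintf("U%05d", seq_along(mixed)),
    origin = c(rep("parasite", n_fam), rep("hostA", length(host_pick)),
               rep("microbial", length(mic_pick))),
    source_id = c(names(pool), names(hostA)[host_pick],
                  names(microbial)[mic_pick]),
    orthogroup = c(families$orthogroup,
                   rep(NA_character_, length(host_pick) + length(mic_pick))),
    goslim = c(families$goslim,
               rep(NA_character_, length(host_pick) + length(mic_pick))),
    stringsAsFactors = FALSE)
  names(mixed) <- unigene_truth$unigene_id

  out <- list(sets = list(parasite_assembly = pool,
                          parasite_ref = parasite_ref,
                          hostA = hostA, hostA_est = hostA_est,
                          hostB = hostB, hostB_est = hostB_est,
                          control = control, microbial = microbial,
                          mixed_unigenes = mixed),
              families = families,
              unigene_truth = unigene_truth,
              config = config)
  if (!is.null(outdir)) write_reference_sets(out, outdir)
  out
}

# GO Slim category draw with the configured enrichment planted by region:
# base weights give "no_category" the largest share (mirroring transcriptome
# profiles dominated by unannotated genes), and within the enriched region
# the enriched category's odds are multiplied by exp(enrichment_log_odds).
draw_goslim <- function(regions, config) {
  cats <- config$goslim_categories
  base <- rep(0.7 / (length(cats) - 1), length(cats))
  names(base) <- cats
  base["no_category"] <- 0.3
  vapply(regions, function(r) {
    w <- base
    if (r == config$enriched_region)
      w[config$enriched_category] <-
        w[config$enriched_category] * exp(config$enrichment_log_odds)
    sample(cats, 1L, prob = w)
  }, character(1), USE.NAMES = FALSE)
}

#' Write simulated reference sets to disk
#'
#' @param refs result of [simulate_reference_sets()].
#' @param outdir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_reference_sets <- function(refs, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(refs$sets)) {
    f <- file.path(outdir, paste0(nm, ".fasta"))
    write_fasta(refs$sets[[nm]], f)
    files <- c(files, f)
  }
  lab <- file.path(outdir, "family_labels.tsv")
  write.table(refs$families, lab, sep = "\t", quote = FALSE,
              row.names = FALSE)
  tru <- file.path(outdir, "unigene_truth.tsv")
  write.table(refs$unigene_truth, tru, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(files, lab, tru))
}
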