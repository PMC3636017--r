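# End-to-end orchestration: synthetic inputs -> trimming -> calibration ->
# read screening -> unigene cascade -> comparative + expression + qPCR,
# with a manifest of every artifact and a human-readable report.

#' Pipeline configuration
#'
#' Aggregates every threshold of the workflow in one record.  The shipped
#' defaults replay the reference parameterization: Q20 end trimming with
#' half-length survival, mapping at length fraction 0.5 / similarity 0.8,
#' a 95 percent identity screen (unless recalibrated), BLAST-style
#' significance via a raw score floor, ORF fraction 0.3 and residual flag
#' bound 4.
#'
#' @param sim a [sim_config()]; drives every synthetic input.
#' @param quality_floor,min_survival_fraction trimming policy (see
#'   [trim_policy()]).
#' @param tau_host,tau_parasite identity thresholds in percent; `NULL`
#'   (default) calibrates `tau_host` from the simulated distributions via
#'   [select_threshold()] and reuses it for the parasite screen.
#' @param length_fraction,min_similarity,min_score read-mapping policy (see
#'   [mapping_policy()]).
#' @param min_orf_fraction translatability filter threshold.
#' @param residual_bound flag bound for GO Slim residuals.
#' @param top_n length of the ranked expression lists.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            quality_floor = 20L,
                            min_survival_fraction = 0.5,
                            tau_host = NULL, tau_parasite = NULL,
                            length_fraction = 0.5, min_similarity = 0.8,
                            min_score = 20L,
                            min_orf_fraction = 0.3,
                            residual_bound = 4,
                            top_n = 20L) {
  stopifnot(is(sim, "sim_config"))
  structure(list(sim = sim, quality_floor = as.integer(quality_floor),
                 min_survival_fraction = min_survival_fraction,
                 tau_host = tau_host, tau_parasite = tau_parasite,
                 length_fraction = length_fraction,
                 min_similarity = min_similarity,
                 min_score = as.integer(min_score),
                 min_orf_fraction = min_orf_fraction,
                 residual_bound = residual_bound,
                 top_n = as.integer(top_n)),
            class = "pipeline_config")
}

#' Run the full pipeline on synthetic data
#'
#' Executes the stages in their declared order: simulate inputs, quality
#' trim and repair pairs, calibrate the host-exclusion threshold, screen
#' host reads, post-process and classify unigenes, partition orthogroups
#' and test GO Slim proportionality, quantify expression and rank, and
#' analyze the qPCR table.  Identical configurations produce identical
#' results; when `outdir` is given every tabular artifact is written there
#' and checksummed in the manifest.
#'
#' @param config a [pipeline_config()].
#' @param outdir optional output directory.
#' @return a `pipeline_manifest` list: per-stage results plus `files`
#'   (data frame of written artifacts with md5 checksums).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  stopifnot(is(config, "pipeline_config"))
  t0 <- Sys.time()
  manifest <- list(config = config, stages = list())
  add_stage <- function(name, value) {
    manifest$stages[[name]] <<- value
    invisible(NULL)
  }

  # 1. synthetic inputs
  refs <- simulate_reference_sets(config$sim)
  lib <- simulate_mixed_library(config$sim, refs, host = "hostA")
  labels <- simulate_comparative_labels(config$sim)
  ct_table <- simulate_qpcr(config$sim)
  add_stage("simulate", list(
    n_unigenes = length(refs$sets$mixed_unigenes),
    n_read_pairs = nrow(lib$pairs),
    true_contamination_fraction = config$sim$contamination_fraction))

  # 2. quality trim + pair repair
  tp <- trim_policy(config$quality_floor, config$min_survival_fraction)
  tr1 <- quality_trim(lib$pairs$mate1, lib$pairs$qual1, tp)
  tr2 <- quality_trim(lib$pairs$mate2, lib$pairs$qual2, tp)
  rp <- repair_pairs(tr1, tr2, lib$pairs$read_id)
  add_stage("trim", list(accounting = rp$accounting))

  # 3. calibrate the host-exclusion threshold: host EST-style collection
  # vs host cDNA gives the host mode; the non-parasitic control gives the
  # incidental mode
  screen_policy <- mapping_policy(length_fraction = config$length_fraction,
                                  min_similarity = config$min_similarity,
                                  min_score = config$min_score)
  host_index <- build_index(refs$sets$hostA, screen_policy$k)
  dist_host <- identity_distribution(refs$sets$hostA_est, host_index,
                                     screen_policy)
  dist_ctrl <- identity_distribution(refs$sets$control, host_index,
                                     screen_policy)
  cal <- select_threshold(dist_host, dist_ctrl)
  tau_host <- if (is.null(config$tau_host)) cal$tau else config$tau_host
  tau_par <- if (is.null(config$tau_parasite)) tau_host
             else config$tau_parasite
  add_stage("calibrate", list(result = cal, tau_host = tau_host,
                              tau_parasite = tau_par))

  # 4. read-level host screen at the calibrated identity
  read_policy <- mapping_policy(length_fraction = config$length_fraction,
                                min_similarity = tau_host / 100,
                                min_score = config$min_score)
  scr <- screen_host_reads(rp$pairs, rp$orphans, host_index, read_policy)
  surv_pairs <- nrow(rp$pairs)
  # pair-level estimator: a pair counts as host-origin only when both mates
  # are host-assigned, which squares the per-read false-positive rate while
  # true host pairs (near-identical to the reference) still map twice
  est_f <- if (surv_pairs > 0)
    sum(scr$pair_flags$mate1_host & scr$pair_flags$mate2_host) / surv_pairs
  else NA
  add_stage("screen_reads", list(
    accounting = scr$accounting,
    estimated_contamination_fraction = est_f))

  # 5. unigene post-processing + classification cascade
  dd <- deduplicate(refs$sets$mixed_unigenes)
  tf <- translatability_filter(dd$retained, config$min_orf_fraction)
  unigenes <- dd$retained[tf$keep]
  labeled_db <- c(refs$sets$control, refs$sets$microbial)
  kingdom <- data.frame(id = names(labeled_db),
                        kingdom = c(rep("plant",
                                        length(refs$sets$control)),
                                    rep("non_plant",
                                        length(refs$sets$microbial))),
                        stringsAsFactors = FALSE)
  cls <- classify_cascade(unigenes, host_index, refs$sets$parasite_ref,
                          labeled_db = labeled_db, labels = kingdom,
                          tau_host = tau_host, tau_parasite = tau_par,
                          policy = screen_policy)
  stats_all <- assembly_stats(unigenes)
  add_stage("classify", list(classified = cls$classified,
                             accounting = cls$accounting,
                             ambiguous = cls$ambiguous,
                             assembly_stats = stats_all,
                             deduplicated = length(dd$removed),
                             untranslatable = sum(!tf$keep)))

  # 6. comparative: orthogroup Venn + GO Slim proportionality
  venn <- venn_partition(labels$sets$intA, labels$sets$intB,
                         labels$sets$above)
  fractions <- interface_fractions(venn)
  ctab <- goslim_contingency(
    labels$unigenes[labels$unigenes$transcriptome == "intA", ])
  enrich <- goslim_chi_square(ctab, flag_bound = config$residual_bound)
  add_stage("comparative", list(venn = venn, fractions = fractions,
                                enrichment = enrich))

  # 7. expression: map retained reads to the parasite assembly, RPKM, rank
  reads <- c(setNames(scr$retained_pairs$mate1,
                      paste0(scr$retained_pairs$read_id, "/1")),
             setNames(scr$retained_pairs$mate2,
                      paste0(scr$retained_pairs$read_id, "/2")),
             setNames(scr$retained_orphans$seq,
                      paste0(scr$retained_orphans$read_id, "/o")))
  mp <- map_reads(reads, refs$sets$parasite_assembly, screen_policy)
  expr <- compute_rpkm(mp$counts,
                       setNames(nchar(refs$sets$parasite_assembly),
                                names(refs$sets$parasite_assembly)))
  fam_venn <- venn_partition(
    refs$families$orthogroup[refs$families$region %in%
      c("shared_all", "interface_shared", "A_interface_unique",
        "A_above_shared")],
    refs$families$orthogroup[refs$families$region %in%
      c("shared_all", "interface_shared", "B_interface_unique",
        "B_above_shared")],
    refs$families$orthogroup[refs$families$region %in%
      c("shared_all", "A_above_shared", "B_above_shared", "above_unique")])
  og_assign <- data.frame(unigene_id = refs$families$transcript_id,
                          orthogroup = refs$families$orthogroup,
                          stringsAsFactors = FALSE)
  top <- lapply(c("interface_shared", "A_interface_unique",
                  "B_interface_unique"),
                function(r) top_expressed(expr, og_assign, fam_venn, r,
                                          config$top_n))
  names(top) <- c("interface_shared", "A_interface_unique",
                  "B_interface_unique")
  add_stage("expression", list(expr = expr, top = top,
                               mapped_reads = sum(mp$counts)))

  # 8. qPCR
  qp <- analyze_qpcr(ct_table, direction = "up")
  add_stage("qpcr", list(result = qp,
                         true_fold = config$sim$qpcr$true_fold))

  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  manifest$files <- data.frame(path = character(0), md5 = character(0),
                               stringsAsFactors = FALSE)
  class(manifest) <- "pipeline_manifest"
  if (!is.null(outdir)) manifest <- write_artifacts(manifest, outdir)
  manifest
}

# Write tabular artifacts and checksum them into the manifest.
write_artifacts <- function(manifest, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(df, name) {
    f <- file.path(outdir, name)
    write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, f)
  }
  st <- manifest$stages
  emit(st$trim$accounting, "trim_accounting.tsv")
  emit(st$screen_reads$accounting, "screen_accounting.tsv")
  emit(st$classify$classified, "classification.tsv")
  emit(st$classify$accounting, "cascade_accounting.tsv")
  emit(data.frame(region = names(st$comparative$venn$counts),
                  count = as.integer(st$comparative$venn$counts)),
       "venn_counts.tsv")
  emit(st$comparative$fractions, "interface_fractions.tsv")
  emit(as.data.frame.table(st$comparative$enrichment$residuals,
                           responseName = "residual"),
       "goslim_residuals.tsv")
  emit(st$expression$expr, "expression.tsv")
  emit(st$qpcr$result$per_sample, "qpcr_folds.tsv")
  cal <- st$calibrate
  jsonlite::write_json(list(tau = cal$tau_host,
                            host_retention = cal$result$host_retention,
                            parasite_loss = cal$result$parasite_loss,
                            separable = cal$result$separable),
                       file.path(outdir, "calibration.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, file.path(outdir, "calibration.json"))
  manifest$files <- data.frame(path = files,
                               md5 = unname(tools::md5sum(files)),
                               stringsAsFactors = FALSE)
  report <- write_report(manifest, file.path(outdir, "report.txt"))
  manifest$files <- rbind(manifest$files,
                          data.frame(path = file.path(outdir, "report.txt"),
                                     md5 = unname(tools::md5sum(
                                       file.path(outdir, "report.txt"))),
                                     stringsAsFactors = FALSE))
  manifest
}

#' Write a human-readable pipeline report
#'
#' Summarizes every completed stage: per-stage read/unigene accounting, the
#' calibrated threshold, Venn counts and interface fractions, flagged
#' enrichment cells, ranked expression lists and qPCR folds.  Stages absent
#' from the manifest are flagged as unavailable rather than omitted.
#'
#' @param manifest a [run_pipeline()] manifest.
#' @param path optional file to write the report to.
#' @return the report lines, invisibly when `path` is given.
#' @export
write_report <- function(manifest, path = NULL) {
  st <- manifest$stages
  lines <- c("Mixed-species interface transcriptome pipeline report",
             strrep("=", 54), "")
  section <- function(title, body) {
    c(title, strrep("-", nchar(title)), body, "")
  }
  fmt_acct <- function(df) sprintf("  %-28s %12s", df$stage,
                                   format(df$count, big.mark = ","))
  lines <- c(lines,
    if (is.null(st$trim)) "[trimming unavailable]"
    else section("Read trimming", fmt_acct(st$trim$accounting)),
    if (is.null(st$calibrate)) "[calibration unavailable]"
    else section("Identity threshold calibration", c(
      sprintf("  tau = %d%% (host retention %.4f, parasite loss %.4f, separable: %s)",
              st$calibrate$tau_host, st$calibrate$result$host_retention,
              st$calibrate$result$parasite_loss,
              st$calibrate$result$separable))),
    if (is.null(st$screen_reads)) "[read screening unavailable]"
    else section("Host read screening", c(
      fmt_acct(st$screen_reads$accounting),
      sprintf("  estimated contamination fraction: %.4f",
              st$screen_reads$estimated_contamination_fraction))),
    if (is.null(st$classify)) "[classification unavailable]"
    else section("Unigene classification", c(
      fmt_acct(st$classify$accounting),
      sprintf("  N50: %d bp over %d unigenes",
              st$classify$assembly_stats$n50,
              st$classify$assembly_stats$n))),
    if (is.null(st$comparative)) "[comparative analysis unavailable]"
    else section("Orthogroup Venn partition", c(
      sprintf("  %-22s %6d", names(st$comparative$venn$counts),
              as.integer(st$comparative$venn$counts)),
      "  interface-only fractions:",
      sprintf("    %-22s %3d%%", st$comparative$fractions$region,
              st$comparative$fractions$percent),
      sprintf("  GO Slim chi-square: X2 = %.1f, df = %d, p = %.3g; %d flagged cells",
              st$comparative$enrichment$statistic,
              st$comparative$enrichment$df,
              st$comparative$enrichment$p_value,
              sum(st$comparative$enrichment$flags != "")))),
    if (is.null(st$expression)) "[expression unavailable]"
    else section("Expression", c(
      sprintf("  mapped reads: %d", st$expression$mapped_reads),
      unlist(lapply(names(st$expression$top), function(r) {
        t <- st$expression$top[[r]]
        c(sprintf("  top expressed, %s:", r),
          if (nrow(t) == 0) "    (empty region)"
          else sprintf("    %2d. %-12s RPKM %10.1f", t$rank, t$unigene_id,
                       t$rpkm))
      })))),
    if (is.null(st$qpcr)) "[qPCR unavailable]"
    else section("qPCR relative quantification", c(
      sprintf("  fold change (2^-ddCt, geometric mean): %.1f",
              st$qpcr$result$fold),
      sprintf("  Welch one-tailed: t = %.3f, df = %.2f, p = %.4f",
              st$qpcr$result$test$t, st$qpcr$result$test$df,
              st$qpcr$result$test$p_value))))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
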