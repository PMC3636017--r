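# Label-universe simulator: orthogroup memberships across the three
# transcriptomes (two interface libraries plus the above-ground reference)
# with planted GO Slim enrichment, independent of the sequence-level
# simulators so that enrichment recovery can be studied at any table size.

region_membership <- function(region) {
  switch(region,
         shared_all = c("intA", "intB", "above"),
         interface_shared = c("intA", "intB"),
         A_interface_unique = "intA",
         B_interface_unique = "intB",
         A_above_shared = c("intA", "above"),
         B_above_shared = c("intB", "above"),
         above_unique = "above")
}

#' Simulate orthogroup memberships and GO Slim labels
#'
#' Builds an orthogroup universe in which each orthogroup is assigned to one
#' of the seven Venn regions over (interface on host A, interface on host B,
#' above-ground reference) with the configured probabilities, populates each
#' present orthogroup with unigenes, and draws a GO Slim category per
#' unigene with the configured enrichment planted in one region.
#'
#' @param config a [sim_config()].
#' @param seed optional seed overriding `config$seed` (useful for replicate
#'   simulations).
#' @return a list with `orthogroups` (data frame `orthogroup`, `region`),
#'   `sets` (list of orthogroup-id character vectors `intA`, `intB`,
#'   `above`), `unigenes` (data frame `unigene_id`, `transcriptome`,
#'   `orthogroup`, `region`, `goslim`) and `truth` (the planted cell).
#' @export
simulate_comparative_labels <- function(config, seed = NULL) {
  stopifnot(is(config, "sim_config"))
  set.seed(if (is.null(seed)) config$seed + 2L else seed)
  n_og <- config$orthogroup_count
  og <- data.frame(orthogroup = sprintf("OGL%05d", seq_len(n_og)),
                   region = sample(names(config$region_weights), n_og,
                                   replace = TRUE,
                                   prob = config$region_weights),
                   stringsAsFactors = FALSE)
  members <- lapply(og$region, region_membership)
  sets <- list(intA = og$orthogroup[vapply(members, function(m)
                 "intA" %in% m, logical(1))],
               intB = og$orthogroup[vapply(members, function(m)
                 "intB" %in% m, logical(1))],
               above = og$orthogroup[vapply(members, function(m)
                 "above" %in% m, logical(1))])
  rows <- list()
  for (i in seq_len(n_og)) {
    for (tr in members[[i]]) {
      k <- 1L + rpois(1L, max(0, config$unigenes_per_og_mean - 1))
      rows[[length(rows) + 1L]] <-
        data.frame(transcriptome = tr,
                   orthogroup = og$orthogroup[i],
                   region = og$region[i],
                   n = k, stringsAsFactors = FALSE)
    }
  }
  uni <- do.call(rbind, rows)
  uni <- uni[rep(seq_len(nrow(uni)), uni$n), c("transcriptome", "orthogroup",
                                               "region")]
  uni$goslim <- draw_goslim(uni$region, config)
  uni <- data.frame(unigene_id = sprintf("LU%06d", seq_len(nrow(uni))), uni,
                    row.names = NULL, stringsAsFactors = FALSE)
  list(orthogroups = og, sets = sets, unigenes = uni,
       truth = list(enriched_category = config$enriched_category,
                    enriched_region = config$enriched_region,
                    enrichment_log_odds = config$enrichment_log_odds))
}
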