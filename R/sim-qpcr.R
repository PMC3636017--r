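# qPCR Ct-table simulator with a configured true fold change.

#' Simulate a qPCR Ct replicate table
#'
#' Generates crossing-point (Ct) values for a target and a reference gene in
#' treatment and control samples.  The target's Ct in the treatment
#' condition is shifted by `-log2(true_fold)` relative to control, so the
#' expected 2^-ddCt of the generated table equals the configured fold
#' change.  Each biological replicate receives a shared normal offset
#' (`bio_noise_sd`) and every Ct value independent technical noise
#' (`ct_noise_sd`).
#'
#' @param config a [sim_config()] (its `qpcr` model is used) or a
#'   [qpcr_model()] directly.
#' @param seed optional seed; defaults to `config$seed + 3` when a full
#'   configuration is given, otherwise 1.
#' @return data frame with columns `sample`, `condition`
#'   (`treatment`/`control`), `gene` (`target`/`reference`), `bio_rep`,
#'   `tech_rep`, `ct`.
#' @export
simulate_qpcr <- function(config, seed = NULL) {
  if (is(config, "sim_config")) {
    model <- config$qpcr
    if (is.null(seed)) seed <- config$seed + 3L
  } else {
    stopifnot(is(config, "qpcr_model"))
    model <- config
    if (is.null(seed)) seed <- 1L
  }
  set.seed(seed)
  rows <- list()
  for (cond in c("treatment", "control")) {
    shift <- if (cond == "treatment") -log2(model$true_fold) else 0
    for (b in seq_len(model$n_bio)) {
      # shared loading offset cancels in dCt; target-only biological
      # expression variation does not, as in real biological replicates
      bio_off <- rnorm(1L, sd = model$bio_noise_sd)
      tgt_off <- rnorm(1L, sd = model$bio_noise_sd)
      sample_id <- sprintf("%s_%d", cond, b)
      for (gene in c("target", "reference")) {
        mu <- if (gene == "target")
          model$base_ct_target + shift + bio_off + tgt_off
        else model$base_ct_reference + bio_off
        ct <- mu + rnorm(model$n_tech, sd = model$ct_noise_sd)
        rows[[length(rows) + 1L]] <-
          data.frame(sample = sample_id, condition = cond, gene = gene,
                     bio_rep = b, tech_rep = seq_len(model$n_tech),
                     ct = ct, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
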