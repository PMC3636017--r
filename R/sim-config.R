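#' qPCR simulation model
#'
#' Parameters of the synthetic Ct-table generator: the true fold change of
#' the target gene in the treatment condition relative to control, the
#' standard deviation of Ct measurement noise, and the replicate structure
#' (biological x technical).
#'
#' @param true_fold true expression fold change (treatment vs control) of the
#'   target gene, on the linear scale.  The default mirrors the >120-fold
#'   host-specific induction the package's reference analysis is built
#'   around.
#' @param ct_noise_sd standard deviation (Ct cycles) of technical noise added
#'   to every Ct value.
#' @param bio_noise_sd standard deviation (Ct cycles) of a per-biological-
#'   replicate offset shared by all technical replicates of a sample.
#' @param n_bio number of biological replicates per condition.
#' @param n_tech number of technical replicates per biological replicate.
#' @param base_ct_target,base_ct_reference mean Ct of the target gene (in the
#'   control condition) and of the reference gene.
#' @return a list of class `qpcr_model`.
#' @export
#' @examples
#' qpcr_model(true_fold = 4, ct_noise_sd = 0)
qpcr_model <- function(true_fold = 120, ct_noise_sd = 0.2, bio_noise_sd = 0.1,
                       n_bio = 3L, n_tech = 3L,
                       base_ct_target = 28, base_ct_reference = 20) {
  if (true_fold <= 0) config_error("true_fold must be positive")
  if (n_bio < 1 || n_tech < 1)
    config_error("replicate counts must be positive")
  if (ct_noise_sd < 0 || bio_noise_sd < 0)
    config_error("noise standard deviations must be non-negative")
  structure(list(true_fold = true_fold, ct_noise_sd = ct_noise_sd,
                 bio_noise_sd = bio_noise_sd, n_bio = as.integer(n_bio),
                 n_tech = as.integer(n_tech), base_ct_target = base_ct_target,
                 base_ct_reference = base_ct_reference),
            class = "qpcr_model")
}

#' Synthetic-data configuration
#'
#' One object holding every knob of the synthetic mixed-species study: the
#' transcript pools and their pairwise divergences, the contaminated read
#' library, the orthogroup/GO Slim label universe with planted enrichment,
#' the negative-binomial expression model and the qPCR model.  The defaults
#' emulate the study design the package reproduces: an 83 x 83 bp paired-end
#' interface library from a parasite growing on two divergent hosts, with a
#' non-parasitic control relative, clearly separable host/parasite identity
#' modes, and Venn-region proportions matching the published orthogroup
#' partition.
#'
#' @param seed integer seed; identical configurations (including the seed)
#'   produce byte-identical outputs.
#' @param n_parasite_transcripts number of parasite gene families simulated.
#' @param n_host_transcripts number of transcripts per host species.
#' @param n_microbial number of microbial (non-plant) reference sequences.
#' @param transcript_length_range min/max simulated transcript length (bp).
#' @param divergence_parasite_host per-site substitution probability between
#'   parasite and host homologs (0.20 puts the incidental identity mode near
#'   80 percent, well below the host mode).
#' @param divergence_within_parasite per-site substitution probability between
#'   the parasite assembly and the parasite reference library.
#' @param divergence_within_host per-site substitution probability between a
#'   host's cDNA reference and its EST-style collection (used to build the
#'   host-positive calibration distribution).
#' @param divergence_control per-site substitution probability between the
#'   parasite assembly and the non-parasitic control relative; kept small so
#'   the control's incidental identity to the hosts matches the parasite's,
#'   which is what makes it a valid calibration control.
#' @param host_homolog_fraction fraction of host transcripts that are
#'   homologous to a parasite family (the rest are host-specific).
#' @param contamination_fraction proportion `f` of read pairs of host origin.
#' @param unigene_contamination_fraction proportion of host-derived unigenes
#'   mixed into the synthetic assembly (emulating host transcripts that
#'   survived read screening and were assembled).
#' @param microbial_contamination number of microbial unigenes mixed into the
#'   synthetic assembly.
#' @param read_length read length in bp (83 matches the emulated platform
#'   protocol).
#' @param n_read_pairs number of simulated read pairs.
#' @param insert_size_range min/max fragment length for paired-end reads.
#' @param base_error_rate per-base sequencing substitution probability on
#'   high-quality bases.
#' @param quality_high,quality_low Phred scores assigned to clean bases and
#'   to low-quality tail bases.
#' @param low_quality_tail_prob probability that a read carries a low-quality
#'   3' tail (exercises end trimming).
#' @param max_tail_fraction maximum tail length as a fraction of read length.
#' @param orthogroup_count number of orthogroups in the label universe used
#'   by [simulate_comparative_labels()]; the default is a one-tenth-scale
#'   replica of the ~11,000-orthogroup universes typical of plant
#'   gene-family classifications.
#' @param region_weights named probabilities of the seven Venn regions for an
#'   orthogroup; defaults follow the published partition proportions.
#' @param goslim_categories character vector of GO Slim category names; must
#'   include `"no_category"` (unigenes lacking a GO Slim term are an explicit
#'   class in the enrichment analysis).
#' @param enriched_category,enriched_region,enrichment_log_odds the planted
#'   enrichment: within `enriched_region`, the log-odds of
#'   `enriched_category` is raised by `enrichment_log_odds`.
#' @param unigenes_per_og_mean mean (Poisson, shifted by 1) number of
#'   unigenes per orthogroup per transcriptome in the label universe.
#' @param nb_mean,nb_size mean and size (dispersion) of the negative-binomial
#'   per-transcript expected read counts used as expression weights.
#' @param qpcr a [qpcr_model()].
#' @return a list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_parasite_transcripts = 20,
#'                   n_host_transcripts = 10, n_read_pairs = 200)
sim_config <- function(seed = 1L,
                       n_parasite_transcripts = 120L,
                       n_host_transcripts = 80L,
                       n_microbial = 12L,
                       transcript_length_range = c(300L, 1200L),
                       divergence_parasite_host = 0.20,
                       divergence_within_parasite = 0.02,
                       divergence_within_host = 0.01,
                       divergence_control = 0.02,
                       host_homolog_fraction = 0.6,
                       contamination_fraction = 0.10,
                       unigene_contamination_fraction = 0.10,
                       microbial_contamination = 4L,
                       read_length = 83L,
                       n_read_pairs = 2000L,
                       insert_size_range = c(180L, 250L),
                       base_error_rate = 0.005,
                       quality_high = 38L,
                       quality_low = 2L,
                       low_quality_tail_prob = 0.35,
                       max_tail_fraction = 0.6,
                       orthogroup_count = 1100L,
                       region_weights = c(shared_all = 0.536,
                                          interface_shared = 0.101,
                                          A_interface_unique = 0.061,
                                          B_interface_unique = 0.033,
                                          A_above_shared = 0.096,
                                          B_above_shared = 0.028,
                                          above_unique = 0.145),
                       goslim_categories = c("no_category",
                                             "transcription factor activity",
                                             "transport",
                                             "metabolic process",
                                             "response to stress",
                                             "signal transduction",
                                             "cell wall organization",
                                             "catalytic activity"),
                       enriched_category = "no_category",
                       enriched_region = "interface_shared",
                       enrichment_log_odds = 1,
                       unigenes_per_og_mean = 2,
                       nb_mean = 50,
                       nb_size = 2,
                       qpcr = qpcr_model()) {
  probs <- c(divergence_parasite_host, divergence_within_parasite,
             divergence_within_host, divergence_control,
             host_homolog_fraction,
             contamination_fraction, unigene_contamination_fraction,
             base_error_rate, low_quality_tail_prob, max_tail_fraction)
  if (any(probs < 0 | probs > 1))
    config_error("all probabilities and fractions must lie in [0, 1]")
  if (n_parasite_transcripts < 1 || n_host_transcripts < 1)
    config_error("transcript counts must be positive")
  if (any(transcript_length_range <= 0) ||
      transcript_length_range[1] > transcript_length_range[2])
    config_error("transcript_length_range must be a positive, ordered pair")
  if (read_length < 1 || n_read_pairs < 0)
    config_error("read_length must be positive and n_read_pairs non-negative")
  if (abs(sum(region_weights) - 1) > 1e-6)
    config_error("region_weights must sum to 1")
  required_regions <- c("shared_all", "interface_shared",
                        "A_interface_unique", "B_interface_unique",
                        "A_above_shared", "B_above_shared", "above_unique")
  if (!setequal(names(region_weights), required_regions))
    config_error("region_weights must name the 7 Venn regions")
  if (!"no_category" %in% goslim_categories)
    config_error("goslim_categories must include 'no_category'")
  if (!enriched_category %in% goslim_categories)
    config_error("enriched_category must be one of goslim_categories")
  if (!enriched_region %in% required_regions)
    config_error("enriched_region must be one of the 7 Venn regions")
  stopifnot(is(qpcr, "qpcr_model"))
  structure(list(seed = as.integer(seed),
                 n_parasite_transcripts = as.integer(n_parasite_transcripts),
                 n_host_transcripts = as.integer(n_host_transcripts),
                 n_microbial = as.integer(n_microbial),
                 transcript_length_range = as.integer(transcript_length_range),
                 divergence_parasite_host = divergence_parasite_host,
                 divergence_within_parasite = divergence_within_parasite,
                 divergence_within_host = divergence_within_host,
                 divergence_control = divergence_control,
                 host_homolog_fraction = host_homolog_fraction,
                 contamination_fraction = contamination_fraction,
                 unigene_contamination_fraction = unigene_contamination_fraction,
                 microbial_contamination = as.integer(microbial_contamination),
                 read_length = as.integer(read_length),
                 n_read_pairs = as.integer(n_read_pairs),
                 insert_size_range = as.integer(insert_size_range),
                 base_error_rate = base_error_rate,
                 quality_high = as.integer(quality_high),
                 quality_low = as.integer(quality_low),
                 low_quality_tail_prob = low_quality_tail_prob,
                 max_tail_fraction = max_tail_fraction,
                 orthogroup_count = as.integer(orthogroup_count),
                 region_weights = region_weights[required_regions],
                 goslim_categories = goslim_categories,
                 enriched_category = enriched_category,
                 enriched_region = enriched_region,
                 enrichment_log_odds = enrichment_log_odds,
                 unigenes_per_og_mean = unigenes_per_og_mean,
                 nb_mean = nb_mean,
                 nb_size = nb_size,
                 qpcr = qpcr),
            class = "sim_config")
}
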