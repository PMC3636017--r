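# Calibration of the host-exclusion identity threshold tau from best-hit
# identity distributions: a host-positive distribution (queries known to be
# host-derived against the host reference) and a control distribution (a
# non-parasitic relative against the same reference, giving the incidental
# identity of sequences that should not be called host).

#' Best-hit identity distribution
#'
#' Queries every sequence against the reference and bins the best-hit
#' percent identity into 1-point bins over [0, 100] (identity 100 falls in
#' the top bin [99, 100]).  Queries without a significant hit are counted
#' separately and contribute to no bin.
#'
#' @param queries named character vector of query sequences.
#' @param reference named character vector of reference transcripts, or a
#'   prebuilt [build_index()].
#' @param policy a [mapping_policy()].
#' @return a list of class `identity_distribution`: `counts` (integer
#'   vector of 100 bins, names `"0"`..`"99"` giving the lower bin edge),
#'   `n_queries`, `n_with_hit`, and `identities` (per-query best-hit
#'   identity, `NA` for no hit).
#' @export
identity_distribution <- function(queries, reference,
                                  policy = mapping_policy()) {
  if (length(queries) == 0) config_error("empty query set")
  index <- if (is(reference, "seed_index")) reference
           else build_index(reference, policy$k)
  hits <- search_hits(queries, index, policy, mode = "global")
  ids <- setNames(rep(NA_real_, length(queries)), names(queries))
  ids[hits$query] <- hits$percent_identity
  new_identity_distribution(ids)
}

# Construct the distribution object from a vector of per-query best-hit
# identities (NA = no hit).  Exposed internally so calibration can also be
# run on precomputed identities.
new_identity_distribution <- function(identities) {
  obs <- identities[!is.na(identities)]
  bins <- pmin(floor(obs), 99)
  counts <- tabulate(bins + 1L, nbins = 100L)
  names(counts) <- as.character(0:99)
  structure(list(counts = counts,
                 n_queries = length(identities),
                 n_with_hit = length(obs),
                 identities = identities),
            class = "identity_distribution")
}

#' Construct an identity distribution from bin counts
#'
#' Convenience constructor for working with histogram shapes directly
#' (e.g. replaying published distribution shapes).
#'
#' @param counts integer vector of up to 100 bin counts; names give the
#'   lower bin edges (defaults to `0:(length(counts)-1)`).
#' @param n_queries total queries; defaults to `sum(counts)` (no no-hit
#'   queries).
#' @return an `identity_distribution`.
#' @export
identity_distribution_from_counts <- function(counts,
                                              n_queries = sum(counts)) {
  full <- setNames(integer(100), as.character(0:99))
  nm <- if (is.null(names(counts))) as.character(seq_along(counts) - 1L)
        else names(counts)
  full[nm] <- as.integer(counts)
  structure(list(counts = full, n_queries = n_queries,
                 n_with_hit = sum(full), identities = NULL),
            class = "identity_distribution")
}

#' Select the host-exclusion identity threshold
#'
#' Formalizes the visual valley-picking of the published calibration: over
#' candidate thresholds tau in 1..100 (bin boundaries), minimizes
#' (host-distribution mass strictly below tau) + (control-distribution mass
#' at or above tau) - i.e. host contamination retained plus parasite-like
#' sequence lost.  Both masses are fractions of the queries with hits
#' (no-hit queries cannot be host contamination by this criterion).  The
#' minimizing set is typically a flat plateau between the two modes; the
#' upper median boundary is returned, favoring parasite retention.  When
#' the minimized sum exceeds `overlap_ceiling` the distributions are not
#' separable; tau is still reported, with `separable = FALSE` and a
#' warning.
#'
#' @param dist_host an `identity_distribution` of host-derived queries
#'   against the host reference (the true-host, high-identity mode).
#' @param dist_control an `identity_distribution` of the non-parasite
#'   control (or reciprocal non-host queries) against the same reference
#'   (the incidental-identity mode).
#' @param overlap_ceiling maximum combined error mass for the two
#'   distributions to count as separable.
#' @return a list of class `calibration_result`: `tau`, `host_retention`
#'   (host mass below tau, i.e. contamination kept), `parasite_loss`
#'   (control mass at/above tau), `separable`, and `error_curve` (data
#'   frame of both masses for every candidate tau).
#' @export
select_threshold <- function(dist_host, dist_control,
                             overlap_ceiling = 0.1) {
  stopifnot(is(dist_host, "identity_distribution"),
            is(dist_control, "identity_distribution"))
  if (dist_host$n_with_hit == 0 || dist_control$n_with_hit == 0)
    config_error("empty identity histogram")
  ph <- dist_host$counts / dist_host$n_with_hit
  pc <- dist_control$counts / dist_control$n_with_hit
  taus <- 1:100
  host_below <- cumsum(ph)            # mass in bins < tau, tau = 1..100
  control_at_or_above <- rev(cumsum(rev(pc)))  # mass in bins >= tau - 1 ...
  # bins are [b, b+1); mass >= tau means bins tau..99
  control_ge <- c(control_at_or_above[-1], 0)
  total <- host_below + control_ge
  minimal <- which(total == min(total))
  pick <- minimal[ceiling((length(minimal) + 1) / 2)]
  tau <- taus[pick]
  separable <- total[pick] <= overlap_ceiling
  if (!separable)
    warning(sprintf("distributions overlap (combined error mass %.3f); threshold %d reported but not separable",
                    total[pick], tau))
  structure(list(tau = tau,
                 host_retention = unname(host_below[pick]),
                 parasite_loss = unname(control_ge[pick]),
                 separable = separable,
                 error_curve = data.frame(tau = taus,
                                          host_retention = unname(host_below),
                                          parasite_loss = unname(control_ge))),
            class = "calibration_result")
}
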