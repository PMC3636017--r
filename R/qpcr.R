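# Relative quantification by 2^-ddCt with a one-tailed Welch test.

#' Per-sample delta-Ct
#'
#' dCt = mean Ct(target) - mean Ct(reference), per sample, from technical
#' replicate means.
#'
#' @param ct_table data frame with columns `sample`, `condition`, `gene`
#'   (`"target"`/`"reference"`), `ct` (one row per technical replicate).
#' @return data frame with `sample`, `condition`, `mean_ct_target`,
#'   `mean_ct_reference`, `delta_ct`.
#' @export
delta_ct <- function(ct_table) {
  need <- c("sample", "condition", "gene", "ct")
  if (!all(need %in% names(ct_table)))
    config_error("ct_table needs columns %s", paste(need, collapse = ", "))
  samples <- unique(ct_table[, c("sample", "condition")])
  rows <- lapply(seq_len(nrow(samples)), function(i) {
    s <- ct_table[ct_table$sample == samples$sample[i], ]
    tgt <- s$ct[s$gene == "target"]
    ref <- s$ct[s$gene == "reference"]
    if (length(tgt) == 0 || length(ref) == 0)
      config_error("sample %s is missing the %s gene", samples$sample[i],
                   if (length(tgt) == 0) "target" else "reference")
    data.frame(sample = samples$sample[i],
               condition = samples$condition[i],
               mean_ct_target = mean(tgt),
               mean_ct_reference = mean(ref),
               delta_ct = mean(tgt) - mean(ref),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fold change by the 2^-ddCt method
#'
#' ddCt of each treatment sample is its dCt minus the mean control dCt;
#' the per-sample fold change is 2^-ddCt and the summary fold across
#' samples is the geometric mean (equivalently 2^-mean(ddCt)).
#'
#' @param dct a [delta_ct()] data frame.
#' @param treatment,control condition labels in `dct$condition`.
#' @return a list with `per_sample` (data frame `sample`, `condition`,
#'   `delta_ct`, `ddct`, `fold`) and `fold` (geometric-mean fold of the
#'   treatment samples).
#' @export
fold_change_ddct <- function(dct, treatment = "treatment",
                             control = "control") {
  dc <- dct$delta_ct[dct$condition == control]
  dt <- dct$delta_ct[dct$condition == treatment]
  if (length(dc) == 0 || length(dt) == 0)
    config_error("both conditions need at least one sample")
  base <- mean(dc)
  per_sample <- data.frame(sample = dct$sample,
                           condition = dct$condition,
                           delta_ct = dct$delta_ct,
                           ddct = dct$delta_ct - base,
                           fold = 2^-(dct$delta_ct - base),
                           stringsAsFactors = FALSE)
  list(per_sample = per_sample,
       fold = 2^-mean(dt - base))
}

#' One-tailed Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and a one-tailed p-value in the stated direction; normally
#' applied to the dCt values of the two conditions.
#'
#' @param group1,group2 numeric vectors (at least 2 values each).
#' @param alternative direction of the alternative for `group1` relative
#'   to `group2`: `"less"` (mean1 < mean2) or `"greater"`.
#' @return a list with `t`, `df`, `p_value`, `alternative`.
#' @export
welch_one_tailed <- function(group1, group2,
                             alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(group1) < 2 || length(group2) < 2)
    config_error("each group needs at least 2 values")
  tt <- stats::t.test(group1, group2, alternative = alternative,
                      var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, alternative = alternative)
}

#' Full qPCR analysis of a Ct table
#'
#' dCt per sample, 2^-ddCt folds, and a one-tailed Welch test on the dCt
#' values of the two conditions.  The test is run on the dCt scale (the
#' approximately normal scale behind 2^-ddCt reporting); `direction
#' = "up"` tests for up-regulation in the treatment (treatment dCt smaller
#' than control).
#'
#' @param ct_table as in [delta_ct()].
#' @param treatment,control condition labels.
#' @param direction `"up"` or `"down"`: expected regulation of the target
#'   in the treatment condition.
#' @return a list with `delta_ct`, `fold` (summary fold), `per_sample`,
#'   and `test` (the [welch_one_tailed()] result).
#' @export
analyze_qpcr <- function(ct_table, treatment = "treatment",
                         control = "control", direction = c("up", "down")) {
  direction <- match.arg(direction)
  dct <- delta_ct(ct_table)
  fc <- fold_change_ddct(dct, treatment, control)
  test <- welch_one_tailed(dct$delta_ct[dct$condition == treatment],
                           dct$delta_ct[dct$condition == control],
                           alternative = if (direction == "up") "less"
                                         else "greater")
  list(delta_ct = dct, fold = fc$fold, per_sample = fc$per_sample,
       test = test)
}
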