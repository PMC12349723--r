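#' Percent survival from MTT plate readings
#'
#' Per-well percent survival is `100 * absorbance / mean(control
#' absorbance)`, where the control group is usually the vehicle-treated
#' wells; absorbances are assumed already corrected for the medium blank.
#' Group summaries (mean, SD, n) are computed per compound and treatment.
#'
#' @param readings data.frame with columns `well_id`, `treatment`,
#'   `compound_id` (NA for controls), `absorbance`; an optional `cell_line`
#'   column is carried through.
#' @param control_group treatment label of the control wells.
#' @return List with `per_well` (the input plus `pct_survival`) and
#'   `groups` (per compound x treatment: `mean_pct`, `sd_pct`, `n`).
#' @export
percent_survival <- function(readings, control_group = "vehicle") {
  need <- c("treatment", "absorbance")
  stopifnot(all(need %in% names(readings)))
  ctrl <- readings$absorbance[readings$treatment == control_group]
  if (length(ctrl) == 0L) {
    stop("no readings in control group '", control_group, "'", call. = FALSE)
  }
  m <- mean(ctrl)
  if (!is.finite(m) || m <= 0) {
    stop("control group mean absorbance must be positive", call. = FALSE)
  }
  readings$pct_survival <- 100 * readings$absorbance / m
  if (!"compound_id" %in% names(readings)) readings$compound_id <- NA
  key <- paste(readings$compound_id, readings$treatment)  # NA-safe grouping
  groups <- do.call(rbind, lapply(split(readings, key), function(g) {
    data.frame(compound_id = g$compound_id[1L],
               treatment = g$treatment[1L],
               mean_pct = mean(g$pct_survival),
               sd_pct = stats::sd(g$pct_survival),
               n = nrow(g),
               stringsAsFactors = FALSE)
  }))
  rownames(groups) <- NULL
  list(per_well = readings, groups = groups)
}

#' Re-sensitization call
#'
#' A compound re-sensitizes resistant cells to the chemotherapeutic when
#' co-treatment lowers percent survival by at least `threshold` percentage
#' points relative to the chemotherapeutic alone (both percentages sharing
#' the same vehicle denominator). The bound is inclusive: a decrease of
#' exactly the threshold is a call.
#'
#' @param pct_chemo_only percent survival under chemotherapeutic alone.
#' @param pct_compound_chemo percent survival under compound plus
#'   chemotherapeutic.
#' @param threshold percentage points (default 30).
#' @return data.frame `decrease`, `resensitizer` (vectorised).
#' @export
resensitization_call <- function(pct_chemo_only, pct_compound_chemo,
                                 threshold = 30) {
  decrease <- pct_chemo_only - pct_compound_chemo
  data.frame(decrease = decrease, resensitizer = decrease >= threshold)
}

#' MTT re-sensitization analysis of a plate table
#'
#' Convenience wrapper: computes percent survival against the vehicle
#' control, then calls [resensitization_call()] per compound comparing the
#' `chemo-only` group with each compound's `compound+chemo` group.
#'
#' @param readings plate data.frame (see [percent_survival()]) with
#'   treatments `vehicle`, `chemo-only` and `compound+chemo`.
#' @param threshold percentage points (default 30).
#' @return data.frame per compound: survival of both groups, `decrease`,
#'   `resensitizer`.
#' @export
mtt_resensitization <- function(readings, threshold = 30) {
  ps <- percent_survival(readings, control_group = "vehicle")
  g <- ps$groups
  chemo <- g[g$treatment == "chemo-only", , drop = FALSE]
  if (nrow(chemo) == 0L) stop("no 'chemo-only' readings", call. = FALSE)
  pct_chemo <- chemo$mean_pct[1L]
  cc <- g[g$treatment == "compound+chemo" & !is.na(g$compound_id), ,
          drop = FALSE]
  call <- resensitization_call(pct_chemo, cc$mean_pct, threshold = threshold)
  data.frame(compound_id = cc$compound_id,
             pct_survival_chemo_only = pct_chemo,
             pct_survival_compound_chemo = cc$mean_pct,
             sd_pct = cc$sd_pct, n = cc$n,
             decrease = call$decrease,
             resensitizer = call$resensitizer,
             stringsAsFactors = FALSE)
}

#' Screening hit rate
#'
#' Percent of tested compounds that passed the reversal criteria.
#'
#' @param n_tested number of compounds tested.
#' @param n_hits number of hits.
#' @param digits rounding of the reported percentage (default 1, matching
#'   the usual reporting precision).
#' @return Hit rate in percent.
#' @export
hit_rate <- function(n_tested, n_hits, digits = 1) {
  stopifnot(n_tested > 0, n_hits >= 0, n_hits <= n_tested)
  round(100 * n_hits / n_tested, digits)
}

#' Internal-standard normalized ratio
#'
#' LC-MS/MS relative quantification: the analyte peak area is divided by
#' the internal-standard peak area, then by the lysate protein content, so
#' samples are comparable across runs and cell yields:
#' `(analyte / IS) / lysate`.
#'
#' @param analyte_peak analyte peak area, counts.
#' @param is_peak internal-standard peak area, counts (> 0).
#' @param lysate lysate content, mg/mL (> 0).
#' @param sample_id labels used in error messages.
#' @return Normalized ratio, (counts/counts)/(mg/mL). Vectorised.
#' @export
normalized_ratio <- function(analyte_peak, is_peak, lysate,
                             sample_id = seq_along(analyte_peak)) {
  bad <- !(is_peak > 0) | !(lysate > 0)
  if (any(bad)) {
    stop("non-positive internal standard or lysate in sample(s): ",
         paste(sample_id[bad], collapse = ", "), call. = FALSE)
  }
  (analyte_peak / is_peak) / lysate
}

#' Mean and SD of normalized ratios
#'
#' Arithmetic mean of the per-sample normalized ratios for one compound,
#' condition and trial (samples are typically triplicates) with the sample
#' standard deviation (n - 1 denominator).
#'
#' @param ratios numeric vector of normalized ratios.
#' @return List `mean`, `sd`, `n`.
#' @export
mean_ratio <- function(ratios) {
  if (length(ratios) == 0L) stop("no ratios", call. = FALSE)
  list(mean = mean(ratios),
       sd = if (length(ratios) > 1L) stats::sd(ratios) else NA_real_,
       n = length(ratios))
}

#' Pooled two-sample t-test from summary statistics
#'
#' Student's t-test with pooled variance and `n1 + n2 - 2` degrees of
#' freedom, computed from group means, SDs and sizes. Two-sided p, capped
#' at 1. When both SDs are zero: equal means give `t = 0, p = 1`; unequal
#' means give an infinite t and `p = 0` with a warning.
#'
#' @param mean1,sd1,n1 first group (for substrate tests: without
#'   tariquidar).
#' @param mean2,sd2,n2 second group (with tariquidar).
#' @return List `t`, `df`, `p`.
#' @export
substrate_ttest <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  delta <- mean2 - mean1
  if (sp2 == 0) {
    if (delta == 0) return(list(t = 0, df = df, p = 1))
    warning("zero variance with unequal means; reporting p = 0")
    return(list(t = sign(delta) * Inf, df = df, p = 0))
  }
  t <- delta / (sqrt(sp2) * sqrt(1 / n1 + 1 / n2))
  p <- min(2 * stats::pt(-abs(t), df), 1)
  list(t = t, df = df, p = p)
}

#' Classify compounds as transport substrates
#'
#' A compound is called a likely transport substrate when, in at least one
#' independent trial, its intracellular accumulation is significantly
#' higher with the efflux pump inhibited than without (two-sided pooled t,
#' `p < alpha`, and the +inhibitor mean exceeding the -inhibitor mean).
#' Trials whose analyte was below quantification (`quantifiable = FALSE`)
#' are recorded as indeterminate and never trigger a substrate call.
#'
#' @param summaries data.frame with one row per compound x trial:
#'   `compound_id`, `trial`, `mean_minus`, `sd_minus`, `mean_plus`,
#'   `sd_plus`, `n` (per group), optional logical `quantifiable`.
#' @param alpha significance level (default 0.05).
#' @return List with `per_trial` (the input plus `t`, `p`, `significant`,
#'   `direction_up`, `indeterminate`) and `calls` (per compound:
#'   `substrate`, `n_trials`, `n_significant`).
#' @export
classify_substrate <- function(summaries, alpha = 0.05) {
  need <- c("compound_id", "trial", "mean_minus", "sd_minus", "mean_plus",
            "sd_plus", "n")
  stopifnot(all(need %in% names(summaries)))
  s <- summaries
  if (!"quantifiable" %in% names(s)) s$quantifiable <- TRUE
  s$quantifiable[is.na(s$quantifiable)] <- TRUE
  s$t <- NA_real_
  s$p <- NA_real_
  for (i in seq_len(nrow(s))) {
    if (!s$quantifiable[i] || is.na(s$mean_minus[i])) next
    tt <- substrate_ttest(s$mean_minus[i], s$sd_minus[i], s$n[i],
                          s$mean_plus[i], s$sd_plus[i], s$n[i])
    s$t[i] <- tt$t
    s$p[i] <- tt$p
  }
  s$indeterminate <- !s$quantifiable | is.na(s$p)
  s$direction_up <- !s$indeterminate & s$mean_plus > s$mean_minus
  s$significant <- !s$indeterminate & s$p < alpha
  calls <- do.call(rbind, lapply(split(s, s$compound_id), function(g) {
    data.frame(compound_id = g$compound_id[1L],
               n_trials = nrow(g),
               n_significant = sum(g$significant & g$direction_up),
               substrate = any(g$significant & g$direction_up),
               stringsAsFactors = FALSE)
  }))
  rownames(calls) <- NULL
  list(per_trial = s, calls = calls)
}

#' LC-MS/MS substrate analysis from raw samples
#'
#' Computes per-sample normalized ratios, per compound x condition x trial
#' means and SDs, and runs [classify_substrate()] on the resulting
#' summaries.
#'
#' @param samples data.frame: `compound_id`, `condition` (`"minus_TQR"` or
#'   `"plus_TQR"`), `trial`, `analyte_peak`, `is_peak`, `lysate`.
#' @param alpha significance level.
#' @return As [classify_substrate()], plus element `summaries`.
#' @export
lcms_substrate_analysis <- function(samples, alpha = 0.05) {
  need <- c("compound_id", "condition", "trial", "analyte_peak", "is_peak",
            "lysate")
  stopifnot(all(need %in% names(samples)))
  samples$ratio <- normalized_ratio(samples$analyte_peak, samples$is_peak,
                                    samples$lysate)
  key <- interaction(samples$compound_id, samples$trial, drop = TRUE)
  summaries <- do.call(rbind, lapply(split(samples, key), function(g) {
    mi <- g$ratio[g$condition == "minus_TQR"]
    pl <- g$ratio[g$condition == "plus_TQR"]
    if (length(mi) < 2L || length(pl) < 2L || length(mi) != length(pl)) {
      stop("need matched replicate groups (n >= 2) per condition for ",
           g$compound_id[1L], " trial ", g$trial[1L], call. = FALSE)
    }
    data.frame(compound_id = g$compound_id[1L], trial = g$trial[1L],
               mean_minus = mean(mi), sd_minus = stats::sd(mi),
               mean_plus = mean(pl), sd_plus = stats::sd(pl),
               n = length(mi), quantifiable = TRUE,
               stringsAsFactors = FALSE)
  }))
  rownames(summaries) <- NULL
  out <- classify_substrate(summaries, alpha = alpha)
  out$summaries <- summaries
  out
}

#' Daunorubicin accumulation fold change
#'
#' Fold change in intracellular daunorubicin fluorescence caused by a
#' compound: `mean(compound + DAU) / mean(DAU alone)`, with a two-sided
#' pooled t-test of the two groups. A fold above 1 with a significant p
#' indicates the compound blocks daunorubicin efflux.
#'
#' @param fluor_compound_dau fluorescence readings, compound + DAU wells.
#' @param fluor_dau_alone fluorescence readings, DAU-alone wells.
#' @param blank optional background fluorescence subtracted from both
#'   groups before analysis.
#' @param alpha significance level.
#' @return List `fold_change`, `t`, `df`, `p`, `significant`, `n`.
#' @export
dau_fold_change <- function(fluor_compound_dau, fluor_dau_alone, blank = 0,
                            alpha = 0.05) {
  if (length(fluor_compound_dau) == 0L || length(fluor_dau_alone) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  a <- fluor_compound_dau - blank
  b <- fluor_dau_alone - blank
  if (mean(b) <= 0) stop("DAU-alone mean must be positive", call. = FALSE)
  tt <- substrate_ttest(mean(b), stats::sd(b), length(b),
                        mean(a), stats::sd(a), length(a))
  list(fold_change = mean(a) / mean(b), t = tt$t, df = tt$df, p = tt$p,
       significant = tt$p < alpha,
       n = c(compound_dau = length(a), dau_alone = length(b)))
}
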