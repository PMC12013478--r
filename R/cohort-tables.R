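#' Baseline PVSvf group summaries of a D-CAA cohort
#'
#' Published per-group summary statistics of baseline perivascular space
#' volume fraction in a hereditary (Dutch-type) cerebral amyloid
#' angiopathy cohort: symptomatic mutation carriers, pre-symptomatic
#' mutation carriers, and two age-matched control groups. Also records
#' how many participants in each group had a follow-up visit. These
#' summaries drive the worked power and descriptive-statistics examples.
#'
#' @return data.frame with columns `group`, `n`, `mean_pvs_vf`,
#'   `sd_pvs_vf`, `n_followup`.
#' @export
dcaa_baseline_summary <- function() {
  data.frame(
    group = c("symptomatic", "presymptomatic",
              "control_over50", "control_under50"),
    n = c(28L, 15L, 10L, 17L),
    mean_pvs_vf = c(0.045, 0.026, 0.015, 0.006),
    sd_pvs_vf = c(0.026, 0.025, 0.005, 0.003),
    n_followup = c(16L, 13L, 3L, 8L)
  )
}

#' CAA small-vessel-disease burden score counts per group
#'
#' Per-score participant counts of the composite CAA cerebral
#' small-vessel-disease burden score (0-6) for the same four groups as
#' [dcaa_baseline_summary()]. Group totals can fall short of the group
#' sizes because of missing scores. Feeding a column to
#' [median_iqr_from_counts()] recovers the published median (IQR)
#' summaries.
#'
#' @return data.frame with column `score` (0-6) and one count column per
#'   group.
#' @export
dcaa_csvd_score_counts <- function() {
  data.frame(
    score = 0:6,
    symptomatic = c(0L, 0L, 0L, 7L, 2L, 9L, 7L),
    presymptomatic = c(6L, 3L, 1L, 2L, 2L, 0L, 1L),
    control_over50 = c(6L, 3L, 1L, 0L, 0L, 0L, 0L),
    control_under50 = c(15L, 2L, 0L, 0L, 0L, 0L, 0L)
  )
}

#' Follow-up availability percentage
#'
#' Percentage of baseline participants with an available follow-up
#' visit, rounded to whole percent as reported in cohort tables.
#'
#' @param n_baseline,n_followup group sizes at baseline and follow-up.
#' @return Percentage(s), rounded to integer.
#' @export
followup_availability_pct <- function(n_baseline, n_followup) {
  if (any(n_baseline <= 0) || any(n_followup < 0) ||
      any(n_followup > n_baseline))
    stop("need 0 <= n_followup <= n_baseline with n_baseline > 0")
  round(100 * n_followup / n_baseline)
}
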