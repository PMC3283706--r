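## extract the titer matrix (patients x antigens) for a set of antigens
.titer_matrix <- function(cohort, antigens) {
  missing <- setdiff(antigens, names(cohort))
  if (length(missing))
    .stopf("cohort lacks antigen column(s): %s",
           paste(missing, collapse = ", "))
  m <- as.matrix(cohort[, antigens, drop = FALSE])
  if (anyNA(m)) .stopf("titer matrix contains missing values")
  ## physical LU are strictly positive; zeros are tolerated here so the
  ## RR = +Inf edge case of cluster assignment stays reachable with
  ## hand-built synthetic input
  if (any(m < 0)) .stopf("titers must be nonnegative LU")
  rownames(m) <- cohort$patient_id
  m
}

#' Calibrate seropositivity cutoffs from healthy controls
#'
#' For each panel antigen, computes the control mean, sample standard
#' deviation (denominator n - 1) and the seropositivity cutoff
#' mean + 3 SD. This is the calibration behind Z-scores and seropositive
#' calls; ROC-optimal cutoffs for diagnostic tables are a separate policy
#' (see [roc_cutoff()]).
#'
#' @param cohort Cohort data frame with a \code{group} column.
#' @param panel Antigen columns to calibrate (default: every antigen in the
#'   cohort).
#' @return A data frame of class \code{control_stats} with columns
#'   \code{antigen}, \code{control_mean}, \code{control_sd}, \code{cutoff}.
#' @export
#' @examples
#' coh <- data.frame(patient_id = c("a", "b", "c"),
#'                   group = "CONTROL", X = c(1, 2, 3))
#' control_stats(coh)  # mean 2, SD 1, cutoff 5
control_stats <- function(cohort, panel = cohort_antigens(cohort)) {
  hc <- cohort[cohort$group == "CONTROL", , drop = FALSE]
  if (nrow(hc) < 2L)
    .stopf("calibration requires at least 2 controls, found %d", nrow(hc))
  m <- .titer_matrix(hc, panel)
  mu <- colMeans(m)
  sd_ <- apply(m, 2, stats::sd)
  if (any(sd_ == 0))
    .stopf("degenerate controls for antigen(s) %s: zero variance, cutoff undefined",
           paste(panel[sd_ == 0], collapse = ", "))
  structure(
    data.frame(antigen = panel, control_mean = unname(mu),
               control_sd = unname(sd_),
               cutoff = unname(mu + 3 * sd_),
               stringsAsFactors = FALSE),
    class = c("control_stats", "data.frame"))
}

## named cutoff / sd lookups with coverage check
.stats_lookup <- function(stats, antigens) {
  missing <- setdiff(antigens, stats$antigen)
  if (length(missing))
    .stopf("control stats missing antigen(s): %s",
           paste(missing, collapse = ", "))
  i <- match(antigens, stats$antigen)
  list(cutoff = stats::setNames(stats$cutoff[i], antigens),
       sd = stats::setNames(stats$control_sd[i], antigens),
       mean = stats::setNames(stats$control_mean[i], antigens))
}

#' Control-referenced Z-scores
#'
#' Z = (titer - cutoff) / control SD for every patient x antigen cell. A
#' titer exactly at the cutoff scores 0 and the control mean scores -3 by
#' construction. Values are not clipped; clipping is a display concern of the
#' heatmap.
#'
#' @param cohort Cohort data frame.
#' @param stats A \code{control_stats} object covering the panel.
#' @param panel Antigens to score (default: all antigens in \code{stats}).
#' @return Numeric matrix (patients x antigens) with the \code{control_stats}
#'   attached as attribute \code{"stats"}.
#' @export
z_scores <- function(cohort, stats, panel = stats$antigen) {
  lk <- .stats_lookup(stats, panel)
  m <- .titer_matrix(cohort, panel)
  z <- sweep(sweep(m, 2, lk$cutoff, "-"), 2, lk$sd, "/")
  attr(z, "stats") <- stats
  z
}

#' Seropositivity calls
#'
#' A patient is seropositive for an antigen iff the titer is strictly greater
#' than the cutoff (equivalently, Z > 0); a titer exactly at the cutoff is
#' negative.
#'
#' @inheritParams z_scores
#' @return Logical matrix (patients x antigens).
#' @export
call_seropositive <- function(cohort, stats, panel = stats$antigen) {
  lk <- .stats_lookup(stats, panel)
  m <- .titer_matrix(cohort, panel)
  sweep(m, 2, lk$cutoff, ">")
}

## sensitivity/specificity of "titer > cutoff" for one antigen
.perf <- function(titer_sle, titer_hc, antigen, cutoff) {
  sens <- 100 * mean(titer_sle > cutoff)
  spec <- 100 * mean(titer_hc <= cutoff)
  structure(
    data.frame(antigen = antigen, cutoff_used = cutoff,
               sensitivity = sens, specificity = spec,
               n_sle = length(titer_sle), n_control = length(titer_hc),
               stringsAsFactors = FALSE),
    class = c("diagnostic_performance", "data.frame"))
}

#' Diagnostic performance of a single antigen at a given cutoff
#'
#' Sensitivity = percent of SLE patients with titer strictly above the
#' cutoff; specificity = percent of controls at or below it. Percentages are
#' returned unrounded; use [round_half_away()] for display.
#'
#' @param cohort Cohort data frame containing both groups.
#' @param antigen Antigen column name.
#' @param cutoff Threshold in LU.
#' @return One-row data frame of class \code{diagnostic_performance}.
#' @export
diagnostic_performance <- function(cohort, antigen, cutoff) {
  sle <- cohort[cohort$group == "SLE", , drop = FALSE]
  hc <- cohort[cohort$group == "CONTROL", , drop = FALSE]
  if (nrow(sle) == 0L || nrow(hc) == 0L)
    .stopf("diagnostic performance needs both SLE and CONTROL patients")
  .perf(.titer_matrix(sle, antigen)[, 1], .titer_matrix(hc, antigen)[, 1],
        antigen, cutoff)
}

#' ROC-optimal cutoff by Youden's J
#'
#' Scans every threshold that yields a distinct classification: the midpoints
#' between adjacent sorted distinct titers plus -Inf and +Inf, and returns
#' the cutoff maximizing Youden's J = sensitivity + specificity - 100. Ties
#' are broken toward higher specificity, then toward the higher cutoff.
#'
#' @param cohort Cohort data frame containing both groups.
#' @param antigen Antigen column name.
#' @return List with \code{cutoff} (LU) and \code{performance} (a
#'   \code{diagnostic_performance} row at that cutoff).
#' @export
roc_cutoff <- function(cohort, antigen) {
  sle <- cohort[cohort$group == "SLE", , drop = FALSE]
  hc <- cohort[cohort$group == "CONTROL", , drop = FALSE]
  if (nrow(sle) == 0L || nrow(hc) == 0L)
    .stopf("ROC requires both SLE and CONTROL patients")
  x_sle <- .titer_matrix(sle, antigen)[, 1]
  x_hc <- .titer_matrix(hc, antigen)[, 1]
  .roc_scan(x_sle, x_hc, antigen)
}

.roc_scan <- function(x_sle, x_hc, label = "score") {
  v <- sort(unique(c(x_sle, x_hc)))
  if (length(v) < 2L)
    .stopf("no separation possible: all titers identical")
  cand <- c(-Inf, (v[-1] + v[-length(v)]) / 2, Inf)
  sens <- vapply(cand, function(ct) 100 * mean(x_sle > ct), numeric(1))
  spec <- vapply(cand, function(ct) 100 * mean(x_hc <= ct), numeric(1))
  j <- sens + spec - 100
  ord <- order(-j, -spec, -cand)
  best <- ord[1]
  list(cutoff = cand[best],
       performance = .perf(x_sle, x_hc, label, cand[best]))
}

#' Panel union sensitivity and specificity
#'
#' A patient is panel-positive iff seropositive for at least one panel
#' antigen. Sensitivity is the percent of panel-positive SLE patients;
#' specificity the percent of controls with zero positive calls.
#'
#' @param cohort Cohort data frame containing both groups.
#' @param stats A \code{control_stats} covering the panel.
#' @param panel Nonempty antigen vector.
#' @return One-row data frame of class \code{diagnostic_performance} with
#'   \code{antigen} set to a panel label and \code{cutoff_used} NA.
#' @export
panel_sensitivity <- function(cohort, stats, panel = stats$antigen) {
  if (length(panel) == 0L) .stopf("panel must be nonempty")
  sle <- cohort[cohort$group == "SLE", , drop = FALSE]
  hc <- cohort[cohort$group == "CONTROL", , drop = FALSE]
  if (nrow(sle) == 0L || nrow(hc) == 0L)
    .stopf("panel performance needs both SLE and CONTROL patients")
  pos_sle <- rowSums(call_seropositive(sle, stats, panel)) > 0
  pos_hc <- rowSums(call_seropositive(hc, stats, panel)) > 0
  structure(
    data.frame(antigen = paste0("panel(", length(panel), ")"),
               cutoff_used = NA_real_,
               sensitivity = 100 * mean(pos_sle),
               specificity = 100 * mean(!pos_hc),
               n_sle = nrow(sle), n_control = nrow(hc),
               stringsAsFactors = FALSE),
    class = c("diagnostic_performance", "data.frame"))
}
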