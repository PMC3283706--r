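#' Fit an autoantibody serology profile
#'
#' The central fitting function of the package. Given a cohort of SLE
#' patients and healthy controls it (1) calibrates per-antigen mean + 3 SD
#' seropositivity cutoffs from the controls, (2) computes control-referenced
#' Z-scores and seropositive calls for every patient, (3) assigns every SLE
#' patient to the Sm/RNP cluster, the Ro/La cluster, or the seronegative
#' remainder by the relative-ratio rule on the six core antigens, and (4)
#' evaluates per-antigen diagnostic performance both at the calibrated
#' cutoffs and at ROC-optimal (Youden) cutoffs, plus the panel union
#' sensitivity. The two cutoff policies are deliberately kept separate and
#' reported side by side.
#'
#' @param cohort Cohort data frame (see [read_cohort()] /
#'   [simulate_cohort()] for the layout).
#' @param panel Antigens to profile (default: all antigen columns). Cluster
#'   assignment requires the six core antigens to be present in the cohort.
#' @return Object of class \code{lips_profile} with components
#'   \code{stats} (control calibration), \code{z} (Z matrix), \code{calls}
#'   (logical matrix), \code{assignments}, \code{prevalence},
#'   \code{performance} (per antigen, both policies), \code{panel_perf},
#'   and \code{cohort}.
#' @seealso [assign_clusters()], [control_stats()], [roc_cutoff()]
#' @export
#' @examples
#' sim <- simulate_cohort(default_sim_config(seed = 11))
#' fit <- lips_profile(sim$cohort)
#' fit
#' coef(fit)
lips_profile <- function(cohort, panel = cohort_antigens(cohort)) {
  stats <- control_stats(cohort, panel)
  z <- z_scores(cohort, stats)
  calls <- call_seropositive(cohort, stats)

  assignments <- NULL
  prevalence <- NULL
  if (all(CORE_ANTIGENS %in% panel)) {
    assignments <- assign_clusters(cohort, stats)
    prevalence <- cluster_prevalence(assignments)
  }

  lk <- .stats_lookup(stats, panel)
  perf <- do.call(rbind, lapply(panel, function(ag) {
    p3 <- diagnostic_performance(cohort, ag, lk$cutoff[[ag]])
    pr <- roc_cutoff(cohort, ag)
    data.frame(antigen = ag,
               cutoff_mean3sd = lk$cutoff[[ag]],
               sens_mean3sd = p3$sensitivity, spec_mean3sd = p3$specificity,
               cutoff_roc = pr$cutoff,
               sens_roc = pr$performance$sensitivity,
               spec_roc = pr$performance$specificity,
               stringsAsFactors = FALSE)
  }))
  union_panel <- if (all(CORE_ANTIGENS %in% panel)) CORE_ANTIGENS else panel
  panel_perf <- panel_sensitivity(cohort, stats, union_panel)

  structure(list(stats = stats, z = z, calls = calls,
                 assignments = assignments, prevalence = prevalence,
                 performance = perf, panel_perf = panel_perf,
                 panel = panel, cohort = cohort,
                 call = match.call()),
            class = "lips_profile")
}

#' @export
print.lips_profile <- function(x, ...) {
  n_sle <- sum(x$cohort$group == "SLE")
  n_hc <- sum(x$cohort$group == "CONTROL")
  cat("Autoantibody serology profile\n")
  cat(sprintf("  %d SLE patients, %d controls, %d antigens\n",
              n_sle, n_hc, length(x$panel)))
  cat(sprintf("  core-panel union: sensitivity %d%%, specificity %d%%\n",
              round_half_away(x$panel_perf$sensitivity),
              round_half_away(x$panel_perf$specificity)))
  if (!is.null(x$prevalence)) print(x$prevalence)
  invisible(x)
}

#' @describeIn lips_profile Per-antigen performance under both cutoff
#'   policies, plus cluster prevalence.
#' @param object,x A \code{lips_profile}.
#' @param ... Unused.
#' @export
summary.lips_profile <- function(object, ...) {
  out <- list(performance = object$performance,
              panel_perf = object$panel_perf,
              prevalence = object$prevalence)
  class(out) <- "summary.lips_profile"
  out
}

#' @export
print.summary.lips_profile <- function(x, ...) {
  cat("Per-antigen diagnostic performance (percent):\n")
  df <- x$performance
  df[-1] <- lapply(df[-1], function(v) signif(v, 4))
  print(df, row.names = FALSE)
  cat(sprintf("\nPanel union: sensitivity %.1f%%, specificity %.1f%%\n",
              x$panel_perf$sensitivity, x$panel_perf$specificity))
  if (!is.null(x$prevalence)) { cat("\n"); print(x$prevalence) }
  invisible(x)
}

#' @describeIn lips_profile Calibrated mean + 3 SD cutoffs as a named
#'   vector (LU).
#' @export
coef.lips_profile <- function(object, ...) {
  stats::setNames(object$stats$cutoff, object$stats$antigen)
}

#' @describeIn lips_profile Apply the fitted calibration to a new cohort:
#'   \code{type = "label"} returns cluster labels for SLE rows,
#'   \code{"call"} the seropositivity matrix, \code{"z"} the Z matrix.
#' @param newdata Cohort data frame; defaults to the training cohort.
#' @param type One of \code{"label"}, \code{"call"}, \code{"z"}.
#' @export
predict.lips_profile <- function(object, newdata = object$cohort,
                                 type = c("label", "call", "z"), ...) {
  type <- match.arg(type)
  switch(type,
         label = {
           a <- assign_clusters(newdata, object$stats)
           stats::setNames(a$label, a$patient_id)
         },
         call = call_seropositive(newdata, object$stats,
                                  intersect(object$panel,
                                            names(newdata))),
         z = z_scores(newdata, object$stats,
                      intersect(object$panel, names(newdata))))
}

#' @describeIn lips_profile Draw the cluster-ordered Z-score heatmap on the
#'   active device (black = at/below cutoff, green = \code{z_max} SD above).
#' @param z_max Display saturation in SD units.
#' @export
plot.lips_profile <- function(x, z_max = 10, ...) {
  if (is.null(x$assignments))
    .stopf("plot needs cluster assignments (six core antigens)")
  ord <- heatmap_order(x$assignments)
  zc <- pmin(pmax(x$z[ord, , drop = FALSE], 0), z_max)
  .heatmap_draw(zc, z_max)
  invisible(x)
}
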