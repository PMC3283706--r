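#' Simulate a six-antigen mixture assay readout
#'
#' Models the single-well mixture test as the sum of the six core individual
#' titers times multiplicative lognormal noise with a given coefficient of
#' variation (mean-1 noise, so the mixture is unbiased for the sum). With
#' \code{noise_cv = 0} the mixture equals the sum exactly.
#'
#' @param cohort Cohort data frame with the six core antigens.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (nonnegative).
#' @param seed Integer seed.
#' @return Named numeric vector of mixture light units, one per patient.
#' @export
simulate_mixture <- function(cohort, noise_cv = 0.2, seed = 1L) {
  if (noise_cv < 0) .stopf("simulate_mixture: noise_cv must be >= 0")
  s <- rowSums(.titer_matrix(cohort, CORE_ANTIGENS))
  if (noise_cv == 0) return(stats::setNames(s, cohort$patient_id))
  sigma <- sqrt(log1p(noise_cv^2))
  .with_seed(seed, {
    noise <- exp(stats::rnorm(length(s), -sigma^2 / 2, sigma))
    stats::setNames(s * noise, cohort$patient_id)
  })
}

#' Compare the mixture assay with the sum of individual titers
#'
#' Computes the Spearman rank correlation between the mixture readout and
#' the sum of the six individual titers, and the mixture's own diagnostic
#' performance at its ROC-optimal (Youden) cutoff against the SLE / control
#' labels.
#'
#' @param mixture Named mixture LU vector as from [simulate_mixture()]
#'   (names = patient ids).
#' @param cohort Cohort data frame with groups and the six core antigens.
#' @return List of class \code{mixture_result}: \code{per_patient} (data
#'   frame patient_id, mixture_lu, sum_individual_lu), \code{spearman_rho},
#'   \code{rho_p}, \code{cutoff}, \code{sensitivity}, \code{specificity}.
#' @export
compare_mixture_to_sum <- function(mixture, cohort) {
  i <- match(cohort$patient_id, names(mixture))
  if (anyNA(i))
    .stopf("mixture values missing for patient id(s): %s",
           paste(utils::head(cohort$patient_id[is.na(i)], 5), collapse = ", "))
  mix <- unname(mixture[i])
  s <- rowSums(.titer_matrix(cohort, CORE_ANTIGENS))
  rho <- spearman_rho(mix, s)
  is_sle <- cohort$group == "SLE"
  roc <- .roc_scan(mix[is_sle], mix[!is_sle], "mixture")
  structure(
    list(per_patient = data.frame(patient_id = cohort$patient_id,
                                  mixture_lu = mix,
                                  sum_individual_lu = unname(s),
                                  stringsAsFactors = FALSE),
         spearman_rho = rho$statistic, rho_p = rho$p_two_sided,
         cutoff = roc$cutoff,
         sensitivity = roc$performance$sensitivity,
         specificity = roc$performance$specificity),
    class = "mixture_result")
}

#' @export
print.mixture_result <- function(x, ...) {
  cat("Mixture assay vs sum of individual titers\n")
  cat(sprintf("  Spearman rho = %.3f (p = %.3g)\n", x$spearman_rho, x$rho_p))
  cat(sprintf("  ROC cutoff %.4g LU: sensitivity %d%%, specificity %d%%\n",
              x$cutoff, round_half_away(x$sensitivity),
              round_half_away(x$specificity)))
  invisible(x)
}
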