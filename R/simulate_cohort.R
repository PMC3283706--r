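#' Analytic generating cutoffs of a simulation configuration
#'
#' The mean + 3 SD threshold of the configured control titer distribution,
#' computed in closed form from the lognormal moments. This is the "true"
#' cutoff the generator itself uses to keep SERONEGATIVE patients below
#' threshold; the analysis pipeline never sees it and must re-estimate cutoffs
#' from the sampled controls.
#'
#' @param cfg A \code{sim_config}.
#' @return Named numeric vector of cutoffs in LU, one per panel antigen.
#' @export
generating_cutoffs <- function(cfg) {
  ag <- cfg$antigen_names
  m <- .lnorm10_mean(cfg$control_log_mean[ag], cfg$control_log_sd[ag])
  s <- .lnorm10_sd(cfg$control_log_mean[ag], cfg$control_log_sd[ag])
  stats::setNames(m + 3 * s, ag)
}

#' Simulate a serology cohort with latent cluster structure
#'
#' Draws a control group from per-antigen log10-lognormal titer
#' distributions, assigns each SLE patient a latent class (Sm/RNP, Ro/La or
#' seronegative), and draws titers antigen by antigen: with the
#' class-specific probability the patient is seropositive and the titer
#' location is shifted up by \code{pos_log_shift} decades, otherwise the
#' titer comes from the control distribution. SERONEGATIVE patients draw all
#' six core-antigen titers from the control distribution truncated at the
#' analytic generating cutoff, so they are never seropositive on a core
#' antigen. Clinical flags are conditionally independent Bernoulli draws
#' given the latent class. All randomness is consumed on a fixed schedule, so
#' a given seed yields a byte-identical cohort regardless of branch outcomes.
#'
#' The latent class is returned as a separate truth table, never as a column
#' of the analysis input, to keep generator truth out of the pipeline under
#' test.
#'
#' @param cfg A \code{sim_config}.
#' @param seed Optional integer overriding \code{cfg$seed}.
#' @return An object of class \code{sim_cohort}: a list with \code{cohort}
#'   (data frame: patient_id, group, one LU column per antigen, clinical
#'   flags as 0/1 with NA for controls, demographics, dsdna_pos) and
#'   \code{truth} (data frame: patient_id, latent_class).
#' @export
#' @examples
#' sim <- simulate_cohort(default_sim_config(seed = 42))
#' table(sim$truth$latent_class)
simulate_cohort <- function(cfg, seed = NULL) {
  validate_sim_config(cfg)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  ag <- cfg$antigen_names
  k <- length(ag)
  n_sle <- cfg$n_sle
  n_hc <- cfg$n_control
  mu <- cfg$control_log_mean[ag]
  sig <- cfg$control_log_sd[ag]
  gen_cut <- generating_cutoffs(cfg)

  .with_seed(cfg$seed, {
    ## 1. control titers
    z_hc <- matrix(stats::rnorm(n_hc * k), n_hc, k)
    hc_titers <- 10^sweep(sweep(z_hc, 2, sig, "*"), 2, mu, "+")

    ## 2. latent classes
    cp <- cfg$cluster_probs[CLASSES]
    u_class <- stats::runif(n_sle)
    latent <- CLASSES[findInterval(u_class, cumsum(cp),
                                   left.open = TRUE) + 1L]

    ## 3. SLE titers (fixed draw schedule: three n_sle x k blocks)
    u_pos <- matrix(stats::runif(n_sle * k), n_sle, k)
    z_sle <- matrix(stats::rnorm(n_sle * k), n_sle, k)
    u_trunc <- matrix(stats::runif(n_sle * k), n_sle, k)

    sle_titers <- matrix(0, n_sle, k, dimnames = list(NULL, ag))
    for (j in seq_len(k)) {
      p_class <- cfg$seropos_prob[ag[j], latent]
      is_pos <- u_pos[, j] < p_class
      lt <- mu[j] + ifelse(is_pos, cfg$pos_log_shift[ag[j]], 0) +
        sig[j] * z_sle[, j]
      titer <- 10^lt
      if (ag[j] %in% CORE_ANTIGENS) {
        ## truncated control draw for the seronegative latent class
        sn <- latent == "SERONEGATIVE"
        if (any(sn)) {
          p_cut <- stats::pnorm((log10(gen_cut[j]) - mu[j]) / sig[j])
          q <- stats::qnorm(u_trunc[sn, j] * p_cut)
          titer[sn] <- 10^(mu[j] + sig[j] * q)
        }
      }
      sle_titers[, j] <- titer
    }

    ## 4. clinical flags, dsDNA
    u_clin <- matrix(stats::runif(n_sle * length(CLINICAL_FLAGS)),
                     n_sle, length(CLINICAL_FLAGS),
                     dimnames = list(NULL, CLINICAL_FLAGS))
    clin <- matrix(0L, n_sle, length(CLINICAL_FLAGS),
                   dimnames = list(NULL, CLINICAL_FLAGS))
    for (fl in CLINICAL_FLAGS)
      clin[, fl] <- as.integer(u_clin[, fl] < cfg$clinical_rates[fl, latent])
    dsdna <- as.integer(stats::runif(n_sle) < cfg$p_dsdna)

    ## 5. demographics for everyone (SLE first, controls after)
    n_all <- n_sle + n_hc
    sex <- ifelse(stats::runif(n_all) < cfg$p_female, "F", "M")
    eth_lab <- names(cfg$ethnicity_probs)
    eth <- eth_lab[findInterval(stats::runif(n_all),
                                cumsum(cfg$ethnicity_probs),
                                left.open = TRUE) + 1L]
    age_lab <- names(cfg$age_probs)
    age <- age_lab[findInterval(stats::runif(n_all), cumsum(cfg$age_probs),
                                left.open = TRUE) + 1L]

    sle_id <- sprintf("S%03d", seq_len(n_sle))
    hc_id <- sprintf("C%03d", seq_len(n_hc))

    titer_df <- as.data.frame(rbind(sle_titers, hc_titers))
    names(titer_df) <- ag
    clin_df <- as.data.frame(rbind(clin,
                                   matrix(NA_integer_, n_hc,
                                          length(CLINICAL_FLAGS))))
    names(clin_df) <- CLINICAL_FLAGS

    cohort <- cbind(
      data.frame(patient_id = c(sle_id, hc_id),
                 group = rep(c("SLE", "CONTROL"), c(n_sle, n_hc)),
                 stringsAsFactors = FALSE),
      titer_df, clin_df,
      data.frame(sex = sex, ethnicity = eth, age_group = age,
                 dsdna_pos = c(dsdna, rep(NA_integer_, n_hc)),
                 stringsAsFactors = FALSE))
    rownames(cohort) <- NULL

    truth <- data.frame(patient_id = sle_id, latent_class = latent,
                        stringsAsFactors = FALSE)
    structure(list(cohort = cohort, truth = truth, config = cfg),
              class = "sim_cohort")
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Simulated serology cohort\n")
  cat(sprintf("  %d SLE patients, %d controls, %d antigens\n",
              x$config$n_sle, x$config$n_control,
              length(x$config$antigen_names)))
  tab <- table(factor(x$truth$latent_class, levels = CLASSES))
  cat("  latent classes:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}
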