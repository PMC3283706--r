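#' Core antigen panel constants
#'
#' The six nuclear antigens used for cluster assignment: the Sm/RNP trio
#' (Sm-D3, RNP-A, RNP-70k) and the Ro/La trio (Ro52, Ro60, La).
#'
#' @format Character vectors of antigen labels.
#' @name core_antigens
NULL

#' @rdname core_antigens
#' @export
SMRNP_TRIO <- c("Sm-D3", "RNP-A", "RNP-70k")

#' @rdname core_antigens
#' @export
ROLA_TRIO <- c("Ro52", "Ro60", "La")

#' @rdname core_antigens
#' @export
CORE_ANTIGENS <- c(SMRNP_TRIO, ROLA_TRIO)

## latent class labels, fixed order
CLASSES <- c("SM_RNP", "RO_LA", "SERONEGATIVE")

## clinical manifestation flags carried by simulated SLE patients
CLINICAL_FLAGS <- c("cns", "musculoskeletal", "mucocutaneous", "nephritis",
                    "serositis", "hematological", "sacq", "quiescent")

#' Simulation configuration for a synthetic serology cohort
#'
#' Bundles and validates every parameter of the cohort generator: sample
#' sizes, the antigen panel, latent-class mixing proportions, class-specific
#' seropositivity probabilities, control titer distributions (log10-lognormal)
#' and seropositive titer shifts, clinical manifestation rates per latent
#' class, demographics, and mixture-assay noise.
#'
#' Titers for antigen \eqn{j} are drawn as \eqn{10^{\mu_j + \sigma_j Z}} with
#' \eqn{Z \sim N(0,1)}; seropositive draws add \code{pos_log_shift[j]} decades
#' to the location. Patients of the SERONEGATIVE latent class have their six
#' core-antigen titers drawn from the control distribution truncated at the
#' analytic mean + 3 SD generating cutoff, so they can never be seropositive
#' on a core antigen by construction.
#'
#' @param n_sle,n_control Group sizes (each at least 1).
#' @param antigen_names Character vector naming the panel, core antigens
#'   first.
#' @param cluster_probs Named numeric of length 3 (SM_RNP, RO_LA,
#'   SERONEGATIVE) summing to 1.
#' @param seropos_prob Antigen-by-class matrix of seropositivity
#'   probabilities; rows named by antigen, columns SM_RNP / RO_LA /
#'   SERONEGATIVE.
#' @param control_log_mean,control_log_sd Per-antigen location and scale of
#'   the control titer distribution on the log10 scale (named numerics).
#' @param pos_log_shift Per-antigen log10 increment applied to seropositive
#'   titers (named numeric).
#' @param clinical_rates Flag-by-class matrix of Bernoulli rates for the
#'   clinical manifestation flags (rows \code{cns}, \code{musculoskeletal},
#'   \code{mucocutaneous}, \code{nephritis}, \code{serositis},
#'   \code{hematological}, \code{sacq}, \code{quiescent}).
#' @param p_female Probability a patient is female.
#' @param ethnicity_probs Named probabilities over C / AA / A.
#' @param age_probs Named probabilities over the \code{<20}, \code{20-40},
#'   \code{>40} age groups.
#' @param p_dsdna Probability an SLE patient is anti-dsDNA positive.
#' @param mixture_noise_cv Coefficient of variation of the multiplicative
#'   mixture-assay noise (nonnegative).
#' @param seed Integer seed making generation deterministic.
#' @return An object of class \code{sim_config} (a validated list).
#' @seealso [default_sim_config()], [simulate_cohort()]
#' @export
sim_config <- function(n_sle, n_control, antigen_names,
                       cluster_probs, seropos_prob,
                       control_log_mean, control_log_sd, pos_log_shift,
                       clinical_rates,
                       p_female = 13 / 14,
                       ethnicity_probs = c(C = 0.60, AA = 0.35, A = 0.05),
                       age_probs = c("<20" = 0.18, "20-40" = 0.59,
                                     ">40" = 0.23),
                       p_dsdna = 0.58,
                       mixture_noise_cv = 0.2,
                       seed = 1L) {
  cfg <- structure(
    list(n_sle = as.integer(n_sle), n_control = as.integer(n_control),
         antigen_names = as.character(antigen_names),
         cluster_probs = cluster_probs, seropos_prob = seropos_prob,
         control_log_mean = control_log_mean,
         control_log_sd = control_log_sd,
         pos_log_shift = pos_log_shift,
         clinical_rates = clinical_rates,
         p_female = p_female, ethnicity_probs = ethnicity_probs,
         age_probs = age_probs, p_dsdna = p_dsdna,
         mixture_noise_cv = mixture_noise_cv, seed = as.integer(seed)),
    class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks probability ranges, positivity of scales and sample sizes, that
#' cluster probabilities sum to one, and that every per-antigen parameter
#' covers every panel antigen. Errors name the offending field.
#'
#' @param cfg A \code{sim_config}.
#' @return \code{cfg}, invisibly, if valid.
#' @export
validate_sim_config <- function(cfg) {
  if (cfg$n_sle < 1L) .stopf("n_sle: must be >= 1, got %d", cfg$n_sle)
  if (cfg$n_control < 1L)
    .stopf("n_control: must be >= 1, got %d", cfg$n_control)
  if (length(cfg$antigen_names) < 1L || anyDuplicated(cfg$antigen_names))
    .stopf("antigen_names: must be nonempty and unique")

  cp <- cfg$cluster_probs
  if (length(cp) != 3L || !setequal(names(cp), CLASSES))
    .stopf("cluster_probs: need the three named classes %s",
           paste(CLASSES, collapse = ", "))
  if (any(cp < 0 | cp > 1))
    .stopf("cluster_probs: probabilities must lie in [0,1]")
  if (abs(sum(cp) - 1) > 1e-9)
    .stopf("cluster_probs: must sum to 1 (got %.12f)", sum(cp))

  sp <- cfg$seropos_prob
  if (!is.matrix(sp) || !all(cfg$antigen_names %in% rownames(sp)) ||
      !all(CLASSES %in% colnames(sp)))
    .stopf("seropos_prob: need an antigen x class matrix covering the panel")
  if (any(sp < 0 | sp > 1))
    .stopf("seropos_prob: probabilities must lie in [0,1]")

  for (fld in c("control_log_mean", "control_log_sd", "pos_log_shift")) {
    v <- cfg[[fld]]
    if (!all(cfg$antigen_names %in% names(v)))
      .stopf("%s: missing entries for some panel antigens", fld)
    if (anyNA(v) || !is.numeric(v)) .stopf("%s: must be numeric", fld)
  }
  if (any(cfg$control_log_sd[cfg$antigen_names] <= 0))
    .stopf("control_log_sd: scales must be > 0")
  if (any(cfg$pos_log_shift[cfg$antigen_names] < 0))
    .stopf("pos_log_shift: shifts must be >= 0")

  cr <- cfg$clinical_rates
  if (!is.matrix(cr) || !all(CLINICAL_FLAGS %in% rownames(cr)) ||
      !all(CLASSES %in% colnames(cr)))
    .stopf("clinical_rates: need a flag x class matrix covering %s",
           paste(CLINICAL_FLAGS, collapse = ", "))
  if (any(cr < 0 | cr > 1))
    .stopf("clinical_rates: rates must lie in [0,1]")

  for (fld in c("p_female", "p_dsdna")) {
    v <- cfg[[fld]]
    if (length(v) != 1L || v < 0 || v > 1)
      .stopf("%s: must be a single probability in [0,1]", fld)
  }
  for (fld in c("ethnicity_probs", "age_probs")) {
    v <- cfg[[fld]]
    if (any(v < 0) || abs(sum(v) - 1) > 1e-9)
      .stopf("%s: must be nonnegative and sum to 1", fld)
  }
  if (cfg$mixture_noise_cv < 0)
    .stopf("mixture_noise_cv: must be >= 0")
  invisible(cfg)
}

## per-antigen calibration table for the default configuration:
## control mean and 95% CI half-width (LU, n = 15 controls), SLE cohort mean
## (LU), marginal seropositive fraction, and (extended panel only) the
## per-cluster seropositivity rates.
.default_calibration <- function() {
  core <- data.frame(
    antigen  = c("Sm-D3", "RNP-A", "RNP-70k", "Ro52", "Ro60", "La"),
    hc_mean  = c(4800, 12600, 28800, 10000, 5000, 4700),
    hc_half  = c(600, 4400, 4000, 4000, 1900, 1400),
    sle_mean = c(77000, 276000, 559000, 895000, 1.2e6, 464000),
    sens     = c(0.65, 0.55, 0.85, 0.51, 0.51, 0.71),
    stringsAsFactors = FALSE)
  extra <- data.frame(
    antigen  = c("IFN-alpha", "IFN-omega", "TH", "AQP-4", "GAD65", "GFAP"),
    hc_mean  = c(2000, 1900, 11600, 10600, 4300, 7700),
    hc_half  = c(450, 150, 8150, 8500, 1650, 2450),
    sle_mean = c(88000, 7800, 15000, 27000, 4200, 21000),
    sens     = c(0.12, 0.38, 0.09, 0.05, 0.05, 0.16),
    rate_rola  = c(0.06, 0.41, 0.08, 0.05, 0.02, 0.15),
    rate_smrnp = c(0.17, 0.35, 0.10, 0.05, 0.06, 0.17),
    stringsAsFactors = FALSE)
  list(core = core, extra = extra, n_hc = 15L)
}

#' Default simulation configuration calibrated to a validation-cohort panel
#'
#' Builds the study-condition defaults of the generator: 129 SLE patients and
#' 15 healthy controls, latent-class proportions 47% Sm/RNP, 51% Ro/La and 2%
#' seronegative, and per-antigen control distributions whose arithmetic means
#' reproduce published healthy-control mean titers (e.g. Sm-D3 4,800 LU,
#' RNP-70k 28,800 LU). Control SDs are back-computed from the 95% CI
#' half-width assuming a normal-theory CI with n = 15. Class-conditional
#' seropositivity probabilities are solved so the marginal per-antigen
#' seropositive fraction matches the published single-antigen sensitivities
#' (own-trio probability fixed at 1, consistent with every cluster member
#' reacting against its own trio). Seropositive log-shifts are deconvolved
#' from the cohort-level SLE mean (positive-subgroup mean approximately
#' \eqn{(m_{SLE} - (1-p) m_{HC})/p}), floored at one decade.
#'
#' @param n_sle,n_control Group sizes (defaults 129 and 15).
#' @param extended If \code{TRUE}, append the cytokine/neuronal antigens
#'   (IFN-alpha, IFN-omega, TH, AQP-4, GAD65, GFAP) with per-cluster
#'   seropositivity rates.
#' @param seed Integer seed stored in the configuration.
#' @return A \code{sim_config}.
#' @export
#' @examples
#' cfg <- default_sim_config(seed = 7)
#' cfg$cluster_probs
default_sim_config <- function(n_sle = 129, n_control = 15,
                               extended = FALSE, seed = 1L) {
  cal <- .default_calibration()
  tab <- cal$core
  if (extended) {
    ex <- cal$extra
    tab <- rbind(tab, ex[, names(tab)])
  }
  cluster_probs <- c(SM_RNP = 0.47, RO_LA = 0.51, SERONEGATIVE = 0.02)

  hc_sd <- tab$hc_half * sqrt(cal$n_hc) / stats::qnorm(0.975)
  par <- .lnorm10_params(tab$hc_mean, hc_sd)
  mu10 <- stats::setNames(par$mu10, tab$antigen)
  sigma10 <- stats::setNames(par$sigma10, tab$antigen)

  ## positive-subgroup mean deconvolved from the cohort mean, floored at 10x
  pos_mean <- (tab$sle_mean - (1 - tab$sens) * tab$hc_mean) / tab$sens
  shift <- pmax(log10(pmax(pos_mean, tab$hc_mean) / tab$hc_mean), 1)
  shift <- stats::setNames(shift, tab$antigen)

  sp <- matrix(0, nrow(tab), 3,
               dimnames = list(tab$antigen, CLASSES))
  for (i in seq_len(nrow(tab))) {
    ag <- tab$antigen[i]
    if (ag %in% SMRNP_TRIO) {
      sp[ag, "SM_RNP"] <- 1
      sp[ag, "RO_LA"] <- min(max((tab$sens[i] - cluster_probs["SM_RNP"]) /
                                   cluster_probs["RO_LA"], 0), 1)
    } else if (ag %in% ROLA_TRIO) {
      sp[ag, "RO_LA"] <- 1
      sp[ag, "SM_RNP"] <- min(max((tab$sens[i] - cluster_probs["RO_LA"]) /
                                    cluster_probs["SM_RNP"], 0), 1)
    } else {
      ex <- cal$extra
      j <- match(ag, ex$antigen)
      sp[ag, ] <- c(ex$rate_smrnp[j], ex$rate_rola[j], ex$sens[j])
    }
  }

  clinical_rates <- cbind(
    SM_RNP = c(cns = 0.02, musculoskeletal = 0.44, mucocutaneous = 0.33,
               nephritis = 0.25, serositis = 0.13, hematological = 0.13,
               sacq = 0.10, quiescent = 0.13),
    RO_LA = c(cns = 0.07, musculoskeletal = 0.30, mucocutaneous = 0.39,
              nephritis = 0.37, serositis = 0.00, hematological = 0.18,
              sacq = 0.07, quiescent = 0.04))
  clinical_rates <- cbind(clinical_rates,
                          SERONEGATIVE = rowMeans(clinical_rates))

  sim_config(n_sle = n_sle, n_control = n_control,
             antigen_names = tab$antigen,
             cluster_probs = cluster_probs,
             seropos_prob = sp,
             control_log_mean = mu10,
             control_log_sd = sigma10,
             pos_log_shift = shift,
             clinical_rates = clinical_rates,
             seed = seed)
}
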