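#' Read and write cohort tables
#'
#' Cohorts are stored as plain CSV, one row per patient: \code{patient_id},
#' \code{group} (SLE or CONTROL), one light-unit column per antigen, clinical
#' flags as 0/1 (empty for controls), demographics and anti-dsDNA status.
#' Latent truth, when present, is a separate two-column CSV
#' (\code{patient_id}, \code{latent_class}) so generator truth never enters
#' the analysis input.
#'
#' @param x A cohort data frame or a \code{sim_cohort}.
#' @param file Path of the cohort CSV.
#' @param truth_file Optional path for the latent-class truth CSV (only
#'   meaningful for simulated cohorts).
#' @return \code{write_cohort} returns \code{file} invisibly;
#'   \code{read_cohort} returns the cohort data frame.
#' @export
write_cohort <- function(x, file, truth_file = NULL) {
  if (inherits(x, "sim_cohort")) {
    if (!is.null(truth_file))
      utils::write.csv(x$truth, truth_file, row.names = FALSE)
    x <- x$cohort
  }
  utils::write.csv(x, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c("patient_id", "group"))
    if (!col %in% names(df))
      .stopf("cohort file %s: missing required column '%s'", file, col)
  if (!all(df$group %in% c("SLE", "CONTROL")))
    .stopf("cohort file %s: group must be SLE or CONTROL", file)
  df
}

#' @rdname write_cohort
#' @export
read_truth <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("patient_id", "latent_class") %in% names(df)))
    .stopf("truth file %s: need columns patient_id, latent_class", file)
  df
}

#' Antigen columns of a cohort table
#'
#' Every column that is neither an identifier, a clinical flag nor a
#' demographic is treated as an antigen titer column.
#'
#' @param cohort Cohort data frame.
#' @return Character vector of antigen column names.
#' @export
cohort_antigens <- function(cohort) {
  reserved <- c("patient_id", "group", CLINICAL_FLAGS,
                "sex", "ethnicity", "age_group", "dsdna_pos")
  setdiff(names(cohort), reserved)
}

## ---- YAML configuration serialization ----

#' Serialize a simulation configuration to YAML
#'
#' Matrices are written as nested maps (row label -> column label -> value)
#' and rebuilt on read, so a configuration round-trips unchanged (up to
#' floating-point formatting at 15 significant digits).
#'
#' @param cfg A \code{sim_config}.
#' @param file YAML path.
#' @return \code{write_sim_config} returns \code{file} invisibly;
#'   \code{read_sim_config} returns a validated \code{sim_config}.
#' @export
write_sim_config <- function(cfg, file) {
  mat2list <- function(m)
    lapply(stats::setNames(rownames(m), rownames(m)),
           function(r) as.list(stats::setNames(m[r, ], colnames(m))))
  lst <- list(
    n_sle = cfg$n_sle, n_control = cfg$n_control,
    antigen_names = as.list(cfg$antigen_names),
    cluster_probs = as.list(cfg$cluster_probs),
    seropos_prob = mat2list(cfg$seropos_prob),
    control_log_mean = as.list(cfg$control_log_mean),
    control_log_sd = as.list(cfg$control_log_sd),
    pos_log_shift = as.list(cfg$pos_log_shift),
    clinical_rates = mat2list(cfg$clinical_rates),
    p_female = cfg$p_female,
    ethnicity_probs = as.list(cfg$ethnicity_probs),
    age_probs = as.list(cfg$age_probs),
    p_dsdna = cfg$p_dsdna,
    mixture_noise_cv = cfg$mixture_noise_cv,
    seed = cfg$seed)
  writeLines(yaml::as.yaml(lst, precision = 15L), file)
  invisible(file)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(file) {
  lst <- yaml::read_yaml(file)
  list2mat <- function(l) {
    rows <- names(l)
    cols <- names(l[[1]])
    m <- matrix(NA_real_, length(rows), length(cols),
                dimnames = list(rows, cols))
    for (r in rows) m[r, ] <- unlist(l[[r]])[cols]
    m
  }
  num <- function(x) unlist(x)
  sim_config(
    n_sle = lst$n_sle, n_control = lst$n_control,
    antigen_names = unlist(lst$antigen_names),
    cluster_probs = num(lst$cluster_probs),
    seropos_prob = list2mat(lst$seropos_prob),
    control_log_mean = num(lst$control_log_mean),
    control_log_sd = num(lst$control_log_sd),
    pos_log_shift = num(lst$pos_log_shift),
    clinical_rates = list2mat(lst$clinical_rates),
    p_female = lst$p_female,
    ethnicity_probs = num(lst$ethnicity_probs),
    age_probs = num(lst$age_probs),
    p_dsdna = lst$p_dsdna,
    mixture_noise_cv = lst$mixture_noise_cv,
    seed = lst$seed)
}
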