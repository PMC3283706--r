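#' Assign SLE patients to autoantibody clusters by the relative-ratio rule
#'
#' Implements the two-stage rule on the six core antigens. A patient
#' seronegative for all six (no call above the mean + 3 SD cutoffs) is
#' labelled SERONEGATIVE and never enters the ratio. Otherwise the relative
#' ratio RR = (Sm-D3 + RNP-A + RNP-70k) / (Ro52 + Ro60 + La), computed on raw
#' titer sums, assigns SM_RNP when RR >= 1 and RO_LA when RR < 1. A zero
#' Ro/La sum (impossible for physical light units, but reachable with
#' synthetic input) yields RR = +Inf and therefore SM_RNP. A patient is
#' flagged \code{pure} when every seropositive call falls within a single
#' trio.
#'
#' @param cohort Cohort data frame; SLE rows are assigned.
#' @param stats A \code{control_stats} covering the six core antigens.
#' @return Data frame of class \code{cluster_assignment}: one row per SLE
#'   patient with \code{patient_id}, \code{sum_smrnp}, \code{sum_rola},
#'   \code{rr}, \code{label} (SM_RNP / RO_LA / SERONEGATIVE), \code{pure}.
#' @export
assign_clusters <- function(cohort, stats) {
  missing <- setdiff(CORE_ANTIGENS, names(cohort))
  if (length(missing))
    .stopf("cluster assignment needs all six core antigens; missing: %s",
           paste(missing, collapse = ", "))
  sle <- cohort[cohort$group == "SLE", , drop = FALSE]
  calls <- call_seropositive(sle, stats, CORE_ANTIGENS)
  titers <- .titer_matrix(sle, CORE_ANTIGENS)

  sum_smrnp <- rowSums(titers[, SMRNP_TRIO, drop = FALSE])
  sum_rola <- rowSums(titers[, ROLA_TRIO, drop = FALSE])
  rr <- ifelse(sum_rola == 0, Inf, sum_smrnp / sum_rola)

  n_pos <- rowSums(calls)
  n_smrnp_pos <- rowSums(calls[, SMRNP_TRIO, drop = FALSE])
  n_rola_pos <- rowSums(calls[, ROLA_TRIO, drop = FALSE])

  label <- ifelse(n_pos == 0L, "SERONEGATIVE",
                  ifelse(rr >= 1, "SM_RNP", "RO_LA"))
  pure <- n_pos > 0L & (n_smrnp_pos == 0L | n_rola_pos == 0L)

  structure(
    data.frame(patient_id = sle$patient_id,
               sum_smrnp = sum_smrnp, sum_rola = sum_rola, rr = rr,
               label = label, pure = pure,
               stringsAsFactors = FALSE, row.names = NULL),
    class = c("cluster_assignment", "data.frame"))
}

#' Cluster prevalence summary
#'
#' Exact integer counts of the three labels and of pure phenotypes, with
#' display percentages rounded half away from zero.
#'
#' @param assignments A \code{cluster_assignment}.
#' @return List of class \code{cluster_prevalence}: \code{n_total}, counts
#'   and percentages per label, and pure counts per cluster.
#' @export
#' @examples
#' a <- data.frame(patient_id = letters[1:4],
#'                 label = c("SM_RNP", "RO_LA", "RO_LA", "SERONEGATIVE"),
#'                 pure = c(TRUE, FALSE, TRUE, FALSE))
#' cluster_prevalence(a)
cluster_prevalence <- function(assignments) {
  if (nrow(assignments) == 0L) .stopf("no assignments to summarize")
  n <- nrow(assignments)
  counts <- vapply(CLASSES, function(cl) sum(assignments$label == cl),
                   integer(1))
  pct <- 100 * counts / n
  structure(
    list(n_total = n,
         n_smrnp = counts[["SM_RNP"]], n_rola = counts[["RO_LA"]],
         n_seroneg = counts[["SERONEGATIVE"]],
         pct_smrnp = pct[["SM_RNP"]], pct_rola = pct[["RO_LA"]],
         pct_seroneg = pct[["SERONEGATIVE"]],
         n_pure_smrnp = sum(assignments$pure &
                              assignments$label == "SM_RNP"),
         n_pure_rola = sum(assignments$pure &
                             assignments$label == "RO_LA")),
    class = "cluster_prevalence")
}

#' @export
print.cluster_prevalence <- function(x, ...) {
  cat(sprintf("Cluster prevalence (n = %d)\n", x$n_total))
  cat(sprintf("  Sm/RNP:       %3d (%d%%), pure %d\n", x$n_smrnp,
              round_half_away(x$pct_smrnp), x$n_pure_smrnp))
  cat(sprintf("  Ro/La:        %3d (%d%%), pure %d\n", x$n_rola,
              round_half_away(x$pct_rola), x$n_pure_rola))
  cat(sprintf("  Seronegative: %3d (%d%%)\n", x$n_seroneg,
              round_half_away(x$pct_seroneg)))
  invisible(x)
}

#' Compare assigned clusters with simulated latent truth
#'
#' Joins assignments to the generator's truth table by patient id and
#' tabulates the 3 x 3 confusion matrix of assigned vs latent class;
#' accuracy is the trace over the total.
#'
#' @param assignments A \code{cluster_assignment}.
#' @param truth Data frame with \code{patient_id}, \code{latent_class}.
#' @return List with \code{confusion} (assigned rows x latent columns) and
#'   \code{accuracy}.
#' @export
recover_latent_labels <- function(assignments, truth) {
  i <- match(assignments$patient_id, truth$patient_id)
  if (anyNA(i))
    .stopf("truth table missing patient id(s): %s",
           paste(utils::head(assignments$patient_id[is.na(i)], 5),
                 collapse = ", "))
  latent <- truth$latent_class[i]
  confusion <- table(assigned = factor(assignments$label, levels = CLASSES),
                     latent = factor(latent, levels = CLASSES))
  list(confusion = confusion,
       accuracy = sum(diag(confusion)) / sum(confusion))
}
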