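## Small cohort builders for unit tests.

## single-antigen cohort from raw titer vectors
make_cohort <- function(sle, hc, antigen = "A") {
  df <- data.frame(
    patient_id = c(sprintf("S%02d", seq_along(sle)),
                   sprintf("C%02d", seq_along(hc))),
    group = rep(c("SLE", "CONTROL"), c(length(sle), length(hc))),
    stringsAsFactors = FALSE)
  df[[antigen]] <- c(sle, hc)
  df
}

## six-core-antigen cohort; sle / hc are matrices (or vectors recycled) with
## columns in CORE_ANTIGENS order
make_core_cohort <- function(sle, hc = matrix(rep(c(1, 2, 3), each = 6),
                                              nrow = 3, byrow = TRUE)) {
  if (!is.matrix(sle)) sle <- matrix(sle, ncol = 6, byrow = TRUE)
  if (!is.matrix(hc)) hc <- matrix(hc, ncol = 6)
  df <- data.frame(
    patient_id = c(sprintf("S%02d", seq_len(nrow(sle))),
                   sprintf("C%02d", seq_len(nrow(hc)))),
    group = rep(c("SLE", "CONTROL"), c(nrow(sle), nrow(hc))),
    stringsAsFactors = FALSE)
  titers <- rbind(sle, hc)
  for (j in seq_along(CORE_ANTIGENS)) df[[CORE_ANTIGENS[j]]] <- titers[, j]
  df
}

## controls {1,2,3} per antigen -> mean 2, SD 1, cutoff 5 on every antigen
toy_controls <- function() {
  m <- matrix(rep(1:3, 6), nrow = 3)
  m
}
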