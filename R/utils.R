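#' Round half away from zero
#'
#' Display rounding used throughout for percentages: exact halves round away
#' from zero (so 11.5 -> 12, -11.5 -> -12), unlike [base::round()]'s
#' round-half-even. Unrounded values are always retained internally; this is a
#' display policy only.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep (default 0).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_away(c(11.5, 12.5, -11.5))
round_half_away <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

## log10-lognormal moment helpers: titers are modelled as
## 10^(mu10 + sigma10 * Z).  Natural-scale arithmetic moments follow from the
## classic lognormal identities with mu = mu10*ln10, sigma = sigma10*ln10.
.lnorm10_mean <- function(mu10, sigma10) {
  exp(mu10 * log(10) + (sigma10 * log(10))^2 / 2)
}

.lnorm10_sd <- function(mu10, sigma10) {
  s2 <- (sigma10 * log(10))^2
  .lnorm10_mean(mu10, sigma10) * sqrt(exp(s2) - 1)
}

## inverse: (mean, sd) on the natural scale -> (mu10, sigma10)
.lnorm10_params <- function(mean, sd) {
  cv2 <- (sd / mean)^2
  sigma <- sqrt(log1p(cv2))
  mu <- log(mean) - sigma^2 / 2
  list(mu10 = mu / log(10), sigma10 = sigma / log(10))
}

## P(titer > cutoff) for a log10-lognormal with optional log10 shift
.lnorm10_exceed <- function(cutoff, mu10, sigma10, shift = 0) {
  stats::pnorm((log10(cutoff) - mu10 - shift) / sigma10, lower.tail = FALSE)
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

## run code under a temporary RNG state, restoring the caller's stream
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}
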