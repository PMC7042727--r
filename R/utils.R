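#' @importFrom stats rnorm runif rbinom setNames cor cor.test lm pt pnorm
#'   coef approx var sd
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed and a stream label
#'
#' All stochastic operations in the package draw their seed through this
#' function so that adding a new generator never perturbs the random stream
#' of an existing one. The mapping is a small deterministic hash of the
#' label folded into the master seed, kept below 2^31.
#'
#' @param seed integer master seed.
#' @param label character stream label, e.g. `"gene_drop"`.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 0
  for (v in utf8ToInt(label)) h <- (h * 131 + v) %% 2147483629
  as.integer((abs(seed) %% 2147483629 + h) %% 2147483629)
}

#' Allele frequency implied by a heterozygous carrier count
#'
#' Converts a count of heterozygous carriers among a set of diploid
#' individuals into an allele frequency, the arithmetic used when reading
#' population databases that report carrier counts (each heterozygote
#' contributes one allele among `2 * n_individuals` chromosomes).
#'
#' @param n_carriers number of heterozygous carriers observed.
#' @param n_individuals number of diploid individuals genotyped.
#' @param digits significant digits to round to; `NULL` for no rounding.
#'   Population databases typically print three.
#' @return The allele frequency as a fraction.
#' @examples
#' allele_freq_from_carriers(9, 138390)   # 3.25e-05
#' @export
allele_freq_from_carriers <- function(n_carriers, n_individuals, digits = 3) {
  stopifnot(n_carriers >= 0, n_individuals > 0, n_carriers <= n_individuals)
  f <- n_carriers / (2 * n_individuals)
  if (!is.null(digits)) f <- signif(f, digits)
  f
}

#' Follow-up cohort sizes used for variant replication
#'
#' Sizes of the three case/control follow-up cohorts (Germany genotyping,
#' UK exome sequencing, and the US WHICAP cohort) in which the candidate
#' variant was screened after the family analysis.
#'
#' @return Named integer vector of cohort sizes.
#' @export
study_cohorts <- function() {
  c(germany = 1045L, uk = 571L, usa = 3834L)
}

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

stop_input <- function(...) stop(..., call. = FALSE)
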