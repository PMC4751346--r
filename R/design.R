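# Training-population design formulas linking LD, effective population
# size, the effective number of chromosome segments and expected genomic
# prediction accuracy.  All map distances here are in Morgans; user-facing
# LD interfaces report centimorgans, so divide by 100 before calling
# sved_ne().

#' Effective population size from mean LD (Sved's relation)
#'
#' Inverts the drift expectation `r2 = 1 / (4 Ne c + 1)`:
#' `Ne = (1/r2 - 1) / (4 c)`.
#'
#' @param r2 mean squared-correlation LD in (0, 1].
#' @param c marker distance in Morgans (> 0); centimorgans / 100.
#' @return Effective population size (>= 0).
#' @export
sved_ne <- function(r2, c) {
  if (any(r2 <= 0 | r2 > 1)) stop("r2 must lie in (0, 1]")
  if (any(c <= 0)) stop("c must be > 0 (Morgans)")
  (1 / r2 - 1) / (4 * c)
}

#' Effective number of chromosome segments
#'
#' `Me = 2 Ne L / ln(4 Ne L)` for genome length `L` in Morgans (8 for
#' perennial ryegrass).
#'
#' @param Ne effective population size (> 0).
#' @param L genome length in Morgans (> 0).
#' @return Me (> 0).
#' @export
effective_segments <- function(Ne, L) {
  if (any(Ne <= 0) || any(L <= 0)) stop("Ne and L must be > 0")
  if (any(4 * Ne * L <= 1)) stop("4*Ne*L must exceed 1 for the log to be defined")
  2 * Ne * L / log(4 * Ne * L)
}

#' Expected genomic prediction accuracy
#'
#' Computes `sqrt(N h2 / (N h2 + Me))`: the accuracy expected from a training
#' population of `N` unrelated individuals when the trait heritability is
#' `h2` and the genome behaves as `Me` independent segments.
#'
#' @param N training population size (> 0).
#' @param h2 heritability in (0, 1].
#' @param Me effective number of chromosome segments (> 0).
#' @return Accuracy r in (0, 1).
#' @export
expected_accuracy <- function(N, h2, Me) {
  if (any(N <= 0) || any(Me <= 0)) stop("N and Me must be > 0")
  if (any(h2 <= 0 | h2 > 1)) stop("h2 must lie in (0, 1]")
  sqrt(N * h2 / (N * h2 + Me))
}

#' Training population size required for a target squared accuracy
#'
#' Exact inverse of [expected_accuracy()]:
#' `N = Me r2_target / (h2 (1 - r2_target))`.
#'
#' @param r2_target target squared accuracy in (0, 1).
#' @param h2 heritability in (0, 1].
#' @param Me effective number of chromosome segments (> 0).
#' @return Required training population size N (> 0).
#' @export
required_training_n <- function(r2_target, h2, Me) {
  if (any(r2_target <= 0 | r2_target >= 1)) stop("r2_target must lie in (0, 1)")
  if (any(h2 <= 0 | h2 > 1)) stop("h2 must lie in (0, 1]")
  if (any(Me <= 0)) stop("Me must be > 0")
  Me * r2_target / (h2 * (1 - r2_target))
}

#' Chain the design formulas from observed LD to required training size
#'
#' Convenience wrapper: Ne from Sved's relation at the observed mean
#' adjacent-marker LD, Me from (Ne, L), then the N needed to reach a target
#' squared accuracy at a given heritability.
#'
#' @inheritParams sved_ne
#' @inheritParams effective_segments
#' @inheritParams required_training_n
#' @return A data.frame with `Ne`, `Me`, `N_required`.
#' @export
design_summary <- function(r2, c, L = 8, h2 = 0.4, r2_target = 0.5) {
  Ne <- sved_ne(r2, c)
  Me <- effective_segments(Ne, L)
  data.frame(Ne = Ne, Me = Me,
             N_required = required_training_n(r2_target, h2, Me))
}
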