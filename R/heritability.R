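#' Broad-sense heritability from half-sib family replicates
#'
#' One-way ANOVA of trait values grouped by half-sib family.  The residual
#' variance is the within-family mean square; the genetic variance is
#' `(MS_between - MS_within) / n0` with the unbalanced-design coefficient
#' `n0 = (N - sum(n_i^2)/N) / (k - 1)`, clamped at zero when negative.
#' Broad-sense heritability is `H2 = sigma_G2 / (sigma_G2 + sigma_E2)`;
#' when the within-family mean square is exactly zero but families differ,
#' `H2 = 1` is reported (the noiseless limit).
#'
#' @param values numeric vector of trait observations (e.g. replicate plot
#'   values of half-sib family means).
#' @param families grouping labels, one per observation.
#' @return A list of class `variance_components`: `sigma_G2`, `sigma_E2`,
#'   `H2`, `n0`, `ms_between`, `ms_within`, `n_families`, `n_obs` and
#'   `jackknife_sd` (`NA` until [jackknife_sd()] is run).
#' @export
heritability_anova <- function(values, families) {
  values <- as.numeric(values)
  families <- factor(families)
  if (length(values) != length(families)) stop("values/families length mismatch")
  if (anyNA(values)) stop("values must be non-missing")
  k <- nlevels(families)
  N <- length(values)
  if (k < 2L) stop("need >= 2 families for a one-way ANOVA")
  if (N - k < 1L)
    stop("no within-family degrees of freedom (all families are singletons)")
  # suppressed warning: anova's F-test caveat on perfect fits is irrelevant
  # here, only the mean squares are used
  aov_tab <- suppressWarnings(stats::anova(stats::lm(values ~ families)))
  ms_b <- aov_tab[["Mean Sq"]][1L]
  ms_w <- aov_tab[["Mean Sq"]][2L]
  ni <- as.numeric(table(families))
  n0 <- (N - sum(ni^2) / N) / (k - 1L)
  sigma_G2 <- max(0, (ms_b - ms_w) / n0)
  if (ms_w == 0) {
    H2 <- if (ms_b > 0) 1 else 0
  } else {
    H2 <- sigma_G2 / (sigma_G2 + ms_w)
  }
  structure(list(sigma_G2 = sigma_G2, sigma_E2 = ms_w, H2 = H2, n0 = n0,
                 ms_between = ms_b, ms_within = ms_w, n_families = k,
                 n_obs = N, jackknife_sd = NA_real_),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("Half-sib one-way ANOVA (%d families, %d observations)\n",
              x$n_families, x$n_obs))
  cat(sprintf("  sigma_G2 = %.4g, sigma_E2 = %.4g, H2 = %.3f", x$sigma_G2,
              x$sigma_E2, x$H2))
  if (!is.na(x$jackknife_sd)) cat(sprintf(" (%.3f)", x$jackknife_sd))
  cat("\n")
  invisible(x)
}

#' Leave-one-out jackknife standard deviation of a statistic
#'
#' Delete-one jackknife over observations:
#' `SD = sqrt((n - 1)/n * sum((theta_{-i} - mean(theta_{-i}))^2))`.
#'
#' @param values,families as in [heritability_anova()].
#' @param statistic function of `(values, families)` returning a scalar or a
#'   `variance_components` object (its `H2` is used).  Default: broad-sense
#'   heritability.
#' @return Non-negative scalar jackknife standard deviation.
#' @export
jackknife_sd <- function(values, families,
                         statistic = function(v, f) heritability_anova(v, f)$H2) {
  n <- length(values)
  theta <- vapply(seq_len(n), function(i) {
    out <- statistic(values[-i], families[-i])
    if (inherits(out, "variance_components")) out$H2 else as.numeric(out)
  }, numeric(1L))
  sqrt((n - 1) / n * sum((theta - mean(theta))^2))
}

#' Table-style heritability report per generation and trait
#'
#' Applies [heritability_anova()] (and optionally [jackknife_sd()]) to every
#' (trait, generation) cell of a per-plot phenotype table, the layout used
#' to summarize half-sib sward trials.
#'
#' @param plots data.frame with columns `individual_id` (family),
#'   `generation`, `trait`, `value` — one row per replicate plot.
#' @param jackknife logical; add the leave-one-out jackknife SD of H2.
#' @return data.frame with columns `trait`, `generation`, `sigma_G2`,
#'   `sigma_E2`, `H2`, `jackknife_sd`.
#' @export
heritability_report <- function(plots, jackknife = FALSE) {
  stopifnot(all(c("individual_id", "generation", "trait", "value") %in%
                  names(plots)))
  cells <- unique(plots[c("trait", "generation")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- plots[plots$trait == cells$trait[i] &
                   plots$generation == cells$generation[i], ]
    vc <- heritability_anova(sub$value, sub$individual_id)
    data.frame(trait = cells$trait[i], generation = cells$generation[i],
               sigma_G2 = vc$sigma_G2, sigma_E2 = vc$sigma_E2, H2 = vc$H2,
               jackknife_sd = if (jackknife)
                 jackknife_sd(sub$value, sub$individual_id) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
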