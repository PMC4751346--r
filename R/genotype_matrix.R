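#' Construct a genotype matrix of additively coded SNP calls
#'
#' The common data currency of the package: mother-plant genotypes coded
#' -1/0/+1 (the two homozygotes and the heterozygote), one row per
#' individual, one column per marker, with a generation label per
#' individual (e.g. `"F5"`, `"F11"` ... `"F14"`).  Missing calls are `NA`
#' until [impute_missing()] replaces them by per-marker means.
#'
#' @param codes numeric matrix, individuals x markers; non-missing entries
#'   must be exactly -1, 0 or +1 unless `imputed = TRUE` (post-imputation
#'   matrices carry continuous values).
#' @param individual_ids character vector of unique row identifiers
#'   (defaults to `rownames(codes)`).
#' @param generation character vector of per-individual generation labels.
#' @param marker_ids character vector of unique column identifiers
#'   (defaults to `colnames(codes)`).
#' @param imputed logical; `TRUE` relaxes the -1/0/1 coding check to the
#'   closed interval \[-1, 1\] (mean-imputed values are continuous).
#' @return An object of class `genotype_matrix`: the codes matrix with
#'   `generation` and `imputed` attributes.
#' @seealso [read_genotypes()], [impute_missing()], [allele_frequency()],
#'   [pca_scores()]
#' @export
genotype_matrix <- function(codes, individual_ids = rownames(codes),
                            generation, marker_ids = colnames(codes),
                            imputed = FALSE) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "double"
  if (is.null(individual_ids))
    individual_ids <- sprintf("ind%0*d", nchar(nrow(codes)), seq_len(nrow(codes)))
  if (is.null(marker_ids))
    marker_ids <- sprintf("m%0*d", nchar(ncol(codes)), seq_len(ncol(codes)))
  individual_ids <- as.character(individual_ids)
  marker_ids <- as.character(marker_ids)
  generation <- as.character(generation)
  if (length(individual_ids) != nrow(codes))
    stop("individual_ids length (", length(individual_ids),
         ") does not match number of rows (", nrow(codes), ")")
  if (length(marker_ids) != ncol(codes))
    stop("marker_ids length (", length(marker_ids),
         ") does not match number of columns (", ncol(codes), ")")
  if (length(generation) == 1L) generation <- rep(generation, nrow(codes))
  if (length(generation) != nrow(codes))
    stop("generation labels length does not match number of individuals")
  if (anyDuplicated(individual_ids))
    stop("duplicate individual ids: ",
         paste(unique(individual_ids[duplicated(individual_ids)]), collapse = ", "))
  if (anyDuplicated(marker_ids))
    stop("duplicate marker ids: ",
         paste(unique(marker_ids[duplicated(marker_ids)]), collapse = ", "))
  obs <- codes[!is.na(codes)]
  if (imputed) {
    if (length(obs) && (min(obs) < -1 || max(obs) > 1))
      stop("imputed genotype codes must lie in [-1, 1]")
  } else if (length(obs) && !all(obs %in% c(-1, 0, 1))) {
    bad <- which(!is.na(codes) & !(codes %in% c(-1, 0, 1)), arr.ind = TRUE)[1L, ]
    stop("invalid genotype code ", codes[bad[1L], bad[2L]],
         " for individual '", individual_ids[bad[1L]],
         "', marker '", marker_ids[bad[2L]], "' (allowed: -1, 0, 1, NA)")
  }
  dimnames(codes) <- list(individual_ids, marker_ids)
  structure(codes, generation = generation, imputed = imputed,
            class = c("genotype_matrix", "matrix", "array"))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  gen <- table(attr(x, "generation"))
  cat("Genotype matrix: ", nrow(x), " individuals x ", ncol(x), " markers",
      if (isTRUE(attr(x, "imputed"))) " (imputed)", "\n", sep = "")
  cat("Generations: ",
      paste(sprintf("%s (n=%d)", names(gen), as.integer(gen)), collapse = ", "),
      "\n", sep = "")
  nmiss <- sum(is.na(x))
  cat("Missing calls: ", nmiss, sprintf(" (%.2f%%)", 100 * nmiss / length(x)),
      "\n", sep = "")
  invisible(x)
}

#' @export
`[.genotype_matrix` <- function(x, i, j, ..., drop = FALSE) {
  gen <- attr(x, "generation")
  imp <- attr(x, "imputed")
  m <- unclass(x)
  attr(m, "generation") <- NULL
  out <- m[i, j, drop = FALSE]
  if (!missing(i)) gen <- gen[if (is.character(i)) match(i, rownames(x)) else i]
  genotype_matrix(out, generation = gen, imputed = imp)
}

#' Per-individual generation labels of a genotype matrix
#' @param g a `genotype_matrix`.
#' @return Character vector, one label per individual.
#' @export
generations <- function(g) attr(g, "generation")

#' Replace missing genotype calls by the per-marker mean
#'
#' Each `NA` is replaced by the mean code of the marker over its non-missing
#' calls, so imputed values are continuous in \[-1, 1\] while observed calls
#' are untouched.  Idempotent.
#'
#' @param g a `genotype_matrix`.
#' @return A `genotype_matrix` with no missing values and `imputed = TRUE`.
#' @export
impute_missing <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!anyNA(g))
    return(genotype_matrix(unclass(g), generation = generations(g), imputed = TRUE))
  nobs <- colSums(!is.na(g))
  if (any(nobs == 0L))
    stop("marker(s) with no observed calls: ",
         paste(colnames(g)[nobs == 0L], collapse = ", "))
  mu <- colMeans(g, na.rm = TRUE)
  codes <- unclass(g)
  idx <- which(is.na(codes), arr.ind = TRUE)
  codes[idx] <- mu[idx[, 2L]]
  genotype_matrix(codes, generation = generations(g), imputed = TRUE)
}

#' Frequency of the +1 allele at each marker
#'
#' With additive codes -1/0/+1 counting copies of the +1 allele, the allele
#' frequency is `(mean(code) + 1) / 2` over non-missing calls.
#'
#' @param g a `genotype_matrix`.
#' @return Named numeric vector of frequencies in \[0, 1\].
#' @export
allele_frequency <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (nrow(g) == 0L || ncol(g) == 0L) stop("empty genotype matrix")
  (colMeans(g, na.rm = TRUE) + 1) / 2
}

#' Principal-component structure diagnostics
#'
#' PCA of the column-centred (not scaled) genotype codes, the standard
#' visual check for stratification between breeding populations.
#'
#' @param g a `genotype_matrix` with no missing values (run
#'   [impute_missing()] first).
#' @param n_components number of components, at most `min(n - 1, M)`.
#' @return A list of class `pca_scores` with `scores` (individuals x
#'   components, rownames = individual ids), `explained` (variance
#'   fractions, non-increasing, summing to <= 1) and `generation`.
#' @export
pca_scores <- function(g, n_components = 2L) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (anyNA(g)) stop("genotype matrix contains missing values; impute first")
  kmax <- min(nrow(g) - 1L, ncol(g))
  if (n_components < 1L || n_components > kmax)
    stop("n_components must be between 1 and min(n - 1, M) = ", kmax)
  pc <- stats::prcomp(unclass(g), center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  structure(list(scores = pc$x[, seq_len(n_components), drop = FALSE],
                 explained = (ev / sum(ev))[seq_len(n_components)],
                 generation = generations(g)),
            class = "pca_scores")
}

#' @export
print.pca_scores <- function(x, ...) {
  cat("PCA scores for", nrow(x$scores), "individuals;",
      length(x$explained), "components\n")
  cat("Explained variance fractions:",
      paste(sprintf("%.3f", x$explained), collapse = ", "), "\n")
  invisible(x)
}

#' @param x a `pca_scores` object.
#' @param components which two components to plot.
#' @param ... passed to [graphics::plot()].
#' @rdname pca_scores
#' @export
plot.pca_scores <- function(x, components = c(1L, 2L), ...) {
  gen <- factor(x$generation)
  graphics::plot(x$scores[, components[1L]], x$scores[, components[2L]],
                 col = as.integer(gen), pch = 19,
                 xlab = sprintf("PC%d (%.1f%%)", components[1L],
                                100 * x$explained[components[1L]]),
                 ylab = sprintf("PC%d (%.1f%%)", components[2L],
                                100 * x$explained[components[2L]]), ...)
  graphics::legend("topright", legend = levels(gen), col = seq_along(levels(gen)),
                   pch = 19, bty = "n")
  invisible(x)
}
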