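# Delimited-text I/O for genotype, map and phenotype tables.  Comma or tab
# is autodetected from the header line; missing genotype calls are empty
# fields or "NA".

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (lengths(regmatches(header, gregexpr("\t", header))) > 0L) "\t" else ","
}

#' Read a genotype table
#'
#' The native dialect is a delimited table (comma or tab, autodetected) with
#' a header row of marker ids; column 1 is the individual id, column 2 the
#' generation label, and the remaining columns hold -1/0/1 codes.  The
#' `plink_additive` dialect accepts 0/1/2 allele dosages in the same layout
#' and maps them to -1/0/+1 by subtracting 1.  Empty fields and `NA` are
#' missing calls.
#'
#' @param path file path.
#' @param dialect `"native"` (-1/0/1) or `"plink_additive"` (0/1/2).
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, dialect = c("native", "plink_additive")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                           na.strings = c("NA", ""), check.names = FALSE,
                           colClasses = "character", comment.char = "")
  if (ncol(tab) < 3L)
    stop("genotype table needs >= 3 columns (id, generation, markers)")
  ids <- tab[[1L]]
  gen <- tab[[2L]]
  marker_ids <- colnames(tab)[-(1:2)]
  codes <- suppressWarnings(
    vapply(tab[-(1:2)], as.numeric, numeric(nrow(tab))))
  codes <- matrix(codes, nrow = nrow(tab),
                  dimnames = list(ids, marker_ids))
  raw_na <- is.na(as.matrix(tab[-(1:2)]))
  if (any(is.na(codes) & !raw_na)) {
    bad <- which(is.na(codes) & !raw_na, arr.ind = TRUE)[1L, ]
    stop("non-numeric genotype code '", as.matrix(tab[-(1:2)])[bad[1L], bad[2L]],
         "' for individual '", ids[bad[1L]], "', marker '",
         marker_ids[bad[2L]], "'")
  }
  allowed <- if (dialect == "native") c(-1, 0, 1) else c(0, 1, 2)
  obs <- !is.na(codes)
  if (any(obs & !(codes %in% allowed))) {
    bad <- which(obs & !matrix(codes %in% allowed, nrow(codes)), arr.ind = TRUE)[1L, ]
    stop("invalid ", dialect, " genotype code ", codes[bad[1L], bad[2L]],
         " for individual '", ids[bad[1L]], "', marker '", marker_ids[bad[2L]],
         "' (allowed: ", paste(allowed, collapse = ", "), ")")
  }
  if (dialect == "plink_additive") codes <- codes - 1
  genotype_matrix(codes, individual_ids = ids, generation = gen)
}

#' Write a genotype table in the native dialect
#'
#' @param g a [genotype_matrix()].
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, sep = "\t") {
  stopifnot(inherits(g, "genotype_matrix"))
  tab <- data.frame(individual_id = rownames(g), generation = generations(g),
                    unclass(g), check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genetic map
#'
#' Native format: delimited text with columns `marker_id`, `chromosome`
#' (integer, 1-7 for perennial ryegrass), `position_cM`.  Files ending in
#' `.map` are read as PLINK maps (chromosome, marker id, genetic position in
#' cM, base-pair position).  Markers are sorted by chromosome and position.
#'
#' @param path file path.
#' @param n_chromosomes chromosomes allowed (default 7); set higher for
#'   non-ryegrass maps.
#' @return A `data.frame` of class `marker_map` with columns `marker_id`,
#'   `chromosome`, `position_cM`.
#' @export
read_map <- function(path, n_chromosomes = 7L) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.map$", path)) {
    tab <- utils::read.table(path, header = FALSE)
    map <- data.frame(marker_id = as.character(tab[[2L]]),
                      chromosome = as.integer(tab[[1L]]),
                      position_cM = as.numeric(tab[[3L]]),
                      stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                             check.names = FALSE)
    map <- data.frame(marker_id = as.character(tab[[1L]]),
                      chromosome = as.integer(tab[[2L]]),
                      position_cM = as.numeric(tab[[3L]]),
                      stringsAsFactors = FALSE)
  }
  marker_map(map, n_chromosomes = n_chromosomes)
}

#' Validate a genetic map table
#'
#' @param map data.frame with columns `marker_id`, `chromosome`,
#'   `position_cM`.
#' @inheritParams read_map
#' @return The validated, sorted map with class `marker_map`.
#' @export
marker_map <- function(map, n_chromosomes = 7L) {
  stopifnot(all(c("marker_id", "chromosome", "position_cM") %in% names(map)))
  map$marker_id <- as.character(map$marker_id)
  if (anyDuplicated(map$marker_id))
    stop("duplicate mapped marker ids: ",
         paste(unique(map$marker_id[duplicated(map$marker_id)]), collapse = ", "))
  if (any(is.na(map$chromosome)) ||
      any(map$chromosome < 1L | map$chromosome > n_chromosomes))
    stop("chromosome must be an integer in 1..", n_chromosomes)
  if (any(!is.finite(map$position_cM)) || any(map$position_cM < 0))
    stop("position_cM must be finite and >= 0")
  map <- map[order(map$chromosome, map$position_cM), , drop = FALSE]
  rownames(map) <- NULL
  class(map) <- c("marker_map", "data.frame")
  map
}

#' Write a genetic map in the native format
#' @param map a `marker_map`.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path, sep = "\t") {
  utils::write.table(as.data.frame(map)[c("marker_id", "chromosome", "position_cM")],
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-format phenotype table
#'
#' Columns: `individual_id`, `generation`, `trait`, `value` — one half-sib
#' family-mean record per mother-plant, generation and trait.
#'
#' @param path file path.
#' @return A validated phenotype `data.frame`.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                           check.names = FALSE, stringsAsFactors = FALSE)
  phenotype_table(tab)
}

#' Validate a phenotype table
#'
#' @param pheno data.frame with columns `individual_id`, `generation`,
#'   `trait`, `value`.
#' @return The validated data.frame.
#' @export
phenotype_table <- function(pheno) {
  need <- c("individual_id", "generation", "trait", "value")
  if (!all(need %in% names(pheno)))
    stop("phenotype table needs columns: ", paste(need, collapse = ", "))
  pheno <- as.data.frame(pheno)[need]
  pheno$individual_id <- as.character(pheno$individual_id)
  pheno$generation <- as.character(pheno$generation)
  pheno$trait <- as.character(pheno$trait)
  pheno$value <- as.numeric(pheno$value)
  if (any(!is.finite(pheno$value))) stop("phenotype values must be finite")
  key <- paste(pheno$individual_id, pheno$trait, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (individual_id, trait) records: ",
         paste(utils::head(unique(gsub("\r", "/", key[duplicated(key)])), 5L),
               collapse = ", "))
  pheno
}

#' Write a long-format phenotype table
#' @param pheno a phenotype data.frame (see [phenotype_table()]).
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path, sep = "\t") {
  utils::write.table(phenotype_table(pheno), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
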