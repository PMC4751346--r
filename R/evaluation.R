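#' Standardize phenotypes within each (generation, trait) subpopulation
#'
#' Subtracts the group mean and divides by the group standard deviation
#' (denominator n - 1) within every (generation, trait) cell, so each
#' subpopulation has mean 0 and variance 1.  Concatenations of standardized
#' subpopulations need not have variance exactly 1.  Because the statistics
#' are computed per generation, a held-out test generation never leaks into
#' the training generations' standardization.
#'
#' @param pheno phenotype table (see [phenotype_table()]).
#' @return The table with standardized `value`s.
#' @export
standardize_by_subpopulation <- function(pheno) {
  pheno <- phenotype_table(pheno)
  grp <- interaction(pheno$generation, pheno$trait, drop = TRUE)
  for (g in levels(grp)) {
    i <- grp == g
    v <- pheno$value[i]
    if (length(unique(v)) < 2L)
      stop("cannot standardize constant group (generation.trait = ", g, ")")
    pheno$value[i] <- (v - mean(v)) / stats::sd(v)
  }
  pheno
}

#' Training-population composition specifications
#'
#' The three compositions of the study plus a custom escape hatch: `F13`
#' (the generation closest to the F14 test set), `INT` (all Intermediate
#' generations F11 + F12 + F13) and `ALL` (INT plus the Late F5
#' population).
#'
#' @param name `"F13"`, `"INT"`, `"ALL"` or `"custom"`.
#' @param generations for `"custom"`, the generation labels to pool.
#' @return A list of class `training_set_spec` with `name` and
#'   `generations`.
#' @export
training_set_spec <- function(name = c("F13", "INT", "ALL", "custom"),
                              generations = NULL) {
  name <- match.arg(name)
  gens <- switch(name,
                 F13 = "F13",
                 INT = c("F11", "F12", "F13"),
                 ALL = c("F5", "F11", "F12", "F13"),
                 custom = generations)
  if (is.null(gens) || !length(gens))
    stop("custom training spec needs a nonempty generation list")
  structure(list(name = name, generations = as.character(gens)),
            class = "training_set_spec")
}

#' @export
print.training_set_spec <- function(x, ...) {
  cat("Training set '", x$name, "': ",
      paste(x$generations, collapse = " + "), "\n", sep = "")
  invisible(x)
}

#' Assemble a training set from named generations
#'
#' Pools the mother-plants of the spec's generations that have both a
#' genotype and a phenotype for the trait; individuals lacking either are
#' excluded and counted.
#'
#' @param data a `gs_dataset` (from [simulate_program()]) or a list with
#'   elements `genotypes` ([genotype_matrix()]) and `phenotypes`
#'   (phenotype table).
#' @param spec a [training_set_spec()].
#' @param trait trait name.
#' @return A list: `genotypes` (training [genotype_matrix()]), `y` (values
#'   aligned to its rows), `n_train`, `n_excluded`.
#' @export
compose_training_set <- function(data, spec, trait) {
  stopifnot(inherits(spec, "training_set_spec"))
  g <- data$genotypes
  pheno <- phenotype_table(data$phenotypes)
  have <- unique(c(generations(g), pheno$generation))
  missing <- setdiff(spec$generations, have)
  if (length(missing))
    stop("training spec names absent generation(s): ",
         paste(missing, collapse = ", "))
  ph <- pheno[pheno$generation %in% spec$generations & pheno$trait == trait, ]
  if (!nrow(ph)) stop("no phenotype records for trait '", trait,
                      "' in generations ", paste(spec$generations, collapse = ", "))
  gen_rows <- rownames(g)[generations(g) %in% spec$generations]
  ids <- intersect(gen_rows, ph$individual_id)
  n_excl <- length(union(gen_rows, ph$individual_id)) - length(ids)
  if (!length(ids))
    stop("no individuals with both genotype and phenotype for trait '",
         trait, "'")
  list(genotypes = g[ids, ], y = ph$value[match(ids, ph$individual_id)],
       n_train = length(ids), n_excluded = n_excl)
}

#' Spearman rank correlation between observed values and GEBVs
#'
#' Pearson correlation of average-tie ranks, the accuracy measure used
#' throughout the evaluation.
#'
#' @param y_observed,gebv numeric vectors of equal length >= 3.
#' @return Correlation in \[-1, 1\].
#' @export
spearman_accuracy <- function(y_observed, gebv) {
  if (length(y_observed) != length(gebv)) stop("length mismatch")
  if (length(y_observed) < 3L) stop("need >= 3 pairs")
  if (stats::sd(y_observed) == 0 || stats::sd(gebv) == 0)
    stop("correlation undefined for a constant vector")
  stats::cor(y_observed, gebv, method = "spearman")
}

default_knn_grid <- function(spec_name, n_train) {
  grid <- switch(spec_name,
                 F13 = 1:10, INT = 3:20, ALL = 4:26,
                 seq_len(min(10L, n_train - 1L)))
  grid[grid < n_train]
}

#' Run the full (training set x trait x method) evaluation grid
#'
#' For every combination: standardize phenotypes per subpopulation, compose
#' the training set, fit the method, predict the test generation's
#' mother-plants and score the Spearman rank correlation against their
#' observed (standardized) family means.  A failed cell is recorded as
#' missing with its error message; it never aborts the grid.  Fully
#' deterministic under (inputs, seed).
#'
#' @param data a `gs_dataset` or list with `genotypes` and `phenotypes`.
#' @param test_generation generation to predict (default `"F14"`); must not
#'   appear in any training spec.
#' @param specs list of [training_set_spec()] objects.
#' @param methods subset of `"BLUP"`, `"KNN"`, `"RF"`, `"GBM"`.
#' @param traits trait names (default: all traits of the test generation).
#' @param seed integer master seed; each cell derives its own.
#' @param knn_grids optional named list mapping spec name to a k grid.
#' @param ensemble an [ensemble_config()].
#' @return An object of class `gs_evaluation`: `results` (long data.frame
#'   with spec, trait, method, n_train, n_test, spearman, error), `tables`
#'   (per-spec trait x method accuracy matrices), `test_generation`,
#'   `seed`.
#' @export
run_evaluation <- function(data, test_generation = "F14",
                           specs = list(training_set_spec("F13"),
                                        training_set_spec("INT"),
                                        training_set_spec("ALL")),
                           methods = c("BLUP", "KNN", "RF", "GBM"),
                           traits = NULL, seed = 1L, knn_grids = NULL,
                           ensemble = ensemble_config()) {
  methods <- match.arg(methods, several.ok = TRUE)
  g <- data$genotypes
  if (anyNA(g)) g <- impute_missing(g)
  pheno <- standardize_by_subpopulation(data$phenotypes)
  for (sp in specs)
    if (test_generation %in% sp$generations)
      stop("test generation '", test_generation, "' appears in training spec '",
           sp$name, "' (data leakage)")
  if (is.null(traits))
    traits <- sort(unique(pheno$trait[pheno$generation == test_generation]))
  dat <- list(genotypes = g, phenotypes = pheno)
  rows <- list()
  for (si in seq_along(specs)) {
    sp <- specs[[si]]
    for (ti in seq_along(traits)) {
      tr <- traits[ti]
      ph_test <- pheno[pheno$generation == test_generation & pheno$trait == tr, ]
      test_ids <- intersect(rownames(g)[generations(g) == test_generation],
                            ph_test$individual_id)
      for (mi in seq_along(methods)) {
        me <- methods[mi]
        cell_seed <- seed + 7919L * si + 101L * ti + mi
        res <- tryCatch({
          if (!length(test_ids)) stop("empty test set for trait '", tr, "'")
          train <- compose_training_set(dat, sp, tr)
          g_test <- g[test_ids, ]
          y_test <- ph_test$value[match(test_ids, ph_test$individual_id)]
          set.seed(cell_seed)
          gebv <- switch(me,
            BLUP = predict(rrblup(train$genotypes, train$y), g_test),
            KNN = {
              grid <- if (!is.null(knn_grids[[sp$name]])) knn_grids[[sp$name]]
                      else default_knn_grid(sp$name, train$n_train)
              k <- select_k_cv(train$genotypes, train$y, k_grid = grid,
                               cv_folds = min(5L, train$n_train))
              predict_knn(train$genotypes, train$y, g_test, k)
            },
            RF = fit_predict_ensemble(train$genotypes, train$y, g_test,
                                      "rf", ensemble, seed = cell_seed),
            GBM = fit_predict_ensemble(train$genotypes, train$y, g_test,
                                       "gbm", ensemble, seed = cell_seed))
          list(n_train = train$n_train, n_test = length(test_ids),
               spearman = spearman_accuracy(y_test, gebv), error = NA_character_)
        }, error = function(e) {
          list(n_train = NA_integer_, n_test = length(test_ids),
               spearman = NA_real_, error = conditionMessage(e))
        })
        rows[[length(rows) + 1L]] <- data.frame(
          spec = sp$name, trait = tr, method = me, n_train = res$n_train,
          n_test = res$n_test, spearman = res$spearman, error = res$error,
          stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, rows)
  tables <- lapply(stats::setNames(nm = vapply(specs, `[[`, "", "name")),
                   function(sn) {
    sub <- results[results$spec == sn, ]
    m <- matrix(NA_real_, length(traits), length(methods),
                dimnames = list(traits, methods))
    m[cbind(sub$trait, sub$method)] <- sub$spearman
    m
  })
  structure(list(results = results, tables = tables,
                 test_generation = test_generation, seed = seed),
            class = "gs_evaluation")
}

#' @export
print.gs_evaluation <- function(x, digits = 3L, ...) {
  cat("Genomic prediction evaluation (test generation ", x$test_generation,
      ")\n", sep = "")
  for (sn in names(x$tables)) {
    tab <- x$tables[[sn]]
    cat("\nTraining set ", sn, " (Spearman r; * = best per trait):\n", sep = "")
    txt <- matrix(ifelse(is.na(tab), "   .", sprintf("%+.*f", digits, tab)),
                  nrow(tab), dimnames = dimnames(tab))
    best <- apply(tab, 1L, function(r)
      if (all(is.na(r))) NA_integer_ else which.max(r))
    for (i in seq_len(nrow(txt)))
      if (!is.na(best[i])) txt[i, best[i]] <- paste0(txt[i, best[i]], "*")
    print(noquote(txt))
  }
  fails <- x$results[!is.na(x$results$error), ]
  if (nrow(fails))
    cat("\nFailed cells:", nrow(fails), "- see $results$error\n")
  invisible(x)
}

#' Write evaluation tables and a run manifest
#'
#' One CSV per training spec in the traits x methods layout, plus a JSON
#' manifest (seed, test generation, package version) when \pkg{jsonlite}
#' is available.
#'
#' @param eval_out a `gs_evaluation`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_evaluation <- function(eval_out, dir) {
  stopifnot(inherits(eval_out, "gs_evaluation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sn in names(eval_out$tables)) {
    tab <- data.frame(trait = rownames(eval_out$tables[[sn]]),
                      eval_out$tables[[sn]], check.names = FALSE)
    utils::write.table(tab, file.path(dir, sprintf("accuracy_%s.csv", sn)),
                       sep = ",", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(eval_out$results, file.path(dir, "results_long.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    manifest <- list(seed = eval_out$seed,
                     test_generation = eval_out$test_generation,
                     package = "polycrossGS",
                     version = as.character(utils::packageVersion("polycrossGS")),
                     r_version = R.version.string)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(dir)
}
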