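# Forward simulator of the recurrent polycross selection scheme.
#
# Populations are stored as a pair of 0/1 haplotype matrices (individuals x
# loci) over markers *and* QTL; the additive genotype code at any locus is
# h1 + h2 - 1.  The hot loop (gamete formation) is compiled (src/meiosis.cpp).
# All randomness uses R's RNG, so everything is reproducible under set.seed().

#' Construct a haplotype population
#'
#' @param h1,h2 0/1 integer matrices, individuals x loci, loci sorted by
#'   chromosome then position.
#' @param loci data.frame with columns `locus_id`, `chromosome`,
#'   `position_cM`, `type` (`"marker"` or `"qtl"`), in matrix column order.
#' @return An object of class `haplotype_population`.
#' @keywords internal
#' @export
haplotype_population <- function(h1, h2, loci) {
  stopifnot(identical(dim(h1), dim(h2)), ncol(h1) == nrow(loci))
  structure(list(h1 = h1, h2 = h2, loci = loci),
            class = "haplotype_population")
}

#' @export
print.haplotype_population <- function(x, ...) {
  cat("Haplotype population:", nrow(x$h1), "individuals,", ncol(x$h1),
      "loci (", sum(x$loci$type == "marker"), "markers,",
      sum(x$loci$type == "qtl"), "QTL )\n")
  invisible(x)
}

n_ind <- function(pop) nrow(pop$h1)

# chromosome bookkeeping for the compiled gamete kernel
loci_index <- function(loci) {
  chr <- loci$chromosome
  ub <- sort(unique(chr))
  begin <- match(ub, chr) - 1L
  end <- length(chr) - match(ub, rev(chr)) + 1L
  # within-chromosome positions in Morgans
  pos <- loci$position_cM / 100
  list(pos = pos, begin = as.integer(begin), end = as.integer(end),
       len = as.numeric(tapply(pos, chr, max)) + 1e-9)
}

#' Simulate gametes (meioses) from a population
#'
#' One gamete per requested parent: crossover counts per chromosome are
#' Poisson with mean equal to the chromosome length in Morgans, crossover
#' positions are uniform, there is no interference (Haldane model), and
#' chromosomes assort independently.
#'
#' @param pop a `haplotype_population`.
#' @param parents integer vector of parent row indices, one meiosis each.
#' @return 0/1 integer matrix, `length(parents)` x loci.
#' @export
meiosis <- function(pop, parents) {
  stopifnot(inherits(pop, "haplotype_population"))
  parents <- as.integer(parents)
  if (any(parents < 1L | parents > n_ind(pop)))
    stop("parent index out of range")
  idx <- loci_index(pop$loci)
  cpp_gametes(pop$h1, pop$h2, parents, idx$pos, idx$begin, idx$end, idx$len)
}

# chromosome lengths in the config, as an evenly spaced locus table
build_loci <- function(config) {
  C <- config$n_chromosomes
  len_cM <- config$chromosome_length * 100
  per_chr <- diff(round(seq(0, config$n_markers, length.out = C + 1L)))
  marker <- do.call(rbind, lapply(seq_len(C), function(c) {
    k <- per_chr[c]
    if (k == 0L) return(NULL)
    data.frame(locus_id = sprintf("chr%d_m%04d", c, seq_len(k)),
               chromosome = c,
               position_cM = seq(0, len_cM[c], length.out = k + 1L)[-1L] -
                 len_cM[c] / (2 * k),
               type = "marker", stringsAsFactors = FALSE)
  }))
  qtl_chr <- sample.int(C, config$n_qtl, replace = TRUE,
                        prob = len_cM / sum(len_cM))
  qtl <- data.frame(locus_id = sprintf("qtl%04d", seq_len(config$n_qtl)),
                    chromosome = qtl_chr,
                    position_cM = stats::runif(config$n_qtl) * len_cM[qtl_chr],
                    type = "qtl", stringsAsFactors = FALSE)
  loci <- rbind(marker, qtl)
  loci <- loci[order(loci$chromosome, loci$position_cM), , drop = FALSE]
  rownames(loci) <- NULL
  loci
}

#' Simulate a founder population with map-consistent LD
#'
#' Draws `effective_size` diploids whose per-locus allele frequencies come
#' from a uniform distribution on \[0.1, 0.9\] (haplotypes independent across
#' loci), then random-mates the population at constant size for
#' `burnin_generations` generations.  Drift at finite size generates linkage
#' disequilibrium that decays with map distance, approaching the Sved
#' expectation r2 = 1/(4 Ne c + 1) once the burn-in is long relative to
#' 1 / (2c + 1/(2 Ne)) at the distances of interest.
#'
#' @param config a [sim_config()].
#' @param loci optional locus table (built from the config if omitted).
#' @return A `haplotype_population` of `effective_size` individuals.
#' @export
simulate_founders <- function(config, loci = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(loci)) loci <- build_loci(config)
  n <- config$effective_size
  L <- nrow(loci)
  p <- stats::runif(L, 0.1, 0.9)
  h1 <- matrix(as.integer(stats::runif(n * L) < rep(p, each = n)), n, L)
  h2 <- matrix(as.integer(stats::runif(n * L) < rep(p, each = n)), n, L)
  pop <- haplotype_population(h1, h2, loci)
  random_mate(pop, generations = config$burnin_generations, size = n)
}

#' Random-mate a population for a number of generations
#'
#' Each offspring unites gametes from two distinct parents drawn uniformly.
#'
#' @param pop a `haplotype_population`.
#' @param generations number of non-overlapping generations.
#' @param size offspring per generation (default: current size).
#' @return The descendant `haplotype_population`.
#' @export
random_mate <- function(pop, generations, size = n_ind(pop)) {
  if (n_ind(pop) < 2L) stop("need >= 2 individuals to mate")
  idx <- loci_index(pop$loci)
  for (g in seq_len(generations)) {
    n <- n_ind(pop)
    mothers <- sample.int(n, size, replace = TRUE)
    shift <- sample.int(n - 1L, size, replace = TRUE)
    fathers <- 1L + (mothers - 1L + shift) %% n   # uniform over parents != mother
    h1 <- cpp_gametes(pop$h1, pop$h2, mothers, idx$pos, idx$begin, idx$end, idx$len)
    h2 <- cpp_gametes(pop$h1, pop$h2, fathers, idx$pos, idx$begin, idx$end, idx$len)
    pop <- haplotype_population(h1, h2, pop$loci)
  }
  pop
}

#' Polycross: open intermating of selected parents
#'
#' Every offspring receives a maternal gamete from its assigned mother and a
#' paternal gamete from a parent drawn uniformly from the polycross
#' excluding the mother (outbreeding; no selfing).  Each mother's offspring
#' form one half-sib family.
#'
#' @param pop a `haplotype_population`: the polycross parents.
#' @param mothers integer indices (into `pop`) of the mother-plants.
#' @param n_per_mother offspring per mother.
#' @return A list: `offspring` (`haplotype_population`) and `mother`
#'   (integer vector assigning each offspring to its mother's index).
#' @export
polycross <- function(pop, mothers = seq_len(n_ind(pop)), n_per_mother = 1L) {
  stopifnot(inherits(pop, "haplotype_population"))
  n <- n_ind(pop)
  if (n < 2L) stop("polycross needs >= 2 parents (selfing is excluded)")
  mothers <- as.integer(mothers)
  if (any(mothers < 1L | mothers > n)) stop("mother index out of range")
  mom <- rep(mothers, each = n_per_mother)
  shift <- sample.int(n - 1L, length(mom), replace = TRUE)
  dad <- 1L + (mom - 1L + shift) %% n
  idx <- loci_index(pop$loci)
  h1 <- cpp_gametes(pop$h1, pop$h2, mom, idx$pos, idx$begin, idx$end, idx$len)
  h2 <- cpp_gametes(pop$h1, pop$h2, dad, idx$pos, idx$begin, idx$end, idx$len)
  list(offspring = haplotype_population(h1, h2, pop$loci), mother = mom)
}

#' Draw a purely additive trait architecture
#'
#' Each trait receives `n_qtl` QTL sampled from the locus table's QTL pool
#' with independent standard-normal additive effects; the plot-level
#' environmental variance is calibrated later, per population, by
#' [sward_phenotype()].
#'
#' @param loci locus table of the simulated genome.
#' @param trait_h2 named vector of target plot-level broad-sense
#'   heritabilities.
#' @param n_qtl QTL per trait (at most the pool size).
#' @return A list of class `trait_architecture`: per trait, a data.frame of
#'   `locus_id`, `effect`, plus the target `h2`.
#' @export
trait_architecture <- function(loci, trait_h2, n_qtl = sum(loci$type == "qtl")) {
  pool <- which(loci$type == "qtl")
  if (length(pool) == 0L) stop("locus table contains no QTL positions")
  n_qtl <- min(n_qtl, length(pool))
  arch <- lapply(names(trait_h2), function(tr) {
    q <- sort(sample(pool, n_qtl))
    list(qtl = data.frame(locus_id = loci$locus_id[q], column = q,
                          effect = stats::rnorm(n_qtl),
                          stringsAsFactors = FALSE),
         h2 = unname(trait_h2[[tr]]))
  })
  names(arch) <- names(trait_h2)
  structure(arch, class = "trait_architecture")
}

# additive genetic values of every individual for one trait
genetic_values <- function(pop, trait) {
  cols <- trait$qtl$column
  (pop$h1[, cols, drop = FALSE] + pop$h2[, cols, drop = FALSE] - 1) %*%
    trait$qtl$effect
}

#' Sward-trial phenotypes of half-sib families
#'
#' For each mother, `progeny_per_family` half-sib progeny are simulated
#' (maternal gamete from the mother, paternal gametes from the polycross
#' pollen pool).  A family's genetic value is the mean progeny additive
#' value; each of `n_plots` replicate plots observes it plus independent
#' normal noise.  The noise variance is solved analytically from the
#' realized genetic variance of the family means so that the plot-level
#' broad-sense heritability sigma_G^2 / (sigma_G^2 + sigma_E^2) equals the
#' trait's target; a target of 0 yields pure unit-variance noise.
#'
#' @param pop polycross parents (`haplotype_population`).
#' @param mothers indices of the mother-plants within `pop`.
#' @param architecture a [trait_architecture()].
#' @param config a [sim_config()] (uses `progeny_per_family`, `n_plots`).
#' @param generation_label label stored in the returned records.
#' @param ids individual ids for the mothers (default `M001`, ...).
#' @return A list: `means` (phenotype table of family means, one record per
#'   mother x trait), `plots` (per-plot records with a `plot` column),
#'   `family_genetic` (true family genetic values) and `mother_tbv`
#'   (each mother's own additive genetic value per trait).
#' @export
sward_phenotype <- function(pop, mothers, architecture, config,
                            generation_label = "G", ids = NULL) {
  stopifnot(inherits(architecture, "trait_architecture"))
  if (is.null(ids))
    ids <- sprintf("%s_%03d", generation_label, seq_along(mothers))
  cross <- polycross(pop, mothers, n_per_mother = config$progeny_per_family)
  fam <- factor(cross$mother, levels = mothers)
  means <- plots <- truth <- vector("list", length(architecture))
  for (i in seq_along(architecture)) {
    tr <- names(architecture)[i]
    a <- architecture[[i]]
    g <- genetic_values(cross$offspring, a)
    fg <- as.numeric(tapply(g, fam, mean))
    if (a$h2 <= 0) {
      sigma_plot <- 1
      fg_used <- rep(0, length(fg))
    } else {
      vg <- stats::var(fg)
      sigma_plot <- if (vg > 0) sqrt(vg * (1 - a$h2) / a$h2) else 1
      fg_used <- fg
    }
    noise <- matrix(stats::rnorm(length(fg) * config$n_plots, sd = sigma_plot),
                    length(fg), config$n_plots)
    plot_values <- fg_used + noise
    means[[i]] <- data.frame(individual_id = ids,
                             generation = generation_label, trait = tr,
                             value = rowMeans(plot_values),
                             stringsAsFactors = FALSE)
    plots[[i]] <- data.frame(individual_id = rep(ids, config$n_plots),
                             generation = generation_label, trait = tr,
                             plot = rep(seq_len(config$n_plots), each = length(ids)),
                             value = as.numeric(plot_values),
                             stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(individual_id = ids,
                             generation = generation_label, trait = tr,
                             family_genetic_value = fg,
                             mother_tbv = as.numeric(
                               genetic_values(pop, a))[mothers],
                             stringsAsFactors = FALSE)
  }
  list(means = do.call(rbind, means), plots = do.call(rbind, plots),
       truth = do.call(rbind, truth))
}

# -1/0/1 marker codes of selected individuals as a genotype_matrix
marker_codes <- function(pop, rows, ids, generation) {
  mk <- which(pop$loci$type == "marker")
  codes <- pop$h1[rows, mk, drop = FALSE] + pop$h2[rows, mk, drop = FALSE] - 1
  dimnames(codes) <- list(ids, pop$loci$locus_id[mk])
  genotype_matrix(codes, generation = generation)
}

#' Simulate the full two-lineage breeding program
#'
#' Runs two independently founded lineages (default: Intermediate and Late)
#' through the configured generation schedule.  Each lineage starts from a
#' burn-in population with drift-generated LD, passes through a founder
#' bottleneck (`founder_count` plants expanded by a polycross) and then
#' iterates the selection cycle: polycross of `polycross_size` parents,
#' selection of `n_mothers` mother-plants (seed yield is not modelled, so
#' this draw is random), sward phenotyping of their half-sib families, and
#' selection of the `n_families` best families on the index trait to parent
#' the next cycle.  Labelled generations emit the genotypes of their first
#' `n_genotyped` mother-plants, all family-mean (and per-plot) phenotypes,
#' and truth records for validation.
#'
#' @param config a [sim_config()]; `config$seed` seeds the run.
#' @return A list of class `gs_dataset`: `genotypes` ([genotype_matrix()]),
#'   `map` (`marker_map`), `phenotypes` (family means), `plots` (per-plot
#'   records), `truth` (list with `qtl_effects` and `breeding_values`) and
#'   `config`.
#' @export
simulate_program <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  loci <- build_loci(config)
  arch <- trait_architecture(loci, config$trait_h2, config$n_qtl)
  sched <- config$generations
  geno <- list(); pheno <- list(); plots <- list(); truth <- list()
  for (lin in unique(sched$lineage)) {
    labels <- sched$label[sched$lineage == lin]
    n_geno <- sched$n_genotyped[sched$lineage == lin]
    base <- simulate_founders(config, loci)
    founders <- sample.int(n_ind(base), min(config$founder_count, n_ind(base)))
    fpop <- subset_population(base, founders)
    expand <- polycross(fpop, mothers = seq_len(n_ind(fpop)),
                        n_per_mother = ceiling(config$polycross_size /
                                                 n_ind(fpop)))$offspring
    parents <- subset_population(expand, seq_len(config$polycross_size))
    n_cycles <- config$pre_label_cycles + length(labels)
    for (cy in seq_len(n_cycles)) {
      lab_i <- cy - config$pre_label_cycles
      labelled <- lab_i >= 1L
      label <- if (labelled) labels[lab_i] else sprintf("%s_pre%d", lin, cy)
      mothers <- sort(sample.int(n_ind(parents), config$n_mothers))
      ids <- sprintf("%s_%03d", label, seq_along(mothers))
      ph <- sward_phenotype(parents, mothers, arch, config,
                            generation_label = label, ids = ids)
      if (labelled) {
        ng <- n_geno[lab_i]
        geno[[label]] <- marker_codes(parents, mothers[seq_len(ng)],
                                      ids[seq_len(ng)], label)
        pheno[[label]] <- ph$means
        plots[[label]] <- ph$plots
        truth[[label]] <- ph$truth
      }
      # family selection on the index trait's family means
      idx_means <- ph$means[ph$means$trait == config$index_trait, ]
      best <- order(idx_means$value, decreasing = TRUE)[seq_len(config$n_families)]
      next_parents <- polycross(parents, mothers[best],
                                n_per_mother = ceiling(config$polycross_size /
                                                         config$n_families))$offspring
      parents <- subset_population(next_parents, seq_len(config$polycross_size))
    }
  }
  g_all <- do.call(rbind, lapply(geno, unclass))
  gen_all <- unlist(lapply(geno, generations), use.names = FALSE)
  mk <- loci[loci$type == "marker", ]
  map <- marker_map(data.frame(marker_id = mk$locus_id,
                               chromosome = mk$chromosome,
                               position_cM = mk$position_cM,
                               stringsAsFactors = FALSE),
                    n_chromosomes = config$n_chromosomes)
  qtl_eff <- do.call(rbind, lapply(names(arch), function(tr)
    data.frame(trait = tr, marker_id = arch[[tr]]$qtl$locus_id,
               effect = arch[[tr]]$qtl$effect, stringsAsFactors = FALSE)))
  structure(list(genotypes = genotype_matrix(g_all, generation = gen_all),
                 map = map,
                 phenotypes = phenotype_table(do.call(rbind, pheno)),
                 plots = do.call(rbind, plots),
                 truth = list(qtl_effects = qtl_eff,
                              breeding_values = do.call(rbind, truth)),
                 config = config),
            class = "gs_dataset")
}

subset_population <- function(pop, rows) {
  haplotype_population(pop$h1[rows, , drop = FALSE],
                       pop$h2[rows, , drop = FALSE], pop$loci)
}

#' @export
print.gs_dataset <- function(x, ...) {
  cat("Simulated genomic-selection dataset\n")
  print(x$genotypes)
  cat("Phenotype records:", nrow(x$phenotypes), "family means over",
      length(unique(x$phenotypes$trait)), "traits\n")
  invisible(x)
}

#' Write a simulated dataset to delimited files
#'
#' Emits `genotypes.tsv`, `map.tsv`, `phenotypes.tsv`, `plots.tsv`,
#' `qtl_effects.tsv` and `breeding_values.tsv` under `dir`.
#'
#' @param data a `gs_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(data, dir) {
  stopifnot(inherits(data, "gs_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(data$genotypes, file.path(dir, "genotypes.tsv"))
  write_map(data$map, file.path(dir, "map.tsv"))
  write_phenotypes(data$phenotypes, file.path(dir, "phenotypes.tsv"))
  utils::write.table(data$plots, file.path(dir, "plots.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data$truth$qtl_effects, file.path(dir, "qtl_effects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data$truth$breeding_values,
                     file.path(dir, "breeding_values.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
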