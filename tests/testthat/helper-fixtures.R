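# Shared fixture builders: everything is generated in code at test time.

# a small valid genotype matrix with optional missingness
toy_genotypes <- function(n = 8, m = 6, generation = "F13", missing = 0,
                          seed = 1) {
  set.seed(seed)
  codes <- matrix(sample(c(-1, 0, 1), n * m, replace = TRUE), n, m,
                  dimnames = list(sprintf("ind%02d", seq_len(n)),
                                  sprintf("mk%02d", seq_len(m))))
  if (missing > 0) codes[sample(length(codes), missing)] <- NA
  genotype_matrix(codes, generation = rep_len(generation, n))
}

toy_map <- function(m = 6, chromosomes = 2) {
  marker_map(data.frame(marker_id = sprintf("mk%02d", seq_len(m)),
                        chromosome = rep_len(seq_len(chromosomes), m),
                        position_cM = seq(0, 50, length.out = m)),
             n_chromosomes = 7)
}

# compact simulator config for fast tests
small_config <- function(...) {
  defaults <- list(n_chromosomes = 2L, chromosome_length = 1,
                   n_markers = 60L, n_qtl = 30L, founder_count = 8L,
                   effective_size = 40L, burnin_generations = 5L,
                   polycross_size = 40L, n_families = 4L, n_mothers = 12L,
                   progeny_per_family = 8L, n_plots = 2L,
                   trait_h2 = c(yield = 0.4),
                   generations = data.frame(
                     lineage = c("A", "B"), label = c("F13", "F5"),
                     n_genotyped = c(10L, 10L), stringsAsFactors = FALSE),
                   pre_label_cycles = 0L, seed = 1L)
  override <- list(...)
  args <- defaults
  for (nm in names(override)) args[[nm]] <- override[[nm]]
  do.call(sim_config, args)
}

# single-lineage schedule helper
lineage_schedule <- function(labels, n_genotyped, lineage = "A") {
  data.frame(lineage = lineage, label = labels, n_genotyped = n_genotyped,
             stringsAsFactors = FALSE)
}

# hand-built dataset (genotypes + family-mean phenotypes) for the
# evaluation pipeline, with a controllable genetic signal
toy_dataset <- function(n_per_gen = c(F13 = 20, F14 = 15), m = 30, h2 = 0.8,
                        traits = c("wsc", "dmd"), seed = 42) {
  set.seed(seed)
  gens <- rep(names(n_per_gen), n_per_gen)
  n <- length(gens)
  codes <- matrix(sample(c(-1, 0, 1), n * m, replace = TRUE), n, m,
                  dimnames = list(sprintf("%s_%02d", gens, unlist(lapply(
                    n_per_gen, seq_len))), sprintf("mk%02d", seq_len(m))))
  g <- genotype_matrix(codes, generation = gens)
  eff <- matrix(stats::rnorm(m * length(traits)), m)
  pheno <- do.call(rbind, lapply(seq_along(traits), function(ti) {
    gv <- as.numeric(codes %*% eff[, ti])
    e <- stats::rnorm(n, sd = sqrt(stats::var(gv) * (1 - h2) / h2))
    data.frame(individual_id = rownames(codes), generation = gens,
               trait = traits[ti], value = gv + e, stringsAsFactors = FALSE)
  }))
  list(genotypes = g, phenotypes = pheno)
}
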