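test_that("founder simulation is deterministic under a seed", {
  cfg <- small_config()
  set.seed(11); p1 <- simulate_founders(cfg)
  set.seed(11); p2 <- simulate_founders(cfg)
  expect_identical(p1, p2)
  set.seed(12); p3 <- simulate_founders(cfg)
  expect_false(identical(p1$h1, p3$h1))
})

test_that("genotype codes always equal h1 + h2 - 1 and lie in {-1,0,1}", {
  cfg <- small_config()
  set.seed(2)
  pop <- simulate_founders(cfg)
  codes <- pop$h1 + pop$h2 - 1
  expect_true(all(codes %in% c(-1, 0, 1)))
  d <- simulate_program(small_config(seed = 5))
  expect_true(all(unclass(d$genotypes) %in% c(-1, 0, 1)))
})

test_that("zero burn-in leaves distant markers in linkage equilibrium", {
  cfg <- small_config(burnin_generations = 0L, effective_size = 300L,
                      n_markers = 40L, n_qtl = 2L)
  set.seed(3)
  pop <- simulate_founders(cfg)
  mk <- which(pop$loci$type == "marker")
  codes <- pop$h1[, mk] + pop$h2[, mk] - 1
  # markers on different chromosomes, founders drawn independently per locus
  c1 <- which(pop$loci$chromosome[mk] == 1)
  c2 <- which(pop$loci$chromosome[mk] == 2)
  r2 <- stats::cor(codes[, c1], codes[, c2])^2
  expect_lt(mean(r2), 3 / nrow(codes))   # sampling noise scale ~1/n
})

test_that("meiosis reproduces Haldane expectations", {
  # homozygous parent: gamete equals the haplotype at every locus
  loci <- data.frame(locus_id = paste0("l", 1:10), chromosome = 1,
                     position_cM = seq(0, 90, 10), type = "marker")
  h <- matrix(rep(c(0L, 1L), 5), 1, 10)
  pop <- haplotype_population(h, h, loci)
  set.seed(4)
  gam <- meiosis(pop, rep(1L, 20))
  expect_true(all(gam == matrix(h, 20, 10, byrow = TRUE)))

  # two loci 0.01 Morgans apart: recombinant fraction ~ (1 - exp(-0.02))/2
  loci2 <- data.frame(locus_id = c("a", "b"), chromosome = 1,
                      position_cM = c(0, 1), type = "marker")
  pop2 <- haplotype_population(matrix(1L, 1, 2), matrix(0L, 1, 2), loci2)
  set.seed(5)
  gam2 <- meiosis(pop2, rep(1L, 1e5))
  rec <- mean(gam2[, 1] != gam2[, 2])
  expected <- (1 - exp(-2 * 0.01)) / 2
  ci <- expected + c(-4, 4) * sqrt(expected * (1 - expected) / 1e5)
  expect_gt(rec, ci[1]); expect_lt(rec, ci[2])

  # loci on different chromosomes assort independently
  loci3 <- data.frame(locus_id = c("a", "b"), chromosome = c(1, 2),
                      position_cM = c(0, 0), type = "marker")
  pop3 <- haplotype_population(matrix(1L, 1, 2), matrix(0L, 1, 2), loci3)
  set.seed(6)
  gam3 <- meiosis(pop3, rep(1L, 2e4))
  rec3 <- mean(gam3[, 1] != gam3[, 2])
  expect_gt(rec3, 0.48); expect_lt(rec3, 0.52)
})

test_that("polycross outbreeds: one gamete from each parent when only two", {
  cfg <- small_config()
  set.seed(7)
  pop <- simulate_founders(cfg)
  two <- haplotype_population(pop$h1[1:2, ], pop$h2[1:2, ], pop$loci)
  # make parent origin identifiable: parent 1 all-0, parent 2 all-1
  two$h1[1, ] <- 0L; two$h2[1, ] <- 0L
  two$h1[2, ] <- 1L; two$h2[2, ] <- 1L
  cross <- polycross(two, mothers = c(1L, 2L), n_per_mother = 10)
  codes <- cross$offspring$h1 + cross$offspring$h2 - 1
  expect_true(all(codes == 0))   # always one 0-gamete + one 1-gamete
  one <- haplotype_population(pop$h1[1, , drop = FALSE],
                              pop$h2[1, , drop = FALSE], pop$loci)
  expect_error(polycross(one), "2 parents")
})

test_that("half-sib families share the maternal gamete: elevated kinship", {
  cfg <- small_config(effective_size = 60L, burnin_generations = 0L,
                      n_markers = 200L, n_qtl = 2L)
  set.seed(8)
  pop <- simulate_founders(cfg)
  cross <- polycross(pop, mothers = 1:10, n_per_mother = 10)
  mk <- cross$offspring$loci$type == "marker"
  codes <- cross$offspring$h1[, mk] + cross$offspring$h2[, mk] - 1
  # centre per locus so row correlations estimate genomic relationship
  cc <- stats::cor(t(scale(codes, center = TRUE, scale = FALSE)))
  fam <- cross$mother
  same <- cc[outer(fam, fam, "==") & upper.tri(cc)]
  diff <- cc[outer(fam, fam, "!=") & upper.tri(cc)]
  # half-sibs: kinship 1/8 -> genotype correlation ~ 2*1/8 = 0.25 above background
  expect_gt(mean(same) - mean(diff), 0.15)
})

test_that("polycross and program runs are reproducible under seed", {
  cfg <- small_config(seed = 99L)
  d1 <- simulate_program(cfg)
  d2 <- simulate_program(cfg)
  expect_identical(d1$genotypes, d2$genotypes)
  expect_identical(d1$phenotypes, d2$phenotypes)
  expect_identical(d1$truth, d2$truth)
})

test_that("sward phenotypes: null trait is noise, noiseless limit is exact", {
  cfg <- small_config(trait_h2 = c(null = 0, hi = 1 - 1e-12),
                      n_mothers = 30L, polycross_size = 60L,
                      progeny_per_family = 10L, n_plots = 4L)
  set.seed(9)
  pop <- simulate_founders(cfg)
  arch <- trait_architecture(pop$loci, cfg$trait_h2, cfg$n_qtl)
  ph <- sward_phenotype(pop, mothers = 1:30, arch, cfg)
  plots_null <- ph$plots[ph$plots$trait == "null", ]
  h2_null <- heritability_anova(plots_null$value, plots_null$individual_id)$H2
  expect_lt(h2_null, 0.25)
  # near-zero plot noise: family mean equals the mean progeny genetic value
  means_hi <- ph$means[ph$means$trait == "hi", ]
  truth_hi <- ph$truth[ph$truth$trait == "hi", ]
  expect_equal(means_hi$value, truth_hi$family_genetic_value, tolerance = 1e-5)
})

test_that("heritability calibration is recovered by the half-sib ANOVA", {
  cfg <- small_config(trait_h2 = c(tr = 0.9), n_mothers = 60L,
                      polycross_size = 100L, progeny_per_family = 12L,
                      n_plots = 4L, effective_size = 100L,
                      burnin_generations = 3L)
  set.seed(10)
  est <- replicate(20, {
    pop <- simulate_founders(cfg)
    arch <- trait_architecture(pop$loci, cfg$trait_h2, cfg$n_qtl)
    ph <- sward_phenotype(pop, mothers = 1:60, arch, cfg)
    heritability_anova(ph$plots$value, ph$plots$individual_id)$H2
  })
  expect_lt(abs(median(est) - 0.9), 0.1)
})

test_that("emitted mother-plant counts match the configured schedule", {
  cfg <- small_config(generations = lineage_schedule(
    c("F12", "F13", "F14"), c(7L, 9L, 12L)), n_mothers = 12L)
  d <- simulate_program(cfg)
  counts <- table(generations(d$genotypes))
  expect_equal(as.integer(counts[c("F12", "F13", "F14")]), c(7L, 9L, 12L))
  # every mother has one family-mean record per trait
  expect_equal(nrow(d$phenotypes),
               length(cfg$trait_h2) * 3 * cfg$n_mothers)
})

test_that("family phenotypes track true family genetic values at sqrt(H2)", {
  h2 <- 0.5
  cfg <- small_config(trait_h2 = c(tr = h2), n_mothers = 400L,
                      polycross_size = 500L, progeny_per_family = 10L,
                      n_plots = 1L, effective_size = 400L,
                      burnin_generations = 3L, n_markers = 40L, n_qtl = 40L)
  set.seed(12)
  pop <- simulate_founders(cfg)
  arch <- trait_architecture(pop$loci, cfg$trait_h2, cfg$n_qtl)
  ph <- sward_phenotype(pop, mothers = 1:400, arch, cfg)
  r <- stats::cor(ph$means$value, ph$truth$family_genetic_value)
  expect_lt(abs(r - sqrt(h2)), 0.08)
})

test_that("allele frequencies drift without directional trend", {
  cfg <- small_config(effective_size = 40L, burnin_generations = 0L,
                      n_markers = 80L, n_qtl = 2L)
  set.seed(13)
  drift <- replicate(25, {
    pop <- simulate_founders(cfg)
    mk <- pop$loci$type == "marker"
    p0 <- colMeans((pop$h1[, mk] + pop$h2[, mk]) / 2)
    pop2 <- random_mate(pop, generations = 5)
    p1 <- colMeans((pop2$h1[, mk] + pop2$h2[, mk]) / 2)
    mean(p1 - p0)
  })
  expect_lt(abs(mean(drift)), 0.01)
})

test_that("default program emits adjacent-marker LD in the observed band", {
  # the study populations show mean adjacent-pair r2 between 0.121 and 0.215;
  # the default configuration is calibrated to land in that band
  in_band <- vapply(1:5, function(s) {
    d <- simulate_program(sim_config(seed = s))
    g <- impute_missing(d$genotypes)
    adj <- vapply(1:7, function(ch) pairwise_ld(g, d$map, ch)$adjacent_mean, 0)
    mean(adj) >= 0.12 && mean(adj) <= 0.22
  }, TRUE)
  expect_gte(sum(in_band), 4)
})
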