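test_that("genotype tables round-trip exactly through write/read", {
  g <- toy_genotypes(n = 10, m = 8, generation = c(rep("F13", 5), rep("F5", 5)),
                     missing = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(g, path)
  g2 <- read_genotypes(path)
  expect_identical(unclass(g2)[, ], unclass(g)[, ])
  expect_identical(rownames(g2), rownames(g))
  expect_identical(colnames(g2), colnames(g))
  expect_identical(generations(g2), generations(g))

  # comma-separated files are autodetected too
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_genotypes(g, path2, sep = ",")
  expect_identical(unclass(read_genotypes(path2))[, ], unclass(g)[, ])
})

test_that("plink additive 0/1/2 codes map to -1/0/1", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("individual_id\tgeneration\tm1\tm2\tm3",
               "a\tF13\t0\t1\t2",
               "b\tF13\t2\tNA\t0"), path)
  g <- read_genotypes(path, dialect = "plink_additive")
  expect_equal(unname(unclass(g)[1, ]), c(-1, 0, 1))
  expect_equal(unname(unclass(g)[2, ]), c(1, NA, -1))
})

test_that("malformed codes and duplicate ids are rejected with coordinates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("individual_id\tgeneration\tm1\tm2",
               "a\tF13\t0\t1",
               "b\tF13\t3\t-1"), path)
  expect_error(read_genotypes(path), "3.*'b'.*'m1'")
  writeLines(c("individual_id\tgeneration\tm1\tm2",
               "a\tF13\t0\t1",
               "a\tF13\t1\t-1"), path)
  expect_error(read_genotypes(path), "duplicate individual ids")
  expect_error(genotype_matrix(matrix(0, 2, 2), generation = "F1",
                               marker_ids = c("m", "m")), "duplicate marker")
})

test_that("mean imputation fills missing calls and is idempotent", {
  codes <- cbind(a = c(-1, 1, NA), b = c(1, 1, NA), c = c(NA, 0, -1))
  g <- genotype_matrix(codes, generation = "F13")
  gi <- impute_missing(g)
  expect_equal(unname(unclass(gi)[3, "a"]), 0)    # mean of -1, 1
  expect_equal(unname(unclass(gi)[3, "b"]), 1)    # mean of constant column
  expect_equal(unname(unclass(gi)[1, "c"]), -0.5)
  expect_false(anyNA(gi))
  # observed entries unchanged
  expect_equal(unclass(gi)[!is.na(codes)], codes[!is.na(codes)])
  expect_equal(unclass(impute_missing(gi))[, ], unclass(gi)[, ])

  g_clean <- toy_genotypes()
  expect_equal(unclass(impute_missing(g_clean))[, ], unclass(g_clean)[, ])

  g_bad <- genotype_matrix(cbind(dead = c(NA, NA), ok = c(0, 1)),
                           generation = "F13")
  expect_error(impute_missing(g_bad), "dead")
})

test_that("allele frequency matches direct gamete counting", {
  g <- genotype_matrix(cbind(fix = c(1, 1, 1), sym = c(-1, 0, 0)),
                       individual_ids = c("a", "b", "c"), generation = "F13")
  expect_equal(unname(allele_frequency(g)["fix"]), 1)
  g2 <- genotype_matrix(cbind(sym = c(-1, 0, 0, 1)), generation = "F13")
  expect_equal(unname(allele_frequency(g2)["sym"]), 0.5)

  # brute-force oracle: count +1 alleles over 2n gametes per marker
  g3 <- toy_genotypes(n = 17, m = 9, missing = 10, seed = 7)
  counted <- apply(unclass(g3), 2, function(col) {
    col <- col[!is.na(col)]
    sum(col + 1) / (2 * length(col))
  })
  expect_equal(allele_frequency(g3), counted)
})

test_that("PCA separates constructed blocks and reports valid variance fractions", {
  # two blocks with disjoint fixed alleles
  codes <- rbind(matrix(rep(c(1, -1), each = 10), 4, 20, byrow = TRUE),
                 matrix(rep(c(-1, 1), each = 10), 4, 20, byrow = TRUE))
  g <- genotype_matrix(codes, generation = rep(c("A", "B"), each = 4))
  pc <- pca_scores(g, 2)
  expect_true(all(sign(pc$scores[1:4, 1]) == sign(pc$scores[1, 1])))
  expect_true(all(sign(pc$scores[5:8, 1]) == -sign(pc$scores[1, 1])))
  expect_true(all(diff(pc$explained) <= 1e-12))
  expect_lte(sum(pc$explained), 1 + 1e-12)

  # centred rank-1 matrix: first component carries all variance
  v <- c(-1, 0, 1, 0, 0)
  w <- rep(c(1, -1), 5)
  r1 <- genotype_matrix(pmax(pmin(outer(v, w), 1), -1), generation = "A")
  pc1 <- pca_scores(r1, 1)
  expect_equal(pc1$explained[1], 1)

  # duplicated individuals get identical scores
  dup <- genotype_matrix(codes[c(1, 1, 2, 5, 6, 7), ],
                         individual_ids = letters[1:6],
                         generation = "A")
  pcd <- pca_scores(dup, 2)
  expect_equal(pcd$scores[1, ], pcd$scores[2, ])

  expect_error(pca_scores(g, 99), "n_components")
  expect_error(pca_scores(toy_genotypes(missing = 3), 2), "impute")
})

test_that("map and phenotype files round-trip and validate", {
  map <- toy_map(10, 3)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_map(map, p)
  expect_equal(as.data.frame(read_map(p)), as.data.frame(map))

  # PLINK .map dialect
  pm <- withr::local_tempfile(fileext = ".map")
  writeLines(c("1\tmkA\t0.0\t100", "1\tmkB\t12.5\t200", "2\tmkC\t3.0\t50"), pm)
  m2 <- read_map(pm)
  expect_equal(m2$marker_id, c("mkA", "mkB", "mkC"))
  expect_equal(m2$position_cM, c(0, 12.5, 3))

  expect_error(marker_map(data.frame(marker_id = "x", chromosome = 9,
                                     position_cM = 1)), "chromosome")

  ph <- data.frame(individual_id = c("a", "b"), generation = "F13",
                   trait = "wsc", value = c(1.2, -0.3))
  pp <- withr::local_tempfile(fileext = ".tsv")
  write_phenotypes(ph, pp)
  expect_equal(read_phenotypes(pp), phenotype_table(ph))
  expect_error(phenotype_table(rbind(ph, ph[1, ])), "duplicate")
})
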