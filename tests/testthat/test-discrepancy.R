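test_that("expected genotype follows the base pair at the marker", {
  we <- worked_example()
  expect_equal(expected_genotype(we$pair, "rs41541913", we$table), "HET")
  mk <- we$markers
  bases <- rbind("A*01:01" = "C", "A*02:01" = "T", "A*03:01" = NA_character_)
  colnames(bases) <- mk$marker_id
  tab <- hla_allele_table("HLA-A", mk, bases)
  expect_equal(expected_genotype(c("A*01:01", "A*01:01"), "rs41541913", tab),
               "HOM_A")
  expect_equal(expected_genotype(c("A*02:01", "A*01:01"), "rs41541913", tab),
               "IMPOSSIBLE")
  expect_equal(expected_genotype(c("A*03:01", "A*01:01"), "rs41541913", tab),
               "UNDEFINED")
  expect_error(expected_genotype(c("A*99:01", "A*01:01"), "rs41541913", tab),
               "not in table")
})

test_that("per-marker discrepancy is the posterior mass off the expected genotype", {
  expect_equal(marker_discrepancy(c(0.10, 0.65, 0.25), "HET"), 0.35)
  expect_equal(marker_discrepancy(c(1, 0, 0), "HOM_A"), 0)
  expect_equal(marker_discrepancy(c(0.2, 0.5, 0.3), "IMPOSSIBLE"), 1)
  # triplets summing below 1 inflate s
  expect_equal(marker_discrepancy(c(0.1, 0.4, 0.1), "HET"), 0.6)
})

test_that("pair discrepancy sums per-marker values over usable markers", {
  we <- worked_example()
  res <- pair_discrepancy(we$gt, "ind1", we$pair, we$table)
  expect_equal(res$D, 0.35)
  expect_equal(res$n_used, 1L)
  # certain posteriors matching every expected genotype give D = 0
  mk <- data.frame(marker_id = c("m1", "m2", "m3"), gene = "HLA-A",
                   cdna_pos = 1:3, strand = "+", alleleA = "C", alleleB = "G",
                   stringsAsFactors = FALSE)
  bases <- rbind("A*01:01" = c("C", "G", "C"), "A*02:01" = c("C", "G", "G"))
  colnames(bases) <- mk$marker_id
  tab <- hla_allele_table("HLA-A", mk, bases)
  # pair (01:01, 02:01): expected HOM_A, HOM_B, HET
  gt <- hla_genotypes("i1", mk, matrix(c(1, 0, 0), 1), matrix(c(0, 0, 1), 1),
                      matrix(c(0, 1, 0), 1))
  expect_equal(pair_discrepancy(gt, "i1", c("A*01:01", "A*02:01"), tab)$D, 0)
  # hand sum: s = 0.1, 0.0, 0.5 -> D = 0.6
  gt2 <- hla_genotypes("i1", mk, matrix(c(0.9, 0, 0.2), 1),
                       matrix(c(0.1, 0, 0.5), 1), matrix(c(0, 1, 0.3), 1))
  res2 <- pair_discrepancy(gt2, "i1", c("A*01:01", "A*02:01"), tab)
  expect_equal(res2$D, 0.1 + 0 + 0.5)
  expect_equal(res2$n_used, 3L)
})

test_that("D is symmetric in pair order and additive over marker subsets", {
  set.seed(21)
  for (rep in 1:10) {
    inst <- random_instance(6L, 8L)
    al <- rownames(inst$table$bases)
    a <- sample(al, 1L); b <- sample(al, 1L)
    d1 <- pair_discrepancy(inst$gt, "ind1", c(a, b), inst$table)
    d2 <- pair_discrepancy(inst$gt, "ind1", c(b, a), inst$table)
    expect_identical(d1$D, d2$D)
    if (d1$status != "ok") next
    # additivity: split the markers into two disjoint tables
    m <- nrow(inst$table$markers)
    if (m < 2L) next
    half <- seq_len(m %/% 2L)
    t1 <- hla_allele_table(inst$table$gene, inst$table$markers[half, ],
                           inst$table$bases[, half, drop = FALSE])
    t2 <- hla_allele_table(inst$table$gene, inst$table$markers[-half, ],
                           inst$table$bases[, -half, drop = FALSE])
    s1 <- pair_discrepancy(inst$gt, "ind1", c(a, b), t1)
    s2 <- pair_discrepancy(inst$gt, "ind1", c(a, b), t2)
    expect_equal(sum(s1$D, s2$D, na.rm = TRUE), d1$D, tolerance = 1e-12)
    expect_true(d1$D >= 0 && d1$D <= d1$n_used)
  }
})

test_that("degenerate zero-marker scores are flagged, not silently 0", {
  mk <- data.frame(marker_id = "m1", gene = "HLA-A", cdna_pos = 1L,
                   strand = "+", alleleA = "C", alleleB = "G",
                   stringsAsFactors = FALSE)
  bases <- rbind("A*01:01" = NA_character_, "A*02:01" = "C")
  colnames(bases) <- mk$marker_id
  tab <- hla_allele_table("HLA-A", mk, bases)
  gt <- hla_genotypes("i1", mk, matrix(1), matrix(0), matrix(0))
  res <- pair_discrepancy(gt, "i1", c("A*01:01", "A*01:01"), tab)
  expect_equal(res$status, "no_markers")
  expect_true(is.na(res$D))
})

test_that("a single-allele table has only the homozygous pair", {
  mk <- data.frame(marker_id = "m1", gene = "HLA-A", cdna_pos = 1L,
                   strand = "+", alleleA = "C", alleleB = "G",
                   stringsAsFactors = FALSE)
  bases <- rbind("A*01:01" = "G")
  colnames(bases) <- mk$marker_id
  tab <- hla_allele_table("HLA-A", mk, bases)
  gt <- hla_genotypes("i1", mk, matrix(0.3), matrix(0.3), matrix(0.4))
  bp <- best_pairs(gt, "i1", tab)
  expect_equal(bp$pairs, "A*01:01/A*01:01")
  expect_equal(bp$D_min, 1 - 0.4)
})

test_that("best-pair search equals the naive enumeration on random instances", {
  set.seed(31)
  for (rep in 1:40) {
    inst <- random_instance(sample(2:12, 1L), sample(3:15, 1L),
                            unknown_rate = runif(1, 0, 0.3))
    mc <- sample(c(0, 0.5), 1L)
    if (!any(rowMeans(!is.na(inst$table$bases)) >= mc)) next
    got <- best_pairs(inst$gt, "ind1", inst$table, min_coverage = mc)
    want <- naive_best_pairs(inst$gt, "ind1", inst$table, min_coverage = mc)
    expect_equal(got$D_min, want$D_min, tolerance = 1e-12)
    expect_equal(got$pairs, want$pairs)
  }
})

test_that("noise-free individuals are recovered with delta zero at the true pair", {
  cfg <- sim_config(n_alleles = 8L, n_markers = 10L, n_individuals = 30L,
                    noise = 0, corrupt_frac = 0, seed = 99L)
  tab <- gen_allele_table(cfg)
  pop <- gen_population(tab, cfg)
  res <- check_assignments(pop$genotypes, pop$truth, tab)
  expect_true(all(res$status == "ok"))
  expect_true(all(res$delta == 0))
  expect_true(all(res$D_attributed == 0))
  # and the true pair is among the best pairs reported
  hit <- mapply(function(att, bp) att %in% strsplit(bp, ";", fixed = TRUE)[[1]],
                res$attributed, res$best_pairs)
  expect_true(all(hit))
})

test_that("a wrong pair differing at k informative markers scores delta = k", {
  cfg <- sim_config(n_alleles = 6L, n_markers = 12L, n_individuals = 5L,
                    noise = 0, corrupt_frac = 0, seed = 7L)
  tab <- gen_allele_table(cfg)
  pop <- gen_population(tab, cfg)
  codes <- hlacheckr:::allele_codes(tab)
  al <- rownames(tab$bases)
  truth <- pop$truth
  i1 <- match(truth$allele1[1], al); i2 <- match(truth$allele2[1], al)
  true_geno <- codes[i1, ] + codes[i2, ]
  # pick a different pair and count markers where the implied genotype differs
  j1 <- 1L; j2 <- 2L
  if (pair_key(al[j1], al[j2]) == pair_key(al[i1], al[i2])) j2 <- 3L
  k <- sum(codes[j1, ] + codes[j2, ] != true_geno)
  wrong <- data.frame(individual_id = truth$individual_id[1], gene = tab$gene,
                      allele1 = al[j1], allele2 = al[j2])
  res <- check_assignments(pop$genotypes, wrong, tab)
  expect_equal(res$delta, k)
})

test_that("attributed pairs in the best set give delta 0; unknown alleles a status", {
  we <- worked_example()
  a <- data.frame(individual_id = "ind1", gene = "HLA-A",
                  allele1 = "A*01:01", allele2 = "A*80:01")
  res <- check_assignments(we$gt, a, we$table)
  expect_equal(res$D_attributed, 0.35)
  expect_equal(res$delta, 0)  # the het pair is optimal among the 3 pairs
  expect_match(res$best_pairs, "A\\*01:01/A\\*80:01")
  bad <- data.frame(individual_id = "ind1", gene = "HLA-A",
                    allele1 = "A*01:01", allele2 = "A*99:99")
  res2 <- check_assignments(we$gt, bad, we$table)
  expect_equal(res2$status, "allele_not_in_db")
  expect_true(is.na(res2$delta))
})

test_that("raising posterior mass on the expected genotype never increases D", {
  set.seed(41)
  we <- worked_example()
  mk <- we$markers
  for (p_het in seq(0, 1, by = 0.1)) {
    rest <- (1 - p_het) / 2
    gt <- hla_genotypes("ind1", mk, matrix(rest), matrix(p_het), matrix(rest))
    D <- pair_discrepancy(gt, "ind1", we$pair, we$table)$D
    expect_equal(D, 1 - p_het)
  }
})
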