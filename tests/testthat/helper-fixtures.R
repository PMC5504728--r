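# Fixtures built in code, shared across test files.

# The single-marker heterozygous fixture: a C/G marker where one allele
# carries G and the other C, and the individual's posteriors are
# p(CC) = 0.10, p(CG) = 0.65, p(GG) = 0.25.
worked_example <- function() {
  mk <- data.frame(marker_id = "rs41541913", gene = "HLA-A", cdna_pos = 1L,
                   strand = "+", alleleA = "C", alleleB = "G",
                   stringsAsFactors = FALSE)
  bases <- matrix(c("G", "C"), 2L, 1L,
                  dimnames = list(c("A*01:01", "A*80:01"), "rs41541913"))
  table <- hla_allele_table("HLA-A", mk, bases)
  gt <- hla_genotypes("ind1", mk, matrix(0.10), matrix(0.65), matrix(0.25))
  list(markers = mk, table = table, gt = gt, pair = c("A*01:01", "A*80:01"))
}

# Random small instance (table + one individual's posteriors), allowing
# unknown bases, off-chip ("third nucleotide") bases and unnormalized
# posterior triplets, for oracle-equivalence sweeps.
random_instance <- function(n_alleles, n_markers, unknown_rate = 0.15,
                            offchip_rate = 0.1) {
  nt <- c("A", "C", "G", "T")
  ab <- t(vapply(seq_len(n_markers), function(j) sample(nt, 2L), character(2L)))
  mk <- data.frame(marker_id = sprintf("m%03d", seq_len(n_markers)),
                   gene = "HLA-T", cdna_pos = seq_len(n_markers),
                   strand = sample(c("+", "-"), n_markers, replace = TRUE),
                   alleleA = ab[, 1L], alleleB = ab[, 2L],
                   stringsAsFactors = FALSE)
  bases <- matrix(NA_character_, n_alleles, n_markers,
                  dimnames = list(sprintf("T*%02d:01", seq_len(n_alleles)),
                                  mk$marker_id))
  for (i in seq_len(n_alleles)) for (j in seq_len(n_markers)) {
    u <- stats::runif(1)
    bases[i, j] <- if (u < unknown_rate) NA_character_
    else if (u < unknown_rate + offchip_rate) setdiff(nt, ab[j, ])[sample.int(2L, 1L)]
    else ab[j, sample.int(2L, 1L)]
  }
  table <- hla_allele_table("HLA-T", mk, bases)
  p <- matrix(stats::runif(3L * n_markers), 3L, n_markers)
  p <- sweep(p, 2L, pmax(colSums(p), 1), "/")  # sums <= 1, sometimes < 1
  miss <- stats::runif(n_markers) < 0.1
  p[, miss] <- NA_real_
  gt <- hla_genotypes("ind1", mk, matrix(p[1L, ], 1L), matrix(p[2L, ], 1L),
                      matrix(p[3L, ], 1L))
  list(table = table, gt = gt)
}

# Independent naive implementation of the exhaustive best-pair search:
# scalar double loop over unordered pairs, per-marker expected-genotype
# logic written out from the definitions.  The oracle for the vectorized
# search.
naive_best_pairs <- function(gt, individual_id, table, min_coverage = 0.5,
                             tie_tol = 1e-9) {
  i <- match(individual_id, gt$samples)
  cov <- rowMeans(!is.na(table$bases))
  alleles <- rownames(table$bases)[cov >= min_coverage]
  mk <- table$markers
  keys <- character(0); Ds <- numeric(0)
  for (ai in seq_along(alleles)) for (bi in ai:length(alleles)) {
    a <- alleles[ai]; b <- alleles[bi]
    D <- 0; used <- 0L
    for (j in seq_len(nrow(mk))) {
      if (is.na(gt$p_AA[i, j])) next
      b1 <- table$bases[a, j]; b2 <- table$bases[b, j]
      if (is.na(b1) || is.na(b2)) next
      chip <- c(mk$alleleA[j], mk$alleleB[j])
      if (!(b1 %in% chip) || !(b2 %in% chip)) {
        s <- 1
      } else {
        nB <- (b1 == chip[2L]) + (b2 == chip[2L])
        p_exp <- c(gt$p_AA[i, j], gt$p_AB[i, j], gt$p_BB[i, j])[nB + 1L]
        s <- min(max(1 - p_exp, 0), 1)
      }
      D <- D + s; used <- used + 1L
    }
    if (used == 0L) next
    keys <- c(keys, paste(sort(c(a, b))[1L], sort(c(a, b))[2L], sep = "/"))
    Ds <- c(Ds, D)
  }
  D_min <- min(Ds)
  list(D_min = D_min, pairs = sort(keys[Ds <= D_min + tie_tol]))
}

# Build an hla_genotypes for a cohort from explicit posterior triplet rows.
make_gt <- function(markers, ids, pAA, pAB, pBB) {
  hla_genotypes(ids, markers,
                matrix(pAA, length(ids), nrow(markers)),
                matrix(pAB, length(ids), nrow(markers)),
                matrix(pBB, length(ids), nrow(markers)))
}
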