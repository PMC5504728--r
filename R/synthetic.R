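# Synthetic allele tables and cohorts with known ground truth, so the whole
# pipeline is testable without any database download or restricted panel.

#' Simulation configuration
#'
#' Defaults describe a desk-scale cohort with the statistical structure the
#' checker is designed for: a handful of database alleles with strongly
#' skewed population frequencies (as HLA allele frequencies are), posteriors
#' concentrated on the genotype implied by the true pair with a small
#' diverted mass, and a small fraction of deliberately corrupted recorded
#' assignments.
#'
#' @param n_alleles Number of database alleles (default 10).
#' @param n_markers Number of exonic biallelic markers (default 20).
#' @param unknown_rate Per-allele-per-marker probability that the database
#'   base is unknown (default 0).
#' @param n_individuals Cohort size (default 300).
#' @param allele_freqs Population frequency simplex over alleles; default a
#'   geometrically decaying spectrum (ratio 0.65) normalized to 1,
#'   emulating the skew of real HLA allele frequencies.
#' @param noise Posterior mass `e` diverted from the true genotype, split
#'   evenly between the two other genotypes (default 0.1).
#' @param corrupt_frac Fraction `f` of individuals whose recorded
#'   assignment is replaced by a random different pair (default 0.05).
#' @param corrupt_min_distance Minimum number of markers at which a
#'   corrupting pair's expected genotypes must differ from the truth's
#'   (default 3), so flagging sensitivity is well defined.
#' @param gene Gene symbol for the simulated locus (default `"HLA-SIM"`).
#' @param seed Integer seed; all generators are deterministic given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_alleles = 10L, n_markers = 20L, unknown_rate = 0,
                       n_individuals = 300L, allele_freqs = NULL,
                       noise = 0.1, corrupt_frac = 0.05,
                       corrupt_min_distance = 3L, gene = "HLA-SIM",
                       seed = 1L) {
  if (is.null(allele_freqs)) {
    allele_freqs <- 0.65^(seq_len(n_alleles) - 1L)
    allele_freqs <- allele_freqs / sum(allele_freqs)
  }
  stopifnot(n_alleles >= 2L, n_markers >= 1L,
            length(allele_freqs) == n_alleles,
            abs(sum(allele_freqs) - 1) <= 1e-9,
            unknown_rate >= 0, unknown_rate < 1,
            noise >= 0, noise < 1,
            corrupt_frac >= 0, corrupt_frac < 1)
  structure(list(n_alleles = as.integer(n_alleles),
                 n_markers = as.integer(n_markers),
                 unknown_rate = unknown_rate,
                 n_individuals = as.integer(n_individuals),
                 allele_freqs = allele_freqs, noise = noise,
                 corrupt_frac = corrupt_frac,
                 corrupt_min_distance = as.integer(corrupt_min_distance),
                 gene = gene, seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic allele table
#'
#' Assigns each marker two distinct nucleotides and a strand, gives every
#' allele one of the two chip alleles at each marker, and masks bases as
#' unknown at `unknown_rate`.  Rejection-samples until every pair of
#' alleles differs at one or more markers where both bases are known
#' (errors out after 1000 attempts).  The complete, unmasked base matrix is
#' attached as attribute `"complete_bases"` -- the simulation ground truth
#' used by [gen_population()] to generate genotypes at masked positions.
#'
#' @param cfg A [sim_config()].
#' @return An [hla_allele_table()] with two-field allele names
#'   (`SIM*01:01`, `SIM*02:01`, ...).
#' @export
gen_allele_table <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  nt <- c("A", "C", "G", "T")
  m <- cfg$n_markers
  ab <- t(vapply(seq_len(m), function(j) sample(nt, 2L), character(2L)))
  locus <- sub("^HLA-", "", cfg$gene)
  markers <- data.frame(
    marker_id = sprintf("rs%06d", seq_len(m) * 7L + 100000L),
    gene = cfg$gene,
    cdna_pos = seq_len(m) * 3L,   # spread along a cDNA
    strand = sample(c("+", "-"), m, replace = TRUE),
    alleleA = ab[, 1L], alleleB = ab[, 2L],
    stringsAsFactors = FALSE
  )
  allele_names <- sprintf("%s*%02d:01", locus, seq_len(cfg$n_alleles))
  for (try in seq_len(1000L)) {
    pick <- matrix(sample(c(0L, 1L), cfg$n_alleles * m, replace = TRUE),
                   cfg$n_alleles, m)
    complete <- matrix(ifelse(pick == 0L, rep(ab[, 1L], each = cfg$n_alleles),
                              rep(ab[, 2L], each = cfg$n_alleles)),
                       cfg$n_alleles, m,
                       dimnames = list(allele_names, markers$marker_id))
    mask <- matrix(stats::runif(cfg$n_alleles * m) < cfg$unknown_rate,
                   cfg$n_alleles, m)
    bases <- complete
    bases[mask] <- NA_character_
    if (all_distinguishable(bases)) {
      tab <- hla_allele_table(cfg$gene, markers, bases)
      attr(tab, "complete_bases") <- complete
      return(tab)
    }
  }
  stop("could not generate ", cfg$n_alleles,
       " pairwise-distinguishable alleles over ", m,
       " markers after 1000 attempts; increase n_markers or lower unknown_rate")
}

all_distinguishable <- function(bases) {
  n <- nrow(bases)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- !is.na(bases[i, ]) & !is.na(bases[j, ])
      if (!any(both & bases[i, ] != bases[j, ])) return(FALSE)
    }
  }
  TRUE
}

#' Generate a synthetic cohort with known ground truth
#'
#' True allele pairs are drawn by Hardy-Weinberg sampling from
#' `cfg$allele_freqs`.  At each marker the posterior puts mass `1 - e` on
#' the genotype implied by the individual's true pair (using the complete,
#' unmasked bases, since real individuals carry real nucleotides even where
#' the database is ignorant) and `e/2` on each of the two other genotypes.
#' A fraction `f` of individuals (Bernoulli per individual) have their
#' recorded assignment replaced by a pair drawn uniformly from all pairs
#' whose expected genotypes differ from the truth's at
#' `cfg$corrupt_min_distance` or more markers.
#'
#' @param table An [hla_allele_table()] from [gen_allele_table()].
#' @param cfg The same [sim_config()].
#' @return A list: `truth` (assignment data.frame, `source = "typed"`),
#'   `recorded` (assignments with corruption, `source = "imputed"`),
#'   `genotypes` (an [hla_genotypes()]), `corrupted_ids` (character).
#' @export
gen_population <- function(table, cfg) {
  stopifnot(inherits(table, "hla_allele_table"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  complete <- attr(table, "complete_bases")
  if (is.null(complete)) complete <- table$bases
  n <- cfg$n_individuals
  m <- nrow(table$markers)
  alleles <- rownames(table$bases)
  n_al <- length(alleles)

  a1 <- sample.int(n_al, n, replace = TRUE, prob = cfg$allele_freqs)
  a2 <- sample.int(n_al, n, replace = TRUE, prob = cfg$allele_freqs)
  ids <- sprintf("ind%04d", seq_len(n))

  # Expected genotype code (1 = HOM_A, 2 = HET, 3 = HOM_B) of every pair on
  # the complete bases; complete bases are always one of the two chip
  # alleles, so no IMPOSSIBLE/UNDEFINED arises here.
  code1 <- matrix(0L, n_al, m)
  for (j in seq_len(m)) {
    code1[, j] <- ifelse(complete[, j] == table$markers$alleleA[j], 0L, 1L)
  }
  geno <- code1[a1, , drop = FALSE] + code1[a2, , drop = FALSE] + 1L  # n x m in 1..3

  e <- cfg$noise
  p <- list(matrix(e / 2, n, m), matrix(e / 2, n, m), matrix(e / 2, n, m))
  for (g in 1:3) p[[g]][geno == g] <- 1 - e
  gt <- hla_genotypes(ids, table$markers, p[[1L]], p[[2L]], p[[3L]])

  truth <- data.frame(individual_id = ids, gene = table$gene,
                      allele1 = pmin(alleles[a1], alleles[a2]),
                      allele2 = pmax(alleles[a1], alleles[a2]),
                      source = "typed", stringsAsFactors = FALSE)

  recorded <- truth
  recorded$source <- "imputed"
  corrupt <- stats::runif(n) < cfg$corrupt_frac
  if (any(corrupt)) {
    pidx <- all_pair_idx(n_al)
    pair_geno <- code1[pidx[, 1L], , drop = FALSE] +
      code1[pidx[, 2L], , drop = FALSE]          # pairs x m in 0..2
    truth_key <- pair_key(alleles[a1], alleles[a2])
    all_keys <- pair_key(alleles[pidx[, 1L]], alleles[pidx[, 2L]])
    for (i in which(corrupt)) {
      my_geno <- code1[a1[i], ] + code1[a2[i], ]
      dist <- rowSums(pair_geno != matrix(my_geno, nrow(pidx), m, byrow = TRUE))
      eligible <- which(all_keys != truth_key[i] &
                          dist >= cfg$corrupt_min_distance)
      if (length(eligible) == 0L) {
        stop("no corrupting pair at distance >= ", cfg$corrupt_min_distance,
             " exists for individual ", ids[i])
      }
      kk <- eligible[sample.int(length(eligible), 1L)]
      recorded$allele1[i] <- min(alleles[pidx[kk, 1L]], alleles[pidx[kk, 2L]])
      recorded$allele2[i] <- max(alleles[pidx[kk, 1L]], alleles[pidx[kk, 2L]])
    }
  }
  list(truth = truth, recorded = recorded, genotypes = gt,
       corrupted_ids = ids[corrupt])
}

#' Write a complete simulated dataset in the pipeline's file dialects
#'
#' Produces the exact formats the readers consume: projected allele-table
#' TSV, marker-mapping TSV, IMPUTE2 GEN + SAMPLE, and assignment TSVs for
#' truth and recorded (corrupted) assignments.
#'
#' @param dir Output directory (created if absent).
#' @param cfg A [sim_config()].
#' @return Invisibly, a named list of the file paths plus the simulation
#'   objects (`table`, `pop`).
#' @export
write_simulation <- function(dir, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  table <- gen_allele_table(cfg)
  pop <- gen_population(table, cfg)
  paths <- list(
    alleles = file.path(dir, "alleles.tsv"),
    markers = file.path(dir, "markers.tsv"),
    gen = file.path(dir, "genotypes.gen"),
    sample = file.path(dir, "genotypes.sample"),
    truth = file.path(dir, "assignments_truth.tsv"),
    recorded = file.path(dir, "assignments_recorded.tsv")
  )
  write_allele_table(table, paths$alleles)
  write_marker_map(table$markers, paths$markers)
  write_gen(pop$genotypes, paths$gen, paths$sample)
  write_assignments(pop$truth, paths$truth)
  write_assignments(pop$recorded, paths$recorded)
  invisible(c(paths, list(table = table, pop = pop)))
}
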