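# Core scoring: per-marker discrepancy s, per-pair summed discrepancy D,
# exhaustive best-pair search, and the delta of an attributed pair.

# Expected-genotype codes used internally:
#   1 = HOM_A, 2 = HET, 3 = HOM_B, 4 = IMPOSSIBLE, NA = UNDEFINED.
GENO_LEVELS <- c("HOM_A", "HET", "HOM_B", "IMPOSSIBLE")

# Per-allele code at each marker: 0 = alleleA, 1 = alleleB, 2 = neither
# (a third nucleotide), NA = unknown base.
allele_codes <- function(table) {
  mk <- table$markers
  codes <- matrix(NA_integer_, nrow(table$bases), ncol(table$bases),
                  dimnames = dimnames(table$bases))
  for (j in seq_len(ncol(codes))) {
    b <- table$bases[, j]
    codes[, j] <- ifelse(is.na(b), NA_integer_,
                         ifelse(b == mk$alleleA[j], 0L,
                                ifelse(b == mk$alleleB[j], 1L, 2L)))
  }
  codes
}

# Expected-genotype code vector over markers for one allele pair,
# given the per-allele code rows.
pair_expected_codes <- function(c1, c2) {
  e <- ifelse(is.na(c1) | is.na(c2), NA_integer_,
              ifelse(c1 == 2L | c2 == 2L, 4L, c1 + c2 + 1L))
  e
}

#' Expected genotype of an allele pair at a marker
#'
#' Maps the two alleles' database bases at a marker to the genotype the pair
#' implies on the chip strand: `HOM_A`, `HET`, `HOM_B`; `UNDEFINED` when
#' either base is unknown; `IMPOSSIBLE` when a known base is neither of the
#' marker's two alleles (that pair cannot match the marker at all).
#'
#' @param pair Character vector of two allele names (homozygous allowed).
#' @param marker_id Marker identifier present in `table`.
#' @param table An [hla_allele_table()].
#' @return One of `"HOM_A"`, `"HET"`, `"HOM_B"`, `"IMPOSSIBLE"`,
#'   `"UNDEFINED"`.
#' @export
expected_genotype <- function(pair, marker_id, table) {
  stopifnot(inherits(table, "hla_allele_table"), length(pair) == 2L)
  pair <- normalize_allele_name(pair)
  missing_alleles <- setdiff(pair, rownames(table$bases))
  if (length(missing_alleles) > 0L) {
    stop("allele(s) not in table: ", paste(missing_alleles, collapse = ", "))
  }
  j <- match(marker_id, table$markers$marker_id)
  if (is.na(j)) stop("marker not in table: ", marker_id)
  codes <- allele_codes(table)
  e <- pair_expected_codes(codes[pair[1L], j], codes[pair[2L], j])
  if (is.na(e)) "UNDEFINED" else GENO_LEVELS[e]
}

#' Per-marker discrepancy of a genotype posterior with an expected genotype
#'
#' The discrepancy `s` is the posterior probability mass inconsistent with
#' the expected genotype: `s = 1 - p(expected)` for a defined genotype,
#' `s = 1` for `IMPOSSIBLE` (no mass can match a base outside the marker's
#' two alleles).  `UNDEFINED` markers must be excluded by the caller -- they
#' contribute nothing and do not count as used.  Posterior triplets summing
#' to less than 1 inflate `s` accordingly (never renormalized).
#'
#' @param posterior Numeric `c(p_AA, p_AB, p_BB)`.
#' @param expected One of `"HOM_A"`, `"HET"`, `"HOM_B"`, `"IMPOSSIBLE"`.
#' @return `s` in `[0, 1]`.
#' @export
marker_discrepancy <- function(posterior, expected) {
  stopifnot(length(posterior) == 3L, all(posterior >= 0), all(posterior <= 1 + 1e-6))
  expected <- match.arg(expected, GENO_LEVELS)
  s <- switch(expected,
              HOM_A = 1 - posterior[1L],
              HET = 1 - posterior[2L],
              HOM_B = 1 - posterior[3L],
              IMPOSSIBLE = 1)
  min(max(s, 0), 1)
}

# Score a set of pairs (rows of pair_idx: allele row indices i <= j) for all
# individuals at once.  Returns D (pairs x individuals) and n_used
# (pairs x individuals).  Markers missing for an individual, and markers
# UNDEFINED for a pair, are excluded from both D and n_used.
score_pairs <- function(gt, table, pair_idx) {
  codes <- allele_codes(table)
  n <- length(gt$samples)
  m <- nrow(gt$markers)
  if (!identical(gt$markers$marker_id, table$markers$marker_id)) {
    keep <- match(table$markers$marker_id, gt$markers$marker_id)
    if (anyNA(keep)) stop("genotype container lacks marker(s): ",
                          paste(table$markers$marker_id[is.na(keep)], collapse = ", "))
    P <- list(gt$p_AA[, keep, drop = FALSE], gt$p_AB[, keep, drop = FALSE],
              gt$p_BB[, keep, drop = FALSE])
    m <- length(keep)
  } else {
    P <- list(gt$p_AA, gt$p_AB, gt$p_BB)
  }
  present <- !is.na(P[[1L]])                     # n x m
  n_pairs <- nrow(pair_idx)
  D <- matrix(NA_real_, n_pairs, n)
  n_used <- matrix(0L, n_pairs, n)
  for (k in seq_len(n_pairs)) {
    e <- pair_expected_codes(codes[pair_idx[k, 1L], ], codes[pair_idx[k, 2L], ])
    defined <- !is.na(e)
    s <- matrix(0, n, m)
    for (g in 1:3) {
      cols <- which(defined & e == g)
      if (length(cols)) {
        sg <- 1 - P[[g]][, cols, drop = FALSE]
        sg[is.na(sg)] <- 0
        s[, cols] <- pmin(pmax(sg, 0), 1)
      }
    }
    imp <- which(defined & e == 4L)
    if (length(imp)) s[, imp] <- 1
    use <- present & matrix(defined, n, m, byrow = TRUE)
    D[k, ] <- rowSums(s * use)
    n_used[k, ] <- rowSums(use)
  }
  list(D = D, n_used = n_used)
}

all_pair_idx <- function(n_alleles) {
  idx <- which(upper.tri(matrix(0L, n_alleles, n_alleles), diag = TRUE),
               arr.ind = TRUE)
  cbind(idx[, "row"], idx[, "col"])
}

#' Summed discrepancy D of one allele pair for one individual
#'
#' Sums the per-marker discrepancy over all markers that are present for
#' the individual and defined (known bases) for the pair.
#'
#' @param gt An [hla_genotypes()].
#' @param individual_id One of `gt$samples`.
#' @param pair Character vector of two allele names.
#' @param table An [hla_allele_table()].
#' @return A list with `D` (`NA` with `status = "no_markers"` when no marker
#'   is usable -- never silently 0), `n_used`, and `status`.
#' @export
pair_discrepancy <- function(gt, individual_id, pair, table) {
  stopifnot(inherits(gt, "hla_genotypes"), inherits(table, "hla_allele_table"))
  i <- match(individual_id, gt$samples)
  if (is.na(i)) stop("unknown individual: ", individual_id)
  pair <- normalize_allele_name(pair)
  miss <- setdiff(pair, rownames(table$bases))
  if (length(miss)) stop("allele(s) not in table: ", paste(miss, collapse = ", "))
  ai <- match(pair, rownames(table$bases))
  sc <- score_pairs(subset_genotypes(gt, i), table,
                    matrix(sort(ai), 1L, 2L))
  n_used <- sc$n_used[1L, 1L]
  if (n_used == 0L) {
    list(D = NA_real_, n_used = 0L, status = "no_markers")
  } else {
    list(D = sc$D[1L, 1L], n_used = n_used, status = "ok")
  }
}

subset_genotypes <- function(gt, i) {
  hla_genotypes(gt$samples[i], gt$markers,
                gt$p_AA[i, , drop = FALSE],
                gt$p_AB[i, , drop = FALSE],
                gt$p_BB[i, , drop = FALSE])
}

#' Exhaustive best-pair search for one individual
#'
#' Enumerates all `n(n+1)/2` unordered allele pairs (homozygous included)
#' of the table, scores each, and returns the exact minimum `D` together
#' with every pair attaining it within the tie tolerance.  Alleles with
#' coverage below `min_coverage` are excluded from the search (poorly
#' characterized alleles are scored over fewer markers, which biases the
#' minimum toward them).
#'
#' @param gt An [hla_genotypes()].
#' @param individual_id One of `gt$samples`.
#' @param table An [hla_allele_table()].
#' @param min_coverage Minimum fraction of known bases for an allele to
#'   enter the search (default 0.5).
#' @param tie_tol Pairs within `tie_tol` of the minimum are reported as
#'   ties (default 1e-9).
#' @return A list: `D_min`, `pairs` (character vector of `"a/b"` keys of
#'   all argmin pairs), `n_used` for the first argmin pair.
#' @export
best_pairs <- function(gt, individual_id, table, min_coverage = 0.5,
                       tie_tol = 1e-9) {
  stopifnot(inherits(gt, "hla_genotypes"), inherits(table, "hla_allele_table"))
  i <- match(individual_id, gt$samples)
  if (is.na(i)) stop("unknown individual: ", individual_id)
  tab <- filter_coverage(table, min_coverage)
  sc <- score_pairs(subset_genotypes(gt, i), tab, all_pair_idx(nrow(tab$bases)))
  finish_best(sc$D[, 1L], sc$n_used[, 1L], rownames(tab$bases),
              all_pair_idx(nrow(tab$bases)), tie_tol)
}

filter_coverage <- function(table, min_coverage) {
  keep <- allele_coverage(table) >= min_coverage
  if (!any(keep)) stop("no allele passes the coverage filter (min_coverage = ",
                       min_coverage, ")")
  if (all(keep)) return(table)
  hla_allele_table(table$gene, table$markers,
                   table$bases[keep, , drop = FALSE], table$resolution)
}

finish_best <- function(D, n_used, alleles, pair_idx, tie_tol) {
  usable <- n_used > 0L
  if (!any(usable)) stop("no usable markers for any allele pair")
  D_min <- min(D[usable])
  hit <- which(usable & D <= D_min + tie_tol)
  keys <- pair_key(alleles[pair_idx[hit, 1L]], alleles[pair_idx[hit, 2L]])
  list(D_min = D_min, pairs = sort(keys), n_used = n_used[hit[1L]])
}

#' Check attributed HLA assignments against the genotype posteriors
#'
#' The main per-individual computation: scores each individual's attributed
#' allele pair, runs the exhaustive best-pair search over the allele table,
#' and reports the difference `delta = D_attributed - D_min`.  `delta = 0`
#' means the attributed pair is among the best-fitting pairs of the whole
#' database; a large `delta` means a better-fitting pair exists and the
#' attribution is implausible.  The attributed pair always participates in
#' the minimum (even when its alleles fail the coverage filter), so
#' `delta >= 0` holds and `delta == 0` exactly when the attributed pair is
#' in `best_pairs`.
#'
#' @param gt An [hla_genotypes()].
#' @param assignments Assignment data.frame (see [read_assignments()]) for
#'   `table$gene`; one row per individual.
#' @param table An [hla_allele_table()].
#' @param min_coverage,tie_tol See [best_pairs()].
#' @return A data.frame with one row per assignment: `individual_id`,
#'   `gene`, `attributed`, `D_attributed`, `D_min`, `delta`, `best_pairs`
#'   (semicolon-joined), `n_markers_used`, `status` (`"ok"`,
#'   `"no_markers"`, `"allele_not_in_db"`, `"no_genotype"`).
#' @export
check_assignments <- function(gt, assignments, table, min_coverage = 0.5,
                              tie_tol = 1e-9) {
  stopifnot(inherits(gt, "hla_genotypes"), inherits(table, "hla_allele_table"))
  assignments <- as_assignments(assignments)
  if (!all(assignments$gene == table$gene)) {
    stop("assignments contain genes other than ", table$gene)
  }
  tab <- filter_coverage(table, min_coverage)
  alleles <- rownames(tab$bases)
  pidx <- all_pair_idx(length(alleles))
  cand <- score_pairs(gt, tab, pidx)

  n_a <- nrow(assignments)
  out <- data.frame(
    individual_id = assignments$individual_id,
    gene = table$gene,
    attributed = pair_key(assignments$allele1, assignments$allele2),
    D_attributed = NA_real_, D_min = NA_real_, delta = NA_real_,
    best_pairs = NA_character_, n_markers_used = NA_integer_,
    status = "ok", stringsAsFactors = FALSE
  )
  full_alleles <- rownames(table$bases)
  for (r in seq_len(n_a)) {
    i <- match(assignments$individual_id[r], gt$samples)
    if (is.na(i)) { out$status[r] <- "no_genotype"; next }
    a12 <- c(assignments$allele1[r], assignments$allele2[r])
    if (!all(a12 %in% full_alleles)) { out$status[r] <- "allele_not_in_db"; next }

    usable <- cand$n_used[, i] > 0L
    if (any(usable)) {
      D_min_cand <- min(cand$D[usable, i])
    } else {
      D_min_cand <- Inf
    }
    att <- pair_discrepancy(gt, assignments$individual_id[r], a12, table)
    if (att$status == "no_markers") {
      out$status[r] <- "no_markers"
      next
    }
    D_min <- min(D_min_cand, att$D)
    hit <- which(usable & cand$D[, i] <= D_min + tie_tol)
    keys <- pair_key(alleles[pidx[hit, 1L]], alleles[pidx[hit, 2L]])
    if (att$D <= D_min + tie_tol) keys <- c(keys, out$attributed[r])
    out$D_attributed[r] <- att$D
    out$D_min[r] <- D_min
    out$delta[r] <- max(att$D - D_min, 0)
    out$best_pairs[r] <- paste(sort(unique(keys)), collapse = ";")
    out$n_markers_used[r] <- att$n_used
  }
  out
}

#' Write per-individual check results to TSV
#'
#' @param results Data.frame from [check_assignments()].
#' @param path Output path.
#' @export
write_check_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
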