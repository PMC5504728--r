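#' Construct a genotype-posterior container
#'
#' Holds, for a cohort, the posterior probabilities of the three genotypes
#' at every marker: `p_AA`, `p_AB`, `p_BB` are numeric matrices
#' (individuals x markers) on the chip strand, where `AA` means homozygous
#' for the marker's `alleleA`.  Missing markers for an individual are `NA`
#' in all three matrices.  Triplets may sum to less than 1 (imputation
#' output permits this); they are never renormalized.
#'
#' @param samples Character vector of individual ids.
#' @param markers Marker data.frame (see [read_marker_map()]).
#' @param p_AA,p_AB,p_BB Numeric matrices, individuals x markers.
#' @return An object of class `hla_genotypes`.
#' @export
hla_genotypes <- function(samples, markers, p_AA, p_AB, p_BB) {
  markers <- validate_markers(markers)
  n <- length(samples)
  m <- nrow(markers)
  for (p in list(p_AA, p_AB, p_BB)) {
    stopifnot(is.matrix(p), nrow(p) == n, ncol(p) == m)
  }
  tot <- p_AA + p_AB + p_BB
  bad <- !is.na(tot) & (tot > 1 + 1e-6 |
                          p_AA < -1e-9 | p_AB < -1e-9 | p_BB < -1e-9)
  if (any(bad)) stop("genotype posteriors outside [0,1] or summing above 1")
  miss_ok <- identical(is.na(p_AA), is.na(p_AB)) && identical(is.na(p_AA), is.na(p_BB))
  if (!miss_ok) stop("missingness must be consistent across the three posterior matrices")
  dn <- list(as.character(samples), markers$marker_id)
  dimnames(p_AA) <- dimnames(p_AB) <- dimnames(p_BB) <- dn
  structure(list(samples = as.character(samples), markers = markers,
                 p_AA = p_AA, p_AB = p_AB, p_BB = p_BB),
            class = "hla_genotypes")
}

#' @export
print.hla_genotypes <- function(x, ...) {
  cat(sprintf("hla_genotypes: %d individuals x %d markers (%.1f%% missing)\n",
              length(x$samples), nrow(x$markers), 100 * mean(is.na(x$p_AA))))
  invisible(x)
}

#' Read IMPUTE2 GEN + SAMPLE genotype posteriors
#'
#' The GEN file has five leading columns (chunk/marker id, rsid, position,
#' alleleA, alleleB) followed by three probabilities per individual:
#' p(AA), p(AB), p(BB).  The SAMPLE file has the standard two header rows.
#' GEN rows whose rsid is absent from `markers` are skipped (a message
#' reports the count).  Rows whose alleles disagree with the marker map are
#' a strand/allele mismatch and raise an error.
#'
#' @param gen_path,sample_path File paths.
#' @param markers Marker data.frame; the single source of truth for the
#'   marker set.
#' @return An [hla_genotypes()] whose marker set is `markers` (markers with
#'   no GEN row are all-`NA`).
#' @export
read_gen <- function(gen_path, sample_path, markers) {
  markers <- validate_markers(markers)
  smp <- utils::read.table(sample_path, header = TRUE, stringsAsFactors = FALSE)
  smp <- smp[-1L, , drop = FALSE]  # drop the type row ("0 0 0")
  samples <- as.character(smp[[1L]])
  n <- length(samples)

  lines <- readLines(gen_path)
  lines <- lines[nzchar(trimws(lines))]
  m <- nrow(markers)
  p_AA <- p_AB <- p_BB <- matrix(NA_real_, n, m,
                                 dimnames = list(samples, markers$marker_id))
  skipped <- 0L
  for (k in seq_along(lines)) {
    f <- strsplit(trimws(lines[k]), "\\s+")[[1L]]
    if (length(f) != 5L + 3L * n) {
      stop("GEN line ", k, ": expected ", 5L + 3L * n, " columns, found ", length(f))
    }
    rsid <- f[2L]
    j <- match(rsid, markers$marker_id)
    if (is.na(j)) { skipped <- skipped + 1L; next }
    if (!identical(f[4L], markers$alleleA[j]) || !identical(f[5L], markers$alleleB[j])) {
      stop("GEN line ", k, " (", rsid, "): alleles ", f[4L], "/", f[5L],
           " do not match marker map ", markers$alleleA[j], "/", markers$alleleB[j],
           " (strand or allele mismatch)")
    }
    p <- suppressWarnings(as.numeric(f[-(1:5)]))
    if (anyNA(p) || any(p < 0) || any(p > 1 + 1e-6)) {
      stop("GEN line ", k, " (", rsid, "): probability outside [0,1]")
    }
    idx <- 3L * (seq_len(n) - 1L)
    p_AA[, j] <- p[idx + 1L]
    p_AB[, j] <- p[idx + 2L]
    p_BB[, j] <- p[idx + 3L]
  }
  if (skipped > 0L) message(skipped, " GEN row(s) absent from the marker map; skipped")
  hla_genotypes(samples, markers, p_AA, p_AB, p_BB)
}

#' Write IMPUTE2 GEN + SAMPLE files
#'
#' @param gt An [hla_genotypes()].
#' @param gen_path,sample_path Output paths.
#' @param digits Decimal places for probabilities (default 6; round-trips
#'   through [read_gen()] to that precision).
#' @export
write_gen <- function(gt, gen_path, sample_path, digits = 6L) {
  stopifnot(inherits(gt, "hla_genotypes"))
  n <- length(gt$samples)
  mk <- gt$markers
  rows <- character(nrow(mk))
  for (j in seq_len(nrow(mk))) {
    trip <- as.vector(rbind(gt$p_AA[, j], gt$p_AB[, j], gt$p_BB[, j]))
    trip[is.na(trip)] <- 0
    rows[j] <- paste(mk$gene[j], mk$marker_id[j], mk$cdna_pos[j],
                     mk$alleleA[j], mk$alleleB[j],
                     paste(formatC(trip, format = "f", digits = digits),
                           collapse = " "))
  }
  writeLines(rows, gen_path)
  writeLines(c("ID_1 ID_2 missing", "0 0 0",
               paste(gt$samples, gt$samples, "0")), sample_path)
  invisible(gen_path)
}

#' Read an HLA assignment TSV
#'
#' Tab-separated columns `individual_id`, `gene`, `allele1`, `allele2`
#' (extra columns such as `source` or `resolution` are kept).  Allele names
#' are normalized and each pair is stored in sorted order, so equality is
#' insensitive to column order.  Duplicate (individual, gene) rows are an
#' error.
#'
#' @param path File path.
#' @return A data.frame of assignments.
#' @export
read_assignments <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("individual_id", "gene", "allele1", "allele2")
  if (!all(need %in% names(df))) {
    stop("assignment table must have columns: ", paste(need, collapse = ", "))
  }
  as_assignments(df)
}

#' Normalize an assignment data.frame
#'
#' @param df Data.frame with columns `individual_id`, `gene`, `allele1`,
#'   `allele2`.
#' @return The same data.frame with normalized, pair-sorted allele names.
#' @export
as_assignments <- function(df) {
  a1 <- normalize_allele_name(as.character(df$allele1))
  a2 <- normalize_allele_name(as.character(df$allele2))
  g1 <- parse_allele_name(a1)$gene
  g2 <- parse_allele_name(a2)$gene
  bad <- g1 != df$gene | g2 != df$gene
  if (any(bad)) {
    stop("allele gene does not match the gene column for individual(s): ",
         paste(df$individual_id[bad], collapse = ", "))
  }
  df$allele1 <- pmin(a1, a2)
  df$allele2 <- pmax(a1, a2)
  key <- paste(df$individual_id, df$gene)
  if (anyDuplicated(key)) {
    stop("duplicate (individual, gene) assignment for: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  df$individual_id <- as.character(df$individual_id)
  rownames(df) <- NULL
  df
}

#' @rdname read_assignments
#' @param df Assignment data.frame to write.
#' @export
write_assignments <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an HLA-marker dosage TSV
#'
#' Columns `individual_id`, `allele`, `dosage` (expected copy count in
#' `[0, 2]` from imputing each HLA allele as a present/absent binary
#' marker).
#'
#' @param path File path.
#' @return A data.frame of dosages.
#' @export
read_dosages <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("individual_id", "allele", "dosage")
  if (!all(need %in% names(df))) {
    stop("dosage table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(df$dosage < 0 | df$dosage > 2)) stop("dosages must lie in [0, 2]")
  df$allele <- normalize_allele_name(df$allele)
  df
}

#' Call HLA allele pairs from posterior dosages
#'
#' Each allele contributes one copy when its dosage exceeds `threshold` (up
#' to 1.5) and two copies when it exceeds 1.5.  An individual is "called"
#' only when exactly two copies result; anything else is a status, not an
#' error.
#'
#' @param dosages Data.frame from [read_dosages()] (one gene).
#' @param threshold Dosage cutoff, strict, in `(0, 1]`; default 0.5.
#' @return A data.frame with one row per individual: `individual_id`,
#'   `allele1`, `allele2` (`NA` when not called), `n_copies`, `called`.
#' @export
call_from_dosage <- function(dosages, threshold = 0.5) {
  stopifnot(threshold > 0, threshold <= 1)
  res <- lapply(split(dosages, dosages$individual_id), function(d) {
    copies <- ifelse(d$dosage > 1.5, 2L, ifelse(d$dosage > threshold, 1L, 0L))
    total <- sum(copies)
    alleles <- rep(d$allele, copies)
    called <- total == 2L
    data.frame(individual_id = d$individual_id[1L],
               allele1 = if (called) min(alleles) else NA_character_,
               allele2 = if (called) max(alleles) else NA_character_,
               n_copies = total, called = called,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
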