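#' Construct an HLA allele table
#'
#' The central container: for one HLA gene, the nucleotide carried by every
#' database allele at every exonic SNP marker, on the chip strand.  Unknown
#' bases (positions outside an allele's characterized sequence) are `NA`.
#'
#' @param gene HLA gene symbol (e.g. `"HLA-A"`).
#' @param markers A data.frame as returned by [read_marker_map()]: columns
#'   `marker_id`, `gene`, `cdna_pos`, `strand`, `alleleA`, `alleleB`.
#' @param bases Character matrix, alleles in rows (rownames = normalized
#'   allele names), markers in columns (colnames = `markers$marker_id`);
#'   entries in `A/C/G/T` or `NA` for unknown.
#' @param resolution Number of name fields represented (inferred from the
#'   allele names when `NULL`).
#' @return An object of class `hla_allele_table`.
#' @export
hla_allele_table <- function(gene, markers, bases, resolution = NULL) {
  markers <- validate_markers(markers)
  stopifnot(is.matrix(bases), is.character(bases))
  if (is.null(rownames(bases)) || anyNA(rownames(bases))) {
    stop("bases must have allele names as rownames")
  }
  if (anyDuplicated(rownames(bases))) {
    stop("duplicate allele names in table: ",
         paste(unique(rownames(bases)[duplicated(rownames(bases))]), collapse = ", "))
  }
  if (!identical(colnames(bases), markers$marker_id)) {
    stop("bases columns must match markers$marker_id exactly")
  }
  ok <- is.na(bases) | bases %in% c("A", "C", "G", "T")
  if (!all(ok)) stop("bases must be A/C/G/T or NA")
  parsed <- parse_allele_name(rownames(bases))
  if (!all(parsed$gene == gene)) {
    stop("all alleles must belong to gene ", gene)
  }
  if (is.null(resolution)) resolution <- max(parsed$n_fields)
  structure(
    list(gene = gene, markers = markers, bases = bases,
         resolution = as.integer(resolution)),
    class = "hla_allele_table"
  )
}

validate_markers <- function(markers) {
  need <- c("marker_id", "gene", "cdna_pos", "strand", "alleleA", "alleleB")
  if (!all(need %in% names(markers))) {
    stop("marker table must have columns: ", paste(need, collapse = ", "))
  }
  markers <- as.data.frame(markers)[need]
  markers$marker_id <- as.character(markers$marker_id)
  markers$cdna_pos <- as.integer(markers$cdna_pos)
  stopifnot(all(markers$cdna_pos >= 1L))
  if (!all(markers$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (!all(markers$alleleA %in% c("A", "C", "G", "T")) ||
      !all(markers$alleleB %in% c("A", "C", "G", "T"))) {
    stop("marker alleles must be A/C/G/T")
  }
  if (any(markers$alleleA == markers$alleleB)) {
    stop("alleleA and alleleB must differ for every marker")
  }
  if (anyDuplicated(markers$marker_id)) stop("duplicate marker ids")
  markers
}

#' @export
print.hla_allele_table <- function(x, ...) {
  cat(sprintf("hla_allele_table: %s, %d alleles x %d markers (resolution: %d fields)\n",
              x$gene, nrow(x$bases), ncol(x$bases), x$resolution))
  cov <- allele_coverage(x)
  cat(sprintf("  coverage: min %.2f, median %.2f, max %.2f\n",
              min(cov), stats::median(cov), max(cov)))
  invisible(x)
}

#' Fraction of markers with a known base, per allele
#'
#' @param table An [hla_allele_table()].
#' @return Named numeric vector in `[0, 1]`, one entry per allele.
#' @export
allele_coverage <- function(table) {
  stopifnot(inherits(table, "hla_allele_table"))
  rowMeans(!is.na(table$bases))
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Parse an IPD-IMGT/HLA-style cDNA nucleotide alignment
#'
#' Reads the compact alignment dialect used for HLA cDNA allele definitions:
#' the first allele row is the reference sequence; subsequent rows use `-`
#' for identity with the reference, `*` for unknown, `.` for an indel
#' placeholder, and plain bases for substitutions.  Exon boundary pipes
#' (`|`) and whitespace inside the sequence are ignored.  A sequence split
#' across several blocks (the allele name appearing on multiple lines) is
#' concatenated in order.
#'
#' Indel columns -- columns where the reference carries `.` -- are dropped
#' from the coordinate frame entirely, so inserted bases in other alleles
#' are discarded; a `.` in an allele where the reference has a base (a
#' deletion) becomes an unknown base at that position.  The resulting
#' gapless reference frame defines the 1-based cDNA coordinates used by
#' [project_to_markers()].
#'
#' @param text Character scalar (whole file) or vector of lines.
#' @param gene HLA gene symbol the alignment describes.
#' @return An object of class `hla_nuc_alignment`: a list with `gene`,
#'   `ref_name`, and `seqs`, a character matrix (alleles x cDNA positions,
#'   `NA` = unknown).
#' @export
parse_nuc_alignment <- function(text, gene) {
  if (length(text) == 1L && grepl("\n", text)) text <- strsplit(text, "\n")[[1]]
  lines <- trimws(text)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  # Drop IMGT block headers such as 'cDNA' / coordinate ruler lines.
  lines <- lines[grepl("\\*", sub("\\s.*$", "", lines))]
  if (length(lines) == 0L) stop("no allele rows found in alignment")

  name_raw <- sub("\\s.*$", "", lines)
  seq_part <- sub("^\\S+\\s*", "", lines)
  seq_part <- gsub("[ |]", "", seq_part)
  names_norm <- normalize_allele_name(name_raw)

  # Concatenate multi-block rows in file order, keyed by allele name.
  order_first <- !duplicated(names_norm)
  alleles <- names_norm[order_first]
  seqs <- vapply(alleles, function(a) paste(seq_part[names_norm == a], collapse = ""), "")

  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    off <- alleles[lens != lens[1L]]
    stop("alignment rows have mismatched lengths for: ", paste(off, collapse = ", "))
  }

  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(mat) <- alleles
  ref <- mat[1L, ]
  if (any(ref %in% c("-", "*"))) {
    stop("reference row (", alleles[1L], ") may not contain '-' or '*'")
  }
  bad <- !mat %in% c("A", "C", "G", "T", "-", "*", ".")
  if (any(bad)) {
    stop("invalid alignment characters in: ",
         paste(unique(rownames(mat)[row(mat)[bad]]), collapse = ", "))
  }

  # Expand against the reference.
  expanded <- mat
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    col[col == "-"] <- ref[j]
    col[col == "*"] <- NA_character_
    expanded[, j] <- col
  }
  # Drop insertion columns; deletions ('.') at reference positions -> unknown.
  keep <- ref != "."
  expanded <- expanded[, keep, drop = FALSE]
  expanded[expanded == "."] <- NA_character_
  colnames(expanded) <- as.character(seq_len(ncol(expanded)))

  structure(list(gene = gene, ref_name = alleles[1L], seqs = expanded),
            class = "hla_nuc_alignment")
}

#' Project aligned allele sequences onto a SNP marker set
#'
#' Looks up each allele's base at every marker's cDNA position and expresses
#' it on the chip strand: for markers on the `-` strand the cDNA base is
#' complemented.  Unknown bases propagate.  A projected base that is neither
#' of the marker's two chip alleles is kept as-is (it is meaningful: any
#' pair containing that allele cannot match the marker) and counted in a
#' message.
#'
#' @param aln An `hla_nuc_alignment` from [parse_nuc_alignment()].
#' @param markers Marker data.frame (see [read_marker_map()]); must all
#'   belong to `aln$gene`.
#' @return An [hla_allele_table()].
#' @export
project_to_markers <- function(aln, markers) {
  stopifnot(inherits(aln, "hla_nuc_alignment"))
  markers <- validate_markers(markers)
  L <- ncol(aln$seqs)
  out_of_range <- markers$cdna_pos > L
  if (any(out_of_range)) {
    stop("marker cdna_pos out of range for markers: ",
         paste(markers$marker_id[out_of_range], collapse = ", "),
         " (cDNA length ", L, ")")
  }
  bases <- aln$seqs[, markers$cdna_pos, drop = FALSE]
  neg <- markers$strand == "-"
  if (any(neg)) {
    bases[, neg] <- apply(bases[, neg, drop = FALSE], 2L, function(b) unname(COMPLEMENT[b]))
  }
  colnames(bases) <- markers$marker_id
  n_off <- 0L
  for (j in seq_len(ncol(bases))) {
    n_off <- n_off + sum(!is.na(bases[, j]) &
                           !bases[, j] %in% c(markers$alleleA[j], markers$alleleB[j]))
  }
  if (n_off > 0L) {
    message(n_off, " projected base(s) match neither chip allele of their marker",
            " (those alleles cannot fit there)")
  }
  hla_allele_table(aln$gene, markers, bases)
}

#' Collapse an allele table to one- or two-field resolution
#'
#' Alleles are grouped by their name truncated to `n_fields`; each group is
#' represented by the member with the lexicographically smallest full name
#' (conventionally the first-numbered allele of the group, which defines the
#' group's protein).  Deterministic; idempotent at a given resolution.
#'
#' @param table An [hla_allele_table()].
#' @param n_fields Target resolution, 1 or 2.
#' @return A new [hla_allele_table()] whose allele names carry `n_fields`
#'   fields.
#' @export
collapse_resolution <- function(table, n_fields) {
  stopifnot(inherits(table, "hla_allele_table"), n_fields %in% c(1L, 2L))
  if (n_fields > table$resolution) {
    stop("cannot collapse to ", n_fields, " fields: table resolution is ",
         table$resolution)
  }
  full <- rownames(table$bases)
  short <- truncate_allele_name(full, n_fields)
  groups <- split(full, short)
  reps <- vapply(groups, function(g) sort(g, method = "radix")[1L], "")
  bases <- table$bases[reps, , drop = FALSE]
  rownames(bases) <- names(groups)
  bases <- bases[order(rownames(bases)), , drop = FALSE]
  hla_allele_table(table$gene, table$markers, bases, resolution = n_fields)
}

#' Read a marker-mapping TSV
#'
#' Tab-separated columns `marker_id`, `gene`, `cdna_pos`, `strand`,
#' `alleleA`, `alleleB`; `#` comment lines allowed.
#'
#' @param path File path.
#' @param gene Optional gene symbol to filter to.
#' @return Marker data.frame suitable for [hla_allele_table()].
#' @export
read_marker_map <- function(path, gene = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, colClasses = "character")
  df <- validate_markers(df)
  if (!is.null(gene)) df <- df[df$gene == gene, , drop = FALSE]
  if (nrow(df) == 0L) stop("no markers", if (!is.null(gene)) paste0(" for gene ", gene))
  rownames(df) <- NULL
  df
}

#' Read/write the projected allele table TSV
#'
#' Columns: `allele`, then one column per marker id; values `A/C/G/T` or `?`
#' for unknown.  `write_allele_table()` then `read_allele_table()` (with the
#' same marker map) reproduces the table exactly.
#'
#' @param path File path.
#' @param markers Marker data.frame giving the table's marker set and gene.
#' @return For the reader, an [hla_allele_table()].
#' @export
read_allele_table <- function(path, markers) {
  markers <- validate_markers(markers)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (names(df)[1L] != "allele") stop("first column must be 'allele'")
  if (!identical(names(df)[-1L], markers$marker_id)) {
    stop("allele table columns do not match the marker map")
  }
  bases <- as.matrix(df[, -1L, drop = FALSE])
  bases[bases == "?"] <- NA_character_
  rownames(bases) <- normalize_allele_name(df$allele)
  hla_allele_table(markers$gene[1L], markers, bases)
}

#' @rdname read_allele_table
#' @param table An [hla_allele_table()] to write.
#' @export
write_allele_table <- function(table, path) {
  stopifnot(inherits(table, "hla_allele_table"))
  bases <- table$bases
  bases[is.na(bases)] <- "?"
  df <- data.frame(allele = rownames(bases), bases, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_marker_map
#' @param markers Marker data.frame to write.
#' @export
write_marker_map <- function(markers, path) {
  markers <- validate_markers(markers)
  utils::write.table(markers, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
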