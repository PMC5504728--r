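#' Parse an HLA allele name
#'
#' Accepts both the short starred form (`"A*01:01"`) and the prefixed form
#' (`"HLA-A*01:01"`) and normalizes to the short form internally.  Names may
#' carry one to four colon-separated numeric fields (one-field serological
#' group up to four-field full resolution).
#'
#' @param x Character vector of allele names.
#' @return A data.frame with one row per name and columns `gene` (full
#'   symbol, e.g. `"HLA-A"`), `short` (normalized short form), `n_fields`,
#'   and `raw` (the input string).  The `fields` are recoverable by
#'   splitting `short` after the `*` on `":"`.
#' @examples
#' parse_allele_name(c("A*01:01", "HLA-B*57"))
#' @export
parse_allele_name <- function(x) {
  stopifnot(is.character(x), length(x) >= 1L)
  m <- regmatches(x, regexec("^(?:HLA-)?([A-Za-z][A-Za-z0-9]*)\\*([0-9]{1,4}(?::[0-9]{1,4}){0,3}[A-Z]?)$", x))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) {
    stop("unparseable HLA allele name(s): ", paste(x[bad], collapse = ", "))
  }
  locus <- vapply(m, `[[`, "", 2L)
  fields <- vapply(m, `[[`, "", 3L)
  data.frame(
    gene = paste0("HLA-", locus),
    short = paste0(locus, "*", fields),
    n_fields = lengths(strsplit(fields, ":", fixed = TRUE)),
    raw = x,
    stringsAsFactors = FALSE
  )
}

#' Normalize allele names to the short starred form
#'
#' @param x Character vector of allele names in either accepted form.
#' @return Character vector of normalized short names (`"A*01:01"` style).
#' @export
normalize_allele_name <- function(x) {
  parse_allele_name(x)$short
}

#' Truncate allele names to a lower field resolution
#'
#' `"A*01:01:02"` truncated to 2 fields is `"A*01:01"`.  Names already at or
#' below the requested resolution are returned unchanged (after
#' normalization).
#'
#' @param x Character vector of allele names.
#' @param n_fields Target number of name fields (1--4).
#' @return Character vector of truncated short-form names.
#' @export
truncate_allele_name <- function(x, n_fields) {
  stopifnot(n_fields >= 1L, n_fields <= 4L)
  p <- parse_allele_name(x)
  fields <- strsplit(sub("^[^*]*\\*", "", p$short), ":", fixed = TRUE)
  kept <- vapply(fields, function(f) paste(f[seq_len(min(length(f), n_fields))], collapse = ":"), "")
  paste0(sub("^HLA-", "", p$gene), "*", kept)
}

# Canonical string for an unordered allele pair: sorted, slash-joined.
pair_key <- function(a1, a2) {
  paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
}
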