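# Shuffled-assignment null calibration of the flagging cutoff, and
# per-allele imputation accuracy evaluation with/without filtering.

#' Shuffle HLA assignments between individuals
#'
#' Draws a uniform random permutation of the allele pairs across
#' individuals; pairs stay intact, so the multiset of pairs is conserved
#' and only their attribution to individuals changes.  This is the null
#' model for calibration: a shuffled pair is an arbitrary (usually wrong)
#' assignment drawn from the cohort's own pair distribution.
#'
#' @param assignments Assignment data.frame for one gene.
#' @param seed Optional integer seed (deterministic permutation when set).
#' @return The assignment data.frame with permuted `allele1`/`allele2`.
#' @export
shuffle_assignments <- function(assignments, seed = NULL) {
  stopifnot(nrow(assignments) >= 2L)
  if (!is.null(seed)) set.seed(seed)
  perm <- sample.int(nrow(assignments))
  out <- assignments
  out$allele1 <- assignments$allele1[perm]
  out$allele2 <- assignments$allele2[perm]
  out
}

#' Calibrate the flagging cutoff from a shuffled-assignment null
#'
#' Pools the `delta` values obtained when the cohort's allele pairs are
#' randomly reattributed to individuals (`n_shuffles` independent
#' permutations), fits the pooled null with its sample mean `mu` and
#' standard deviation `sigma`, and derives the cutoff:
#'
#' * `tail = "lower"` (default): `cutoff = max(0, mu - k*sigma)` -- the
#'   lower edge of the wrong-assignment null.  An individual whose `delta`
#'   exceeds it fits no better than a randomly attributed pair and is
#'   flagged.  This is the operating point that separates correct
#'   assignments (`delta` near 0) from the null bulk.
#' * `tail = "upper"`: `cutoff = mu + k*sigma` -- flags only values extreme
#'   even for the null (about 2.3% of genuinely normal null draws at
#'   `k = 2`).
#'
#' @param gt An [hla_genotypes()].
#' @param assignments Assignment data.frame for `table$gene`.
#' @param table An [hla_allele_table()].
#' @param n_shuffles Number of full-cohort permutations pooled (default 10).
#' @param seed Integer seed for the permutations.
#' @param rounding `"none"` (default) or `"integer"` (round the cutoff to
#'   the nearest integer, as is conventional when publishing per-gene
#'   cutoffs).
#' @param tail `"lower"` or `"upper"` (see above).
#' @param k Number of standard deviations (default 2).
#' @param min_coverage Passed to [check_assignments()].
#' @return An object of class `hla_calibration`: `gene`, `null_deltas`,
#'   `mu`, `sigma`, `cutoff`, `n_shuffles`, `seed`, `tail`, `k`,
#'   `rounding`.
#' @export
calibrate_cutoff <- function(gt, assignments, table, n_shuffles = 10L,
                             seed = NULL, rounding = c("none", "integer"),
                             tail = c("lower", "upper"), k = 2,
                             min_coverage = 0.5) {
  rounding <- match.arg(rounding)
  tail <- match.arg(tail)
  stopifnot(n_shuffles >= 1L)
  assignments <- as_assignments(assignments)
  if (nrow(assignments) < 2L) stop("calibration needs at least 2 individuals")
  n_distinct <- length(unique(pair_key(assignments$allele1, assignments$allele2)))
  if (n_distinct < 2L) {
    stop("calibration impossible: fewer than 2 distinct allele pairs in the cohort")
  }
  if (!is.null(seed)) set.seed(seed)
  null_deltas <- numeric(0)
  for (b in seq_len(n_shuffles)) {
    sh <- shuffle_assignments(assignments)
    res <- check_assignments(gt, sh, table, min_coverage = min_coverage)
    null_deltas <- c(null_deltas, res$delta[res$status == "ok"])
  }
  if (length(null_deltas) == 0L) stop("no usable null delta values")
  cal <- make_calibration(table$gene, null_deltas, n_shuffles, seed,
                          rounding, tail, k)
  cal
}

make_calibration <- function(gene, null_deltas, n_shuffles, seed,
                             rounding, tail, k) {
  mu <- mean(null_deltas)
  sigma <- stats::sd(null_deltas)
  if (is.na(sigma)) sigma <- 0
  cutoff <- if (tail == "upper") mu + k * sigma else max(0, mu - k * sigma)
  if (rounding == "integer") cutoff <- round(cutoff)
  structure(list(gene = gene, null_deltas = null_deltas, mu = mu,
                 sigma = sigma, cutoff = cutoff,
                 n_shuffles = as.integer(n_shuffles), seed = seed,
                 tail = tail, k = k, rounding = rounding),
            class = "hla_calibration")
}

#' @export
print.hla_calibration <- function(x, ...) {
  cat(sprintf(
    "hla_calibration: %s  mu = %.3f, sigma = %.3f, cutoff = %.3f (%s tail, k = %g, %d shuffles, %d null values)\n",
    x$gene, x$mu, x$sigma, x$cutoff, x$tail, x$k, x$n_shuffles,
    length(x$null_deltas)))
  invisible(x)
}

#' Partition check results into kept and flagged individuals
#'
#' An individual is flagged when `delta` is strictly greater than the
#' cutoff (a `delta` exactly at the cutoff is kept).  Rows whose `delta`
#' could not be computed (`status != "ok"`) are kept, with their status
#' preserved for inspection.  The partition is exhaustive and disjoint.
#'
#' @param results Data.frame from [check_assignments()].
#' @param cutoff Finite numeric cutoff (a number or an `hla_calibration`).
#' @return A list of two data.frames, `kept` and `flagged`.
#' @export
flag_individuals <- function(results, cutoff) {
  if (inherits(cutoff, "hla_calibration")) cutoff <- cutoff$cutoff
  stopifnot(is.finite(cutoff))
  flag <- !is.na(results$delta) & results$status == "ok" & results$delta > cutoff
  list(kept = results[!flag, , drop = FALSE],
       flagged = results[flag, , drop = FALSE])
}

#' Per-allele imputation accuracy against gold-standard typings
#'
#' Accuracy is the fraction of correctly assigned alleles over all called
#' alleles.  For each called individual the two called alleles are compared
#' with the two true alleles as multisets after truncating names to the
#' requested resolution, so each individual contributes 0, 1 or 2 correct
#' alleles and a homozygous call cannot double-count a single true copy.
#' Individuals lacking a truth record are excluded with a warning.
#'
#' @param called Assignment data.frame of called (e.g. imputed)
#'   assignments.
#' @param truth Assignment data.frame of gold-standard typings.
#' @param resolution 1 or 2 name fields for the comparison.
#' @return A one-row data.frame: `gene`, `resolution`, `n_individuals`,
#'   `n_called_alleles`, `n_correct`, `accuracy`.
#' @export
hla_accuracy <- function(called, truth, resolution = 2L) {
  stopifnot(resolution %in% c(1L, 2L))
  called <- as_assignments(called)
  truth <- as_assignments(truth)
  idx <- match(called$individual_id, truth$individual_id)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " called individual(s) lack a truth record; excluded")
    called <- called[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  n_correct <- 0L
  for (r in seq_len(nrow(called))) {
    imp <- truncate_allele_name(c(called$allele1[r], called$allele2[r]), resolution)
    tru <- truncate_allele_name(c(truth$allele1[idx[r]], truth$allele2[idx[r]]), resolution)
    n_correct <- n_correct + multiset_overlap(imp, tru)
  }
  n_alleles <- 2L * nrow(called)
  data.frame(gene = if (nrow(called)) called$gene[1L] else NA_character_,
             resolution = resolution,
             n_individuals = nrow(called),
             n_called_alleles = n_alleles,
             n_correct = n_correct,
             accuracy = if (n_alleles > 0L) n_correct / n_alleles else NA_real_,
             stringsAsFactors = FALSE)
}

multiset_overlap <- function(a, b) {
  n <- 0L
  b_left <- b
  for (x in a) {
    hit <- match(x, b_left)
    if (!is.na(hit)) { n <- n + 1L; b_left <- b_left[-hit] }
  }
  n
}

#' Evaluate filtering: accuracy before and after removing flagged individuals
#'
#' Mirrors the standard reporting layout "base imputation | people removed |
#' sub-population imputation": per-allele accuracy on all called
#' individuals, the number removed by the cutoff, the fraction of removed
#' individuals whose call was actually fully correct, and the accuracy on
#' the kept subset.
#'
#' @param results Data.frame from [check_assignments()] on the called
#'   assignments.
#' @param called,truth Assignment data.frames (see [hla_accuracy()]).
#' @param cutoff Numeric cutoff or `hla_calibration`.
#' @param resolution 1 or 2 fields.
#' @return A one-row data.frame: `gene`, `resolution`, `n_called`,
#'   `base_accuracy`, `n_removed`, `removed_correct_frac`,
#'   `filtered_accuracy`.
#' @export
evaluate_filtering <- function(results, called, truth, cutoff, resolution = 2L) {
  called <- as_assignments(called)
  truth <- as_assignments(truth)
  part <- flag_individuals(results, cutoff)
  base <- hla_accuracy(called, truth, resolution)
  kept_ids <- part$kept$individual_id
  flag_ids <- part$flagged$individual_id
  kept_called <- called[called$individual_id %in% kept_ids, , drop = FALSE]
  filt <- if (nrow(kept_called)) hla_accuracy(kept_called, truth, resolution) else
    data.frame(accuracy = NA_real_)
  removed_called <- called[called$individual_id %in% flag_ids, , drop = FALSE]
  removed_correct <- if (nrow(removed_called)) {
    # fraction of removed individuals with both alleles correct
    both <- vapply(seq_len(nrow(removed_called)), function(r) {
      i <- match(removed_called$individual_id[r], truth$individual_id)
      imp <- truncate_allele_name(c(removed_called$allele1[r], removed_called$allele2[r]), resolution)
      tru <- truncate_allele_name(c(truth$allele1[i], truth$allele2[i]), resolution)
      multiset_overlap(imp, tru) == 2L
    }, logical(1L))
    mean(both)
  } else NA_real_
  data.frame(gene = base$gene, resolution = resolution,
             n_called = nrow(called),
             base_accuracy = base$accuracy,
             n_removed = nrow(removed_called),
             removed_correct_frac = removed_correct,
             filtered_accuracy = filt$accuracy,
             stringsAsFactors = FALSE)
}

#' Pre-filter gold-standard typed individuals
#'
#' Applies the check to experimentally typed (not imputed) assignments and
#' removes individuals whose typed pair is too discrepant with their SNP
#' posteriors -- likely typing errors that would poison downstream
#' evaluation.  Reports counts in the conventional "removed/total" shape.
#'
#' @param gt An [hla_genotypes()].
#' @param typed Assignment data.frame of typed individuals.
#' @param table An [hla_allele_table()].
#' @param cutoff Numeric cutoff or `hla_calibration`.
#' @param min_coverage Passed to [check_assignments()].
#' @return A list: `kept`, `flagged` (check-result data.frames),
#'   `n_removed`, `n_total`, `summary` (e.g. `"18/865"`).
#' @export
prefilter_typed <- function(gt, typed, table, cutoff, min_coverage = 0.5) {
  res <- check_assignments(gt, typed, table, min_coverage = min_coverage)
  part <- flag_individuals(res, cutoff)
  n_rm <- nrow(part$flagged)
  n_tot <- nrow(res)
  c(part, list(n_removed = n_rm, n_total = n_tot,
               summary = sprintf("%d/%d", n_rm, n_tot)))
}

#' Write calibration and accuracy TSVs
#'
#' @param cal An `hla_calibration`.
#' @param path Output path.
#' @export
write_calibration <- function(cal, path) {
  df <- data.frame(gene = cal$gene, n_shuffles = cal$n_shuffles,
                   n_null = length(cal$null_deltas),
                   mu = cal$mu, sigma = cal$sigma, cutoff = cal$cutoff,
                   tail = cal$tail, k = cal$k,
                   seed = if (is.null(cal$seed)) NA_integer_ else cal$seed,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calibration
#' @param report Accuracy or evaluation data.frame.
#' @export
write_accuracy <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
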