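#' Marker retention mask from minor-allele filters
#'
#' A site is excluded iff its minor allele frequency is `<= maf_threshold`
#' or its minor allele count is `<= mac_threshold` ("at the threshold" is
#' excluded). By default frequencies are computed over the admixed query
#' haplotypes; pass a [haplotype_panel()] to filter on reference-panel
#' frequencies instead. For multi-allelic sites the minor count aggregates
#' every non-major allele.
#'
#' @param x A [query_set()] or [haplotype_panel()].
#' @param maf_threshold Minor allele frequency cutoff (default 0.005).
#' @param mac_threshold Minor allele count cutoff (default 50).
#' @return Logical vector over sites; `TRUE` marks retained sites.
#' @export
marker_filter_mask <- function(x, maf_threshold = 0.005, mac_threshold = 50) {
  haps <- if (inherits(x, "query_set")) x$haplotypes else x$alleles
  if (is.null(haps) || nrow(haps) == 0) abort("no haplotypes to filter on")
  K <- max(2L, max(haps, na.rm = TRUE) + 1L)
  counts <- vapply(seq_len(K) - 1L,
                   function(a) colSums(haps == a, na.rm = TRUE),
                   numeric(ncol(haps)))
  counts <- matrix(counts, ncol = K)
  tot <- rowSums(counts)
  mac <- tot - apply(counts, 1, max)
  maf <- mac / ifelse(tot == 0, 1, tot)
  !(maf <= maf_threshold | mac <= mac_threshold)
}

#' Ancestry-call accuracy rate
#'
#' Fraction of correctly inferred (haplotype, marker) ancestry labels over
#' the retained markers.
#'
#' @param truth,inferred Integer matrices (query haplotype x site) of
#'   population indices.
#' @param mask Logical site mask of retained markers (default all).
#' @return A fraction in `[0, 1]`.
#' @export
accuracy_rate <- function(truth, inferred, mask = NULL) {
  truth <- as.matrix(truth)
  inferred <- as.matrix(inferred)
  if (!all(dim(truth) == dim(inferred))) abort("truth/inferred shapes differ")
  if (is.null(mask)) mask <- rep(TRUE, ncol(truth))
  if (!any(mask)) abort("no markers retained by the filter mask")
  mean(truth[, mask, drop = FALSE] == inferred[, mask, drop = FALSE])
}

#' Ancestry-dosage r-squared (LAMP-LD style)
#'
#' For each population, true and inferred per-individual ancestry dosages
#' (0/1/2 haplotype labels per diploid individual and marker) are
#' correlated; the squared Pearson correlation is averaged over
#' populations. The default pools individuals x retained markers into one
#' correlation per population; `method = "per_marker"` instead averages
#' per-marker correlations. A population whose true or inferred dosage
#' vector has zero variance contributes 1 if the vectors are identical and
#' 0 otherwise (degenerate-case convention, logged).
#'
#' @param truth,inferred Integer matrices (query haplotype x site).
#' @param sample_id Character vector pairing haplotype rows into diploid
#'   individuals (exactly two rows per id).
#' @param mask Logical site mask of retained markers (default all).
#' @param p Number of populations.
#' @param method `"pooled"` (default) or `"per_marker"`.
#' @return A list with `r2` (mean over populations),
#'   `per_population_r2`, `n_markers_evaluated`, `n_markers_filtered`.
#' @export
r2_lampld <- function(truth, inferred, sample_id, mask = NULL, p,
                      method = c("pooled", "per_marker")) {
  method <- match.arg(method)
  truth <- as.matrix(truth)
  inferred <- as.matrix(inferred)
  if (!all(dim(truth) == dim(inferred))) abort("truth/inferred shapes differ")
  if (length(sample_id) != nrow(truth)) {
    abort("sample_id must have one entry per haplotype row")
  }
  counts <- table(sample_id)
  if (any(counts != 2)) {
    abort("haplotypes must pair into diploid individuals (two rows per sample)")
  }
  if (is.null(mask)) mask <- rep(TRUE, ncol(truth))
  if (!any(mask)) abort("no markers retained by the filter mask")
  ids <- unique(sample_id)
  row1 <- match(ids, sample_id)
  row2 <- nrow(truth) + 1L - match(ids, rev(sample_id))
  keep <- which(mask)
  degenerate <- FALSE
  r2_pop <- vapply(seq_len(p), function(l) {
    dt <- (truth[row1, keep, drop = FALSE] == l) +
          (truth[row2, keep, drop = FALSE] == l)
    di <- (inferred[row1, keep, drop = FALSE] == l) +
          (inferred[row2, keep, drop = FALSE] == l)
    if (method == "pooled") {
      r2_safe(as.vector(dt), as.vector(di))
    } else {
      mean(vapply(seq_along(keep),
                  function(jj) r2_safe(dt[, jj], di[, jj]),
                  numeric(1)))
    }
  }, numeric(1))
  list(
    r2 = mean(r2_pop),
    per_population_r2 = r2_pop,
    n_markers_evaluated = length(keep),
    n_markers_filtered = sum(!mask)
  )
}

# Squared Pearson correlation with the degenerate-variance convention.
r2_safe <- function(x, y) {
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(if (all(x == y)) 1 else 0)
  }
  cor(x, y)^2
}

#' Score paintings against ground truth
#'
#' Applies the minor-allele marker filter, then computes the accuracy rate
#' and the population-averaged ancestry-dosage r-squared.
#'
#' @param paintings List of `ancestry_painting` (one per query haplotype,
#'   in query order), or an inferred label matrix.
#' @param truth Integer matrix (query haplotype x site) of true labels.
#' @param queries The [query_set()] the paintings were inferred for (used
#'   for the marker filter and diploid pairing).
#' @param maf_threshold,mac_threshold Filter cutoffs; see
#'   [marker_filter_mask()].
#' @param r2_method Passed to [r2_lampld()].
#' @return An object of class `lai_evaluation` with fields `accuracy`,
#'   `r2`, `per_population_r2`, `n_markers_evaluated`,
#'   `n_markers_filtered`.
#' @export
evaluate_painting <- function(paintings, truth, queries,
                              maf_threshold = 0.005, mac_threshold = 50,
                              r2_method = "pooled") {
  inferred <- if (is.matrix(paintings)) paintings
              else painting_labels_matrix(paintings)
  mask <- marker_filter_mask(queries, maf_threshold, mac_threshold)
  p <- max(truth)
  acc <- accuracy_rate(truth, inferred, mask)
  r2 <- r2_lampld(truth, inferred, queries$sample_id, mask, p,
                  method = r2_method)
  structure(
    list(accuracy = acc, r2 = r2$r2,
         per_population_r2 = r2$per_population_r2,
         n_markers_evaluated = r2$n_markers_evaluated,
         n_markers_filtered = r2$n_markers_filtered),
    class = "lai_evaluation"
  )
}

painting_labels_matrix <- function(paintings) {
  do.call(rbind, lapply(paintings, function(pt) pt$labels))
}

#' @export
print.lai_evaluation <- function(x, ...) {
  cat(sprintf(
    "<lai_evaluation> accuracy %.4f, mean r2 %.4f over %d markers (%d filtered)\n",
    x$accuracy, x$r2, x$n_markers_evaluated, x$n_markers_filtered))
  invisible(x)
}

#' @export
glance.lai_evaluation <- function(x, ...) {
  tibble::tibble(
    accuracy = x$accuracy,
    r2 = x$r2,
    n_markers_evaluated = x$n_markers_evaluated,
    n_markers_filtered = x$n_markers_filtered
  )
}

#' @export
tidy.lai_evaluation <- function(x, ...) {
  tibble::tibble(
    population = seq_along(x$per_population_r2),
    r2 = x$per_population_r2
  )
}
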