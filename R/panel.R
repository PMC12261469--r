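#' Construct a labeled haplotype panel
#'
#' A haplotype panel is the reference input to local ancestry inference: an
#' integer matrix of allele codes (one row per haplotype, one column per
#' site), per-haplotype population labels, and per-site metadata. Allele
#' codes run from 0 to K-1 (bi-allelic panels use 0/1); missing alleles are
#' `NA`.
#'
#' @param alleles Integer matrix, haplotypes x sites; values in `[0, K-1]`
#'   or `NA` for missing.
#' @param sites A data frame with columns `chrom`, `pos` (1-based bp),
#'   `id`, `ref`, `alt` (alt may be a comma-separated string for
#'   multi-allelic records). One row per site, ordered along the chromosome.
#' @param hap_population Integer vector, one population index per haplotype
#'   (in `[1, p]`).
#' @param population_names Character vector of the p population names, in
#'   index order.
#' @param phased Logical; whether the source genotypes were phased. Panel
#'   collapsing is phase-insensitive, so unphased panels are accepted.
#' @param sample_id Optional character vector naming each haplotype's sample.
#' @param hap_index Optional integer vector (1 or 2) giving which haplotype
#'   of the diploid sample each row is.
#'
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(alleles, sites, hap_population, population_names,
                            phased = TRUE, sample_id = NULL, hap_index = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  sites <- tibble::as_tibble(sites)
  needed <- c("chrom", "pos", "id", "ref", "alt")
  missing_cols <- setdiff(needed, names(sites))
  if (length(missing_cols) > 0) {
    abort(paste0("sites is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(sites) != ncol(alleles)) {
    abort("number of site rows must equal the number of allele columns")
  }
  if (length(hap_population) != nrow(alleles)) {
    abort("hap_population must have one entry per haplotype row")
  }
  hap_population <- as.integer(hap_population)
  p <- length(population_names)
  if (any(hap_population < 1L | hap_population > p)) {
    abort("hap_population indices must lie in [1, p]")
  }
  for (ch in unique(sites$chrom)) {
    pos <- sites$pos[sites$chrom == ch]
    if (any(diff(pos) <= 0)) {
      abort(paste0("site positions must be strictly increasing on chromosome ", ch))
    }
  }
  if (any(alleles < 0L, na.rm = TRUE)) abort("allele codes must be non-negative")
  structure(
    list(
      alleles = alleles,
      sites = sites,
      hap_population = hap_population,
      population_names = as.character(population_names),
      phased = isTRUE(phased),
      sample_id = sample_id,
      hap_index = hap_index
    ),
    class = "haplotype_panel"
  )
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf(
    "<haplotype_panel> %d haplotypes x %d sites, %d populations (%s)%s\n",
    nrow(x$alleles), ncol(x$alleles), length(x$population_names),
    paste(x$population_names, collapse = ", "),
    if (x$phased) ", phased" else ", unphased"
  ))
  counts <- table(factor(x$hap_population, levels = seq_along(x$population_names)))
  cat("  haplotypes per population:",
      paste(sprintf("%s=%d", x$population_names, as.integer(counts)), collapse = " "),
      "\n")
  invisible(x)
}

n_sites <- function(panel) ncol(panel$alleles)
n_haplotypes <- function(panel) nrow(panel$alleles)
n_populations <- function(panel) length(panel$population_names)

# Largest allele code observed (+1) -> K; panels with all-missing columns
# still get K >= 2 so downstream arrays are well-formed.
panel_n_alleles <- function(panel) {
  max(2L, max(panel$alleles, na.rm = TRUE) + 1L)
}

#' Summarize a haplotype panel as a tibble
#'
#' One row per site with per-population allele counts collapsed into a
#' compact string, convenient for inspection and joins.
#'
#' @param x A `haplotype_panel`.
#' @param ... Unused.
#' @return A tibble with the site metadata plus `n_alleles_observed`.
#' @export
tidy.haplotype_panel <- function(x, ...) {
  observed <- apply(x$alleles, 2, function(col) length(unique(col[!is.na(col)])))
  dplyr::mutate(x$sites, n_alleles_observed = as.integer(observed))
}

#' Construct a query haplotype set aligned to a panel
#'
#' @param haplotypes Integer matrix, query haplotypes x sites; allele codes
#'   as in the panel, `NA` for missing.
#' @param sites Site metadata, identical in order, position and alleles to
#'   the reference panel's.
#' @param sample_id Character vector naming each haplotype's sample.
#' @param hap_index Integer vector (1 or 2): which haplotype of its sample
#'   each row is.
#' @return An object of class `query_set`.
#' @export
query_set <- function(haplotypes, sites, sample_id, hap_index) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  sites <- tibble::as_tibble(sites)
  if (nrow(sites) != ncol(haplotypes)) {
    abort("query site metadata must match the haplotype matrix width")
  }
  if (length(sample_id) != nrow(haplotypes) ||
      length(hap_index) != nrow(haplotypes)) {
    abort("sample_id and hap_index must have one entry per query haplotype")
  }
  structure(
    list(haplotypes = haplotypes, sites = sites,
         sample_id = as.character(sample_id), hap_index = as.integer(hap_index)),
    class = "query_set"
  )
}

#' @export
print.query_set <- function(x, ...) {
  cat(sprintf("<query_set> %d haplotypes (%d samples) x %d sites\n",
              nrow(x$haplotypes), length(unique(x$sample_id)), ncol(x$haplotypes)))
  invisible(x)
}

# Shared-site check used by inference and IO: chromosome, position, ref and
# alt must all agree, in order.
assert_same_sites <- function(a, b, what = "query") {
  same <- nrow(a) == nrow(b) &&
    all(a$chrom == b$chrom) && all(a$pos == b$pos) &&
    all(a$ref == b$ref) && all(a$alt == b$alt)
  if (!same) {
    abort(paste0(what, " sites do not match the reference panel's site list"))
  }
  invisible(TRUE)
}
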