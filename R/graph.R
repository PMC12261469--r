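new_compact_graph <- function(present, sites, population_names) {
  structure(
    list(
      present = present,  # K x p x n logical: allele a+1, population l, site j
      sites = tibble::as_tibble(sites),
      population_names = as.character(population_names),
      n = dim(present)[3],
      p = dim(present)[2],
      K = dim(present)[1]
    ),
    class = "compact_population_graph"
  )
}

#' Collapse a labeled haplotype panel into a compact population graph
#'
#' At every site the panel's haplotype alleles are collapsed to the set of
#' unique (allele, population) pairs: a node exists for population l and
#' allele a iff some haplotype labeled l carries a at that site. Missing
#' alleles contribute nothing. The node set per site therefore has at most
#' K*p members (2p for bi-allelic panels), independent of panel depth, and
#' is invariant to duplicating haplotypes and to phase within an
#' individual.
#'
#' @param panel A [haplotype_panel()] with at least two populations, each
#'   represented by at least one haplotype.
#' @return An object of class `compact_population_graph`.
#' @export
build_compact_graph <- function(panel) {
  p <- n_populations(panel)
  if (p < 2) abort("at least 2 populations are required")
  counts <- tabulate(panel$hap_population, nbins = p)
  if (any(counts == 0)) {
    abort(paste0("population(s) with zero haplotypes: ",
                 paste(panel$population_names[counts == 0], collapse = ", ")))
  }
  K <- panel_n_alleles(panel)
  n <- n_sites(panel)
  present <- array(FALSE, dim = c(K, p, n))
  for (l in seq_len(p)) {
    rows <- panel$alleles[panel$hap_population == l, , drop = FALSE]
    for (a in seq_len(K) - 1L) {
      present[a + 1L, l, ] <- colSums(rows == a, na.rm = TRUE) > 0
    }
  }
  new_compact_graph(present, panel$sites, panel$population_names)
}

#' @export
print.compact_population_graph <- function(x, ...) {
  sizes <- apply(x$present, 3, sum)
  cat(sprintf(
    "<compact_population_graph> %d sites, %d populations, K=%d; node-set sizes %d..%d (mean %.2f)\n",
    x$n, x$p, x$K, min(sizes), max(sizes), mean(sizes)))
  cat(sprintf("  dAIMs: %d of %d sites\n", length(identify_daims(x)), x$n))
  invisible(x)
}

#' Per-site node sets of a compact graph as a tibble
#'
#' @param x A `compact_population_graph`.
#' @param ... Unused.
#' @return A tibble with one row per node: `site`, `chrom`, `pos`,
#'   `allele`, `population`.
#' @export
tidy.compact_population_graph <- function(x, ...) {
  idx <- which(x$present, arr.ind = TRUE)
  tibble::tibble(
    site = as.integer(idx[, 3]),
    chrom = x$sites$chrom[idx[, 3]],
    pos = x$sites$pos[idx[, 3]],
    allele = as.integer(idx[, 1]) - 1L,
    population = x$population_names[idx[, 2]]
  ) |>
    dplyr::arrange(.data$site, .data$allele, .data$population)
}

# Node-set equality, used by invariance tests and round-trip checks.
compact_graphs_equal <- function(a, b) {
  isTRUE(a$p == b$p) && isTRUE(a$n == b$n) &&
    identical(a$population_names, b$population_names) &&
    dim(a$present)[1] == dim(b$present)[1] &&
    identical(a$present, b$present)
}

#' Identify discrete ancestry informative markers (dAIMs)
#'
#' A site is a dAIM when some allele is present in one population's panel
#' but absent from at least one other population. After collapsing, dAIMs
#' are the only sites whose node sets differ between populations, hence
#' the sole source of between-population signal.
#'
#' @param graph A `compact_population_graph`.
#' @return Sorted integer vector of dAIM site indices.
#' @export
identify_daims <- function(graph) {
  pres <- graph$present
  # allele a discriminates at site j iff present in >=1 pop and absent in >=1
  any_pop <- apply(pres, c(1, 3), any)    # K x n
  all_pop <- apply(pres, c(1, 3), all)    # K x n
  which(colSums(any_pop & !all_pop) > 0)
}

#' Compute normalized switch penalties from a genetic map
#'
#' For each adjacent site pair the recombination rate is the genetic
#' distance (cM) over the physical distance (Mb). Rates are min-max
#' normalized to `[0, 1]` over the region's n-1 intervals and transformed
#' by the reciprocal map `R' = 2 / (Rnorm + 1)`, giving penalties in
#' `[1, 2]`: the hottest interval is cheapest to switch across (R' = 1),
#' the coldest most expensive (R' = 2). cM at site positions is obtained by
#' piecewise-linear interpolation of the map (constant-rate extrapolation
#' of the flanking interval beyond it); negative interpolated cM
#' differences are clipped to 0, and a zero bp gap defines rate 0.
#'
#' When every interval has the same raw rate, min-max normalization is
#' degenerate; the convention here sets Rnorm = 0 so all penalties equal 2
#' (no rate signal: switching maximally penalized uniformly) and a warning
#' is emitted.
#'
#' @param sites Site metadata (tibble with `pos`), or an object carrying
#'   `$sites` such as a panel or compact graph.
#' @param map A [genetic_map()].
#' @return An object of class `switch_penalties` with fields `values`
#'   (length n-1, in `[1, 2]`), `raw_rates` (cM/Mb), and the min-max
#'   constants used.
#' @export
compute_switch_penalties <- function(sites, map) {
  if (!is.data.frame(sites) && !is.null(sites$sites)) sites <- sites$sites
  pos <- as.numeric(sites$pos)
  if (length(pos) < 2) abort("at least 2 sites are needed for switch penalties")
  if (any(diff(pos) < 0)) abort("site positions must be non-decreasing")
  cm <- interpolate_cM(map, pos)
  d_cm <- pmax(diff(cm), 0)
  d_mb <- diff(pos) / 1e6
  rates <- ifelse(d_mb > 0, d_cm / d_mb, 0)
  rmin <- min(rates)
  rmax <- max(rates)
  if (rmax == rmin) {
    warn("all interval recombination rates are equal; using Rnorm = 0 (all penalties = 2)")
    rnorm <- rep(0, length(rates))
  } else {
    rnorm <- (rates - rmin) / (rmax - rmin)
  }
  values <- 2 / (rnorm + 1)
  structure(
    list(values = values, raw_rates = rates,
         normalization_min = rmin, normalization_max = rmax,
         pos_left = pos[-length(pos)], pos_right = pos[-1]),
    class = "switch_penalties"
  )
}

#' @export
print.switch_penalties <- function(x, ...) {
  cat(sprintf(
    "<switch_penalties> %d intervals; raw rate %.4g..%.4g cM/Mb; penalties %.4f..%.4f\n",
    length(x$values), x$normalization_min, x$normalization_max,
    min(x$values), max(x$values)))
  invisible(x)
}

#' Switch penalties as a tibble
#'
#' @param x A `switch_penalties` object.
#' @param ... Unused.
#' @return A tibble with `pos_left`, `pos_right`, `rate_cM_per_Mb`,
#'   `penalty` (one row per adjacent-site interval), suitable for export as
#'   a diagnostic TSV.
#' @export
tidy.switch_penalties <- function(x, ...) {
  tibble::tibble(
    pos_left = x$pos_left,
    pos_right = x$pos_right,
    rate_cM_per_Mb = x$raw_rates,
    penalty = x$values
  )
}

#' @export
autoplot.switch_penalties <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$pos_left + .data$pos_right) / 2,
                                   y = .data$penalty)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "position (bp)", y = "switch penalty R'",
                  title = "Between-population switch penalties") +
    ggplot2::ylim(1, 2)
}

#' Mask population-rare alleles before graph construction
#'
#' For each site and population, alleles carried by a fraction of that
#' population's (non-missing) haplotypes strictly below `threshold` are set
#' to missing, so they contribute no graph node. This can create dAIMs in
#' panels that otherwise have few or none. If masking would remove every
#' allele of a population at a site, the population's majority allele is
#' retained instead.
#'
#' @param panel A [haplotype_panel()].
#' @param threshold Frequency in `[0, 0.5)`; 0 leaves the panel unchanged.
#' @return A [haplotype_panel()] with rare alleles masked.
#' @export
prune_rare_alleles <- function(panel, threshold) {
  if (threshold < 0) abort("threshold must be >= 0")
  if (threshold >= 0.5) abort("threshold must be < 0.5 (would mask majority alleles)")
  if (threshold == 0) return(panel)
  alleles <- panel$alleles
  p <- n_populations(panel)
  K <- panel_n_alleles(panel)
  for (l in seq_len(p)) {
    rows <- which(panel$hap_population == l)
    block <- alleles[rows, , drop = FALSE]
    counts <- vapply(seq_len(K) - 1L,
                     function(a) colSums(block == a, na.rm = TRUE),
                     numeric(ncol(block)))
    counts <- matrix(counts, ncol = K)  # site x allele
    tot <- rowSums(counts)
    freq <- counts / ifelse(tot == 0, 1, tot)
    rare <- freq < threshold & counts > 0
    keep_all_rare <- rowSums(rare) == rowSums(counts > 0) & tot > 0
    if (any(keep_all_rare)) {
      # retain the majority allele (lowest code on ties)
      maj <- max.col(counts[keep_all_rare, , drop = FALSE], ties.method = "first")
      rare[cbind(which(keep_all_rare), maj)] <- FALSE
    }
    for (a in seq_len(K) - 1L) {
      sites_mask <- which(rare[, a + 1L])
      if (length(sites_mask) > 0) {
        sub <- block[, sites_mask, drop = FALSE]
        sub[sub == a] <- NA_integer_
        block[, sites_mask] <- sub
      }
    }
    alleles[rows, ] <- block
  }
  out <- panel
  out$alleles <- alleles
  out
}
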