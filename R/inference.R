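#' Penalty parameters for threading-path inference
#'
#' @param w Non-negative scale factor balancing mismatch against
#'   recombination cost. Default 1.5.
#' @param within_population_switch_cost Template-change cost multiplier for
#'   staying within a population. Default 0, the model's defining choice:
#'   switching copying templates inside one population is free, which both
#'   collapses the state space to populations and amplifies the
#'   between-population signal. A nonzero value restores a uniform
#'   within-population template-change term for ablation experiments.
#' @param missing_population_cost Mismatch cost charged when a population
#'   has no observed allele at a site (all-missing genotypes). Default 1:
#'   absence of evidence is treated as a mismatch, so it never beats an
#'   explicit match.
#' @return An object of class `penalty_params`.
#' @export
penalty_params <- function(w = 1.5, within_population_switch_cost = 0,
                           missing_population_cost = 1) {
  if (w < 0) abort("w must be >= 0")
  if (within_population_switch_cost < 0) abort("within-population cost must be >= 0")
  structure(
    list(w = w,
         mismatch_cost = 1,
         within_population_switch_cost = within_population_switch_cost,
         missing_population_cost = missing_population_cost),
    class = "penalty_params"
  )
}

# p x nq mismatch block for site j. Rules: matching allele 0, non-matching 1,
# missing query allele 0 for every population (uninformative), population
# with no node at the site -> missing_population_cost.
mismatch_block <- function(graph, qa, j, miss_cost) {
  p <- graph$p
  nq <- length(qa)
  idx <- qa + 1L
  idx[!is.na(idx) & (idx < 1L | idx > graph$K)] <- NA_integer_
  m <- matrix(0, nrow = p, ncol = nq)
  pres_j <- graph$present[, , j, drop = FALSE]
  dim(pres_j) <- c(graph$K, p)
  pop_empty <- colSums(pres_j) == 0
  for (l in seq_len(p)) {
    v <- pres_j[idx, l]
    row <- as.numeric(!v)
    if (pop_empty[l]) row[] <- miss_cost
    row[is.na(qa)] <- 0
    m[l, ] <- row
  }
  m
}

#' Per-site, per-population mismatch costs for a query
#'
#' With the within-population switch cost at zero, the best-matching node
#' of each population is attainable for free, so the site cost of
#' population l reduces to 0 if the query allele is present in l's node
#' set and 1 otherwise. Missing query alleles cost 0 against every
#' population (uninformative); a population with no node at a site costs
#' `missing_population_cost`.
#'
#' @param graph A `compact_population_graph`.
#' @param query Integer vector of query alleles, length n (`NA` missing).
#' @param params A [penalty_params()].
#' @return An n x p numeric matrix of site costs.
#' @export
site_population_mismatch <- function(graph, query, params = penalty_params()) {
  if (length(query) != graph$n) abort("query length must equal the graph's site count")
  out <- matrix(0, nrow = graph$n, ncol = graph$p)
  for (j in seq_len(graph$n)) {
    out[j, ] <- mismatch_block(graph, query[j], j,
                               params$missing_population_cost)
  }
  colnames(out) <- graph$population_names
  out
}

new_ancestry_painting <- function(labels, total_cost, mismatch_sum, switch_sum,
                                  query_id, sites, population_names, w) {
  structure(
    list(labels = as.integer(labels),
         total_cost = total_cost,
         mismatch_cost_sum = mismatch_sum,
         switch_cost_sum = switch_sum,
         query_id = query_id,
         sites = sites,
         population_names = population_names,
         w = w),
    class = "ancestry_painting"
  )
}

#' @export
print.ancestry_painting <- function(x, ...) {
  r <- rle(x$labels)
  cat(sprintf(
    "<ancestry_painting> %s: %d sites, %d segment(s), cost %.4f (mismatch %.4f + %.2g * switch %.4f)\n",
    x$query_id, length(x$labels), length(r$values), x$total_cost,
    x$mismatch_cost_sum, x$w, x$switch_cost_sum))
  invisible(x)
}

#' Tidy and summary views of an ancestry painting
#'
#' `tidy()` returns one row per site with the inferred population;
#' `glance()` returns a one-row cost summary.
#'
#' @param x An `ancestry_painting`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ancestry_painting <- function(x, ...) {
  tibble::tibble(
    query_id = x$query_id,
    site = seq_along(x$labels),
    chrom = x$sites$chrom,
    pos = x$sites$pos,
    label = x$labels,
    population = x$population_names[x$labels]
  )
}

#' @rdname tidy.ancestry_painting
#' @export
glance.ancestry_painting <- function(x, ...) {
  tibble::tibble(
    query_id = x$query_id,
    n_sites = length(x$labels),
    n_switches = sum(diff(x$labels) != 0),
    total_cost = x$total_cost,
    mismatch_cost_sum = x$mismatch_cost_sum,
    switch_cost_sum = x$switch_cost_sum,
    w = x$w
  )
}

#' @export
autoplot.ancestry_painting <- function(object, ...) {
  plot_paintings(list(object))
}

#' Plot ancestry paintings as horizontal tract bars
#'
#' @param paintings A list of `ancestry_painting` objects sharing a site
#'   list (or a single painting).
#' @param population_names Optional population names; defaults to the
#'   first painting's.
#' @return A ggplot object: one horizontal bar per query haplotype,
#'   colored by inferred population along physical position.
#' @export
plot_paintings <- function(paintings, population_names = NULL) {
  if (inherits(paintings, "ancestry_painting")) paintings <- list(paintings)
  if (is.null(population_names)) population_names <- paintings[[1]]$population_names
  segs <- purrr::map_dfr(paintings, segment_table,
                         population_names = population_names)
  segs$hap <- factor(segs$hap, levels = rev(unique(segs$hap)))
  ggplot2::ggplot(segs) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start_pos, xmax = .data$end_pos,
                                    ymin = as.integer(.data$hap) - 0.4,
                                    ymax = as.integer(.data$hap) + 0.4,
                                    fill = .data$population)) +
    ggplot2::scale_y_continuous(breaks = seq_along(levels(segs$hap)),
                                labels = levels(segs$hap)) +
    ggplot2::labs(x = "position (bp)", y = NULL, fill = "ancestry",
                  title = "Inferred local ancestry")
}

# Batch dynamic program over population states for a block of queries.
# Q: nq x n integer matrix. Returns labels (nq x n) and totals (nq).
#
# Recurrence (site j, population l, query q):
#   C[1][l] = m[1][l]
#   C[j][l] = m[j][l] + min( C[j-1][l] + stay_pen,
#                            min_{l' != l} C[j-1][l'] + w * R'_{j-1,j} )
# stay_pen is 0 by default (w * R' * within_cost under ablation). Ties
# prefer staying in the same population, then the lowest population index;
# the final state ties break to the lowest index. Cost accumulation uses
# the fixed operation order m + (prev + pen) so the enumeration oracle can
# reproduce totals bit-exactly.
dp_paint_block <- function(graph, penalties, Q, params) {
  n <- graph$n
  p <- graph$p
  nq <- nrow(Q)
  if (ncol(Q) != n) abort("query length must equal the graph's site count")
  if (p < 2) abort("at least 2 populations are required for inference")
  if (n > 1 && length(penalties$values) != n - 1) {
    abort("penalties must have n-1 values")
  }
  w <- params$w
  within <- params$within_population_switch_cost
  miss <- params$missing_population_cost
  seq_nq <- seq_len(nq)

  C <- mismatch_block(graph, Q[, 1], 1L, miss)
  pred <- array(0L, dim = c(p, nq, n))
  if (n > 1) {
    for (j in 2:n) {
      pen <- w * penalties$values[j - 1]
      minC <- C[1, ]
      if (p > 1) for (l in 2:p) minC <- pmin(minC, C[l, ])
      am1 <- integer(nq)
      for (l in p:1) am1[C[l, ] == minC] <- l
      C2 <- C
      C2[cbind(am1, seq_nq)] <- Inf
      min2 <- C2[1, ]
      if (p > 1) for (l in 2:p) min2 <- pmin(min2, C2[l, ])
      am2 <- integer(nq)
      for (l in p:1) am2[C2[l, ] == min2] <- l
      m_j <- mismatch_block(graph, Q[, j], j, miss)
      newC <- C
      for (l in seq_len(p)) {
        self_best <- am1 == l
        other_min <- ifelse(self_best, min2, minC)
        other_arg <- ifelse(self_best, am2, am1)
        switch_val <- other_min + pen
        stay_val <- if (within == 0) C[l, ] else C[l, ] + pen * within
        stay <- stay_val <= switch_val
        newC[l, ] <- m_j[l, ] + ifelse(stay, stay_val, switch_val)
        pred[l, , j] <- ifelse(stay, l, other_arg)
      }
      C <- newC
    }
  }
  totals <- C[1, ]
  if (p > 1) for (l in 2:p) totals <- pmin(totals, C[l, ])
  final <- integer(nq)
  for (l in p:1) final[C[l, ] == totals] <- l
  labels <- matrix(0L, nrow = nq, ncol = n)
  labels[, n] <- final
  if (n > 1) {
    cur <- final
    for (j in (n - 1):1) {
      cur <- pred[cbind(cur, seq_nq, j + 1L)]
      labels[, j] <- cur
    }
  }
  list(labels = labels, totals = totals)
}

# Decompose a label path's cost into mismatch and switch components.
path_cost_components <- function(graph, penalties, Q, labels, params) {
  n <- graph$n
  nq <- nrow(Q)
  miss <- params$missing_population_cost
  within <- params$within_population_switch_cost
  mismatch <- numeric(nq)
  for (j in seq_len(n)) {
    blk <- mismatch_block(graph, Q[, j], j, miss)
    mismatch <- mismatch + blk[cbind(labels[, j], seq_len(nq))]
  }
  switch_sum <- numeric(nq)
  if (n > 1) {
    changed <- labels[, -1, drop = FALSE] != labels[, -n, drop = FALSE]
    rmat <- matrix(penalties$values, nrow = nq, ncol = n - 1, byrow = TRUE)
    switch_sum <- rowSums(rmat * (changed + (!changed) * within))
  }
  list(mismatch = mismatch, switch = switch_sum)
}

#' Paint one query haplotype by the minimum-penalty threading path
#'
#' Finds a source-to-sink path through the compact population graph
#' minimizing total penalty: per-site 0/1 mismatches plus `w` times the
#' recombination-scaled penalty for each between-population switch
#' (within-population switches are free). Solved exactly by dynamic
#' programming over population states in O(np) time and space. Ties prefer
#' staying in the current population, then the lowest population index
#' (applied from the final site backwards), so output is deterministic.
#'
#' @param graph A `compact_population_graph`.
#' @param penalties A [compute_switch_penalties()] result (ignored when the
#'   graph has a single site).
#' @param query Integer vector of query alleles (length n, `NA` missing).
#' @param params A [penalty_params()].
#' @param query_id Identifier recorded in the painting.
#' @return An `ancestry_painting`: per-site population labels, the
#'   minimized total cost, and its mismatch/switch decomposition.
#' @export
infer_path <- function(graph, penalties, query, params = penalty_params(),
                       query_id = "query") {
  if (length(query) != graph$n) abort("query length must equal the graph's site count")
  res <- dp_paint_block(graph, penalties, matrix(as.integer(query), nrow = 1),
                        params)
  comp <- path_cost_components(graph, penalties,
                               matrix(as.integer(query), nrow = 1),
                               res$labels, params)
  new_ancestry_painting(res$labels[1, ], res$totals[1],
                        comp$mismatch[1], comp$switch[1],
                        query_id, graph$sites, graph$population_names,
                        params$w)
}

#' Paint every haplotype of a query set
#'
#' Batch driver over [infer_path()]: queries are independent, and results
#' are deterministic given inputs. Sites excluded by `marker_mask` are kept
#' in the path (switch penalties unchanged) but score 0 against every
#' population, i.e. they are treated as uninformative.
#'
#' @param graph A `compact_population_graph`.
#' @param penalties A [compute_switch_penalties()] result.
#' @param queries A [query_set()] aligned to the graph's sites.
#' @param params A [penalty_params()].
#' @param marker_mask Optional logical vector (length n): `FALSE` sites are
#'   ignored as evidence.
#' @param verbose Log per-query cost summaries.
#' @return A list of `ancestry_painting`, one per query haplotype.
#' @export
infer_queryset <- function(graph, penalties, queries,
                           params = penalty_params(), marker_mask = NULL,
                           verbose = FALSE) {
  assert_same_sites(queries$sites, graph$sites, what = "query")
  Q <- queries$haplotypes
  if (!is.null(marker_mask)) {
    if (length(marker_mask) != graph$n) abort("marker_mask must have length n")
    Q[, !marker_mask] <- NA_integer_  # missing alleles score 0 everywhere
  }
  res <- dp_paint_block(graph, penalties, Q, params)
  comp <- path_cost_components(graph, penalties, Q, res$labels, params)
  ids <- paste0(queries$sample_id, "_", queries$hap_index)
  paintings <- purrr::map(seq_len(nrow(Q)), function(i) {
    new_ancestry_painting(res$labels[i, ], res$totals[i],
                          comp$mismatch[i], comp$switch[i],
                          ids[i], graph$sites, graph$population_names,
                          params$w)
  })
  if (verbose) {
    n_daims <- length(identify_daims(graph))
    for (pt in paintings) {
      inform(sprintf("%s: cost %.4f over %d sites (%d dAIMs in panel)",
                     pt$query_id, pt$total_cost, graph$n, n_daims))
    }
  }
  paintings
}
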