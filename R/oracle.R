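#' Exhaustive enumeration oracle for the threading-path objective
#'
#' Evaluates the path objective over every population-label sequence (valid
#' because, with free within-population switching, the best node of each
#' population at a site reduces to the per-population site cost) and
#' returns the exact minimum with one argmin path. Intended as an
#' independent check of [infer_path()] on small instances; guarded at
#' p^n <= 1e6.
#'
#' Tie-breaking uses the same total order as the dynamic program: among
#' minimum-cost paths, compare from the final site backwards; at the first
#' site where two paths differ, prefer the path that keeps its following
#' site's population (fewer switches), then the lower population index.
#' Cost accumulation uses the same operation order as the dynamic program,
#' so agreement is bit-exact.
#'
#' @inheritParams infer_path
#' @return A list with `min_cost` and `labels` (length-n integer vector).
#' @export
enumerate_paths_oracle <- function(graph, penalties, query,
                                   params = penalty_params()) {
  n <- graph$n
  p <- graph$p
  if (p^n > 1e6) abort("enumeration guard exceeded: p^n > 1e6")
  m <- site_population_mismatch(graph, query, params)
  w <- params$w
  within <- params$within_population_switch_cost
  paths <- as.matrix(expand.grid(rep(list(seq_len(p)), n)))
  colnames(paths) <- NULL
  acc <- m[1, paths[, 1]]
  if (n > 1) {
    for (j in 2:n) {
      pen <- w * penalties$values[j - 1]
      stayed <- paths[, j] == paths[, j - 1]
      pen_vec <- if (within == 0) ifelse(stayed, 0, pen)
                 else ifelse(stayed, pen * within, pen)
      acc <- m[j, paths[, j]] + (acc + pen_vec)
    }
  }
  min_cost <- min(acc)
  cand <- which(acc == min_cost)
  best <- cand[1]
  if (length(cand) > 1) {
    for (k in cand[-1]) {
      if (path_preferred(paths[k, ], paths[best, ])) best <- k
    }
  }
  list(min_cost = min_cost, labels = as.integer(paths[best, ]))
}

# TRUE iff label path a is preferred over b under the suffix-first
# tie-break shared with the dynamic program.
path_preferred <- function(a, b) {
  n <- length(a)
  for (j in n:1) {
    if (a[j] == b[j]) next
    if (j == n) return(a[j] < b[j])
    nxt <- a[j + 1]  # paths agree on all sites > j
    a_stays <- a[j] == nxt
    b_stays <- b[j] == nxt
    if (a_stays != b_stays) return(a_stays)
    return(a[j] < b[j])
  }
  FALSE
}

# Node-level dynamic program over the uncollapsed (allele, population)
# states of the compact graph. Used in tests to confirm that collapsing the
# state space to populations (justified by the zero within-population
# switch cost) preserves the optimum. Only meaningful when within-population
# switching is free and every population has a node at every site.
dp_paint_nodes <- function(graph, penalties, query, params = penalty_params()) {
  n <- graph$n
  w <- params$w
  nodes_at <- function(j) {
    idx <- which(matrix(graph$present[, , j], nrow = graph$K), arr.ind = TRUE)
    data.frame(allele = idx[, 1] - 1L, pop = idx[, 2])
  }
  node_cost <- function(nd, qa) {
    if (is.na(qa)) rep(0, nrow(nd)) else as.numeric(nd$allele != qa)
  }
  nd <- nodes_at(1)
  C <- node_cost(nd, query[1])
  if (n > 1) {
    for (j in 2:n) {
      pen <- w * penalties$values[j - 1]
      nd_new <- nodes_at(j)
      C_new <- numeric(nrow(nd_new))
      for (v in seq_len(nrow(nd_new))) {
        trans <- ifelse(nd$pop == nd_new$pop[v], 0, pen)
        C_new[v] <- node_cost(nd_new[v, ], query[j]) + min(C + trans)
      }
      nd <- nd_new
      C <- C_new
    }
  }
  min(C)
}
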