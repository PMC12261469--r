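test_that("site costs follow the presence rule with missing-data conventions", {
  # site 1: pop1 {0,1}, pop2 {0}; site 2: both pops {0,1}
  panel <- make_panel(rbind(c(0, 0), c(1, 1), c(0, 0), c(0, 1)),
                      pops = c(1, 1, 2, 2))
  g <- build_compact_graph(panel)
  m <- site_population_mismatch(g, c(1L, 0L))
  expect_equal(unname(m[1, ]), c(0, 1))
  expect_equal(unname(m[2, ]), c(0, 0))  # non-dAIM site carries no signal
  m_na <- site_population_mismatch(g, c(NA_integer_, NA_integer_))
  expect_equal(unname(m_na), matrix(0, 2, 2))
  expect_error(site_population_mismatch(g, c(0L)), "length")
})

test_that("a population with no observed allele at a site pays the missing cost", {
  panel <- make_panel(rbind(c(0, 0), c(1, NA), c(0, NA)), pops = c(1, 1, 2))
  g <- build_compact_graph(panel)
  m <- site_population_mismatch(g, c(0L, 0L))
  expect_equal(unname(m[2, ]), c(0, 1))
  m2 <- site_population_mismatch(
    g, c(0L, 0L), penalty_params(missing_population_cost = 0.25))
  expect_equal(unname(m2[2, ]), c(0, 0.25))
})

test_that("a perfect copy paints constant with zero cost", {
  panel <- make_panel(rbind(matrix(0L, 2, 8), matrix(1L, 2, 8)),
                      pops = c(1, 1, 2, 2), pop_names = c("A", "B"))
  g <- build_compact_graph(panel)
  pen <- uniform_penalties(8)
  pt <- infer_path(g, pen, rep(0L, 8))
  expect_equal(pt$labels, rep(1L, 8))
  expect_equal(pt$total_cost, 0)
})

test_that("one clean ancestry switch costs exactly w * R'", {
  panel <- make_panel(rbind(matrix(0L, 2, 8), matrix(1L, 2, 8)),
                      pops = c(1, 1, 2, 2), pop_names = c("A", "B"))
  g <- build_compact_graph(panel)
  pen <- uniform_penalties(8, value = 2)
  q <- c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L)
  pt <- infer_path(g, pen, q, penalty_params(w = 1.5))
  expect_equal(pt$labels, rep(c(1L, 2L), each = 4))
  expect_equal(pt$total_cost, 3)
  orc <- enumerate_paths_oracle(g, pen, q, penalty_params(w = 1.5))
  expect_equal(orc$min_cost, 3)
  expect_equal(orc$labels, pt$labels)
})

test_that("the two-site hand-enumerated tie resolves to the lowest final label", {
  # m = [[0,1],[1,0]], w * R' = 3: paths (1,1)=1, (1,2)=3, (2,1)=5, (2,2)=1;
  # tie between (1,1) and (2,2) resolves to label 1 at the final site
  panel <- make_panel(rbind(c(0, 0), c(1, 1)), pops = c(1, 2))
  g <- build_compact_graph(panel)
  pen <- uniform_penalties(2, value = 2)
  par <- penalty_params(w = 1.5)
  q <- c(0L, 1L)
  orc <- enumerate_paths_oracle(g, pen, q, par)
  expect_equal(orc$min_cost, 1)
  expect_equal(orc$labels, c(1L, 1L))
  pt <- infer_path(g, pen, q, par)
  expect_equal(pt$total_cost, 1)
  expect_equal(pt$labels, c(1L, 1L))
})

test_that("dynamic program and enumeration oracle agree on random instances", {
  for (seed in 1:60) {
    inst <- random_instance(seed, missing_rate = if (seed %% 3 == 0) 0.1 else 0)
    pt <- infer_path(inst$graph, inst$penalties, inst$query, inst$params)
    orc <- enumerate_paths_oracle(inst$graph, inst$penalties, inst$query,
                                  inst$params)
    expect_equal(pt$total_cost, orc$min_cost, tolerance = 1e-12)
    expect_equal(pt$labels, orc$labels)
  }
})

test_that("oracle equivalence also holds under a within-population penalty", {
  for (seed in 1:15) {
    inst <- random_instance(seed + 500)
    par <- penalty_params(w = inst$params$w,
                          within_population_switch_cost = 0.3)
    pt <- infer_path(inst$graph, inst$penalties, inst$query, par)
    orc <- enumerate_paths_oracle(inst$graph, inst$penalties, inst$query, par)
    expect_equal(pt$total_cost, orc$min_cost, tolerance = 1e-12)
    expect_equal(pt$labels, orc$labels)
    # extra within-population terms can only raise the optimum
    base <- infer_path(inst$graph, inst$penalties, inst$query, inst$params)
    expect_gte(pt$total_cost + 1e-12, base$total_cost)
  }
})

test_that("the population-state DP matches a node-level DP", {
  for (seed in 1:20) {
    inst <- random_instance(seed + 900)
    pt <- infer_path(inst$graph, inst$penalties, inst$query, inst$params)
    node_cost <- lapaint:::dp_paint_nodes(inst$graph, inst$penalties,
                                          inst$query, inst$params)
    expect_equal(pt$total_cost, node_cost, tolerance = 1e-9)
  }
})

test_that("reported cost decomposes into mismatch plus weighted switch terms", {
  for (seed in 1:20) {
    inst <- random_instance(seed + 40)
    pt <- infer_path(inst$graph, inst$penalties, inst$query, inst$params)
    labs <- pt$labels
    m <- site_population_mismatch(inst$graph, inst$query, inst$params)
    mismatch <- sum(m[cbind(seq_along(labs), labs)])
    switches <- sum(inst$penalties$values[which(diff(labs) != 0)])
    expect_equal(pt$mismatch_cost_sum, mismatch, tolerance = 1e-9)
    expect_equal(pt$switch_cost_sum, switches, tolerance = 1e-9)
    expect_equal(pt$total_cost, mismatch + inst$params$w * switches,
                 tolerance = 1e-9)
  }
})

test_that("switch counts fall and the limit painting emerges as w grows", {
  for (seed in 1:8) {
    inst <- random_instance(seed + 70, max_n = 12, max_hap = 8)
    m <- site_population_mismatch(inst$graph, inst$query)
    n_switches <- vapply(c(0.1, 0.5, 1.5, 5, 50), function(w) {
      pt <- infer_path(inst$graph, inst$penalties, inst$query,
                       penalty_params(w = w))
      sum(diff(pt$labels) != 0)
    }, numeric(1))
    expect_true(all(diff(n_switches) <= 0))
    # w -> infinity: constant painting at the best single population
    pt_inf <- infer_path(inst$graph, inst$penalties, inst$query,
                         penalty_params(w = 1e9))
    expect_equal(length(unique(pt_inf$labels)), 1)
    expect_equal(sum(m[, pt_inf$labels[1]]), min(colSums(m)),
                 tolerance = 1e-12)
    # w = 0: per-site argmin of m under the shared tie-break
    pt0 <- infer_path(inst$graph, inst$penalties, inst$query,
                      penalty_params(w = 0))
    expect_equal(m[cbind(seq_len(nrow(m)), pt0$labels)],
                 apply(m, 1, min), ignore_attr = TRUE)
  }
})

test_that("permuting population indices permutes the painting identically", {
  for (seed in 1:10) {
    set.seed(seed)
    panel <- random_panel(seed + 300, n_hap = 9, n_sites = 10, p = 3)
    perm <- sample(3)
    panel_perm <- haplotype_panel(panel$alleles, panel$sites,
                                  perm[panel$hap_population],
                                  panel$population_names[order(perm)])
    pen <- fixed_penalties(runif(9, 1, 2))
    q <- rbinom(10, 1, 0.5)
    g1 <- build_compact_graph(panel)
    g2 <- build_compact_graph(panel_perm)
    pt <- infer_path(g1, pen, q)
    pt_perm <- infer_path(g2, pen, q)
    expect_equal(pt_perm$total_cost, pt$total_cost, tolerance = 1e-12)
    # the permuted labels attain the same optimum in the permuted instance;
    # with a unique optimum they are the DP output itself (the lowest-index
    # tie-break is deliberately not permutation-equivariant under exact ties)
    m2 <- site_population_mismatch(g2, q)
    labs <- perm[pt$labels]
    cost <- sum(m2[cbind(seq_along(labs), labs)]) +
      1.5 * sum(pen$values[which(diff(labs) != 0)])
    expect_equal(cost, pt_perm$total_cost, tolerance = 1e-9)
  }
})

test_that("batch inference equals per-query calls and is deterministic", {
  panel <- random_panel(5, n_hap = 8, n_sites = 12, p = 3)
  g <- build_compact_graph(panel)
  set.seed(99)
  pen <- fixed_penalties(runif(11, 1, 2))
  Q <- matrix(rbinom(4 * 12, 1, 0.5), nrow = 4)
  Q[4, ] <- Q[1, ]  # duplicated query
  qs <- query_set(Q, panel$sites, sample_id = c("a", "a", "b", "b"),
                  hap_index = c(1, 2, 1, 2))
  batch <- infer_queryset(g, pen, qs)
  expect_length(batch, 4)
  for (i in 1:4) {
    single <- infer_path(g, pen, Q[i, ])
    expect_equal(batch[[i]]$labels, single$labels)
    expect_equal(batch[[i]]$total_cost, single$total_cost)
  }
  expect_equal(batch[[1]]$labels, batch[[4]]$labels)
})

test_that("marker-masked sites contribute no evidence", {
  panel <- make_panel(rbind(matrix(0L, 2, 6), matrix(1L, 2, 6)),
                      pops = c(1, 1, 2, 2))
  g <- build_compact_graph(panel)
  pen <- uniform_penalties(6)
  q <- c(0L, 0L, 0L, 1L, 1L, 1L)
  qs <- query_set(matrix(q, 1), panel$sites, "s", 1L)
  # masking the pop-2 half leaves only pop-1 evidence: constant painting
  masked <- infer_queryset(g, pen, qs, marker_mask = c(rep(TRUE, 3), rep(FALSE, 3)))
  expect_equal(masked[[1]]$labels, rep(1L, 6))
})

test_that("glance and tidy summarize paintings coherently", {
  panel <- make_panel(rbind(matrix(0L, 2, 4), matrix(1L, 2, 4)),
                      pops = c(1, 1, 2, 2), pop_names = c("A", "B"))
  g <- build_compact_graph(panel)
  pt <- infer_path(g, uniform_penalties(4, value = 1), c(0L, 0L, 1L, 1L),
                   query_id = "q7")
  td <- tidy(pt)
  expect_equal(nrow(td), 4)
  expect_equal(td$population, c("A", "A", "B", "B"))
  gl <- glance(pt)
  expect_equal(gl$n_switches, 1)
  expect_equal(gl$query_id, "q7")
  expect_equal(gl$total_cost, gl$mismatch_cost_sum + gl$w * gl$switch_cost_sum)
  expect_s3_class(autoplot(pt), "ggplot")
})
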