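test_that("a phased two-sample VCF yields four labeled haplotypes", {
  vcf <- write_mini_vcf(withr::local_tempfile(fileext = ".vcf"),
                        samples = c("sA", "sB"),
                        gt_rows = list("0|1\t1|1", "0|0\t0|1", "1|0\t0|0"))
  map <- write_pop_map(withr::local_tempfile(fileext = ".tsv"),
                       c("sA", "sB"), c("popA", "popB"))
  panel <- read_reference_panel(vcf, map)
  expect_equal(nrow(panel$alleles), 4)
  expect_equal(ncol(panel$alleles), 3)
  expect_equal(panel$population_names, c("popA", "popB"))
  expect_equal(panel$hap_population, c(1L, 1L, 2L, 2L))
  expect_true(panel$phased)
  expect_equal(panel$alleles[, 1], c(0L, 1L, 1L, 1L))
})

test_that("unphased reference genotypes collapse to the same graph", {
  gt_phased <- list("0|1\t1|1", "0|0\t0|1", "1|0\t0|0")
  gt_variants <- list(
    list("0/1\t1|1", "0|0\t0|1", "0|1\t0|0"),   # '/' and within-sample swap
    list("1|0\t1/1", "0/0\t1|0", "1/0\t0/0")
  )
  map <- write_pop_map(withr::local_tempfile(fileext = ".tsv"),
                       c("sA", "sB"), c("popA", "popB"))
  base <- build_compact_graph(read_reference_panel(
    write_mini_vcf(withr::local_tempfile(fileext = ".vcf"),
                   c("sA", "sB"), gt_phased), map))
  for (gt in gt_variants) {
    vcf <- write_mini_vcf(withr::local_tempfile(fileext = ".vcf"),
                          c("sA", "sB"), gt)
    panel <- read_reference_panel(vcf, map)
    expect_false(panel$phased)
    expect_true(lapaint:::compact_graphs_equal(base, build_compact_graph(panel)))
  }
})

test_that("a mapped sample missing from the VCF is a named error", {
  vcf <- write_mini_vcf(withr::local_tempfile(fileext = ".vcf"),
                        "sA", list("0|1", "1|1"))
  map <- write_pop_map(withr::local_tempfile(fileext = ".tsv"),
                       c("sA", "sGhost"), c("popA", "popB"))
  expect_error(read_reference_panel(vcf, map), "sGhost")
})

test_that("multi-allelic records are rejected unless enabled", {
  vcf <- write_mini_vcf(withr::local_tempfile(fileext = ".vcf"),
                        c("sA", "sB"), list("0|2\t1|1", "0|0\t0|1"),
                        alt = "C,G")
  map <- write_pop_map(withr::local_tempfile(fileext = ".tsv"),
                       c("sA", "sB"), c("popA", "popB"))
  expect_error(read_reference_panel(vcf, map), "multi-allelic")
  panel <- read_reference_panel(vcf, map, multiallelic = TRUE)
  expect_equal(max(panel$alleles), 2L)
  expect_equal(lapaint:::panel_n_alleles(panel), 3L)
})

test_that("query reading enforces phasing and site agreement", {
  map <- write_pop_map(withr::local_tempfile(fileext = ".tsv"),
                       c("sA", "sB"), c("popA", "popB"))
  ref_vcf <- write_mini_vcf(withr::local_tempfile(fileext = ".vcf"),
                            c("sA", "sB"),
                            list("0|1\t1|1", "0|0\t0|1", "1|0\t0|0"))
  panel <- read_reference_panel(ref_vcf, map)

  q_same <- write_mini_vcf(withr::local_tempfile(fileext = ".vcf"),
                           "q1", list("0|1", "1|0", "0|0"))
  qs <- read_query_haplotypes(q_same, panel)
  expect_equal(nrow(qs$haplotypes), 2)
  expect_equal(attr(qs, "panel_site_index"), 1:3)

  q_unphased <- write_mini_vcf(withr::local_tempfile(fileext = ".vcf"),
                               "q1", list("0/1", "1|0", "0|0"))
  expect_error(read_query_haplotypes(q_unphased, panel), "phased")

  q_extra <- write_mini_vcf(withr::local_tempfile(fileext = ".vcf"),
                            "q1", list("0|1", "1|0", "0|0", "1|1"),
                            pos = c(1000, 2000, 3000, 4000))
  expect_error(read_query_haplotypes(q_extra, panel), "intersect")
  expect_message(
    qs2 <- read_query_haplotypes(q_extra, panel, intersect = TRUE),
    "kept 3 shared sites")
  expect_equal(ncol(qs2$haplotypes), 3)
  expect_equal(attr(qs2, "panel_site_index"), 1:3)

  q_none <- write_mini_vcf(withr::local_tempfile(fileext = ".vcf"),
                           "q1", list("0|1"), pos = 99L)
  expect_error(read_query_haplotypes(q_none, panel, intersect = TRUE),
               "no sites")
})

test_that("genetic map dialects are auto-detected and equivalent", {
  hapmap <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Chromosome\tPosition(bp)\tRate(cM/Mb)\tMap(cM)",
               "1\t100\t1.0\t0.0",
               "1\t1100\t2.0\t0.001",
               "1\t2100\t0.0\t0.003"), hapmap)
  plink <- withr::local_tempfile(fileext = ".map")
  writeLines(c("1\trs1\t0.0\t100",
               "1\trs2\t0.001\t1100",
               "1\trs3\t0.003\t2100"), plink)
  m1 <- read_genetic_map(hapmap)
  m2 <- read_genetic_map(plink)
  expect_equal(nrow(m1), 3)
  expect_equal(m1$pos, m2$pos)
  expect_equal(m1$cM, m2$cM)

  bad <- withr::local_tempfile(fileext = ".map")
  writeLines(c("1\trs1\t0.5\t100", "1\trs2\t0.1\t1100"), bad)
  expect_error(read_genetic_map(bad), "row 2")
  empty <- withr::local_tempfile(fileext = ".map")
  writeLines(character(0), empty)
  expect_error(read_genetic_map(empty), "empty")
})

test_that("panel VCF round trip preserves alleles and labels", {
  for (seed in 1:5) {
    panel <- random_panel(seed, n_hap = 6, n_sites = 12, p = 3)
    # diploid samples: both haplotypes of a sample share its population
    panel$hap_population <- rep(1:3, each = 2)
    panel$sample_id <- rep(paste0("S", 1:3), each = 2)
    panel$hap_index <- rep(1:2, 3)
    vcf <- withr::local_tempfile(fileext = ".vcf")
    write_haplotypes_vcf(panel, vcf)
    pm <- write_pop_map(withr::local_tempfile(fileext = ".tsv"),
                        paste0("S", 1:3),
                        panel$population_names[panel$hap_population[c(1, 3, 5)]])
    back <- read_reference_panel(vcf, pm)
    expect_identical(back$alleles, panel$alleles)
    expect_equal(back$hap_population, panel$hap_population)
    expect_equal(back$sites$pos, panel$sites$pos)
  }
})

test_that("compact panel round trip reproduces the graph node sets", {
  for (seed in 1:25) {
    panel <- random_panel(seed, n_hap = sample(4:10, 1),
                          n_sites = sample(3:15, 1),
                          p = sample(2:4, 1), missing_rate = 0.05)
    g <- build_compact_graph(panel)
    path <- withr::local_tempfile(fileext = ".vcf")
    write_compact_panel(g, path)
    g2 <- read_compact_panel(path)
    expect_true(lapaint:::compact_graphs_equal(g, g2))
  }
})

test_that("writing an empty compact graph errors", {
  g <- lapaint:::new_compact_graph(array(FALSE, dim = c(2, 2, 0)),
                                   make_sites(integer(0)), c("A", "B"))
  expect_error(write_compact_panel(g, withr::local_tempfile()), "zero sites")
})

test_that("painting output follows the per-site and segment conventions", {
  sites <- make_sites(c(100L, 200L, 300L))
  pt <- lapaint:::new_ancestry_painting(c(1L, 1L, 2L), 0, 0, 0, "q_1",
                                        sites, c("A", "B"), 1.5)
  prefix <- withr::local_tempfile()
  files <- write_painting(pt, c("A", "B"), prefix)
  site_lines <- readLines(files[1])
  expect_equal(site_lines[1], "#chrom\tpos\tq_1")
  expect_equal(length(site_lines), 4)
  segs <- read.table(files[2], header = TRUE, sep = "\t")
  expect_equal(segs$start_pos, c(100L, 300L))
  expect_equal(segs$end_pos, c(300L, 301L))
  expect_equal(segs$population, c("A", "B"))

  pt2 <- lapaint:::new_ancestry_painting(c(2L, 2L, 2L), 0, 0, 0, "q_2",
                                         sites, c("A", "B"), 1.5)
  files2 <- write_painting(list(pt, pt2), c("A", "B"), withr::local_tempfile())
  expect_equal(strsplit(readLines(files2[1])[1], "\t")[[1]],
               c("#chrom", "pos", "q_1", "q_2"))

  pt3 <- lapaint:::new_ancestry_painting(c(1L, 2L), 0, 0, 0, "q_3",
                                         make_sites(c(10L, 20L)),
                                         c("A", "B"), 1.5)
  expect_error(write_painting(list(pt, pt3), c("A", "B"),
                              withr::local_tempfile()),
               "share one site list")
})
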