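# Fixtures are built in code; nothing is stored on disk.

make_sites <- function(pos, chrom = "1") {
  tibble::tibble(chrom = chrom, pos = as.integer(pos),
                 id = paste0("s", seq_along(pos)), ref = "A", alt = "C")
}

make_panel <- function(alleles, pops, pop_names = NULL, pos = NULL,
                       phased = TRUE) {
  alleles <- as.matrix(alleles)
  if (is.null(pop_names)) pop_names <- paste0("P", seq_len(max(pops)))
  if (is.null(pos)) pos <- seq_len(ncol(alleles)) * 1000L
  haplotype_panel(alleles, make_sites(pos), pops, pop_names, phased = phased)
}

# Random bi-allelic panel with >= 1 haplotype per population.
random_panel <- function(seed, n_hap = 8, n_sites = 10, p = 2,
                         missing_rate = 0) {
  set.seed(seed)
  alleles <- matrix(rbinom(n_hap * n_sites, 1, runif(n_sites, 0.1, 0.9)[
    rep(seq_len(n_sites), each = n_hap)]), nrow = n_hap)
  if (missing_rate > 0) {
    alleles[runif(length(alleles)) < missing_rate] <- NA_integer_
  }
  pops <- c(seq_len(p), sample.int(p, n_hap - p, replace = TRUE))
  make_panel(alleles, pops)
}

# Switch penalties built directly (values in [1, 2]).
fixed_penalties <- function(values) {
  structure(list(values = values, raw_rates = rep(NA_real_, length(values)),
                 normalization_min = NA_real_, normalization_max = NA_real_,
                 pos_left = seq_along(values), pos_right = seq_along(values) + 1),
            class = "switch_penalties")
}

uniform_penalties <- function(n_sites, value = 2) {
  fixed_penalties(rep(value, n_sites - 1))
}

# Random small inference instance for oracle-equivalence checks.
random_instance <- function(seed, max_n = 10, max_p = 3, max_hap = 8,
                            w_choices = c(0.5, 1.5, 3), missing_rate = 0) {
  set.seed(seed)
  n <- sample(2:max_n, 1)
  p <- sample(2:max_p, 1)
  n_hap <- sample(p:max_hap, 1)
  panel <- random_panel(seed + 7919, n_hap = max(n_hap, p), n_sites = n, p = p,
                        missing_rate = missing_rate)
  graph <- build_compact_graph(panel)
  penalties <- fixed_penalties(runif(n - 1, 1, 2))
  query <- rbinom(n, 1, 0.5)
  if (missing_rate > 0) query[runif(n) < missing_rate] <- NA_integer_
  params <- penalty_params(w = sample(w_choices, 1))
  list(graph = graph, penalties = penalties, query = query, params = params)
}

# Minimal VCF text written from explicit GT strings.
write_mini_vcf <- function(path, samples, gt_rows, pos = NULL,
                           ref = "A", alt = "C") {
  n <- length(gt_rows)
  if (is.null(pos)) pos <- seq_len(n) * 1000L
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(n), function(j) {
    paste(c("1", pos[j], paste0("s", j), ref, alt, ".", "PASS", ".", "GT",
            gt_rows[[j]]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

write_pop_map <- function(path, samples, pops) {
  writeLines(paste(samples, pops, sep = "\t"), path)
  path
}
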