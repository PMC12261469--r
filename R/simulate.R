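#' Define a synthetic admixture scenario
#'
#' The generator emulates the statistical structure of a forward admixture
#' simulation at desk scale: founder populations diverge under a
#' Balding-Nichols allele-frequency model, an admixed population descends
#' from founders g generations back (crossovers Poisson on the genetic
#' map), and a small genotyping error is added to reference and admixed
#' haplotypes alike. Reference and founder haplotypes are disjoint, so
#' queries are never copies of panel rows.
#'
#' @param p Number of founder populations (default 3).
#' @param n_sites Number of bi-allelic sites (default 5000).
#' @param fst Divergence parameter F in (0, 1) of the Balding-Nichols
#'   model (default 0.2, an inter-continental level of differentiation).
#' @param n_ref_per_pop Reference haplotypes per population (default 100).
#' @param n_founder_per_pop Founder haplotypes per population, held out
#'   from the reference panel (default 50).
#' @param n_queries Number of admixed query haplotypes; keep even so they
#'   pair into diploid individuals (default 200).
#' @param generations Generations g since the admixture event (default 15).
#' @param admixture_proportions Length-p simplex of ancestry proportions
#'   (default equal).
#' @param error_rate Per-allele flip probability (default 2e-4, i.e. 0.02%
#'   genotyping error).
#' @param chrom_length_bp Chromosome length in bp (default 1e7, giving an
#'   array-like marker density of one site per 2 kb at the default
#'   `n_sites`).
#' @param map_style `"uniform"` (constant recombination rate) or
#'   `"hotspot"` (cM concentrated into 5% of intervals over a low
#'   background, exercising non-uniform switch penalties; default).
#' @param avg_rate_cM_per_Mb Chromosome-average recombination rate
#'   (default 1.46 cM/Mb).
#' @param seed Integer seed; every random draw derives from it.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(p = 3, n_sites = 5000, fst = 0.2,
                         n_ref_per_pop = 100, n_founder_per_pop = 50,
                         n_queries = 200, generations = 15,
                         admixture_proportions = rep(1 / p, p),
                         error_rate = 2e-4, chrom_length_bp = 1e7,
                         map_style = c("hotspot", "uniform"),
                         avg_rate_cM_per_Mb = 1.46, seed = 1) {
  map_style <- match.arg(map_style)
  if (fst <= 0 || fst >= 1) abort("fst must lie in (0, 1)")
  if (generations < 1) abort("generations must be >= 1")
  if (length(admixture_proportions) != p) {
    abort("admixture_proportions must have length p")
  }
  if (abs(sum(admixture_proportions) - 1) > 1e-12) {
    abort("admixture_proportions must sum to 1")
  }
  if (error_rate < 0 || error_rate >= 1) abort("error_rate must lie in [0, 1)")
  structure(
    list(p = p, n_sites = n_sites, fst = fst,
         n_ref_per_pop = n_ref_per_pop,
         n_founder_per_pop = n_founder_per_pop,
         n_queries = n_queries, generations = generations,
         admixture_proportions = admixture_proportions,
         error_rate = error_rate, chrom_length_bp = chrom_length_bp,
         map_style = map_style, avg_rate_cM_per_Mb = avg_rate_cM_per_Mb,
         seed = as.integer(seed)),
    class = "sim_scenario"
  )
}

# Deterministic child seeds so each sub-operation is reproducible on its own.
derive_seeds <- function(seed, k) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, k)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(value) {
  if (is.null(value)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", value, envir = globalenv())
  }
}

#' Draw diverged population allele frequencies (Balding-Nichols)
#'
#' Per site an ancestral frequency q ~ Uniform(0.05, 0.95) is drawn; each
#' population's frequency is Beta(q(1-F)/F, (1-q)(1-F)/F) with F the
#' divergence parameter, so across-population variance is F q(1-q).
#'
#' @param p Number of populations.
#' @param n_sites Number of sites.
#' @param fst Divergence F in (0, 1).
#' @param seed Integer seed.
#' @return An n_sites x p matrix of alternate-allele frequencies.
#' @export
draw_population_frequencies <- function(p, n_sites, fst, seed) {
  if (fst <= 0 || fst >= 1) abort("fst must lie in (0, 1)")
  set.seed(seed)
  q <- runif(n_sites, 0.05, 0.95)
  shape_scale <- (1 - fst) / fst
  freqs <- matrix(rbeta(n_sites * p,
                        shape1 = rep(q * shape_scale, p),
                        shape2 = rep((1 - q) * shape_scale, p)),
                  nrow = n_sites, ncol = p)
  attr(freqs, "ancestral") <- q
  freqs
}

#' Sample founder and reference haplotype pools
#'
#' Alleles are drawn independently per site from each population's
#' frequency; the pool is split into disjoint founder and reference
#' subsets per population.
#'
#' @param freqs Site x population frequency matrix.
#' @param n_founder_per_pop,n_ref_per_pop Haplotypes per population in each
#'   subset.
#' @param seed Integer seed.
#' @return A list with `founders` and `reference`, each a list (per
#'   population) of haplotype x site 0/1 matrices.
#' @export
simulate_haplotype_pool <- function(freqs, n_founder_per_pop, n_ref_per_pop,
                                    seed) {
  set.seed(seed)
  p <- ncol(freqs)
  n <- nrow(freqs)
  n_tot <- n_founder_per_pop + n_ref_per_pop
  founders <- vector("list", p)
  reference <- vector("list", p)
  for (l in seq_len(p)) {
    pool <- matrix(rbinom(n_tot * n, 1L, rep(freqs[, l], each = n_tot)),
                   nrow = n_tot, ncol = n)
    storage.mode(pool) <- "integer"
    founders[[l]] <- pool[seq_len(n_founder_per_pop), , drop = FALSE]
    reference[[l]] <- pool[n_founder_per_pop + seq_len(n_ref_per_pop), ,
                           drop = FALSE]
  }
  list(founders = founders, reference = reference)
}

# A synthetic genetic map over [1, chrom_length_bp]. "uniform" is a
# constant rate; "hotspot" keeps a 0.1 cM/Mb background and concentrates
# the remaining genetic length into 5% of the anchor intervals, mimicking
# recombination hotspots.
simulate_genetic_map <- function(chrom_length_bp, style = "hotspot",
                                 avg_rate_cM_per_Mb = 1.46, seed = 1,
                                 n_anchors = 201, chrom = "1") {
  pos <- unique(round(seq(1, chrom_length_bp, length.out = n_anchors)))
  widths_mb <- diff(pos) / 1e6
  total_cM <- avg_rate_cM_per_Mb * (chrom_length_bp - 1) / 1e6
  if (style == "uniform") {
    rates <- rep(avg_rate_cM_per_Mb, length(widths_mb))
  } else {
    set.seed(seed)
    base <- 0.1
    n_int <- length(widths_mb)
    hot <- sample.int(n_int, max(1L, round(0.05 * n_int)))
    rates <- rep(base, n_int)
    excess <- total_cM - sum(base * widths_mb)
    share <- runif(length(hot))
    rates[hot] <- rates[hot] + excess * (share / sum(share)) / widths_mb[hot]
  }
  genetic_map(pos, c(0, cumsum(rates * widths_mb)), chrom = chrom)
}

#' Simulate one admixed haplotype as a founder mosaic
#'
#' Crossover count ~ Poisson(g * L) with L the map length in Morgans;
#' breakpoints are uniform on the genetic scale and mapped back to bp.
#' Each inter-breakpoint segment draws its ancestry from the admixture
#' proportions and copies its alleles from a uniformly chosen founder
#' haplotype of that ancestry (a fresh founder per segment).
#'
#' @param founders List (per population) of founder haplotype matrices.
#' @param map A [genetic_map()].
#' @param site_pos Integer vector of site positions (bp).
#' @param g Generations since admixture.
#' @param proportions Length-p ancestry simplex.
#' @param seed Integer seed.
#' @return A list with `haplotype` (length-n integer), `labels` (per-site
#'   true ancestry), and `breakpoints` (bp positions).
#' @export
simulate_admixed_haplotype <- function(founders, map, site_pos, g,
                                       proportions, seed) {
  set.seed(seed)
  sim_admixed_one(founders, map, site_pos, g, proportions)
}

sim_admixed_one <- function(founders, map, site_pos, g, proportions) {
  p <- length(founders)
  active <- which(proportions > 0)
  if (any(vapply(founders[active], nrow, 1L) == 0)) {
    abort("every population with nonzero proportion needs founder haplotypes")
  }
  L <- map_length_morgans(map)
  if (L <= 0) abort("genetic map has zero length")
  k <- rpois(1, g * L)
  bp_cM <- sort(runif(k, min(map$cM), max(map$cM)))
  site_cM <- interpolate_cM(map, site_pos)
  seg_of_site <- findInterval(site_cM, bp_cM) + 1L
  n_seg <- k + 1L
  seg_anc <- sample.int(p, n_seg, replace = TRUE, prob = proportions)
  hap <- integer(length(site_pos))
  labels <- integer(length(site_pos))
  for (s in seq_len(n_seg)) {
    idx <- which(seg_of_site == s)
    anc <- seg_anc[s]
    if (length(idx) > 0) {
      donor <- sample.int(nrow(founders[[anc]]), 1)
      hap[idx] <- founders[[anc]][donor, idx]
      labels[idx] <- anc
    }
  }
  bp_pos <- if (k > 0) approx(map$cM, map$pos, xout = bp_cM, ties = "ordered")$y
            else numeric(0)
  list(haplotype = hap, labels = labels, breakpoints = bp_pos)
}

#' Add independent genotyping errors
#'
#' Each allele is replaced, independently with probability `rate`, by a
#' different allele code drawn uniformly from the remaining K-1 codes
#' (for bi-allelic data this is a flip). Missing alleles are untouched.
#'
#' @param haplotypes Integer haplotype x site matrix.
#' @param rate Flip probability in `[0, 1)`.
#' @param seed Integer seed.
#' @param K Number of allele codes (default 2).
#' @return The perturbed matrix.
#' @export
add_genotyping_error <- function(haplotypes, rate, seed, K = 2) {
  if (rate < 0 || rate >= 1) abort("rate must lie in [0, 1)")
  if (rate == 0) return(haplotypes)
  set.seed(seed)
  flip <- matrix(runif(length(haplotypes)) < rate, nrow = nrow(haplotypes))
  flip[is.na(haplotypes)] <- FALSE
  idx <- which(flip)
  if (length(idx) > 0) {
    shift <- sample.int(K - 1L, length(idx), replace = TRUE)
    haplotypes[idx] <- (haplotypes[idx] + shift) %% K
  }
  haplotypes
}

#' Run a full synthetic admixture scenario
#'
#' Composes frequency divergence, founder/reference pools, admixed query
#' haplotypes with ground-truth ancestry tracts, and genotyping error into
#' the objects the rest of the package consumes. Optionally writes
#' on-disk fixtures (reference VCF, population map, query VCF, genetic
#' map, truth TSV) in the formats the readers and the command-line
#' interface accept.
#'
#' @param scenario A [sim_scenario()].
#' @param out_dir Optional directory for fixture files.
#' @return An object of class `sim_result`: `panel` (reference
#'   [haplotype_panel()]), `queries` ([query_set()]), `truth` (query x
#'   site matrix of population indices), `founders`, `map`, `breakpoints`,
#'   `scenario`, and (if written) `files`.
#' @export
simulate_scenario <- function(scenario, out_dir = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  seeds <- derive_seeds(scenario$seed, 6 + scenario$n_queries)
  p <- scenario$p
  pop_names <- paste0("POP", seq_len(p))

  freqs <- draw_population_frequencies(p, scenario$n_sites, scenario$fst,
                                       seeds[1])
  pools <- simulate_haplotype_pool(freqs, scenario$n_founder_per_pop,
                                   scenario$n_ref_per_pop, seeds[2])
  map <- simulate_genetic_map(scenario$chrom_length_bp, scenario$map_style,
                              scenario$avg_rate_cM_per_Mb, seeds[3])
  set.seed(seeds[4])
  site_pos <- sort(sample.int(scenario$chrom_length_bp, scenario$n_sites))
  sites <- tibble::tibble(
    chrom = "1", pos = site_pos,
    id = paste0("snp", seq_len(scenario$n_sites)),
    ref = "A", alt = "C"
  )

  ref_alleles <- do.call(rbind, pools$reference)
  hap_population <- rep(seq_len(p), vapply(pools$reference, nrow, 1L))
  n_ref_hap <- nrow(ref_alleles)
  if (n_ref_hap %% 2 != 0) abort("reference haplotype count must be even")
  ref_alleles <- add_genotyping_error(ref_alleles, scenario$error_rate,
                                      seeds[5])
  sample_id <- rep(sprintf("R%04d", seq_len(n_ref_hap / 2)), each = 2)
  panel <- haplotype_panel(ref_alleles, sites, hap_population, pop_names,
                           phased = TRUE, sample_id = sample_id,
                           hap_index = rep(1:2, n_ref_hap / 2))

  truth <- matrix(0L, nrow = scenario$n_queries, ncol = scenario$n_sites)
  qhaps <- matrix(0L, nrow = scenario$n_queries, ncol = scenario$n_sites)
  breakpoints <- vector("list", scenario$n_queries)
  for (i in seq_len(scenario$n_queries)) {
    one <- simulate_admixed_haplotype(pools$founders, map, site_pos,
                                      scenario$generations,
                                      scenario$admixture_proportions,
                                      seeds[6 + i])
    qhaps[i, ] <- one$haplotype
    truth[i, ] <- one$labels
    breakpoints[[i]] <- one$breakpoints
  }
  qhaps <- add_genotyping_error(qhaps, scenario$error_rate, seeds[6])
  q_sample <- rep(sprintf("Q%04d", seq_len(ceiling(scenario$n_queries / 2))),
                  each = 2)[seq_len(scenario$n_queries)]
  q_hap_index <- rep(1:2, length.out = scenario$n_queries)
  queries <- query_set(qhaps, sites, q_sample, q_hap_index)

  result <- structure(
    list(panel = panel, queries = queries, truth = truth,
         founders = pools$founders, map = map, breakpoints = breakpoints,
         scenario = scenario),
    class = "sim_result"
  )
  if (!is.null(out_dir)) {
    result$files <- write_sim_fixtures(result, out_dir)
  }
  result
}

#' @export
print.sim_result <- function(x, ...) {
  sc <- x$scenario
  cat(sprintf(
    "<sim_result> %d populations, %d sites, %d reference + %d founder haplotypes/pop, %d queries (g=%d, fst=%.2f)\n",
    sc$p, sc$n_sites, sc$n_ref_per_pop, sc$n_founder_per_pop,
    sc$n_queries, sc$generations, sc$fst))
  invisible(x)
}

write_sim_fixtures <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    reference_vcf = file.path(out_dir, "reference.vcf"),
    pop_map = file.path(out_dir, "pop_map.tsv"),
    query_vcf = file.path(out_dir, "query.vcf"),
    genetic_map = file.path(out_dir, "genetic.map"),
    truth = file.path(out_dir, "truth.tsv")
  )
  write_haplotypes_vcf(result$panel, paths$reference_vcf)
  samples <- result$panel$sample_id[seq(1, length(result$panel$sample_id), 2)]
  pops <- result$panel$population_names[
    result$panel$hap_population[seq(1, length(result$panel$sample_id), 2)]]
  writeLines(paste(samples, pops, sep = "\t"), paths$pop_map)
  write_haplotypes_vcf(result$queries, paths$query_vcf)
  # PLINK .map style: chrom id cM bp
  writeLines(paste("1", paste0("m", seq_len(nrow(result$map))),
                   result$map$cM, result$map$pos, sep = "\t"),
             paths$genetic_map)
  ids <- paste0(result$queries$sample_id, "_", result$queries$hap_index)
  pop_names <- result$panel$population_names
  con <- file(paths$truth, "w")
  writeLines(paste(c("#chrom", "pos", ids), collapse = "\t"), con)
  lab_chr <- matrix(pop_names[result$truth], nrow = nrow(result$truth))
  writeLines(paste(result$queries$sites$chrom, result$queries$sites$pos,
                   apply(lab_chr, 2, paste, collapse = "\t"), sep = "\t"),
             con)
  close(con)
  paths
}
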