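#' Read a labeled reference panel from VCF
#'
#' Each diploid sample listed in the population map contributes two
#' haplotype rows carrying the sample's population label. Unphased
#' genotypes (`/` separator) are accepted for the reference panel because
#' graph collapsing is phase-insensitive; the panel is then flagged
#' `phased = FALSE`. Missing alleles (`.`) become `NA` and contribute no
#' graph node.
#'
#' @param vcf_path Path to a VCF (optionally bgzipped) with GT for all
#'   mapped samples.
#' @param pop_map_path Two-column TSV `sample_id<TAB>population_name`
#'   (header optional). Population order follows first appearance in the
#'   map. Samples in the VCF but not in the map are ignored; samples in the
#'   map but absent from the VCF are an error.
#' @param multiallelic Allow records with more than one ALT allele
#'   (allele codes 0..K-1). Default `FALSE`: such records are an error.
#' @return A [haplotype_panel()].
#' @export
read_reference_panel <- function(vcf_path, pop_map_path, multiallelic = FALSE) {
  pop_map <- read_pop_map(pop_map_path)
  parsed <- read_vcf_haplotypes(vcf_path, samples = pop_map$sample_id,
                                multiallelic = multiallelic,
                                require_phased = FALSE)
  pop_names <- unique(pop_map$population)
  pop_of_sample <- setNames(match(pop_map$population, pop_names),
                            pop_map$sample_id)
  hap_population <- as.integer(pop_of_sample[parsed$sample_id])
  haplotype_panel(
    alleles = parsed$alleles,
    sites = parsed$sites,
    hap_population = hap_population,
    population_names = pop_names,
    phased = parsed$phased,
    sample_id = parsed$sample_id,
    hap_index = parsed$hap_index
  )
}

read_pop_map <- function(path) {
  tab <- read.table(path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE, comment.char = "#",
                    col.names = c("sample_id", "population"))
  if (nrow(tab) > 0 &&
      tolower(tab$sample_id[1]) %in% c("sample", "sample_id", "id")) {
    tab <- tab[-1, , drop = FALSE]
  }
  if (nrow(tab) == 0) abort("population map is empty")
  if (anyDuplicated(tab$sample_id)) {
    abort("population map lists a sample more than once")
  }
  tab
}

# Shared VCF -> haplotype-matrix reader. Returns one row per haplotype
# (two per diploid GT, one per haploid GT).
read_vcf_haplotypes <- function(vcf_path, samples = NULL,
                                multiallelic = FALSE, require_phased = FALSE) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0) abort(paste0("no records in VCF: ", vcf_path))
  vcf_samples <- colnames(vcf@gt)[-1]
  if (is.null(samples)) {
    samples <- vcf_samples
  } else {
    missing_s <- setdiff(samples, vcf_samples)
    if (length(missing_s) > 0) {
      abort(paste0("sample(s) in population map absent from VCF: ",
                   paste(missing_s, collapse = ", ")))
    }
  }
  alt <- fix[, "ALT"]
  n_alt <- lengths(strsplit(ifelse(is.na(alt), "", alt), ",", fixed = TRUE))
  if (!multiallelic && any(n_alt > 1)) {
    abort(paste0(sum(n_alt > 1), " multi-allelic record(s) found; ",
                 "set multiallelic = TRUE to decompose them to K-allele codes"))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[, samples, drop = FALSE]
  unphased_seen <- any(grepl("/", gt, fixed = TRUE), na.rm = TRUE)
  if (require_phased && unphased_seen) {
    abort("query genotypes must be phased ('|' separator); found '/'")
  }
  hap_rows <- list()
  sample_of_row <- character(0)
  hap_index <- integer(0)
  n_rec <- nrow(gt)
  for (s in samples) {
    col <- gt[, s]
    col[is.na(col)] <- "."
    split1 <- sub("^([^/|]*)[/|]?.*$", "\\1", col)
    has_second <- grepl("[/|]", col)
    split2 <- ifelse(has_second, sub("^[^/|]*[/|](.*)$", "\\1", col), NA)
    a1 <- suppressWarnings(as.integer(split1))
    hap_rows[[length(hap_rows) + 1L]] <- a1
    sample_of_row <- c(sample_of_row, s)
    hap_index <- c(hap_index, 1L)
    if (any(has_second)) {
      a2 <- suppressWarnings(as.integer(split2))
      hap_rows[[length(hap_rows) + 1L]] <- a2
      sample_of_row <- c(sample_of_row, s)
      hap_index <- c(hap_index, 2L)
    }
  }
  alleles <- do.call(rbind, hap_rows)
  max_code <- suppressWarnings(max(alleles, na.rm = TRUE))
  if (is.finite(max_code) && any(alleles > n_alt[col(alleles)], na.rm = TRUE)) {
    abort("GT allele code exceeds the number of ALT alleles at a record")
  }
  sites <- tibble::tibble(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    id = ifelse(is.na(fix[, "ID"]), ".", fix[, "ID"]),
    ref = fix[, "REF"],
    alt = ifelse(is.na(alt), ".", alt)
  )
  list(alleles = alleles, sites = sites, sample_id = sample_of_row,
       hap_index = hap_index, phased = !unphased_seen, n_records = n_rec)
}

#' Read phased query haplotypes from VCF, aligned to a panel
#'
#' Queries must be phased: each diploid sample yields two haplotype rows.
#' By default the query's site list must equal the panel's exactly
#' (chromosome, position, REF, ALT, in order); with `intersect = TRUE` both
#' are restricted to the shared sites and the subsetting is logged.
#'
#' @param vcf_path Path to a phased query VCF.
#' @param panel The [haplotype_panel()] the queries will be painted against.
#' @param intersect Subset to shared sites instead of erroring on
#'   differences.
#' @param multiallelic Passed through to the VCF reader.
#' @return A [query_set()]. Attribute `panel_site_index` holds the panel
#'   column indices corresponding to the query's sites (identity in strict
#'   mode); use [subset_panel_sites()] to align the panel when intersecting.
#' @export
read_query_haplotypes <- function(vcf_path, panel, intersect = FALSE,
                                  multiallelic = FALSE) {
  parsed <- read_vcf_haplotypes(vcf_path, samples = NULL,
                                multiallelic = multiallelic,
                                require_phased = TRUE)
  qs <- parsed$sites
  ps <- panel$sites
  qkey <- paste(qs$chrom, qs$pos, qs$ref, qs$alt, sep = "\r")
  pkey <- paste(ps$chrom, ps$pos, ps$ref, ps$alt, sep = "\r")
  q_in_p <- match(qkey, pkey)
  if (!intersect) {
    if (nrow(qs) != nrow(ps) || anyNA(q_in_p) || any(q_in_p != seq_len(nrow(ps)))) {
      abort(paste0("query sites do not match the panel site list ",
                   "(use intersect = TRUE to subset to shared sites)"))
    }
    keep_q <- seq_len(nrow(qs))
    panel_idx <- seq_len(nrow(ps))
  } else {
    keep_q <- which(!is.na(q_in_p))
    if (length(keep_q) == 0) abort("query and panel share no sites")
    panel_idx <- q_in_p[keep_q]
    dropped_q <- nrow(qs) - length(keep_q)
    dropped_p <- nrow(ps) - length(panel_idx)
    inform(sprintf(
      "site intersection: kept %d shared sites (dropped %d query-only, %d panel-only)",
      length(keep_q), dropped_q, dropped_p))
  }
  out <- query_set(
    haplotypes = parsed$alleles[, keep_q, drop = FALSE],
    sites = qs[keep_q, , drop = FALSE],
    sample_id = parsed$sample_id,
    hap_index = parsed$hap_index
  )
  attr(out, "panel_site_index") <- panel_idx
  out
}

#' Restrict a haplotype panel to a subset of sites
#'
#' @param panel A [haplotype_panel()].
#' @param keep Integer vector of site (column) indices to retain, in order.
#' @return A [haplotype_panel()] over the retained sites.
#' @export
subset_panel_sites <- function(panel, keep) {
  haplotype_panel(
    alleles = panel$alleles[, keep, drop = FALSE],
    sites = panel$sites[keep, , drop = FALSE],
    hap_population = panel$hap_population,
    population_names = panel$population_names,
    phased = panel$phased,
    sample_id = panel$sample_id,
    hap_index = panel$hap_index
  )
}

vcf_header_lines <- function(extra = character(0)) {
  c("##fileformat=VCFv4.2",
    paste0("##source=lapaint ",
           as.character(utils::packageVersion("lapaint"))),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    extra)
}

# Assemble and write a VCF from a haplotype matrix whose rows pair into
# samples. `sep` is the GT separator ("|" phased, "/" unphased).
write_haplotype_vcf <- function(alleles, sites, sample_id, path, sep = "|",
                                extra_header = character(0)) {
  if (nrow(alleles) == 0 || ncol(alleles) == 0) abort("nothing to write")
  samples <- unique(sample_id)
  gt_cols <- vapply(samples, function(s) {
    rows <- which(sample_id == s)
    if (length(rows) > 2) abort(paste0("sample ", s, " has >2 haplotypes"))
    block <- alleles[rows, , drop = FALSE]
    block_chr <- matrix(as.character(block), nrow = nrow(block))
    block_chr[is.na(block)] <- "."
    if (nrow(block) == 1) block_chr[1, ]
    else paste(block_chr[1, ], block_chr[2, ], sep = sep)
  }, character(ncol(alleles)))
  gt_cols <- matrix(gt_cols, nrow = ncol(alleles))
  body <- paste(
    sites$chrom, sites$pos, sites$id, sites$ref, sites$alt, ".", "PASS", ".",
    "GT",
    apply(gt_cols, 1, paste, collapse = "\t"),
    sep = "\t")
  header <- c(vcf_header_lines(extra_header),
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Write a haplotype panel (or query set) as a VCF file
#'
#' Companion writer for simulator output and round-trip tests. Haplotype
#' rows are paired into diploid samples by their `sample_id`.
#'
#' @param x A [haplotype_panel()] or [query_set()].
#' @param path Output path (plain-text VCF).
#' @return The path, invisibly.
#' @export
write_haplotypes_vcf <- function(x, path) {
  alleles <- if (inherits(x, "query_set")) x$haplotypes else x$alleles
  sample_id <- x$sample_id
  if (is.null(sample_id)) {
    if (nrow(alleles) %% 2 != 0) {
      abort("cannot pair haplotypes into samples: odd row count and no sample_id")
    }
    sample_id <- rep(sprintf("S%d", seq_len(nrow(alleles) / 2)), each = 2)
  }
  sep <- if (inherits(x, "haplotype_panel") && !x$phased) "/" else "|"
  write_haplotype_vcf(alleles, x$sites, sample_id, path, sep = sep)
}

#' Serialize a compact population graph as VCF
#'
#' The compact panel keeps only population-level information: per site,
#' which (allele, population) pairs exist. The VCF dialect used here has
#' one pseudo-sample column per population; its GT lists the population's
#' present allele codes joined by `/` (e.g. `0`, `1`, `0/1`), or `.` when
#' the population has no observed allele at the site. Population names and
#' the tool version are recorded in header lines, so
#' [read_compact_panel()] reconstructs a graph with identical node sets.
#'
#' @param graph A [build_compact_graph()] result.
#' @param path Output path (plain-text VCF).
#' @return The path, invisibly.
#' @export
write_compact_panel <- function(graph, path) {
  stopifnot(inherits(graph, "compact_population_graph"))
  if (graph$n == 0) abort("cannot write a compact panel with zero sites")
  pres <- graph$present  # K x p x n
  K <- dim(pres)[1]
  codes <- as.character(seq_len(K) - 1L)
  gt_cols <- matrix("", nrow = graph$n, ncol = graph$p)
  for (l in seq_len(graph$p)) {
    gt_cols[, l] <- apply(pres[, l, , drop = FALSE], 3, function(v) {
      present <- codes[v]
      if (length(present) == 0) "." else paste(present, collapse = "/")
    })
  }
  body <- paste(
    graph$sites$chrom, graph$sites$pos, graph$sites$id,
    graph$sites$ref, graph$sites$alt, ".", "PASS", ".", "GT",
    apply(gt_cols, 1, paste, collapse = "\t"),
    sep = "\t")
  extra <- paste0("##compact_populations=",
                  paste(graph$population_names, collapse = ","))
  header <- c(vcf_header_lines(extra),
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", graph$population_names),
                    collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read a compact population graph from its VCF serialization
#'
#' @param path A file written by [write_compact_panel()].
#' @return A `compact_population_graph` with the same node sets.
#' @export
read_compact_panel <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  meta <- vcf@meta
  pop_line <- grep("^##compact_populations=", meta, value = TRUE)
  if (length(pop_line) != 1) {
    abort("not a compact panel: missing ##compact_populations header")
  }
  population_names <- strsplit(sub("^##compact_populations=", "", pop_line),
                               ",", fixed = TRUE)[[1]]
  p <- length(population_names)
  fix <- vcf@fix
  n <- nrow(fix)
  gt <- vcf@gt[, population_names, drop = FALSE]
  alt <- ifelse(is.na(fix[, "ALT"]), ".", fix[, "ALT"])
  n_alt <- lengths(strsplit(ifelse(alt == ".", "", alt), ",", fixed = TRUE))
  K <- max(2L, max(n_alt) + 1L)
  present <- array(FALSE, dim = c(K, p, n))
  for (l in seq_len(p)) {
    toks <- strsplit(gt[, l], "/", fixed = TRUE)
    for (j in seq_len(n)) {
      codes <- suppressWarnings(as.integer(toks[[j]]))
      codes <- codes[!is.na(codes)]
      if (length(codes) > 0) present[codes + 1L, l, j] <- TRUE
    }
  }
  sites <- tibble::tibble(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    id = ifelse(is.na(fix[, "ID"]), ".", fix[, "ID"]),
    ref = fix[, "REF"],
    alt = alt
  )
  new_compact_graph(present, sites, population_names)
}

#' Write ancestry paintings to per-site and segment files
#'
#' Two tab-separated files are produced:
#' * `<prefix>.painting.tsv`: header `#chrom  pos  <query columns>`, one row
#'   per site, population names as values;
#' * `<prefix>.segments.tsv`: `chrom  start_pos  end_pos  hap  population`,
#'   one row per maximal constant-label run, half-open `[start, end)` bp
#'   intervals anchored at site positions (the final run closes at last
#'   position + 1).
#'
#' @param paintings A single [ancestry_painting] or list of them, sharing
#'   one site list.
#' @param population_names Population names indexed by painting labels.
#' @param prefix Output path prefix.
#' @return Character vector of the two file paths, invisibly.
#' @export
write_painting <- function(paintings, population_names, prefix) {
  if (inherits(paintings, "ancestry_painting")) paintings <- list(paintings)
  if (length(paintings) == 0) abort("no paintings to write")
  sites <- paintings[[1]]$sites
  for (pt in paintings) {
    if (is.null(pt$sites) || nrow(pt$sites) != nrow(sites) ||
        any(pt$sites$pos != sites$pos) || any(pt$sites$chrom != sites$chrom)) {
      abort("paintings do not share one site list")
    }
  }
  ids <- vapply(paintings, function(pt) pt$query_id, character(1))
  lab_mat <- vapply(paintings,
                    function(pt) population_names[pt$labels],
                    character(nrow(sites)))
  lab_mat <- matrix(lab_mat, nrow = nrow(sites), dimnames = list(NULL, ids))
  site_path <- paste0(prefix, ".painting.tsv")
  con <- file(site_path, "w")
  writeLines(paste(c("#chrom", "pos", ids), collapse = "\t"), con)
  writeLines(paste(sites$chrom, sites$pos,
                   apply(lab_mat, 1, paste, collapse = "\t"), sep = "\t"), con)
  close(con)

  seg_rows <- purrr::map_dfr(seq_along(paintings), function(i) {
    segment_table(paintings[[i]], population_names)
  })
  seg_path <- paste0(prefix, ".segments.tsv")
  write.table(seg_rows, seg_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(c(site_path, seg_path))
}

# Run-length encode one painting into half-open bp segments.
segment_table <- function(painting, population_names) {
  labs <- painting$labels
  pos <- painting$sites$pos
  chrom <- painting$sites$chrom
  r <- rle(labs)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- c(1L, head(ends_idx, -1) + 1L)
  start_pos <- pos[starts_idx]
  end_pos <- c(pos[starts_idx[-1]], pos[length(pos)] + 1L)
  tibble::tibble(
    chrom = chrom[starts_idx],
    start_pos = start_pos,
    end_pos = end_pos,
    hap = painting$query_id,
    population = population_names[r$values]
  )
}
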