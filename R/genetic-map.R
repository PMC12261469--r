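#' Construct a genetic map
#'
#' A genetic map relates physical position (bp) to cumulative genetic
#' position (centiMorgan) along one chromosome. It supplies the
#' recombination rates that scale the between-population switch penalty.
#'
#' @param pos Integer vector of physical positions (bp), strictly increasing.
#' @param cM Numeric vector of genetic positions (centiMorgan),
#'   non-decreasing, same length as `pos`.
#' @param chrom Optional chromosome name (metadata only).
#' @return A tibble of class `genetic_map` with columns `pos` and `cM`.
#' @export
genetic_map <- function(pos, cM, chrom = NA_character_) {
  if (length(pos) != length(cM)) abort("pos and cM must have equal length")
  if (length(pos) == 0) abort("genetic map is empty")
  ord <- order(pos)
  pos <- as.numeric(pos)[ord]
  cM <- as.numeric(cM)[ord]
  keep <- !duplicated(pos)
  pos <- pos[keep]
  cM <- cM[keep]
  if (any(diff(pos) <= 0)) abort("map positions must be strictly increasing")
  bad <- which(diff(cM) < 0)
  if (length(bad) > 0) {
    abort(paste0("genetic positions decrease at map row ", bad[1] + 1))
  }
  out <- tibble::tibble(pos = pos, cM = cM)
  class(out) <- c("genetic_map", class(out))
  attr(out, "chrom") <- chrom
  out
}

#' Read a genetic map file
#'
#' Two common dialects are supported and auto-detected:
#' * PLINK `.map` style: four columns `chrom id cM bp`, no header;
#' * HapMap style: four columns `chrom bp rate(cM/Mb) cM`, usually with a
#'   header line.
#'
#' Detection: a non-numeric token in columns 2-4 of the first line marks a
#' header (HapMap style); otherwise a non-numeric column 2 marks PLINK ids;
#' if both parse as numeric, the column whose values are strictly increasing
#' integers and largest is taken as bp (column 4 = PLINK, column 2 = HapMap).
#'
#' @param path Path to the map file (plain text, whitespace-delimited).
#' @return A [genetic_map()] with entries sorted by position; duplicate
#'   positions keep the first entry.
#' @export
read_genetic_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(paste0("genetic map file is empty: ", path))
  first <- strsplit(trimws(lines[[1]]), "[ \t,]+")[[1]]
  numish <- function(x) !is.na(suppressWarnings(as.numeric(x)))
  # PLINK data rows may carry non-numeric ids in column 2, but columns 3-4
  # (cM, bp) are numeric; only a header line breaks that.
  has_header <- length(first) >= 4 && !all(numish(first[3:4]))
  tab <- read.table(text = lines, header = has_header,
                    stringsAsFactors = FALSE, comment.char = "")
  if (ncol(tab) < 4) abort("genetic map must have at least 4 columns")
  chrom <- as.character(tab[[1]][1])
  if (has_header || !numish(tab[[2]][1])) {
    if (has_header) {
      pos <- as.numeric(tab[[2]]); cm <- as.numeric(tab[[4]])
    } else {
      # PLINK: chrom id cM bp
      pos <- as.numeric(tab[[4]]); cm <- as.numeric(tab[[3]])
    }
  } else {
    c2 <- as.numeric(tab[[2]]); c3 <- as.numeric(tab[[3]]); c4 <- as.numeric(tab[[4]])
    plink_like <- all(c4 == round(c4)) && max(c4) >= max(c2)
    if (plink_like) { pos <- c4; cm <- c3 } else { pos <- c2; cm <- c4 }
  }
  if (anyNA(pos) || anyNA(cm)) abort("non-numeric values in genetic map columns")
  # Duplicate-position collapse keeps the first occurrence; a later duplicate
  # with a larger cM would otherwise smuggle in a decreasing check bypass,
  # so validate monotonicity on the raw order first.
  ord <- order(pos)
  pos <- pos[ord]; cm <- cm[ord]
  keep <- !duplicated(pos)
  bad <- which(diff(cm[keep]) < 0)
  if (length(bad) > 0) {
    abort(paste0("genetic positions decrease at map row ", bad[1] + 1))
  }
  genetic_map(pos[keep], cm[keep], chrom = chrom)
}

# cM at arbitrary bp positions: piecewise-linear inside the map, constant
# extrapolation of the flanking interval's rate outside it (a single-entry
# map extends at rate 0). Interpolated cM differences are clipped at >= 0
# downstream.
interpolate_cM <- function(map, pos) {
  mp <- map$pos
  mc <- map$cM
  if (length(mp) == 1) {
    return(rep(mc, length(pos)))
  }
  out <- approx(mp, mc, xout = pos, rule = 2)$y
  left_rate <- (mc[2] - mc[1]) / (mp[2] - mp[1])
  k <- length(mp)
  right_rate <- (mc[k] - mc[k - 1]) / (mp[k] - mp[k - 1])
  low <- pos < mp[1]
  high <- pos > mp[k]
  out[low] <- mc[1] - (mp[1] - pos[low]) * max(left_rate, 0)
  out[high] <- mc[k] + (pos[high] - mp[k]) * max(right_rate, 0)
  out
}

# Total map length in Morgans (used by the admixture simulator).
map_length_morgans <- function(map) {
  (max(map$cM) - min(map$cM)) / 100
}
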