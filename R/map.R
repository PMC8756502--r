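#' Genetic maps
#'
#' A genetic map is a table of anchor points `(chrom, pos, cM)` giving the
#' cumulative genetic distance (centimorgans) at physical positions (base
#' pairs, 1-based as in VCF). Genetic positions between anchors are obtained
#' by piecewise-linear interpolation; positions beyond the anchored range are
#' clamped to the boundary value (extrapolation at rate 0).
#'
#' @param chrom character vector of chromosome labels.
#' @param pos integer vector of physical positions (bp).
#' @param cM numeric vector of map positions (centimorgans).
#' @return An object of class `genetic_map` (a data frame with columns
#'   `chrom`, `pos`, `cM`).
#' @examples
#' gm <- genetic_map(rep("1", 2), c(1L, 1000000L), c(0, 1))
#' interpolate_map(gm, "1", 500000)  # 0.5 cM
#' @export
genetic_map <- function(chrom, pos, cM) {
  if (length(chrom) == 0L) stop("empty genetic map")
  m <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                  cM = as.numeric(cM), stringsAsFactors = FALSE)
  m <- m[order(m$chrom, m$pos), , drop = FALSE]
  for (ch in unique(m$chrom)) {
    sub <- m[m$chrom == ch, ]
    if (nrow(sub) < 2L) stop("genetic map needs >= 2 anchors per chromosome")
    if (any(diff(sub$pos) <= 0)) stop("map positions must be strictly increasing")
    if (any(diff(sub$cM) < 0)) stop("map cM values must be non-decreasing")
  }
  rownames(m) <- NULL
  class(m) <- c("genetic_map", "data.frame")
  m
}

#' Build a uniform-rate genetic map
#'
#' Convenience constructor for synthetic genomes: each chromosome gets two
#' anchors, at bp 1 (0 cM) and at its physical length (its genetic length),
#' i.e. a constant recombination rate along the chromosome.
#'
#' @param chrom_lengths_bp named numeric vector of chromosome lengths in bp;
#'   names are chromosome labels.
#' @param morgans numeric vector (recycled) of genetic lengths in Morgans.
#' @return A `genetic_map`.
#' @export
uniform_genetic_map <- function(chrom_lengths_bp, morgans = 1) {
  stopifnot(!is.null(names(chrom_lengths_bp)))
  morgans <- rep_len(morgans, length(chrom_lengths_bp))
  genetic_map(chrom = rep(names(chrom_lengths_bp), each = 2L),
              pos = as.vector(rbind(1, chrom_lengths_bp)),
              cM = as.vector(rbind(0, morgans * 100)))
}

#' Interpolate genetic map positions
#'
#' @param map a `genetic_map`.
#' @param chrom chromosome label(s), recycled against `pos`.
#' @param pos physical position(s) in bp.
#' @return Numeric vector of map positions in cM.
#' @export
interpolate_map <- function(map, chrom, pos) {
  stopifnot(inherits(map, "genetic_map"))
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.numeric(pos), n)
  out <- numeric(n)
  for (ch in unique(chrom)) {
    sub <- map[map$chrom == ch, ]
    if (nrow(sub) == 0L) stop("chromosome not in map: ", ch)
    i <- chrom == ch
    out[i] <- approx(sub$pos, sub$cM, xout = pos[i], rule = 2)$y
  }
  out
}

# Inverse interpolation: cM -> bp (used when placing recombination
# breakpoints drawn on the genetic scale). Monotone maps only.
map_position_at_cM <- function(map, chrom, cM) {
  sub <- map[map$chrom == chrom, ]
  if (nrow(sub) == 0L) stop("chromosome not in map: ", chrom)
  if (length(cM) == 0L) return(numeric(0))
  approx(sub$cM, sub$pos, xout = cM, rule = 2, ties = "ordered")$y
}

#' Chromosome extents of a genetic map
#'
#' @param map a `genetic_map`.
#' @return Data frame with one row per chromosome: `chrom`, `start_bp`,
#'   `end_bp` (last anchor), `cM` (genetic length), `morgans`.
#' @export
map_chromosomes <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  chs <- unique(map$chrom)
  out <- do.call(rbind, lapply(chs, function(ch) {
    sub <- map[map$chrom == ch, ]
    data.frame(chrom = ch, start_bp = min(sub$pos), end_bp = max(sub$pos),
               cM = max(sub$cM) - min(sub$cM), stringsAsFactors = FALSE)
  }))
  out$morgans <- out$cM / 100
  rownames(out) <- NULL
  out
}
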