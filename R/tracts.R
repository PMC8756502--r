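#' Genetic length of ancestry tracts
#'
#' Tracts are half-open bp intervals `[start, end)`; the genetic length is
#' `cM(end) - cM(start)` under clamped interpolation, so tracts that tile a
#' chromosome have genetic lengths summing exactly to its map length.
#'
#' @param tracts data frame with `chrom`, `start`, `end`.
#' @param map a [genetic_map].
#' @return Numeric vector of lengths in cM.
#' @export
tract_cM <- function(tracts, map) {
  interpolate_map(map, tracts$chrom, tracts$end) -
    interpolate_map(map, tracts$chrom, tracts$start)
}

# Basic structural checks: half-open, positive-length, non-overlapping
# within each haplotype. Used by tests and on tract-file input.
validate_tracts <- function(tracts) {
  stopifnot(all(c("haplotype_id", "chrom", "start", "end", "ancestry",
                  "certainty") %in% names(tracts)))
  if (any(tracts$end <= tracts$start)) stop("tracts must have end > start")
  key <- paste(tracts$haplotype_id, tracts$chrom)
  for (k in unique(key)) {
    sub <- tracts[key == k, ]
    sub <- sub[order(sub$start), ]
    if (any(sub$start[-1] < sub$end[-nrow(sub)]))
      stop("overlapping tracts on ", k)
  }
  invisible(tracts)
}

#' Read and write ancestry tracts as BED-like TSV
#'
#' Columns: `haplotype_id`, `chrom`, `start`, `end`, `ancestry`,
#' `certainty`, with half-open `[start, end)` bp intervals.
#'
#' @param tracts tract data frame.
#' @param path file path.
#' @return `read_tracts` returns the tract data frame.
#' @export
write_tracts <- function(tracts, path) {
  write.table(tracts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracts
#' @export
read_tracts <- function(path) {
  t <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  colClasses = c(chrom = "character"))
  validate_tracts(t)
}
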