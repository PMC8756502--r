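#' Write phased haplotypes as VCF
#'
#' Minimal VCFv4.2 writer for the package's haplotype matrices: one sample
#' column per individual with phased GT (`a|b`). A missing haplotype copy
#' (e.g. the absent second X of a male) yields a haploid call (`a`), and
#' fully missing sites `.`.
#'
#' @param haplotypes matrix with rows `<id>_1`, `<id>_2` (`NA` = missing).
#' @param sites a [site_table].
#' @param path output file (plain text).
#' @export
write_vcf <- function(haplotypes, sites, path) {
  ids <- unique(sub("_[12]$", "", rownames(haplotypes)))
  h1 <- haplotypes[paste0(ids, "_1"), , drop = FALSE]
  h2 <- haplotypes[paste0(ids, "_2"), , drop = FALSE]
  gt <- matrix("", nrow(sites), length(ids))
  for (i in seq_along(ids)) {
    a <- h1[i, ]; b <- h2[i, ]
    gt[, i] <- ifelse(is.na(a) & is.na(b), ".",
                ifelse(is.na(b), as.character(a),
                 ifelse(is.na(a), as.character(b),
                        paste0(a, "|", b))))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=admixkit",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", ids), collapse = "\t")),
             con)
  body <- cbind(sites$chrom, sites$pos,
                paste0("site", sites$index), sites$ref, sites$alt,
                ".", ".", ".", "GT", gt)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read phased haplotypes from a VCF
#'
#' Reads a phased, biallelic VCF (as written by [write_vcf], or any plain
#' VCF with `GT` first in FORMAT) back into a haplotype matrix and site
#' table. Uses `vcfR` when installed, otherwise a minimal text parser.
#'
#' @param path VCF file path.
#' @return List with `haplotypes` (rows `<id>_1`, `<id>_2`) and `sites`.
#' @export
read_vcf <- function(path) {
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    gt <- vcfR::extract.gt(v, element = "GT")
  } else {
    lines <- readLines(path)
    hdr <- grep("^#CHROM", lines)
    cols <- strsplit(lines[hdr], "\t")[[1]]
    tab <- read.table(text = lines[-seq_len(hdr)], sep = "\t",
                      stringsAsFactors = FALSE,
                      colClasses = "character")
    colnames(tab) <- cols
    fix <- as.matrix(tab[, c("#CHROM", "POS", "ID", "REF", "ALT")])
    colnames(fix) <- c("CHROM", "POS", "ID", "REF", "ALT")
    gt <- as.matrix(tab[, -seq_len(9L), drop = FALSE])
    rownames(gt) <- tab$ID
  }
  sites <- site_table(fix[, "CHROM"], as.integer(fix[, "POS"]),
                      fix[, "REF"], fix[, "ALT"])
  ids <- colnames(gt)
  H <- matrix(NA_integer_, 2L * length(ids), nrow(sites),
              dimnames = list(as.vector(rbind(paste0(ids, "_1"),
                                              paste0(ids, "_2"))), NULL))
  for (i in seq_along(ids)) {
    parts <- strsplit(gt[, i], "[|/]")
    a <- vapply(parts, function(p) p[1], character(1))
    b <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_,
                character(1))
    H[2L * i - 1L, ] <- suppressWarnings(as.integer(a))
    H[2L * i, ] <- suppressWarnings(as.integer(b))
  }
  list(haplotypes = H, sites = sites)
}

#' Read and write genetic maps as 3-column TSV
#'
#' Columns `chrom`, `pos` (bp), `cM`.
#'
#' @param map a [genetic_map]; `path` file path.
#' @export
write_genetic_map <- function(map, path) {
  write.table(as.data.frame(unclass(map)), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genetic_map
#' @export
read_genetic_map <- function(path) {
  m <- read.table(path, header = TRUE, sep = "\t",
                  colClasses = c(chrom = "character"))
  genetic_map(m$chrom, m$pos, m$cM)
}
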