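#' X-versus-autosome sex-biased admixture statistic
#'
#' The normalized difference between an ancestry's X-chromosome and
#' autosomal fractions, weighted by its genome-wide fraction:
#' \deqn{\Delta Admix = F_{total} \frac{F_X - F_{auto}}{F_X + F_{auto}}}
#' Positive values indicate female-biased admixture for that ancestry (the
#' X spends two thirds of its history in females), negative values
#' male-biased admixture. When `F_X + F_auto = 0` the statistic is defined
#' as 0 (no information, no bias).
#'
#' @param F_total,F_X,F_auto genome-wide, X-chromosome and autosomal
#'   ancestry fractions, each in `[0, 1]` (vectorized).
#' @return Numeric vector of the statistic; `|value| <= F_total`.
#' @examples
#' delta_admix(0.5, 0.6, 0.4)  # 0.1, female-biased
#' @export
delta_admix <- function(F_total, F_X, F_auto) {
  n <- max(length(F_total), length(F_X), length(F_auto))
  F_total <- rep_len(F_total, n); F_X <- rep_len(F_X, n)
  F_auto <- rep_len(F_auto, n)
  args <- c(F_total, F_X, F_auto)
  if (any(is.na(args)) || any(args < 0 | args > 1))
    stop("fractions must lie in [0, 1]")
  den <- F_X + F_auto
  ifelse(den == 0, 0, F_total * (F_X - F_auto) / den)
}

#' Cohort-level sex-biased admixture from ancestry tracts
#'
#' Computes per-individual, per-ancestry genome-wide, X-chromosome and
#' autosomal fractions from tract genetic lengths (via
#' [chromosome_ancestry_fractions]; a male's single X copy contributes one
#' haplotype, a female's two), applies [delta_admix], and reports
#' per-ancestry medians. Individuals with no labeled X-chromosome tracts
#' are skipped with a warning.
#'
#' @param tracts tract data frame including X-chromosome tracts.
#' @param map a [genetic_map] covering all tract chromosomes.
#' @param x_chrom X chromosome label (default `"X"`).
#' @return Object of class `delta_admix_records`: `records` (data frame
#'   `individual`, `ancestry`, `F_total`, `F_X`, `F_auto`, `delta`) and
#'   `medians` (named per-ancestry median delta).
#' @export
cohort_delta_admix <- function(tracts, map, x_chrom = "X") {
  chroms <- unique(tracts$chrom)
  if (!x_chrom %in% chroms) stop("no X-chromosome tracts present")
  autos <- setdiff(chroms, x_chrom)
  if (length(autos) == 0) stop("no autosomal tracts present")
  Ftot <- chromosome_ancestry_fractions(tracts, map)
  FX <- chromosome_ancestry_fractions(tracts, map, chroms = x_chrom)
  Fauto <- chromosome_ancestry_fractions(tracts, map, chroms = autos)
  skipped <- setdiff(rownames(Ftot),
                     setdiff(rownames(FX), attr(FX, "flagged")))
  if (length(skipped))
    warning("skipping individuals with no labeled X data: ",
            paste(skipped, collapse = ", "))
  ids <- setdiff(rownames(Ftot), skipped)
  labs <- colnames(Ftot)
  rec <- expand.grid(individual = ids, ancestry = labs,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  zero <- function(M, i, a) {
    v <- if (a %in% colnames(M) && i %in% rownames(M)) M[i, a] else 0
    if (is.na(v)) 0 else v
  }
  rec$F_total <- mapply(zero, list(Ftot), rec$individual, rec$ancestry)
  rec$F_X <- mapply(zero, list(FX), rec$individual, rec$ancestry)
  rec$F_auto <- mapply(zero, list(Fauto), rec$individual, rec$ancestry)
  rec$delta <- delta_admix(rec$F_total, rec$F_X, rec$F_auto)
  med <- tapply(rec$delta, rec$ancestry, median)
  structure(list(records = rec, medians = med[labs]),
            class = "delta_admix_records")
}

#' @export
print.delta_admix_records <- function(x, ...) {
  cat("delta_admix_records:", length(unique(x$records$individual)),
      "individuals\n")
  cat("median delta by ancestry (positive = female-biased):\n")
  print(round(x$medians, 4))
  invisible(x)
}
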