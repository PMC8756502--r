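#' Reported mean continental ancestry of admixed American populations
#'
#' Published mean continental ancestry percentages (African, European,
#' Native American, East Asian) for four Ecuadorian ethnic groups
#' (Afro-Ecuadorian, Mestizo, Montubio, Tsachila) and six admixed American
#' reference populations. Shipped as a plain TSV under `extdata`; used by
#' the worked examples and the acceptance script to compute population
#' admixture entropies from reported means.
#'
#' @return Data frame with `population` and four `*_pct` columns (rows sum
#'   to ~100 up to printed rounding).
#' @examples
#' m <- reported_ancestry_means()
#' admixture_entropy(as.numeric(m[m$population == "Mestizo", -1]) / 100)
#' @export
reported_ancestry_means <- function() {
  path <- system.file("extdata", "american_admixed_ancestry_means.tsv",
                      package = "admixkit", mustWork = TRUE)
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
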