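#' KING-robust pairwise kinship coefficients
#'
#' Between-family robust kinship estimated from identity-state counts:
#' \deqn{\hat\phi_{ij} = \frac{N_{Aa,Aa} - 2 N_{AA,aa}}
#'   {N_{Aa}^{(i)} + N_{Aa}^{(j)}}}
#' where `N_Aa,Aa` counts sites where both individuals are heterozygous,
#' `N_AA,aa` counts opposite homozygotes, and `N_Aa^(i)` counts heterozygous
#' sites of individual i (all counts over sites non-missing in both). A
#' duplicated sample gives 0.5; unrelated individuals concentrate near 0.
#'
#' @param genotypes n x L dosage matrix (0/1/2, `NA` allowed).
#' @param min_sites pairs with fewer informative (jointly non-missing)
#'   sites are flagged `unreliable` (default 100).
#' @return Data frame of class `kinship_records` with columns `id1`, `id2`,
#'   `phi`, `n_sites`, `unreliable`.
#' @export
kinship_matrix <- function(genotypes, min_sites = 100L) {
  G <- as.matrix(genotypes)
  if (nrow(G) < 2) stop("need at least 2 individuals")
  ids <- rownames(G) %||% paste0("ind", seq_len(nrow(G)))
  V <- !is.na(G)
  Gz <- G; Gz[!V] <- 0L
  Het <- (Gz == 1L) & V
  Hom0 <- (Gz == 0L) & V
  Hom2 <- (Gz == 2L) & V
  Vn <- V * 1
  Hetn <- Het * 1
  n_hethet <- Hetn %*% t(Hetn)
  n_opp <- (Hom0 * 1) %*% t(Hom2 * 1) + (Hom2 * 1) %*% t(Hom0 * 1)
  n_het_i <- Hetn %*% t(Vn)          # het in i, valid in j
  n_both <- Vn %*% t(Vn)
  den <- n_het_i + t(n_het_i)
  phi <- (n_hethet - 2 * n_opp) / den
  pr <- which(upper.tri(phi), arr.ind = TRUE)
  rec <- data.frame(id1 = ids[pr[, 1]], id2 = ids[pr[, 2]],
                    phi = phi[pr], n_sites = n_both[pr],
                    unreliable = n_both[pr] < min_sites,
                    stringsAsFactors = FALSE)
  class(rec) <- c("kinship_records", "data.frame")
  rec
}

#' Kinship-based sample exclusion
#'
#' Flags every pair whose KING-robust kinship exceeds `threshold` and
#' greedily removes one member per flagged pair until no reliable pair
#' exceeds it: at each step the individual involved in the most flagged
#' pairs is dropped, with ties broken by higher missingness and then by
#' lexicographically later identifier. Pairs with too few informative sites
#' are flagged unreliable and never trigger exclusion.
#'
#' @param genotypes n x L dosage matrix (0/1/2, `NA` allowed).
#' @param threshold kinship coefficient above which a pair is flagged
#'   (default 0.25, i.e. closer than second degree).
#' @param min_sites see [kinship_matrix].
#' @return List: `retained` ids, `removed` ids, `records` (all pairwise
#'   [kinship_matrix] records).
#' @export
kinship_filter <- function(genotypes, threshold = 0.25, min_sites = 100L) {
  G <- as.matrix(genotypes)
  ids <- rownames(G) %||% paste0("ind", seq_len(nrow(G)))
  rownames(G) <- ids
  if (nrow(G) < 2)
    return(list(retained = ids, removed = character(0),
                records = data.frame()))
  rec <- kinship_matrix(G, min_sites = min_sites)
  miss <- rowMeans(is.na(G))
  names(miss) <- ids
  active <- rec[!rec$unreliable & rec$phi > threshold, c("id1", "id2")]
  removed <- character(0)
  while (nrow(active) > 0) {
    cnt <- table(c(active$id1, active$id2))
    cand <- names(cnt)[cnt == max(cnt)]
    if (length(cand) > 1) {
      mm <- miss[cand]
      cand <- cand[mm == max(mm)]
      cand <- sort(cand, decreasing = TRUE)[1]  # later id dropped
    }
    removed <- c(removed, cand[1])
    active <- active[active$id1 != cand[1] & active$id2 != cand[1], ,
                     drop = FALSE]
  }
  list(retained = setdiff(ids, removed), removed = removed, records = rec)
}
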