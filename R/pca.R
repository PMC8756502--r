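#' Principal component analysis of genotype dosages
#'
#' Monomorphic sites are dropped; each remaining site is centered at twice
#' its allele frequency and scaled by `sqrt(2 p (1-p))` (the usual
#' frequency standardization), and the scores are the left singular vectors
#' scaled by their singular values. Components are ordered by explained
#' variance.
#'
#' @param genotypes n x L dosage matrix (0/1/2).
#' @param n_components number of components to keep (default
#'   `min(n, 10)`).
#' @return Object of class `genotype_pca`: `scores` (n x k), `varprop`
#'   (explained-variance proportions, non-increasing), `sites_used`.
#' @export
pca_genotypes <- function(genotypes, n_components = NULL) {
  G <- as.matrix(genotypes)
  if (nrow(G) < 2) stop("need at least 2 individuals")
  if (ncol(G) < 1) stop("need at least 1 site")
  p <- colMeans(G, na.rm = TRUE) / 2
  keep <- p > 0 & p < 1 & !is.na(p)
  if (!any(keep)) stop("no polymorphic sites")
  G <- G[, keep, drop = FALSE]
  p <- p[keep]
  X <- sweep(G, 2, 2 * p)
  X <- sweep(X, 2, sqrt(2 * p * (1 - p)), "/")
  X[is.na(X)] <- 0
  k <- min(n_components %||% 10L, nrow(G) - 1L, ncol(G))
  s <- svd(X, nu = k, nv = 0)
  scores <- s$u * rep(s$d[seq_len(k)], each = nrow(G))
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(G)
  structure(list(scores = scores,
                 varprop = s$d^2 / sum(s$d^2),
                 sites_used = sum(keep)),
            class = "genotype_pca")
}

#' @export
print.genotype_pca <- function(x, ...) {
  cat("genotype_pca:", nrow(x$scores), "individuals,", x$sites_used,
      "polymorphic sites\n")
  cat("explained variance:",
      paste(sprintf("%.1f%%", 100 * head(x$varprop, 5)), collapse = ", "),
      "...\n")
  invisible(x)
}
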