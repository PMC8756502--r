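#' Windowed local-ancestry inference
#'
#' Assigns continental ancestry to haplotype windows with a naive-Bayes
#' classifier: within each window of `window_sites` consecutive sites, the
#' log-likelihood of the haplotype under each panel's allele frequencies is
#' summed over sites (independent-site binomial model, frequencies clipped),
#' and the posterior over ancestries is formed with a uniform prior. A
#' window is labeled with its maximum-posterior ancestry only when that
#' posterior reaches `certainty` (default 95%); otherwise it is labeled
#' `"UNKNOWN"`. Adjacent same-label windows are merged into tracts carrying
#' the minimum window certainty.
#'
#' @param haplotypes haplotype matrix (rows `<id>_1`, `<id>_2`; 0/1, `NA`
#'   for missing copies).
#' @param freqs L x K panel allele-frequency matrix (columns labeled).
#' @param sites a [site_table].
#' @param map a [genetic_map] (supplies chromosome extents for tract
#'   boundaries).
#' @param window_sites sites per window (>= 5; a window larger than a
#'   chromosome becomes a single window).
#' @param certainty posterior threshold for assignment (default 0.95).
#' @param eps frequency clipping bound.
#' @return Tract data frame (`haplotype_id`, `chrom`, `start`, `end`,
#'   `ancestry`, `certainty`) tiling each haplotype; `ancestry` may be
#'   `"UNKNOWN"`.
#' @export
infer_local_ancestry <- function(haplotypes, freqs, sites, map,
                                 window_sites = 50L, certainty = 0.95,
                                 eps = 1e-4) {
  if (window_sites < 5) stop("window_sites must be >= 5")
  H <- as.matrix(haplotypes)
  Fm <- pmin(pmax(as.matrix(freqs), eps), 1 - eps)
  lf <- log(Fm); lc <- log(1 - Fm)
  K <- ncol(Fm)
  labels <- colnames(Fm) %||% paste0("pop", seq_len(K))
  A <- H; A[is.na(A)] <- 0
  V <- (!is.na(H)) * 1
  chrom_info <- map_chromosomes(map)

  out <- list()
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    nw <- max(1L, floor(length(idx) / window_sites))
    wid <- pmin(ceiling(seq_along(idx) / window_sites), nw)
    ci <- chrom_info[chrom_info$chrom == ch, ]
    # window bp bounds: first starts at chromosome start, each subsequent
    # window starts at its first site, last ends past the terminus
    w_first <- tapply(idx, wid, min)
    w_start <- c(ci$start_bp, sites$pos[w_first[-1]])
    w_end <- c(w_start[-1], ci$end_bp + 1)

    post_lab <- matrix("UNKNOWN", nrow(H), nw)
    post_cert <- matrix(NA_real_, nrow(H), nw)
    any_data <- matrix(FALSE, nrow(H), nw)
    for (w in seq_len(nw)) {
      cols <- idx[wid == w]
      ll <- A[, cols, drop = FALSE] %*% lf[cols, , drop = FALSE] +
        (V[, cols, drop = FALSE] - A[, cols, drop = FALSE]) %*%
          lc[cols, , drop = FALSE]
      mx <- apply(ll, 1, max)
      pw <- exp(ll - mx)
      pw <- pw / rowSums(pw)
      best <- max.col(pw, ties.method = "first")
      bc <- pw[cbind(seq_len(nrow(pw)), best)]
      lab <- ifelse(bc >= certainty, labels[best], "UNKNOWN")
      post_lab[, w] <- lab
      post_cert[, w] <- bc
      any_data[, w] <- rowSums(V[, cols, drop = FALSE]) > 0
    }
    for (i in seq_len(nrow(H))) {
      if (!any(any_data[i, ])) next  # copy absent on this chromosome
      r <- rle(post_lab[i, ])
      ends <- cumsum(r$lengths)
      starts <- c(1L, head(ends, -1L) + 1L)
      cert <- vapply(seq_along(starts), function(s)
        min(post_cert[i, starts[s]:ends[s]]), numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        haplotype_id = rownames(H)[i], chrom = ch,
        start = w_start[starts], end = w_end[ends],
        ancestry = r$values, certainty = cert, stringsAsFactors = FALSE)
    }
  }
  tr <- do.call(rbind, out)
  rownames(tr) <- NULL
  tr
}

#' Mask a genome down to one ancestry's haplotypes
#'
#' Sites falling inside tracts of `target_ancestry` are kept; all other
#' sites (including `UNKNOWN` tracts) are set missing (`NA`).
#'
#' @param haplotypes haplotype matrix (rows are haplotype ids matching the
#'   tract table).
#' @param tracts tract data frame tiling the haplotypes.
#' @param target_ancestry ancestry label to retain.
#' @param sites a [site_table].
#' @return Object of class `masked_genome`: `haplotypes` (masked matrix),
#'   `target_ancestry`, `retained` (per-haplotype retained-site fraction).
#' @export
mask_genome <- function(haplotypes, tracts, target_ancestry, sites) {
  H <- as.matrix(haplotypes)
  keep <- matrix(FALSE, nrow(H), ncol(H), dimnames = dimnames(H))
  sel <- tracts[tracts$ancestry == target_ancestry &
                  tracts$haplotype_id %in% rownames(H), , drop = FALSE]
  if (nrow(sel) == 0)
    warning("no tracts of ancestry '", target_ancestry,
            "': masked genome is empty")
  for (r in seq_len(nrow(sel))) {
    cols <- sites$chrom == sel$chrom[r] &
      sites$pos >= sel$start[r] & sites$pos < sel$end[r]
    keep[sel$haplotype_id[r], cols] <- TRUE
  }
  Hm <- H
  Hm[!keep] <- NA_integer_
  structure(list(haplotypes = Hm, target_ancestry = target_ancestry,
                 retained = rowMeans(keep)),
            class = "masked_genome")
}

#' Per-ancestry genetic-length fractions over a chromosome set
#'
#' For each individual, the fraction of labeled genetic length (cM)
#' assigned to each ancestry over the requested chromosomes. `UNKNOWN`
#' tracts are excluded from the denominator. Individuals with zero labeled
#' cM get `NA` fractions and are listed in the `flagged` attribute.
#'
#' @param tracts tract data frame.
#' @param map a [genetic_map].
#' @param chroms chromosome labels to include (default: all in `tracts`).
#' @param by `"individual"` (haplotype ids `<id>_1/2` are pooled) or
#'   `"haplotype"`.
#' @return Matrix (rows = individuals or haplotypes, columns = ancestries)
#'   of fractions summing to 1 per row, with attribute `flagged`.
#' @export
chromosome_ancestry_fractions <- function(tracts, map, chroms = NULL,
                                          by = c("individual", "haplotype")) {
  by <- match.arg(by)
  t <- tracts
  if (!is.null(chroms)) t <- t[t$chrom %in% chroms, , drop = FALSE]
  if (nrow(t) == 0) stop("no tracts on requested chromosomes")
  cm <- tract_cM(t, map)
  grp <- if (by == "individual") sub("_[0-9]+$", "", t$haplotype_id)
         else t$haplotype_id
  labs <- setdiff(unique(t$ancestry), "UNKNOWN")
  groups <- unique(grp)
  M <- matrix(0, length(groups), length(labs),
              dimnames = list(groups, labs))
  for (a in labs) {
    sel <- t$ancestry == a
    agg <- tapply(cm[sel], grp[sel], sum)
    M[names(agg), a] <- agg
  }
  tot <- rowSums(M)
  flagged <- rownames(M)[tot == 0]
  M <- M / tot
  attr(M, "flagged") <- flagged
  M
}
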