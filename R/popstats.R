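#' Population allele-frequency tables
#'
#' @param label population label.
#' @param p per-site alternate-allele frequencies in `[0, 1]`.
#' @param n haploid sample size (>= 2).
#' @return Object of class `freq_table`.
#' @export
freq_table <- function(label, p, n) {
  if (n < 2) stop("haploid sample size must be >= 2")
  if (any(p < 0 | p > 1)) stop("frequencies must lie in [0, 1]")
  structure(list(label = label, p = as.numeric(p), n = n),
            class = "freq_table")
}

#' @rdname freq_table
#' @param panel a `haplotype_panel`.
#' @export
panel_freq_table <- function(panel) {
  freq_table(panel$label, colMeans(panel$haplotypes),
             nrow(panel$haplotypes))
}

#' Hudson pairwise F_ST (ratio of averages)
#'
#' Per site `j`,
#' `N_j = (p_a - p_b)^2 - p_a(1-p_a)/(n_a-1) - p_b(1-p_b)/(n_b-1)` and
#' `D_j = p_a(1-p_b) + p_b(1-p_a)`; the estimate is `sum(N) / sum(D)`.
#' Sites monomorphic for the same allele in both populations are dropped.
#' The raw estimate may be slightly negative for undifferentiated
#' populations; [fst_matrix] clamps at 0 when building distance input for
#' tree construction.
#'
#' @param a,b `freq_table`s over shared sites.
#' @return F_ST estimate (scalar, unclamped).
#' @export
pairwise_fst <- function(a, b) {
  stopifnot(inherits(a, "freq_table"), inherits(b, "freq_table"))
  if (length(a$p) != length(b$p)) stop("frequency tables must share sites")
  keep <- !((a$p == 0 & b$p == 0) | (a$p == 1 & b$p == 1))
  pa <- a$p[keep]; pb <- b$p[keep]
  if (!length(pa)) stop("no polymorphic sites shared")
  N <- (pa - pb)^2 - pa * (1 - pa) / (a$n - 1) - pb * (1 - pb) / (b$n - 1)
  D <- pa * (1 - pb) + pb * (1 - pa)
  sum(N) / sum(D)
}

#' Pairwise F_ST distance matrix
#'
#' @param tables list of `freq_table`s over shared sites.
#' @param clamp clamp negative estimates to 0 (default TRUE; required for
#'   neighbor joining). The unclamped values are kept in attribute `raw`.
#' @return Symmetric matrix with zero diagonal, labeled by population.
#' @export
fst_matrix <- function(tables, clamp = TRUE) {
  K <- length(tables)
  labs <- vapply(tables, function(t) t$label, character(1))
  D <- matrix(0, K, K, dimnames = list(labs, labs))
  for (i in seq_len(K - 1)) for (j in seq(i + 1, K))
    D[i, j] <- D[j, i] <- pairwise_fst(tables[[i]], tables[[j]])
  raw <- D
  if (clamp) D <- pmax(D, 0)
  attr(D, "raw") <- raw
  D
}

#' Neighbor-joining tree from an F_ST distance matrix
#'
#' Canonical neighbor joining (Saitou-Nei, via [ape::nj]) on a symmetric
#' non-negative distance matrix. With `per_site_tables` given, bootstrap
#' replicates resample sites, recompute the F_ST matrix and tree, and
#' report clade frequencies ([ape::prop.clades]) as internal node labels.
#'
#' @param d symmetric distance matrix (>= 3 populations, zero diagonal).
#' @param bootstrap_replicates number of site-resampling replicates
#'   (default 0: no supports).
#' @param per_site_tables list of `freq_table`s (required when
#'   `bootstrap_replicates > 0`).
#' @param seed seed for the bootstrap resampling.
#' @return An [ape::phylo] tree (unrooted); bootstrap supports, if
#'   computed, are stored in `node.label`.
#' @export
neighbor_joining <- function(d, bootstrap_replicates = 0,
                             per_site_tables = NULL, seed = 1L) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("need at least 3 populations")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix must be symmetric")
  tree <- ape::nj(stats::as.dist(pmax(d, 0)))
  if (bootstrap_replicates > 0) {
    if (is.null(per_site_tables))
      stop("per_site_tables needed for bootstrap")
    set.seed(as.integer(seed))
    L <- length(per_site_tables[[1]]$p)
    boots <- vector("list", bootstrap_replicates)
    for (b in seq_len(bootstrap_replicates)) {
      idx <- sample.int(L, L, replace = TRUE)
      tabs <- lapply(per_site_tables, function(t)
        freq_table(t$label, t$p[idx], t$n))
      boots[[b]] <- ape::nj(stats::as.dist(fst_matrix(tabs)))
    }
    supp <- ape::prop.clades(tree, boots, rooted = FALSE)
    tree$node.label <- round(supp / bootstrap_replicates, 3)
  }
  tree
}

#' Write a tree in Newick format
#'
#' Branch lengths at 6 decimals; bootstrap supports (if present) as
#' internal node labels.
#'
#' @param tree an [ape::phylo].
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}

#' Outgroup f3 statistic with block-jackknife errors
#'
#' `f3(O; A, B)` measures the shared drift of `A` and `B` relative to the
#' outgroup `O`: per site `(p_o - p_a)(p_o - p_b) - p_o(1-p_o)/(n_o - 1)`
#' (the correction removes the bias from estimating the outgroup
#' frequency), averaged over sites. The standard error is a delete-one
#' block jackknife over contiguous site blocks; `Z = f3 / SE`.
#'
#' @param outgroup,a,b `freq_table`s over shared sites.
#' @param block_size_sites sites per jackknife block (default 500). With
#'   fewer sites than one block the SE is undefined and flagged `NA`.
#' @return Object of class `f3_result`: `f3`, `se`, `Z`, `n_blocks`,
#'   labels.
#' @export
outgroup_f3 <- function(outgroup, a, b, block_size_sites = 500L) {
  stopifnot(inherits(outgroup, "freq_table"))
  L <- length(outgroup$p)
  if (length(a$p) != L || length(b$p) != L)
    stop("frequency tables must share sites")
  t_j <- (outgroup$p - a$p) * (outgroup$p - b$p) -
    outgroup$p * (1 - outgroup$p) / (outgroup$n - 1)
  f3 <- mean(t_j)
  if (L < block_size_sites) {
    se <- NA_real_; nb <- 0L
  } else {
    blk <- ceiling(seq_len(L) / block_size_sites)
    nb <- max(blk)
    theta_i <- vapply(seq_len(nb), function(i) mean(t_j[blk != i]),
                      numeric(1))
    se <- sqrt((nb - 1) / nb * sum((theta_i - mean(theta_i))^2))
  }
  structure(list(outgroup = outgroup$label, a = a$label, b = b$label,
                 f3 = f3, se = se, Z = f3 / se, n_blocks = nb),
            class = "f3_result")
}

#' @export
print.f3_result <- function(x, ...) {
  cat(sprintf("f3(%s; %s, %s) = %.6f  SE = %s  Z = %s  (%d blocks)\n",
              x$outgroup, x$a, x$b, x$f3,
              ifelse(is.na(x$se), "NA (too few sites)", sprintf("%.6f", x$se)),
              ifelse(is.na(x$se), "NA", sprintf("%.2f", x$Z)), x$n_blocks))
  invisible(x)
}
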