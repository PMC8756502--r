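#' Site table constructor
#'
#' Biallelic sites with 1-based physical coordinates, strictly increasing
#' within each chromosome.
#'
#' @param chrom,pos chromosome label and bp position per site.
#' @param ref,alt single-nucleotide alleles (defaults A/G).
#' @return Data frame of class `site_table` with columns `chrom`, `pos`,
#'   `ref`, `alt` and a dense ordinal `index`.
#' @export
site_table <- function(chrom, pos, ref = "A", alt = "G") {
  s <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                  ref = rep_len(ref, length(pos)), alt = rep_len(alt, length(pos)),
                  stringsAsFactors = FALSE)
  s <- s[order(s$chrom, s$pos), , drop = FALSE]
  for (ch in unique(s$chrom))
    if (any(diff(s$pos[s$chrom == ch]) <= 0))
      stop("site positions must be strictly increasing within a chromosome")
  s$index <- seq_len(nrow(s))
  rownames(s) <- NULL
  class(s) <- c("site_table", "data.frame")
  s
}

#' Simulate drifted founder haplotype panels
#'
#' Draws `K` reference populations under the Balding-Nichols model: for each
#' site an ancestral allele frequency `p ~ Uniform(0.05, 0.95)`, then each
#' population's frequency `p_k ~ Beta(p (1-F_k)/F_k, (1-p)(1-F_k)/F_k)`
#' (mean `p`, variance `F_k p (1-p)`), and haplotype alleles i.i.d. Bernoulli
#' at that frequency. Sites are placed uniformly at random along the
#' chromosomes of a constant-rate genetic map.
#'
#' @param K number of populations (>= 2).
#' @param F_k drift parameter per population, each in (0, 1); recycled.
#' @param n_sites total number of biallelic sites (>= 1).
#' @param n_hap haplotypes per population (even: diploid source).
#' @param seed integer seed (mandatory; panels are deterministic given it).
#' @param chrom_lengths_bp named vector of chromosome lengths (bp).
#' @param morgans genetic length per chromosome (recycled).
#' @param labels population labels (default `pop1..popK`).
#' @return Object of class `panel_set`: a list with `panels` (list of
#'   `haplotype_panel`: `label`, `haplotypes` H x L 0/1 matrix, `role`),
#'   `sites` (a [site_table]), `map` (a [genetic_map]) and the drawn
#'   ancestral frequencies `p_anc`.
#' @examples
#' ps <- generate_founder_panels(2, 0.1, n_sites = 200, n_hap = 20, seed = 1)
#' sapply(ps$panels, function(p) dim(p$haplotypes))
#' @export
generate_founder_panels <- function(K, F_k, n_sites, n_hap = 40, seed,
                                    chrom_lengths_bp = c("1" = 1e6),
                                    morgans = 1,
                                    labels = paste0("pop", seq_len(K))) {
  if (missing(seed)) stop("seed is required")
  if (K < 2) stop("K must be >= 2")
  if (n_sites < 1) stop("n_sites must be >= 1")
  F_k <- rep_len(F_k, K)
  if (any(F_k <= 0 | F_k >= 1)) stop("F_k must lie in (0, 1)")
  if (n_hap %% 2 != 0) stop("n_hap must be even (diploid source)")
  set.seed(as.integer(seed))

  map <- uniform_genetic_map(chrom_lengths_bp, morgans)
  # spread sites over chromosomes proportionally to physical length
  w <- chrom_lengths_bp / sum(chrom_lengths_bp)
  per <- diff(round(c(0, cumsum(w * n_sites))))
  per[length(per)] <- n_sites - sum(per[-length(per)])
  chrom <- rep(names(chrom_lengths_bp), per)
  pos <- unlist(lapply(seq_along(per), function(i) {
    if (per[i] == 0) return(integer(0))
    sort(sample.int(chrom_lengths_bp[i] - 2L, per[i]) + 1L)
  }), use.names = FALSE)
  sites <- site_table(chrom, pos)

  p_anc <- runif(n_sites, 0.05, 0.95)
  panels <- vector("list", K)
  for (k in seq_len(K)) {
    a <- p_anc * (1 - F_k[k]) / F_k[k]
    b <- (1 - p_anc) * (1 - F_k[k]) / F_k[k]
    fk <- rbeta(n_sites, a, b)
    H <- matrix(rbinom(n_hap * n_sites, 1L, rep(fk, each = n_hap)),
                nrow = n_hap, ncol = n_sites,
                dimnames = list(paste0(labels[k], "_h", seq_len(n_hap)), NULL))
    panels[[k]] <- structure(list(label = labels[k], haplotypes = H,
                                  role = "training", F = F_k[k]),
                             class = "haplotype_panel")
  }
  names(panels) <- labels
  structure(list(panels = panels, sites = sites, map = map, p_anc = p_anc),
            class = "panel_set")
}

#' Split a panel into training and validation halves
#'
#' Individuals (consecutive haplotype pairs) are alternately assigned, so
#' both halves keep an even haplotype count.
#'
#' @param panel a `haplotype_panel`.
#' @param training_fraction fraction of individuals for the training half.
#' @return List with `training` and `validation` panels.
#' @export
split_panel <- function(panel, training_fraction = 0.5) {
  H <- nrow(panel$haplotypes)
  n_ind <- H %/% 2L
  n_tr <- max(1L, round(n_ind * training_fraction))
  if (n_tr >= n_ind) stop("training_fraction leaves no validation individuals")
  idx_tr <- as.vector(vapply(seq_len(n_tr), function(i) c(2L * i - 1L, 2L * i),
                             integer(2)))
  mk <- function(rows, role) {
    p <- panel
    p$haplotypes <- panel$haplotypes[rows, , drop = FALSE]
    p$role <- role
    p
  }
  list(training = mk(idx_tr, "training"),
       validation = mk(setdiff(seq_len(H), idx_tr), "validation"))
}

#' Recombinant panel members from a founder haplotype pool
#'
#' Models within-population haplotype sharing: each output haplotype is a
#' mosaic of the panel's existing haplotypes, with breakpoints drawn as a
#' Poisson process at `rate_per_morgan` along the genetic map and each
#' segment copied from a uniformly chosen founder. Members of a population
#' share long identical segments with each other (and with admixed genomes
#' simulated from the same pool) the way samples from a real population do;
#' the haplotype-painting reference panels are built this way.
#'
#' @param panel a `haplotype_panel` serving as the founder pool.
#' @param sites,map the shared [site_table] and [genetic_map].
#' @param n_out number of recombinant haplotypes to produce (even).
#' @param rate_per_morgan breakpoint density (default 3; segments average
#'   ~1/3 Morgan).
#' @param seed integer seed (mandatory).
#' @param role role label for the output panel (default `"validation"`).
#' @return A `haplotype_panel` of `n_out` recombinant haplotypes.
#' @export
recombine_panel <- function(panel, sites, map, n_out, rate_per_morgan = 3,
                            seed, role = "validation") {
  if (missing(seed)) stop("seed is required")
  if (n_out %% 2 != 0) stop("n_out must be even")
  set.seed(as.integer(seed))
  src <- panel$haplotypes
  info <- map_chromosomes(map)
  H <- matrix(NA_integer_, n_out, nrow(sites),
              dimnames = list(paste0(panel$label, "_r", seq_len(n_out)), NULL))
  for (i in seq_len(n_out)) {
    for (ci in seq_len(nrow(info))) {
      ch <- info$chrom[ci]
      idx <- which(sites$chrom == ch)
      if (!length(idx)) next
      bk <- sort(runif(rpois(1L, rate_per_morgan * info$morgans[ci]),
                       0, info$cM[ci]))
      edges_bp <- c(info$start_bp[ci],
                    round(map_position_at_cM(map, ch, bk)),
                    info$end_bp[ci] + 1)
      edges_bp <- cummax(edges_bp)
      pos <- sites$pos[idx]
      for (s in seq_len(length(edges_bp) - 1L)) {
        sel <- pos >= edges_bp[s] & pos < edges_bp[s + 1L]
        if (!any(sel)) next
        H[i, idx[sel]] <- src[sample.int(nrow(src), 1L), idx[sel]]
      }
    }
  }
  structure(list(label = panel$label, haplotypes = H, role = role,
                 F = panel$F), class = "haplotype_panel")
}

#' Panel alternate-allele frequencies
#'
#' @param panels list of `haplotype_panel` objects over the same sites.
#' @param eps clipping bound applied to each frequency (likelihood safety).
#' @return L x K matrix of allele frequencies, columns named by population.
#' @export
panel_frequencies <- function(panels, eps = 0) {
  Fm <- vapply(panels, function(p) colMeans(p$haplotypes),
               numeric(ncol(panels[[1]]$haplotypes)))
  colnames(Fm) <- vapply(panels, function(p) p$label, character(1))
  if (eps > 0) Fm <- pmin(pmax(Fm, eps), 1 - eps)
  Fm
}

#' @export
print.panel_set <- function(x, ...) {
  cat("panel_set:", length(x$panels), "populations,",
      nrow(x$sites), "sites,",
      length(unique(x$sites$chrom)), "chromosome(s)\n")
  for (p in x$panels)
    cat(sprintf("  %s: %d haplotypes (F = %.3g, %s)\n",
                p$label, nrow(p$haplotypes), p$F, p$role))
  invisible(x)
}
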