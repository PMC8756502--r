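#' Simulate one admixed haploid chromosome copy
#'
#' Single-pulse Markov model: recombination breakpoints form a Poisson
#' process with rate `g` per Morgan along the genetic map; each
#' inter-breakpoint segment draws its ancestry independently from `m`; the
#' segment's sequence is copied from a uniformly chosen training haplotype
#' of that ancestry. Adjacent same-ancestry segments are merged in the
#' returned truth tracts (certainty 1).
#'
#' @keywords internal
simulate_haploid_copy <- function(panels, sites, map, chrom, m, g,
                                  fill = NULL) {
  info <- map_chromosomes(map)
  info <- info[info$chrom == chrom, ]
  M_cM <- info$cM
  start_bp <- info$start_bp
  end_bp <- info$end_bp
  K <- length(panels)

  nb <- rpois(1L, g * M_cM / 100)
  bk <- sort(runif(nb, 0, M_cM))
  inner_bp <- round(map_position_at_cM(map, chrom, bk))
  edges <- c(start_bp, pmin(pmax(inner_bp, start_bp + 1), end_bp), end_bp + 1)
  edges <- cummax(edges)
  anc <- sample.int(K, length(edges) - 1L, replace = TRUE, prob = m)
  keep <- diff(edges) > 0
  anc <- anc[keep]
  seg_start <- edges[-length(edges)][keep]
  seg_end <- edges[-1L][keep]

  idx <- which(sites$chrom == chrom)
  hap <- if (is.null(fill)) rep(NA_integer_, length(idx)) else fill
  if (length(idx)) {
    pos <- sites$pos[idx]
    for (s in seq_along(anc)) {
      in_seg <- pos >= seg_start[s] & pos < seg_end[s]
      if (!any(in_seg)) next
      H <- panels[[anc[s]]]$haplotypes
      src <- H[sample.int(nrow(H), 1L), idx[in_seg]]
      hap[in_seg] <- src
    }
  }
  r <- rle(anc)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  tracts <- data.frame(chrom = chrom,
                       start = seg_start[starts], end = seg_end[ends],
                       ancestry = names(panels)[r$values],
                       certainty = 1, stringsAsFactors = FALSE)
  list(hap = hap, tracts = tracts)
}

#' Simulate a cohort of admixed diploid genomes with truth tracts
#'
#' Generates `n` individuals under the single-pulse admixture model (see
#' [simulate_haploid_copy] for the per-chromosome mechanism). Sex-biased
#' founding can be emulated by giving `m_by_chrom` a different ancestry
#' proportion vector for the X chromosome: since an X chromosome spends two
#' thirds of its history in females, founding proportions `m_female` and
#' `m_male` imply `m_X = (2 m_female + m_male)/3` versus
#' `m_auto = (m_female + m_male)/2` (see [sex_biased_proportions]). When
#' `sexes` are supplied, males carry a single X haplotype.
#'
#' @param panels named list of training `haplotype_panel`s (ancestry labels).
#' @param sites a [site_table] shared by the panels.
#' @param map a [genetic_map] covering the sites.
#' @param n number of diploid individuals.
#' @param m ancestry proportion vector (simplex over the panels).
#' @param g generations since the admixture pulse (>= 1).
#' @param seed integer seed (mandatory).
#' @param m_by_chrom optional named list of per-chromosome proportion
#'   overrides, e.g. `list(X = c(0.6, 0.4))`.
#' @param sexes optional character vector (`"F"`/`"M"`, recycled) assigning
#'   a sex to each individual; males get one haplotype on `x_chrom`.
#' @param x_chrom chromosome label treated as the X chromosome.
#' @param genotypes if `FALSE`, skip sequence copying (tracts only; faster).
#' @param id_prefix prefix for individual identifiers.
#' @return Object of class `admixed_cohort`: `haplotypes` (2n x L 0/1
#'   matrix, rows `<id>_1`, `<id>_2`, `NA` where a copy does not exist),
#'   `tracts` (data frame `haplotype_id`, `chrom`, `start`, `end`,
#'   `ancestry`, `certainty`; half-open bp intervals), `truth_fractions`
#'   (n x K matrix of realized genome-wide ancestry fractions in cM),
#'   `meta` (individual, sex), plus `sites`, `map`, `labels`, `m`, `g`.
#' @examples
#' ps <- generate_founder_panels(2, 0.1, n_sites = 300, n_hap = 20, seed = 1)
#' co <- simulate_admixed_cohort(ps$panels, ps$sites, ps$map, n = 3,
#'                               m = c(0.5, 0.5), g = 10, seed = 2)
#' head(co$tracts)
#' @export
simulate_admixed_cohort <- function(panels, sites, map, n, m, g, seed,
                                    m_by_chrom = NULL, sexes = NULL,
                                    x_chrom = "X", genotypes = TRUE,
                                    id_prefix = "ind") {
  if (missing(seed)) stop("seed is required")
  if (g < 1) stop("g must be >= 1")
  m <- check_simplex(m, length(panels))
  if (is.null(names(panels)))
    names(panels) <- vapply(panels, function(p) p$label, character(1))
  for (p in panels)
    if (!identical(p$role, "training"))
      stop("simulation panels must have role 'training'")
  if (!is.null(m_by_chrom))
    m_by_chrom <- lapply(m_by_chrom, check_simplex, K = length(panels))
  set.seed(as.integer(seed))

  chs <- unique(sites$chrom)
  info <- map_chromosomes(map)
  L <- nrow(sites)
  ids <- sprintf("%s%03d", id_prefix, seq_len(n))
  sexes <- if (is.null(sexes)) rep(NA_character_, n) else rep_len(sexes, n)

  hap_mat <- matrix(NA_integer_, nrow = 2L * n, ncol = L,
                    dimnames = list(as.vector(rbind(paste0(ids, "_1"),
                                                    paste0(ids, "_2"))), NULL))
  tract_list <- list()
  K <- length(panels)
  truth <- matrix(0, n, K, dimnames = list(ids, names(panels)))

  for (i in seq_len(n)) {
    for (copy in 1:2) {
      hid <- paste0(ids[i], "_", copy)
      for (ch in chs) {
        if (ch == x_chrom && copy == 2L && identical(sexes[i], "M")) next
        m_ch <- if (!is.null(m_by_chrom) && ch %in% names(m_by_chrom))
          m_by_chrom[[ch]] else m
        sim <- simulate_haploid_copy(panels, sites, map, ch, m_ch, g)
        if (genotypes)
          hap_mat[hid, sites$chrom == ch] <- sim$hap
        sim$tracts <- cbind(haplotype_id = hid, sim$tracts)
        tract_list[[length(tract_list) + 1L]] <- sim$tracts
      }
    }
  }
  tracts <- do.call(rbind, tract_list)
  rownames(tracts) <- NULL

  cm_len <- tract_cM(tracts, map)
  ind <- sub("_[12]$", "", tracts$haplotype_id)
  for (k in names(panels)) {
    sel <- tracts$ancestry == k
    agg <- tapply(cm_len[sel], ind[sel], sum)
    truth[names(agg), k] <- agg
  }
  truth <- truth / rowSums(truth)

  structure(list(haplotypes = if (genotypes) hap_mat else NULL,
                 tracts = tracts, truth_fractions = truth,
                 meta = data.frame(individual = ids, sex = sexes,
                                   stringsAsFactors = FALSE),
                 sites = sites, map = map, labels = names(panels),
                 m = m, g = g),
            class = "admixed_cohort")
}

#' @export
print.admixed_cohort <- function(x, ...) {
  cat("admixed_cohort:", nrow(x$meta), "individuals,",
      length(x$labels), "ancestries (", paste(x$labels, collapse = ", "),
      "), g =", x$g, "\n")
  cat("mean truth fractions:",
      paste(sprintf("%s=%.3f", x$labels, colMeans(x$truth_fractions)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Diploid genotype dosages of a cohort
#'
#' @param cohort an `admixed_cohort` (or any haplotype matrix with rows
#'   `<id>_1`, `<id>_2`).
#' @return n x L matrix of alternate-allele counts (0/1/2).
#' @export
cohort_genotypes <- function(cohort) {
  H <- if (is.matrix(cohort)) cohort else cohort$haplotypes
  if (is.null(H)) stop("cohort was simulated without genotypes")
  ids <- unique(sub("_[12]$", "", rownames(H)))
  G <- H[paste0(ids, "_1"), , drop = FALSE] + H[paste0(ids, "_2"), , drop = FALSE]
  rownames(G) <- ids
  G
}

#' Founding proportions under sex-biased admixture
#'
#' Converts sex-specific founding ancestry proportions into the expected
#' autosomal and X-chromosome proportions: autosomes average the two sexes
#' equally, while the X spends 2/3 of its transmission history in females.
#'
#' @param m_female,m_male simplex vectors of founding proportions by sex.
#' @return List with `m_auto` and `m_X`.
#' @export
sex_biased_proportions <- function(m_female, m_male) {
  m_female <- check_simplex(m_female, length(m_female))
  m_male <- check_simplex(m_male, length(m_female))
  list(m_auto = (m_female + m_male) / 2,
       m_X = (2 * m_female + m_male) / 3)
}

# One diploid genome whose segment ancestries are assigned by randomized
# quota on genetic length: segments (drawn exactly as in the i.i.d. model)
# are visited in random order and each draws its ancestry with probability
# proportional to the ancestry's remaining genetic-length quota m_k * total.
# The realized proportions then match the target within about one segment
# length, emulating simulations that control admixture proportions exactly.
# Uses the current RNG state.
simulate_quota_genome <- function(panels, sites, map, m, g, id = "sim") {
  info <- map_chromosomes(map)
  K <- length(panels)
  seg_list <- list()
  for (copy in 1:2) for (ci in seq_len(nrow(info))) {
    ch <- info$chrom[ci]
    bk <- sort(runif(rpois(1L, g * info$morgans[ci]), 0, info$cM[ci]))
    edges <- c(info$start_bp[ci],
               pmin(pmax(round(map_position_at_cM(map, ch, bk)),
                         info$start_bp[ci] + 1), info$end_bp[ci]),
               info$end_bp[ci] + 1)
    edges <- cummax(edges)
    w <- diff(edges) > 0
    seg_list[[length(seg_list) + 1L]] <- data.frame(
      copy = copy, chrom = ch,
      start = edges[-length(edges)][w], end = edges[-1L][w],
      stringsAsFactors = FALSE)
  }
  segs <- do.call(rbind, seg_list)
  cm <- tract_cM(segs, map)
  quota <- m * sum(cm)
  anc <- integer(nrow(segs))
  for (s in sample.int(nrow(segs))) {
    pr <- pmax(quota, 0)
    if (sum(pr) <= 0) pr <- m
    anc[s] <- sample.int(K, 1L, prob = pr)
    quota[anc[s]] <- quota[anc[s]] - cm[s]
  }

  L <- nrow(sites)
  H <- matrix(NA_integer_, 2L, L,
              dimnames = list(paste0(id, c("_1", "_2")), NULL))
  tract_list <- list()
  for (copy in 1:2) {
    for (ch in unique(segs$chrom)) {
      sel <- which(segs$copy == copy & segs$chrom == ch)
      sel <- sel[order(segs$start[sel])]
      idx <- which(sites$chrom == ch)
      pos <- sites$pos[idx]
      for (s in sel) {
        in_seg <- pos >= segs$start[s] & pos < segs$end[s]
        if (any(in_seg)) {
          Hp <- panels[[anc[s]]]$haplotypes
          H[copy, idx[in_seg]] <- Hp[sample.int(nrow(Hp), 1L), idx[in_seg]]
        }
      }
      r <- rle(anc[sel])
      ends <- cumsum(r$lengths)
      starts <- c(1L, head(ends, -1L) + 1L)
      tract_list[[length(tract_list) + 1L]] <- data.frame(
        haplotype_id = paste0(id, "_", copy), chrom = ch,
        start = segs$start[sel][starts], end = segs$end[sel][ends],
        ancestry = names(panels)[r$values], certainty = 1,
        stringsAsFactors = FALSE)
    }
  }
  realized <- vapply(seq_len(K), function(k) sum(cm[anc == k]), numeric(1))
  list(haplotypes = H, tracts = do.call(rbind, tract_list),
       realized = setNames(realized / sum(cm), names(panels)))
}

#' Simulated validation cohorts over an admixture-proportion grid
#'
#' For each focal region (reference population), simulates admixed genomes
#' whose focal ancestry proportion runs over `grid` (default 20%-80% in 5%
#' steps) with the remaining proportion split evenly among the other
#' regions, `genomes_per_point` genomes per grid point. The expected
#' proportion vector of every genome is stored alongside it.
#'
#' @param panels named list of training `haplotype_panel`s (>= 2 regions).
#' @param sites,map shared [site_table] and [genetic_map].
#' @param g generations since admixture for the simulated genomes.
#' @param grid focal proportions (default `seq(0.2, 0.8, by = 0.05)`).
#' @param genomes_per_point simulated genomes per grid point (default 20).
#' @param proportion_control `"quota"` (default) assigns segment ancestries
#'   by randomized genetic-length quota so each genome's realized
#'   proportions match its expected vector (emulating simulations with
#'   controlled admixture fractions); `"iid"` draws each segment's ancestry
#'   independently as in [simulate_admixed_cohort].
#' @param seed integer seed (mandatory).
#' @return Object of class `validation_cohort`: list `regions` keyed by
#'   focal label, each with `haplotypes` (list of 2 x L matrices) and
#'   `expected` (genome x K matrix of expected proportions), plus shared
#'   `sites`, `map`, `labels`, `grid`.
#' @export
generate_validation_cohort <- function(panels, sites, map, g = 10,
                                       grid = seq(0.2, 0.8, by = 0.05),
                                       genomes_per_point = 20,
                                       proportion_control = c("quota", "iid"),
                                       seed) {
  if (missing(seed)) stop("seed is required")
  proportion_control <- match.arg(proportion_control)
  K <- length(panels)
  if (K < 2) stop("need at least two regions")
  if (is.null(names(panels)))
    names(panels) <- vapply(panels, function(p) p$label, character(1))
  labels <- names(panels)
  regions <- vector("list", K)
  names(regions) <- labels
  for (r in seq_len(K)) {
    haps <- list()
    expected <- matrix(NA_real_, length(grid) * genomes_per_point, K,
                       dimnames = list(NULL, labels))
    gi <- 0L
    for (f in grid) {
      mvec <- rep((1 - f) / (K - 1), K)
      mvec[r] <- f
      set.seed(substream_seed(seed, paste0("grid_", labels[r], "_", f)))
      for (j in seq_len(genomes_per_point)) {
        gi <- gi + 1L
        if (proportion_control == "quota") {
          sim <- simulate_quota_genome(panels, sites, map, mvec, g)
          haps[[gi]] <- sim$haplotypes
        } else {
          co <- simulate_admixed_cohort(panels, sites, map, n = 1L,
                                        m = mvec, g = g,
                                        seed = sample.int(2^31 - 1, 1L))
          haps[[gi]] <- co$haplotypes
        }
        expected[gi, ] <- mvec
      }
    }
    regions[[r]] <- list(haplotypes = haps, expected = expected)
  }
  structure(list(regions = regions, sites = sites, map = map,
                 labels = labels, grid = grid,
                 genomes_per_point = genomes_per_point),
            class = "validation_cohort")
}

# Simplex check shared by the simulation and inference stages.
check_simplex <- function(m, K, tol = 1e-8) {
  if (length(m) != K) stop("proportion vector has wrong length")
  if (any(m < -tol)) stop("proportions must be non-negative")
  if (abs(sum(m) - 1) > 1e-6) stop("proportions must sum to 1")
  pmax(m, 0) / sum(pmax(m, 0))
}
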