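# Per-site genetic-length weights used when crediting copied runs: each
# site carries the cM interval from itself to the next site on the same
# chromosome (the last site runs to the chromosome terminus), so the
# weights of a chromosome's sites sum to its map length minus the leading
# gap before the first site.
site_weights_cM <- function(sites, map) {
  cm <- interpolate_map(map, sites$chrom, sites$pos)
  info <- map_chromosomes(map)
  end_cM <- setNames(info$cM, info$chrom)
  w <- numeric(nrow(sites))
  for (ch in unique(sites$chrom)) {
    i <- which(sites$chrom == ch)
    w[i] <- c(diff(cm[i]), end_cM[[ch]] - cm[i[length(i)]])
  }
  w
}

#' Paint haplotypes against reference panels
#'
#' Computes a copying profile ("painting vector") for a target genome: a
#' greedy left-to-right longest-exact-match copying model walks each
#' haplotype over its unmasked sites, at each position crediting the
#' genetic length (cM) of the longest identical run to the reference
#' haplotype's population (ties split equally). Profiles of the genome's
#' haplotype copies are summed.
#'
#' @param haplotypes haplotype matrix for the target genome (typically the
#'   two rows of one individual; `NA` = masked site), or a `masked_genome`.
#' @param panels named list of reference `haplotype_panel`s sharing the
#'   site table.
#' @param sites,map shared [site_table] and [genetic_map].
#' @param exclude_rows optional reference row names to leave out (used for
#'   leave-one-individual-out self-copying).
#' @return Named numeric vector of class `painting_vector`: copied cM per
#'   reference population (entries >= 0, total > 0).
#' @export
paint_haplotypes <- function(haplotypes, panels, sites, map,
                             exclude_rows = NULL) {
  H <- if (inherits(haplotypes, "masked_genome")) haplotypes$haplotypes
       else as.matrix(haplotypes)
  if (all(is.na(H)))
    stop("empty ancestry component: all sites are masked")
  ref <- do.call(rbind, lapply(panels, function(p) p$haplotypes))
  pop <- rep(seq_along(panels),
             vapply(panels, function(p) nrow(p$haplotypes), integer(1)))
  if (!is.null(exclude_rows)) {
    keep <- !(rownames(ref) %in% exclude_rows)
    ref <- ref[keep, , drop = FALSE]
    pop <- pop[keep]
  }
  w <- site_weights_cM(sites, map)
  chrom_code <- as.integer(factor(sites$chrom, levels = unique(sites$chrom)))
  out <- numeric(length(panels))
  for (i in seq_len(nrow(H))) {
    if (all(is.na(H[i, ]))) next
    out <- out + paint_copying_cpp(as.integer(H[i, ]), ref, pop,
                                   length(panels), w, chrom_code)
  }
  names(out) <- names(panels) %||%
    vapply(panels, function(p) p$label, character(1))
  class(out) <- c("painting_vector", class(out))
  out
}

#' @export
print.painting_vector <- function(x, ...) {
  v <- unclass(x)
  cat("painting_vector (cM copied per reference population):\n")
  print(round(v, 3))
  cat("shares:", paste(sprintf("%s=%.3f", names(v), v / sum(v)),
                       collapse = ", "), "\n")
  invisible(x)
}

#' Self-copy matrix of reference populations
#'
#' Column `k` is the mean painting vector of population `k`'s individuals,
#' each painted against the full panel set with that individual's two
#' haplotypes left out (leave-one-individual-out, so an individual cannot
#' trivially copy itself). Columns are normalized to sum 1. This matrix is
#' the design matrix of the NNLS conversion from painting vectors to
#' ancestry proportions.
#'
#' @param panels named list of reference `haplotype_panel`s.
#' @param sites,map shared [site_table] and [genetic_map].
#' @return K x K matrix; rows and columns named by population.
#' @export
self_copy_matrix <- function(panels, sites, map) {
  K <- length(panels)
  labels <- names(panels) %||%
    vapply(panels, function(p) p$label, character(1))
  A <- matrix(0, K, K, dimnames = list(labels, labels))
  for (k in seq_len(K)) {
    Hk <- panels[[k]]$haplotypes
    n_ind <- nrow(Hk) %/% 2L
    acc <- numeric(K)
    for (i in seq_len(n_ind)) {
      rows <- rownames(Hk)[c(2L * i - 1L, 2L * i)]
      v <- paint_haplotypes(Hk[rows, , drop = FALSE], panels, sites, map,
                            exclude_rows = rows)
      acc <- acc + v / sum(v)
    }
    A[, k] <- acc / n_ind
  }
  sweep(A, 2, colSums(A), "/")
}

#' Individuals eligible for ancestry-specific painting
#'
#' Subcontinental inference on a masked genome is only meaningful when the
#' individual carries an appreciable amount of the target ancestry; genomes
#' whose genome-wide fraction of the target component is at or below
#' `min_fraction` (default 3%) are excluded.
#'
#' @param fractions per-individual ancestry fraction matrix (rows =
#'   individuals), e.g. `$Q` of [estimate_ancestry_fractions] or
#'   [chromosome_ancestry_fractions] output.
#' @param target_ancestry column to threshold.
#' @param min_fraction exclusion threshold (default 0.03).
#' @return Named logical vector: eligible individuals.
#' @export
eligible_for_painting <- function(fractions, target_ancestry,
                                  min_fraction = 0.03) {
  f <- fractions[, target_ancestry]
  setNames(!is.na(f) & f > min_fraction, rownames(fractions))
}

#' Convert a painting vector to ancestry proportions by NNLS
#'
#' Solves `min || A x - b ||_2` subject to `x >= 0` (Lawson-Hanson NNLS via
#' [pracma::lsqnonneg]) where `b` is the individual's painting vector and
#' `A` the [self_copy_matrix], both normalized to sum 1, and returns the
#' normalized solution as a proportion vector.
#'
#' @param b painting vector (length K, non-negative, positive total).
#' @param A K x K self-copy matrix with unit-sum columns.
#' @return Named proportion vector on the simplex.
#' @export
nnls_ancestry <- function(b, A) {
  b <- as.numeric(b) / sum(b)
  if (!is.finite(sum(b)) || sum(b) <= 0) stop("no signal: empty painting vector")
  x <- pracma::lsqnonneg(as.matrix(A), b)$x
  if (sum(x) <= 0) stop("no signal: NNLS solution is zero")
  setNames(x / sum(x), colnames(A))
}

#' Validate subcontinental inference on a simulated proportion grid
#'
#' Runs the painting + NNLS pipeline on every genome of a
#' [generate_validation_cohort] and compares observed to expected focal
#' ancestry proportions: Pearson r (and r squared) per focal region, and a
#' pooled R squared over all regions.
#'
#' @param cohort a `validation_cohort`.
#' @param panels named list of validation reference `haplotype_panel`s
#'   (held out from the simulation's training haplotypes).
#' @return Object of class `validation_report`: `pairs` (data frame with
#'   region, expected and observed focal proportions), `per_region`
#'   (r and R squared per focal region), `pooled_r2`, `failures`.
#' @export
validate_inference <- function(cohort, panels) {
  stopifnot(inherits(cohort, "validation_cohort"))
  sites <- cohort$sites; map <- cohort$map
  A <- self_copy_matrix(panels, sites, map)
  rows <- list(); failures <- character(0)
  for (lab in names(cohort$regions)) {
    reg <- cohort$regions[[lab]]
    for (i in seq_along(reg$haplotypes)) {
      obs <- tryCatch({
        v <- paint_haplotypes(reg$haplotypes[[i]], panels, sites, map)
        nnls_ancestry(v, A)
      }, error = function(e) e)
      if (inherits(obs, "error")) {
        failures <- c(failures, sprintf("%s genome %d: %s", lab, i,
                                        conditionMessage(obs)))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        region = lab, genome = i,
        expected = reg$expected[i, lab],
        observed = unname(obs[lab]), stringsAsFactors = FALSE)
    }
  }
  if (length(failures))
    warning(length(failures), " genome(s) failed painting; excluded")
  pairs <- do.call(rbind, rows)
  per_region <- do.call(rbind, lapply(split(pairs, pairs$region), function(d)
    data.frame(region = d$region[1], n = nrow(d),
               r = cor(d$expected, d$observed),
               r2 = cor(d$expected, d$observed)^2)))
  rownames(per_region) <- NULL
  structure(list(pairs = pairs, per_region = per_region,
                 pooled_r2 = cor(pairs$expected, pairs$observed)^2,
                 failures = failures),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation_report:", nrow(x$pairs), "genomes,",
      nrow(x$per_region), "focal regions\n")
  for (i in seq_len(nrow(x$per_region)))
    cat(sprintf("  %s: r = %.4f (R2 = %.4f, n = %d)\n",
                x$per_region$region[i], x$per_region$r[i],
                x$per_region$r2[i], x$per_region$n[i]))
  cat(sprintf("pooled R2 = %.4f\n", x$pooled_r2))
  if (length(x$failures)) cat(length(x$failures), "failures\n")
  invisible(x)
}
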