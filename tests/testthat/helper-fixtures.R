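# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; no stored data.

# Small multi-chromosome panel set.
tiny_panels <- function(K = 3, F_k = 0.1, n_sites = 1500, n_hap = 40,
                        n_chrom = 3, morgans = 1, seed = 101) {
  chr <- setNames(rep(1e6, n_chrom), as.character(seq_len(n_chrom)))
  generate_founder_panels(K, F_k, n_sites = n_sites, n_hap = n_hap,
                          seed = seed, chrom_lengths_bp = chr,
                          morgans = morgans)
}

# Per-site ancestry labels of one haplotype implied by a tract table.
site_ancestry <- function(tracts, sites, hap) {
  out <- rep(NA_character_, nrow(sites))
  sub <- tracts[tracts$haplotype_id == hap, , drop = FALSE]
  for (r in seq_len(nrow(sub))) {
    sel <- sites$chrom == sub$chrom[r] &
      sites$pos >= sub$start[r] & sites$pos < sub$end[r]
    out[sel] <- sub$ancestry[r]
  }
  out
}

# Hand-built tract table (half-open bp intervals) for arithmetic checks.
toy_tracts <- function(haplotype_id, chrom, start, end, ancestry,
                       certainty = 1) {
  data.frame(haplotype_id = haplotype_id, chrom = as.character(chrom),
             start = start, end = end, ancestry = ancestry,
             certainty = certainty, stringsAsFactors = FALSE)
}

# Brute-force simplex grid search minimizing ||Ax - b|| at step 0.01;
# independent oracle for the NNLS conversion (3 populations).
grid_search_simplex3 <- function(A, b, step = 0.01) {
  best <- NULL; best_val <- Inf
  for (x1 in seq(0, 1, by = step)) {
    for (x2 in seq(0, 1 - x1, by = step)) {
      x <- c(x1, x2, 1 - x1 - x2)
      v <- sum((A %*% x - b)^2)
      if (v < best_val) { best_val <- v; best <- x }
    }
  }
  best
}
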