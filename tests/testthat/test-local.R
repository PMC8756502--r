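test_that("a verbatim panel haplotype is labeled its own population", {
  ps <- tiny_panels(K = 3, F_k = 0.2, n_sites = 1500, seed = 71)
  H <- ps$panels[[1]]$haplotypes[1:2, , drop = FALSE]
  rownames(H) <- c("ind1_1", "ind1_2")
  tr <- infer_local_ancestry(H, panel_frequencies(ps$panels), ps$sites,
                             ps$map, window_sites = 50)
  # never mislabeled; the occasional uninformative window may abstain
  expect_true(all(tr$ancestry %in% c("pop1", "UNKNOWN")))
  cm <- tract_cM(tr, ps$map)
  lab <- tr$ancestry == "pop1"
  expect_gt(sum(cm[lab]) / sum(cm), 0.9)
  expect_true(all(tr$certainty[lab] >= 0.95))
})

test_that("identical panels leave every window UNKNOWN", {
  ps <- tiny_panels(K = 2, n_sites = 600, seed = 73)
  panels <- list(a = ps$panels[[1]], b = ps$panels[[1]])
  Fm <- panel_frequencies(panels)
  H <- ps$panels[[1]]$haplotypes[1:2, , drop = FALSE]
  rownames(H) <- c("x_1", "x_2")
  tr <- infer_local_ancestry(H, Fm, ps$sites, ps$map, window_sites = 50)
  expect_true(all(tr$ancestry == "UNKNOWN"))
})

test_that("inferred ancestry matches truth on >= 90% of labeled sites", {
  # Band fixed after pilot runs at these conditions (F = 0.1, g = 10,
  # window 50, 1000 sites/Morgan): mean site-level accuracy ~0.93.
  ps <- generate_founder_panels(3, 0.1, n_sites = 4000, n_hap = 40,
                                seed = 75,
                                chrom_lengths_bp =
                                  setNames(rep(1e6, 4), as.character(1:4)),
                                morgans = 1)
  co <- simulate_admixed_cohort(ps$panels, ps$sites, ps$map, n = 6,
                                m = c(0.4, 0.35, 0.25), g = 10, seed = 76)
  tr <- infer_local_ancestry(co$haplotypes, panel_frequencies(ps$panels),
                             ps$sites, ps$map, window_sites = 50)
  accs <- vapply(rownames(co$haplotypes), function(h) {
    truth <- site_ancestry(co$tracts, ps$sites, h)
    inf <- site_ancestry(tr, ps$sites, h)
    lab <- inf != "UNKNOWN"
    mean(inf[lab] == truth[lab])
  }, numeric(1))
  expect_gte(mean(accs), 0.90)
})

test_that("raising the certainty threshold never increases the labeled fraction", {
  ps <- tiny_panels(K = 3, F_k = 0.1, n_sites = 1500, seed = 77)
  co <- simulate_admixed_cohort(ps$panels, ps$sites, ps$map, n = 3,
                                m = c(1, 2, 1) / 4, g = 10, seed = 78)
  lf <- vapply(c(0.5, 0.9, 0.99), function(ct) {
    tr <- infer_local_ancestry(co$haplotypes,
                               panel_frequencies(ps$panels),
                               ps$sites, ps$map, window_sites = 25,
                               certainty = ct)
    cm <- tract_cM(tr, ps$map)
    sum(cm[tr$ancestry != "UNKNOWN"]) / sum(cm)
  }, numeric(1))
  expect_true(all(diff(lf) <= 0))
  expect_lt(lf[3], 1)
})

test_that("labeled plus UNKNOWN tract lengths tile each haplotype", {
  ps <- tiny_panels(K = 2, n_sites = 800, n_chrom = 2, seed = 79)
  co <- simulate_admixed_cohort(ps$panels, ps$sites, ps$map, n = 2,
                                m = c(0.5, 0.5), g = 8, seed = 80)
  tr <- infer_local_ancestry(co$haplotypes, panel_frequencies(ps$panels),
                             ps$sites, ps$map, window_sites = 25)
  span <- tapply(tr$end - tr$start, paste(tr$haplotype_id, tr$chrom), sum)
  expect_true(all(span == 1e6))
  expect_silent(admixkit:::validate_tracts(tr))
})

test_that("masking keeps target-ancestry sites and blanks the rest", {
  ps <- tiny_panels(K = 2, n_sites = 400, n_chrom = 1, seed = 81)
  H <- ps$panels[[1]]$haplotypes[1:2, , drop = FALSE]
  rownames(H) <- c("i_1", "i_2")
  all_a <- toy_tracts(rep(c("i_1", "i_2"), 1), "1", 1, 1e6 + 1, "A")
  mg <- mask_genome(H, all_a, "A", ps$sites)
  expect_identical(mg$haplotypes, H)      # identity when fully target
  expect_warning(mg0 <- mask_genome(H, all_a, "B", ps$sites), "empty")
  expect_true(all(is.na(mg0$haplotypes)))  # nothing retained
  # split tracts: retained fraction matches the target tract span
  half <- rbind(toy_tracts(c("i_1", "i_2"), "1", 1, 5e5, "A"),
                toy_tracts(c("i_1", "i_2"), "1", 5e5, 1e6 + 1, "B"))
  mgh <- mask_genome(H, half, "A", ps$sites)
  expect_equal(unname(mgh$retained), rep(0.5, 2), tolerance = 0.06)
})

test_that("masking truth tracts retains the truth ancestry fraction of sites", {
  ps <- tiny_panels(K = 2, n_sites = 800, n_chrom = 4, seed = 83)
  co <- simulate_admixed_cohort(ps$panels, ps$sites, ps$map, n = 50,
                                m = c(0.4, 0.6), g = 10, seed = 84)
  mg <- mask_genome(co$haplotypes, co$tracts, "pop1", ps$sites)
  retained <- mean(mg$retained)
  f1 <- co$truth_fractions[, "pop1"]
  se <- sd(rowMeans(matrix(mg$retained, ncol = 2, byrow = TRUE))) / sqrt(50)
  expect_lt(abs(retained - 0.4), 3 * se + 0.01)
  # per-haplotype retained fraction tracks its own truth tract fraction
  expect_equal(retained, mean(f1), tolerance = 0.02)
})

test_that("chromosome ancestry fractions do plain genetic-length arithmetic", {
  gm <- uniform_genetic_map(c("1" = 1e6, "2" = 1e6), morgans = 1)
  tr <- rbind(toy_tracts("i_1", "1", 1, 1e6 + 1, "A"),
              toy_tracts("i_1", "2", 1, 1e6 + 1, "A"),
              toy_tracts("i_2", "1", 1, 5e5 + 1, "A"),
              toy_tracts("i_2", "1", 5e5 + 1, 1e6 + 1, "B"),
              toy_tracts("i_2", "2", 1, 1e6 + 1, "B"))
  fr <- chromosome_ancestry_fractions(tr, gm)
  expect_equal(unname(fr["i", c("A", "B")]), c(0.625, 0.375),
               tolerance = 1e-4)
  single <- chromosome_ancestry_fractions(tr[1:2, , drop = FALSE], gm)
  expect_equal(unname(single["i", "A"]), 1)
  # UNKNOWN excluded from the denominator
  tru <- rbind(toy_tracts("j_1", "1", 1, 5e5, "A"),
               toy_tracts("j_1", "1", 5e5, 1e6 + 1, "UNKNOWN"))
  fru <- chromosome_ancestry_fractions(tru, gm)
  expect_equal(unname(fru["j", "A"]), 1)
})
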