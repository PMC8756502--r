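test_that("founder panels are deterministic and validate their parameters", {
  a <- generate_founder_panels(2, 0.1, n_sites = 300, n_hap = 20, seed = 7)
  b <- generate_founder_panels(2, 0.1, n_sites = 300, n_hap = 20, seed = 7)
  expect_identical(a$panels[[1]]$haplotypes, b$panels[[1]]$haplotypes)
  expect_identical(a$sites, b$sites)
  expect_error(generate_founder_panels(2, 0, n_sites = 10, n_hap = 4,
                                       seed = 1), "F_k")
  expect_error(generate_founder_panels(2, 1, n_sites = 10, n_hap = 4,
                                       seed = 1), "F_k")
  expect_error(generate_founder_panels(1, 0.1, n_sites = 10, n_hap = 4,
                                       seed = 1), "K")
  expect_error(generate_founder_panels(2, 0.1, n_sites = 10, n_hap = 4),
               "seed")
})

test_that("no-drift limit gives indistinguishable panels", {
  ps <- generate_founder_panels(2, 1e-6, n_sites = 10000, n_hap = 100,
                                seed = 11)
  fst <- pairwise_fst(panel_freq_table(ps$panels[[1]]),
                      panel_freq_table(ps$panels[[2]]))
  expect_lt(abs(fst), 0.005)
})

test_that("Hudson F_ST of F = 0.1 panels falls in the simulation-oracle band", {
  # Band [0.09, 0.11] pre-registered from brute-force replicates of this
  # generator: the Hudson ratio-of-averages estimator concentrates on the
  # drift parameter F itself (mean 0.100, sd 0.0014 at this size).
  ps <- generate_founder_panels(2, 0.1, n_sites = 10000, n_hap = 100,
                                seed = 13)
  fst <- pairwise_fst(panel_freq_table(ps$panels[[1]]),
                      panel_freq_table(ps$panels[[2]]))
  expect_gt(fst, 0.09)
  expect_lt(fst, 0.11)
})

test_that("tract counts match the Poisson-breakpoint oracle", {
  # 10 chromosomes x 1 Morgan, g = 10, two ancestries at 1/2: merged tract
  # count per haploid genome is (ancestry switches) + (chromosomes), with
  # E[switches] = g * M * (1 - sum(m^2)) = 50.
  ps <- tiny_panels(K = 2, n_sites = 200, n_chrom = 10, seed = 17)
  co <- simulate_admixed_cohort(ps$panels, ps$sites, ps$map, n = 100,
                                m = c(0.5, 0.5), g = 10, seed = 18,
                                genotypes = FALSE)
  per_hap <- table(co$tracts$haplotype_id)
  expect_equal(length(per_hap), 200)
  se <- sd(per_hap) / sqrt(length(per_hap))
  expect_lt(abs(mean(per_hap) - 60), 3 * se)
})

test_that("degenerate proportions give a single-ancestry genome", {
  ps <- tiny_panels(K = 3, n_sites = 300, seed = 19)
  co <- simulate_admixed_cohort(ps$panels, ps$sites, ps$map, n = 3,
                                m = c(1, 0, 0), g = 5, seed = 20)
  expect_true(all(co$tracts$ancestry == "pop1"))
  expect_equal(unname(co$truth_fractions[, "pop1"]), rep(1, 3))
})

test_that("truth ancestry fractions converge to m and tracts tile exactly", {
  ps <- tiny_panels(K = 2, n_sites = 200, n_chrom = 6, seed = 23)
  co <- simulate_admixed_cohort(ps$panels, ps$sites, ps$map, n = 100,
                                m = c(0.5, 0.5), g = 10, seed = 24,
                                genotypes = FALSE)
  expect_silent(admixkit:::validate_tracts(co$tracts))
  # bp coverage: every haplotype-chromosome tiled from 1 to end+1
  span <- tapply(co$tracts$end - co$tracts$start,
                 paste(co$tracts$haplotype_id, co$tracts$chrom), sum)
  expect_true(all(span == 1e6))
  f1 <- co$truth_fractions[, 1]
  se <- sd(f1) / sqrt(length(f1))
  expect_lt(abs(mean(f1) - 0.5), 3 * se)
})

test_that("merged tract lengths are exponential at rate g(1 - m)", {
  # chromosomes long (5 Morgans) relative to the ~1/7 Morgan mean tract so
  # finite-window truncation of complete tracts is negligible
  ps <- tiny_panels(K = 2, n_sites = 120, n_chrom = 4, morgans = 5,
                    seed = 27)
  co <- simulate_admixed_cohort(ps$panels, ps$sites, ps$map, n = 60,
                                m = c(0.3, 0.7), g = 10, seed = 28,
                                genotypes = FALSE)
  tl <- collect_tract_lengths(co$tracts, ps$map, "pop1")
  lens <- tl$lengths[!tl$censored]
  expect_gt(length(lens), 2000)
  set.seed(29)
  ks <- suppressWarnings(stats::ks.test(sample(lens, 2000), "pexp",
                                        rate = 10 * 0.7))
  expect_gt(ks$p.value, 0.01)
})

test_that("validation grid has the stated geometry and simplex closure", {
  ps <- tiny_panels(K = 4, n_sites = 120, n_chrom = 2, seed = 31)
  vc <- generate_validation_cohort(ps$panels, ps$sites, ps$map, g = 10,
                                   genomes_per_point = 20, seed = 32)
  # 20%-80% in 5% increments, 20 genomes each: 13 x 20 = 260 per region
  expect_equal(length(vc$grid), 13)
  expect_equal(nrow(vc$regions[[1]]$expected), 260)
  expect_equal(length(vc$regions[[1]]$haplotypes), 260)
  for (r in vc$regions)
    expect_equal(unname(rowSums(r$expected)), rep(1, 260))
  # focal 0.80 with 4 regions: the rest split evenly at 0.2/3
  e <- vc$regions[["pop1"]]$expected
  top <- e[e[, "pop1"] == 0.80, , drop = FALSE]
  expect_equal(unname(top[1, c("pop2", "pop3", "pop4")]),
               rep(0.2 / 3, 3), tolerance = 1e-12)
})

test_that("quota-controlled genomes realize their expected proportions", {
  ps <- tiny_panels(K = 3, n_sites = 300, n_chrom = 6, seed = 33)
  set.seed(34)
  for (m1 in c(0.2, 0.5, 0.8)) {
    m <- c(m1, (1 - m1) / 2, (1 - m1) / 2)
    sim <- admixkit:::simulate_quota_genome(ps$panels, ps$sites, ps$map,
                                            m, g = 10)
    expect_lt(max(abs(sim$realized - m)), 0.05)
    expect_silent(admixkit:::validate_tracts(sim$tracts))
  }
})

test_that("cohort simulation is bit-reproducible under a fixed seed", {
  ps <- tiny_panels(K = 2, n_sites = 200, seed = 37)
  a <- simulate_admixed_cohort(ps$panels, ps$sites, ps$map, n = 4,
                               m = c(0.6, 0.4), g = 8, seed = 38)
  b <- simulate_admixed_cohort(ps$panels, ps$sites, ps$map, n = 4,
                               m = c(0.6, 0.4), g = 8, seed = 38)
  expect_identical(a$haplotypes, b$haplotypes)
  expect_identical(a$tracts, b$tracts)
})

test_that("training/validation splits keep diploid pairing and disjointness", {
  ps <- tiny_panels(K = 2, n_sites = 100, seed = 39)
  sp <- split_panel(ps$panels[[1]], training_fraction = 0.5)
  expect_identical(sp$training$role, "training")
  expect_identical(sp$validation$role, "validation")
  expect_equal(nrow(sp$training$haplotypes) %% 2, 0)
  expect_equal(nrow(sp$training$haplotypes) +
                 nrow(sp$validation$haplotypes), 40)
  expect_length(intersect(rownames(sp$training$haplotypes),
                          rownames(sp$validation$haplotypes)), 0)
})

test_that("recombinant panel members are mosaics of their founder pool", {
  ps <- tiny_panels(K = 2, n_sites = 400, seed = 41)
  rp <- recombine_panel(ps$panels[[1]], ps$sites, ps$map, n_out = 10,
                        seed = 42)
  expect_equal(nrow(rp$haplotypes), 10)
  expect_identical(rp$role, "validation")
  # every site's allele exists among the founders (it was copied)
  src <- ps$panels[[1]]$haplotypes
  for (j in sample(ncol(src), 50))
    expect_true(all(rp$haplotypes[, j] %in% src[, j]))
})
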