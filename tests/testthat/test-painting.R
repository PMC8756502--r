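test_that("a haplotype identical to one reference copies 100% from its population", {
  ps <- tiny_panels(K = 2, F_k = 0.1, n_sites = 500, n_hap = 10, seed = 91)
  target <- ps$panels[[1]]$haplotypes[1, , drop = FALSE]
  rownames(target) <- "t_1"
  v <- paint_haplotypes(target, ps$panels, ps$sites, ps$map)
  expect_gt(v[["pop1"]] / sum(v), 0.999)
})

test_that("identical reference populations split copying about 50/50", {
  ps <- tiny_panels(K = 2, n_sites = 500, n_hap = 10, seed = 93)
  dup <- list(a = ps$panels[[1]], b = ps$panels[[1]])
  dup$a$label <- "a"; dup$b$label <- "b"
  target <- ps$panels[[2]]$haplotypes[1, , drop = FALSE]
  rownames(target) <- "t_1"
  v <- paint_haplotypes(target, dup, ps$sites, ps$map)
  expect_equal(unname(v[1] / sum(v)), 0.5, tolerance = 0.02)
})

test_that("a 70/30 mosaic painted against its source panels recovers the shares", {
  # exact 70/30 mosaic: the first 70% of every chromosome's genetic length
  # copied from a pop1 haplotype, the rest from pop2 (F = 0.05 panels);
  # verbatim copying lets longest-match credit the true sources
  chr <- setNames(rep(1e6, 4), as.character(1:4))
  ps <- generate_founder_panels(2, 0.05, n_sites = 2000, n_hap = 30,
                                seed = 95, chrom_lengths_bp = chr)
  set.seed(96)
  H <- matrix(NA_integer_, 1, nrow(ps$sites),
              dimnames = list("mix_1", NULL))
  for (ch in unique(ps$sites$chrom)) {
    idx <- which(ps$sites$chrom == ch)
    cut <- ps$sites$pos[idx] <= 0.7 * 1e6
    H[1, idx[cut]] <- ps$panels[[1]]$haplotypes[sample(30, 1), idx[cut]]
    H[1, idx[!cut]] <- ps$panels[[2]]$haplotypes[sample(30, 1), idx[!cut]]
  }
  v <- paint_haplotypes(H, ps$panels, ps$sites, ps$map)
  shares <- v / sum(v)
  expect_lt(abs(shares[["pop1"]] - 0.7), 0.10)
  expect_lt(abs(shares[["pop2"]] - 0.3), 0.10)
})

test_that("painting an entirely masked genome is an error", {
  ps <- tiny_panels(K = 2, n_sites = 100, n_hap = 6, seed = 97)
  H <- matrix(NA_integer_, 2, 100, dimnames = list(c("x_1", "x_2"), NULL))
  expect_error(paint_haplotypes(H, ps$panels, ps$sites, ps$map),
               "empty ancestry component")
})

test_that("NNLS conversion is exact on columns and linear mixtures", {
  A <- matrix(c(0.6, 0.25, 0.15,
                0.2, 0.55, 0.25,
                0.15, 0.2, 0.65), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(unname(nnls_ancestry(A[, 2], A)), c(0, 1, 0),
               tolerance = 1e-8)
  mix <- 0.5 * A[, 1] + 0.5 * A[, 2]
  expect_equal(unname(nnls_ancestry(mix, A)), c(0.5, 0.5, 0),
               tolerance = 1e-8)
  expect_error(nnls_ancestry(c(0, 0, 0), A), "no signal")
})

test_that("NNLS tolerates noise and matches a brute-force simplex grid search", {
  # well-conditioned self-copy matrix (strong diagonal)
  A <- matrix(c(0.70, 0.18, 0.12,
                0.15, 0.70, 0.15,
                0.12, 0.18, 0.70), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  set.seed(99)
  for (rep in 1:10) {
    x_true <- c(0.5, 0.3, 0.2)[sample(3)]
    b <- as.vector(A %*% x_true) + rnorm(3, 0, 0.01)
    b <- pmax(b, 0)
    x <- nnls_ancestry(b, A)
    expect_lt(max(abs(x - x_true)), 0.05)
    # independent oracle: exhaustive 0.01-step simplex search
    x_grid <- grid_search_simplex3(A, b / sum(b))
    expect_lt(max(abs(x - x_grid)), 0.02)
  }
})

test_that("the 3% minimum-ancestry rule excludes near-zero components", {
  Q <- matrix(c(0.50, 0.029, 0.031, 0.0,
                0.50, 0.971, 0.969, 1.0), 4, 2,
              dimnames = list(paste0("s", 1:4), c("AFR", "EUR")))
  el <- eligible_for_painting(Q, "AFR")
  expect_equal(unname(el), c(TRUE, FALSE, TRUE, FALSE))
  expect_true(all(eligible_for_painting(Q, "AFR", min_fraction = 0)[1:3]))
})

test_that("the validation report is near-perfect on a shared-signal grid and
           collapses under permutation of expectations", {
  chr <- setNames(rep(1e6, 4), as.character(1:4))
  ps <- generate_founder_panels(2, c(0.02, 0.03), n_sites = 2000,
                                n_hap = 12, seed = 103,
                                chrom_lengths_bp = chr)
  val <- lapply(ps$panels, function(p)
    recombine_panel(p, ps$sites, ps$map, n_out = 32,
                    seed = 104 + match(p$label, names(ps$panels))))
  vc <- generate_validation_cohort(ps$panels, ps$sites, ps$map, g = 10,
                                   grid = c(0.2, 0.4, 0.6, 0.8),
                                   genomes_per_point = 6, seed = 105)
  rep_ <- validate_inference(vc, val)
  expect_s3_class(rep_, "validation_report")
  expect_gt(rep_$pooled_r2, 0.9)
  expect_true(all(abs(rep_$per_region$r) <= 1))
  # permutation null: shuffling expected values destroys the correlation
  set.seed(106)
  shuffled <- sample(rep_$pairs$expected)
  expect_lt(abs(cor(shuffled, rep_$pairs$observed)), 0.2)
})

test_that("validation R2 is invariant to relabeling the reference populations", {
  chr <- setNames(rep(1e6, 2), as.character(1:2))
  ps <- generate_founder_panels(2, c(0.02, 0.03), n_sites = 800,
                                n_hap = 12, seed = 107,
                                chrom_lengths_bp = chr)
  val <- lapply(ps$panels, function(p)
    recombine_panel(p, ps$sites, ps$map, n_out = 24,
                    seed = 108 + match(p$label, names(ps$panels))))
  vc <- generate_validation_cohort(ps$panels, ps$sites, ps$map, g = 10,
                                   grid = c(0.3, 0.7), genomes_per_point = 4,
                                   seed = 109)
  r1 <- validate_inference(vc, val)
  # relabel: swap the order of reference panels handed to the pipeline
  r2 <- validate_inference(vc, rev(val))
  expect_equal(r1$pooled_r2, r2$pooled_r2, tolerance = 1e-9)
})
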