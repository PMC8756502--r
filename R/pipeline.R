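#' Demonstration pipeline configuration
#'
#' A small but complete configuration exercising every stage on synthetic
#' data: 4 founder panels, a 60-genome admixed cohort with a sex-biased
#' X chromosome, local ancestry, a reduced painting-validation grid,
#' population statistics and tract-based dating.
#'
#' @param seed root seed (mandatory; all stage streams derive from it).
#' @param out_dir output directory.
#' @return Named list understood by [run_pipeline].
#' @export
demo_config <- function(seed, out_dir = tempfile("admixkit_demo")) {
  if (missing(seed)) stop("seed is required")
  list(
    seed = seed,
    out_dir = out_dir,
    panels = list(K = 4, F = c(0.08, 0.1, 0.12, 0.1), n_sites = 2000,
                  n_hap = 40,
                  labels = c("AFR", "EUR", "NAM", "EAS"),
                  chrom_bp = 1e6, chrom_morgans = 1, n_autosomes = 8,
                  x_morgans = 1.5),
    cohort = list(n = 60, m = c(0.35, 0.25, 0.35, 0.05), g = 10,
                  sex_bias = list(
                    m_female = c(0.30, 0.10, 0.55, 0.05),
                    m_male = c(0.40, 0.40, 0.15, 0.05))),
    local = list(window_sites = 25, certainty = 0.95),
    grid = list(enabled = TRUE, regions = 2, grid = c(0.3, 0.5, 0.7),
                genomes_per_point = 5),
    popstats = list(block_size_sites = 200, nj_bootstrap = 50),
    timing = list(ancestry = 1, n_boot = 200)
  )
}

validate_config <- function(config) {
  fail <- function(...) stop("config error: ", ..., call. = FALSE)
  if (is.null(config$seed)) fail("seed is mandatory")
  if (is.null(config$out_dir)) fail("out_dir is mandatory")
  for (f in c("panels", "cohort")) if (is.null(config[[f]]))
    fail("missing section '", f, "'")
  p <- config$panels
  for (f in c("K", "F", "n_sites", "n_hap")) if (is.null(p[[f]]))
    fail("panels$", f, " is mandatory")
  co <- config$cohort
  for (f in c("n", "m", "g")) if (is.null(co[[f]]))
    fail("cohort$", f, " is mandatory")
  if (length(co$m) != p$K) fail("cohort$m must have K entries")
  if (abs(sum(co$m) - 1) > 1e-6) fail("cohort$m must sum to 1")
  invisible(TRUE)
}

#' Run the end-to-end synthetic admixture pipeline
#'
#' Executes the stages in dependency order — founder-panel simulation,
#' admixed-cohort simulation, global ancestry (fractions, entropy, kinship,
#' PCA), local ancestry, sex-biased admixture, painting validation grid,
#' population statistics (F_ST, neighbor joining, outgroup f3) and
#' tract-based admixture dating — writing every intermediate as plain text
#' (VCF, TSV, Newick, JSON) plus a manifest with md5 checksums and a JSON
#' summary. All randomness derives from the root seed through named
#' per-stage substreams, so reruns with the same configuration are
#' bit-identical.
#'
#' @param config configuration list (see [demo_config]) or path to a YAML
#'   file with the same structure.
#' @return Invisibly, a list with `manifest` (file, md5, stage), `summary`
#'   (per-population mean fractions and entropy, delta-admix medians,
#'   validation R squared, g estimate, F_ST matrix), and `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  manifest <- data.frame(file = character(0), md5 = character(0),
                         stage = character(0), stringsAsFactors = FALSE)
  emit <- function(stage, file) {
    manifest[nrow(manifest) + 1L, ] <<-
      list(basename(file), unname(tools::md5sum(file)), stage)
  }
  summary <- list()
  pc <- config$panels

  # --- panels ---------------------------------------------------------
  n_auto <- pc$n_autosomes %||% 8
  chrom_bp <- rep(pc$chrom_bp %||% 1e6, n_auto)
  names(chrom_bp) <- as.character(seq_len(n_auto))
  morg <- rep(pc$chrom_morgans %||% 1, n_auto)
  sexed <- !is.null(config$cohort$sex_bias)
  if (sexed) {
    chrom_bp <- c(chrom_bp, X = pc$chrom_bp %||% 1e6)
    morg <- c(morg, pc$x_morgans %||% 1.5)
  }
  ps <- generate_founder_panels(pc$K, pc$F, pc$n_sites,
                                n_hap = pc$n_hap,
                                seed = substream_seed(seed, "panels"),
                                chrom_lengths_bp = chrom_bp, morgans = morg,
                                labels = pc$labels %||%
                                  paste0("pop", seq_len(pc$K)))
  training <- ps$panels
  # painting references: recombinant mosaics of each founder pool, so
  # reference individuals share haplotypes with the simulated genomes the
  # way members of a real population do
  validation <- lapply(ps$panels, function(p)
    recombine_panel(p, ps$sites, ps$map,
                    n_out = pc$n_val %||% (2L * pc$n_hap),
                    seed = substream_seed(seed, paste0("val_", p$label))))
  write_genetic_map(ps$map, file.path(out_dir, "map.tsv"))
  emit("panels", file.path(out_dir, "map.tsv"))
  fr <- panel_frequencies(ps$panels)
  write.table(cbind(ps$sites[, c("chrom", "pos")], round(fr, 6)),
              file.path(out_dir, "panel_frequencies.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  emit("panels", file.path(out_dir, "panel_frequencies.tsv"))

  # --- cohort ---------------------------------------------------------
  cc <- config$cohort
  m_by_chrom <- NULL
  sexes <- NULL
  m_auto <- cc$m
  if (sexed) {
    sb <- sex_biased_proportions(cc$sex_bias$m_female, cc$sex_bias$m_male)
    m_auto <- sb$m_auto
    m_by_chrom <- list(X = sb$m_X)
    sexes <- rep(c("F", "M"), length.out = cc$n)
  }
  cohort <- simulate_admixed_cohort(training, ps$sites, ps$map,
                                    n = cc$n, m = m_auto, g = cc$g,
                                    seed = substream_seed(seed, "cohort"),
                                    m_by_chrom = m_by_chrom, sexes = sexes)
  write_vcf(cohort$haplotypes, ps$sites,
            file.path(out_dir, "cohort.vcf"))
  emit("cohort", file.path(out_dir, "cohort.vcf"))
  write_tracts(cohort$tracts, file.path(out_dir, "truth_tracts.tsv"))
  emit("cohort", file.path(out_dir, "truth_tracts.tsv"))

  # --- global ancestry ------------------------------------------------
  G <- cohort_genotypes(cohort)
  auto_sites <- ps$sites$chrom != "X"
  fit <- estimate_ancestry_fractions(G[, auto_sites, drop = FALSE],
                                     panel_frequencies(ps$panels)[auto_sites, ])
  qt <- data.frame(individual = rownames(fit$Q), round(fit$Q, 6))
  write.table(qt, file.path(out_dir, "ancestry_fractions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  emit("global", file.path(out_dir, "ancestry_fractions.tsv"))
  summary$mean_fractions <- colMeans(fit$Q)
  summary$admixture_entropy <- admixture_entropy(colMeans(fit$Q))
  kin <- kinship_filter(G)
  summary$kinship_removed <- kin$removed
  pca <- pca_genotypes(G[, auto_sites, drop = FALSE])
  write.table(round(pca$scores[, 1:2], 6),
              file.path(out_dir, "pca.tsv"), sep = "\t", quote = FALSE)
  emit("global", file.path(out_dir, "pca.tsv"))

  # --- local ancestry -------------------------------------------------
  lc <- config$local %||% list()
  la <- infer_local_ancestry(cohort$haplotypes,
                             panel_frequencies(ps$panels),
                             ps$sites, ps$map,
                             window_sites = lc$window_sites %||% 25,
                             certainty = lc$certainty %||% 0.95)
  write_tracts(la, file.path(out_dir, "inferred_tracts.tsv"))
  emit("local", file.path(out_dir, "inferred_tracts.tsv"))

  # --- sex bias -------------------------------------------------------
  if (sexed) {
    da <- cohort_delta_admix(cohort$tracts, ps$map)
    write.table(da$records, file.path(out_dir, "delta_admix.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    emit("sexbias", file.path(out_dir, "delta_admix.tsv"))
    summary$delta_admix_medians <- da$medians
  }

  # --- painting validation grid --------------------------------------
  gc_ <- config$grid %||% list(enabled = FALSE)
  if (isTRUE(gc_$enabled)) {
    reg <- seq_len(min(gc_$regions %||% 2, pc$K))
    vc <- generate_validation_cohort(training[reg], ps$sites, ps$map,
                                     g = cc$g,
                                     grid = gc_$grid %||% c(0.3, 0.5, 0.7),
                                     genomes_per_point =
                                       gc_$genomes_per_point %||% 5,
                                     seed = substream_seed(seed, "grid"))
    rep_ <- validate_inference(vc, validation[reg])
    write.table(rep_$pairs, file.path(out_dir, "validation_pairs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    emit("validate", file.path(out_dir, "validation_pairs.tsv"))
    summary$validation_r2 <- rep_$pooled_r2
  }

  # --- population statistics -----------------------------------------
  st <- config$popstats %||% list()
  tabs <- lapply(ps$panels, panel_freq_table)
  D <- fst_matrix(tabs)
  write.table(round(D, 6), file.path(out_dir, "fst.tsv"),
              sep = "\t", quote = FALSE)
  emit("popstats", file.path(out_dir, "fst.tsv"))
  summary$fst <- D[upper.tri(D)]
  if (length(tabs) >= 3) {
    tree <- neighbor_joining(D,
                             bootstrap_replicates = st$nj_bootstrap %||% 0,
                             per_site_tables = tabs,
                             seed = substream_seed(seed, "nj"))
    write_newick(tree, file.path(out_dir, "nj_tree.nwk"))
    emit("popstats", file.path(out_dir, "nj_tree.nwk"))
    f3 <- outgroup_f3(tabs[[1]], tabs[[2]], tabs[[3]],
                      block_size_sites = st$block_size_sites %||% 200)
    summary$f3 <- f3$f3
  }

  # --- timing ---------------------------------------------------------
  tc <- config$timing %||% list()
  anc_idx <- tc$ancestry %||% 1
  anc_lab <- if (is.numeric(anc_idx)) names(training)[anc_idx] else anc_idx
  auto_tracts <- cohort$tracts[cohort$tracts$chrom != "X", , drop = FALSE]
  tl <- collect_tract_lengths(auto_tracts, ps$map, anc_lab)
  pe <- estimate_pulse_time(tl, proportion = m_auto[match(anc_lab,
                                                          names(training))],
                            n_boot = tc$n_boot %||% 200,
                            seed = substream_seed(seed, "timing"))
  summary$g_hat <- pe$g_hat
  summary$g_ci <- pe$ci

  # --- summary + manifest --------------------------------------------
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  emit("summary", file.path(out_dir, "summary.json"))
  write.table(manifest, file.path(out_dir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(manifest = manifest, summary = summary, out_dir = out_dir))
}
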