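#' Collect ancestry tract lengths in Morgans
#'
#' Converts the bp extent of each tract of the requested ancestry to
#' genetic length (Morgans) via the map and flags censored tracts. A tract
#' whose end abuts the chromosome terminus is censored: its underlying
#' length was cut by the end of the chromosome. A tract starting at the
#' chromosome start but ending at an interior ancestry switch is a complete
#' observation (the switch-distance law is memoryless), so it is not
#' flagged.
#'
#' @param tracts tract data frame.
#' @param map a [genetic_map].
#' @param ancestry ancestry label to collect.
#' @return Object of class `tract_length_sample`: `ancestry`, `lengths`
#'   (Morgans, > 0), `censored` (logical), `empty` flag.
#' @export
collect_tract_lengths <- function(tracts, map, ancestry) {
  sel <- tracts[tracts$ancestry == ancestry, , drop = FALSE]
  if (nrow(sel) == 0) {
    warning("no tracts of ancestry '", ancestry, "'")
    return(structure(list(ancestry = ancestry, lengths = numeric(0),
                          censored = logical(0), empty = TRUE),
                     class = "tract_length_sample"))
  }
  info <- map_chromosomes(map)
  term <- setNames(info$end_bp, info$chrom)
  lens <- tract_cM(sel, map) / 100
  cens <- sel$end > term[sel$chrom]
  keep <- lens > 0
  structure(list(ancestry = ancestry, lengths = lens[keep],
                 censored = cens[keep], empty = FALSE),
            class = "tract_length_sample")
}

#' Single-pulse admixture time from tract lengths
#'
#' Under a single admixture pulse `g` generations ago, recombination breaks
#' ancestry blocks at rate `g` per Morgan, and after merging of adjacent
#' same-ancestry segments the observed tract lengths of an ancestry with
#' proportion `m` are exponential with rate `g (1 - m)`. The rate is
#' estimated by the censored-exponential maximum likelihood
#' `rate = n_uncensored / sum(all lengths)` (right-censored tracts
#' contribute exposure but no event). By default `g_hat` is the rate
#' itself; supplying the ancestry `proportion` applies the `1/(1 - m)`
#' correction mapping the merged-tract rate back to generations. The
#' confidence interval is a percentile bootstrap over tracts.
#'
#' @param sample a `tract_length_sample` (needs >= `min_tracts` uncensored
#'   tracts).
#' @param proportion optional ancestry proportion `m` for the `1/(1-m)`
#'   merged-tract correction (default `NULL`: `g_hat` equals the raw rate).
#' @param n_boot bootstrap replicates for the CI (default 1000).
#' @param conf confidence level (default 0.95).
#' @param seed seed for the bootstrap.
#' @param min_tracts minimum number of uncensored tracts (default 30).
#' @return Object of class `pulse_estimate`: `g_hat`, `ci`, `rate`,
#'   `n_tracts`, `n_uncensored`, `ancestry`.
#' @export
estimate_pulse_time <- function(sample, proportion = NULL, n_boot = 1000L,
                                conf = 0.95, seed = 1L, min_tracts = 30L) {
  stopifnot(inherits(sample, "tract_length_sample"))
  n_unc <- sum(!sample$censored)
  if (n_unc < min_tracts)
    stop("insufficient tracts: ", n_unc, " uncensored (need >= ",
         min_tracts, ")")
  corr <- if (is.null(proportion)) 1 else {
    if (proportion < 0 || proportion >= 1) stop("proportion must be in [0,1)")
    1 / (1 - proportion)
  }
  rate_of <- function(len, cen) sum(!cen) / sum(len)
  rate <- rate_of(sample$lengths, sample$censored)
  set.seed(as.integer(seed))
  n <- length(sample$lengths)
  boots <- vapply(seq_len(n_boot), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    rate_of(sample$lengths[i], sample$censored[i])
  }, numeric(1)) * corr
  alpha <- (1 - conf) / 2
  structure(list(g_hat = rate * corr,
                 ci = unname(quantile(boots, c(alpha, 1 - alpha))),
                 rate = rate, n_tracts = n, n_uncensored = n_unc,
                 conf = conf, ancestry = sample$ancestry),
            class = "pulse_estimate")
}

#' @export
print.pulse_estimate <- function(x, ...) {
  cat(sprintf(
    "pulse_estimate [%s]: g_hat = %.2f generations (%d%% CI %.2f-%.2f)\n",
    x$ancestry, x$g_hat, round(100 * x$conf), x$ci[1], x$ci[2]))
  cat(sprintf("  %d tracts (%d uncensored), raw switch rate %.3f / Morgan\n",
              x$n_tracts, x$n_uncensored, x$rate))
  invisible(x)
}
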