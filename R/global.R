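#' Supervised estimation of genome-wide ancestry fractions
#'
#' Maximum-likelihood estimation of each individual's ancestry fraction
#' vector `q` against fixed reference-panel allele frequencies, under the
#' standard binomial admixture likelihood
#' \deqn{\ell(q) = \sum_j [ g_j \log(\sum_k q_k f_{kj}) +
#'   (2-g_j) \log(\sum_k q_k (1-f_{kj})) ]}
#' maximized over the simplex by EM. The EM update is the usual
#' responsibility-weighted average, so the log-likelihood is non-decreasing
#' at every iteration (asserted). Frequencies are clipped to
#' `[eps, 1-eps]` before use.
#'
#' @param genotypes n x L matrix of alternate-allele dosages (0/1/2).
#' @param freqs L x K matrix of panel allele frequencies (columns = panels).
#' @param eps frequency clipping bound (default 1e-4).
#' @param tol EM stops when the log-likelihood improves by less than this
#'   (default 1e-7) or after `max_iter` iterations (default 2000).
#' @param max_iter maximum EM iterations.
#' @return Object of class `ancestry_fractions`: `Q` (n x K simplex rows),
#'   `loglik`, `iterations`, `converged` per individual, and an
#'   `identifiable` flag (FALSE when two panels have numerically identical
#'   frequency vectors, in which case the maximizer is not unique).
#' @examples
#' ps <- generate_founder_panels(2, 0.1, n_sites = 500, n_hap = 20, seed = 1)
#' G <- ps$panels[[1]]$haplotypes[1:2, ] + ps$panels[[1]]$haplotypes[3:4, ]
#' fit <- estimate_ancestry_fractions(G, panel_frequencies(ps$panels))
#' fit$Q  # rows close to (1, 0)
#' @export
estimate_ancestry_fractions <- function(genotypes, freqs, eps = 1e-4,
                                        tol = 1e-7, max_iter = 2000L) {
  G <- as.matrix(genotypes)
  Fm <- pmin(pmax(as.matrix(freqs), eps), 1 - eps)
  if (ncol(G) != nrow(Fm)) stop("genotypes and freqs disagree on site count")
  K <- ncol(Fm)
  raw <- as.matrix(freqs)
  mono <- apply(raw, 1, function(r) all(r <= eps) || all(r >= 1 - eps))
  if (all(mono))
    stop("all sites monomorphic across panels: ancestry is unidentifiable")
  identifiable <- TRUE
  if (K > 1) {
    for (a in seq_len(K - 1)) for (b in seq(a + 1, K))
      if (max(abs(Fm[, a] - Fm[, b])) < 1e-12) identifiable <- FALSE
  }
  if (!identifiable)
    warning("two panels have identical frequencies; fractions not identifiable")

  n <- nrow(G)
  Q <- matrix(NA_real_, n, K,
              dimnames = list(rownames(G), colnames(Fm)))
  ll_out <- numeric(n)
  iters <- integer(n)
  conv <- logical(n)
  Fc <- 1 - Fm
  for (i in seq_len(n)) {
    g <- G[i, ]
    ok <- !is.na(g)
    gv <- g[ok]
    Fi <- Fm[ok, , drop = FALSE]
    Ci <- Fc[ok, , drop = FALSE]
    q <- rep(1 / K, K)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      num1 <- Fi * rep(q, each = nrow(Fi))
      den1 <- rowSums(num1)
      num0 <- Ci * rep(q, each = nrow(Ci))
      den0 <- rowSums(num0)
      ll <- sum(gv * log(den1) + (2 - gv) * log(den0))
      if (ll < ll_old - 1e-8)
        stop("internal error: EM log-likelihood decreased")
      if (ll - ll_old < tol) { conv[i] <- TRUE; ll_old <- ll; break }
      ll_old <- ll
      q <- colSums(gv * num1 / den1 + (2 - gv) * num0 / den0) /
        (2 * length(gv))
      q <- q / sum(q)
    }
    Q[i, ] <- q
    ll_out[i] <- ll_old
    iters[i] <- it
  }
  structure(list(Q = Q, loglik = ll_out, iterations = iters,
                 converged = conv, identifiable = identifiable),
            class = "ancestry_fractions")
}

#' @export
print.ancestry_fractions <- function(x, ...) {
  cat("ancestry_fractions:", nrow(x$Q), "individuals x", ncol(x$Q),
      "components\n")
  cat("mean fractions:",
      paste(sprintf("%s=%.4f", colnames(x$Q), colMeans(x$Q)),
            collapse = ", "), "\n")
  if (!x$identifiable) cat("warning: components not identifiable\n")
  invisible(x)
}

#' @export
summary.ancestry_fractions <- function(object, ...) {
  s <- list(mean = colMeans(object$Q),
            se = apply(object$Q, 2, sd) / sqrt(nrow(object$Q)),
            entropy = admixture_entropy(colMeans(object$Q)),
            converged = all(object$converged))
  class(s) <- "summary.ancestry_fractions"
  s
}

#' @export
print.summary.ancestry_fractions <- function(x, ...) {
  cat("mean fractions (+- SE):\n")
  print(round(rbind(mean = x$mean, se = x$se), 4))
  cat(sprintf("admixture entropy: %.3f bits\n", x$entropy))
  invisible(x)
}

#' Shannon admixture entropy
#'
#' The admixture entropy of a population is the Shannon entropy of its mean
#' ancestry component fractions, `S = -sum_i p_i log2(p_i)` with
#' `0 log 0 = 0`. Base 2 (bits) is the default; a population evenly mixed
#' over four components scores 2 bits, an unadmixed one 0.
#'
#' @param p vector of mean ancestry fractions; must be non-negative and sum
#'   to 1 within `tol` (it is renormalized, so fraction vectors reported as
#'   rounded percentages can be passed directly after dividing by 100).
#' @param base logarithm base (default 2).
#' @param tol allowed deviation of `sum(p)` from 1 (default 0.01, absorbing
#'   rounding of printed percentage tables).
#' @return The entropy `S` (scalar).
#' @examples
#' admixture_entropy(c(0.25, 0.25, 0.25, 0.25))  # 2 bits
#' admixture_entropy(c(1, 0, 0, 0))              # 0
#' @export
admixture_entropy <- function(p, base = 2, tol = 0.01) {
  if (any(is.na(p)) || any(p < 0)) stop("fractions must be non-negative")
  if (abs(sum(p) - 1) > tol) stop("fractions must sum to 1")
  p <- p / sum(p)
  nz <- p > 0
  -sum(p[nz] * log(p[nz], base = base))
}
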