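# Weighted expectation-maximization for 1-D Gaussian mixtures.
#
# The fit treats (x, w) as binned observations: x are sorted sample locations
# (e.g. m/z channel centers) and w nonnegative masses (e.g. intensities of the
# average spectrum). Each component's density is evaluated only inside a
# +/- window_sd * sigma window, so models with thousands of narrow peaks stay
# linear in the number of components rather than quadratic.

fit_gmm1d <- function(x, w = NULL, mu0, sigma0, pi0 = NULL,
                      max_iter = 500L, tol = 1e-8,
                      sigma_floor = NULL, window_sd = 8) {
  n <- length(x)
  if (is.null(w)) w <- rep(1, n)
  stopifnot(length(w) == n, all(w >= 0), !is.unsorted(x))
  G <- length(mu0)
  stopifnot(G >= 1L, length(sigma0) %in% c(1L, G))
  sigma <- rep(sigma0, length.out = G)
  mu <- as.numeric(mu0)
  pis <- if (is.null(pi0)) rep(1 / G, G) else pi0 / sum(pi0)
  if (is.null(sigma_floor)) {
    sigma_floor <- if (n > 1L) min(diff(x)) / 2 else 1e-6
  }
  wtot <- sum(w)
  if (wtot <= 0) stop("all weights are zero")

  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    lo <- findInterval(mu - window_sd * sigma, x) + 1L
    hi <- findInterval(mu + window_sd * sigma, x)
    lo <- pmax(lo, 1L); hi <- pmin(hi, n)
    total <- numeric(n)
    dens <- vector("list", G)
    for (k in seq_len(G)) {
      if (lo[k] > hi[k]) { dens[[k]] <- numeric(0); next }
      idx <- lo[k]:hi[k]
      d <- pis[k] * dnorm(x[idx], mu[k], sigma[k])
      dens[[k]] <- d
      total[idx] <- total[idx] + d
    }
    pos <- w > 0 & total > 0
    ll <- sum(w[pos] * log(total[pos]))

    nk <- numeric(G)
    for (k in seq_len(G)) {
      if (lo[k] > hi[k]) next
      idx <- lo[k]:hi[k]
      tk <- total[idx]
      r <- ifelse(tk > 0, dens[[k]] / tk, 0)
      wk <- w[idx] * r
      sk <- sum(wk)
      nk[k] <- sk
      if (sk > wtot * 1e-12) {
        mk <- sum(wk * x[idx]) / sk
        vk <- sum(wk * (x[idx] - mk)^2) / sk
        mu[k] <- mk
        sigma[k] <- max(sqrt(vk), sigma_floor)
      }
    }
    pis <- nk / sum(nk)

    if (is.finite(ll) && is.finite(ll_old) &&
        abs(ll - ll_old) <= tol * (abs(ll) + tol)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  ord <- order(mu)
  list(mu = mu[ord], sigma = sigma[ord], weight = pis[ord],
       loglik = ll_old, iterations = iter, converged = converged)
}

# Convenience: 2-component fit on raw (unweighted) samples, as used by the
# region-driven feature filters. Initialized from the lower/upper tertiles.
fit_gmm1d_2comp <- function(values) {
  v <- sort(values)
  n <- length(v)
  q <- quantile(v, c(1 / 6, 5 / 6), names = FALSE, type = 7)
  s0 <- max(sd(v) / 2, 1e-8)
  fit_gmm1d(v, mu0 = q, sigma0 = c(s0, s0), max_iter = 200L, tol = 1e-8,
            sigma_floor = max(diff(range(v)) * 1e-6, 1e-12))
}
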