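# Shared fixtures, built in code. The small dataset is generated once per
# test run and reused by several files.

small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_dataset(sim_config(n_patients = 3, rng_seed = 42))
    cache
  }
})

small_processed <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- preprocess_dataset(small_dataset())
    cache
  }
})

# brute-force per-point Savitzky-Golay: least-squares polynomial fit over
# the window (shifted to a full window anchored at the ends), evaluated at
# the target point
sg_bruteforce <- function(x, window, order) {
  n <- length(x)
  half <- (window - 1) / 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, min(i - half, n - window + 1))
    idx <- lo:(lo + window - 1)
    fit <- stats::lm(y ~ stats::poly(t, order, raw = TRUE),
                     data = data.frame(t = idx - i, y = x[idx]))
    out[i] <- unname(stats::predict(fit, data.frame(t = 0)))
  }
  out
}

# O(n^2) pairwise AUC oracle (ties count 1/2)
auc_pairwise <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# numerical Hankel-transform evaluation of the diffusion dipole reflectance
# (Sommerfeld-identity frequency-domain form of the same Green's function)
hankel_reflectance <- function(rho_cm, mua, musp, n_rel = 1.4) {
  mut <- mua + musp
  z0 <- 1 / mut
  D <- 1 / (3 * mut)
  mueff <- sqrt(3 * mua * mut)
  rd <- -1.440 / n_rel^2 + 0.710 / n_rel + 0.668 + 0.0636 * n_rel
  A <- (1 + rd) / (1 - rd)
  zb <- 2 * A * D
  zi <- z0 + 2 * zb
  f <- function(s) {
    s * (exp(-sqrt(s^2 + mueff^2) * z0) +
           exp(-sqrt(s^2 + mueff^2) * zi)) * besselJ(s * rho_cm, 0)
  }
  stats::integrate(f, 0, Inf, rel.tol = 1e-10,
                   subdivisions = 2000L)$value / (4 * pi)
}
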