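# Shared fixture builders. Everything is generated in code under fixed
# seeds; nothing is read from disk.

# Cross-block cache for the acceptance suite: the calibration fixture is
# reused by the power check.
.acceptance_cache <- new.env(parent = emptyenv())

# A one-layer scenario small enough for fast unit tests.
tiny_scenario <- function(seed = 1, n_samples = 200, n_features = 10L,
                          layer = "protein", rho = 0.3, n_exposures = 3L,
                          n_categorical = 0L, ...) {
  sim_scenario(
    n_samples = n_samples,
    n_cohorts = 2,
    exposure_spec = tibble::tibble(
      family = "metals", n_exposures = n_exposures, rho = rho,
      n_categorical = n_categorical
    ),
    omics_spec = tibble::tibble(
      layer = layer, n_features = n_features, scale =
        if (layer == "methylation") "beta_0_1" else "log2", noise_sd = 0.5
    ),
    seed = seed,
    ...
  )
}

# Hand-built association records for rule-level tests.
make_records <- function(exposure, feature, effect, p,
                         layer = "protein", period = "childhood",
                         family = "metals", contrast = NA_character_,
                         se = 0.1, n = 100L, model_tag = "main",
                         significant = NULL) {
  out <- tibble::tibble(
    exposure = exposure, period = period, family = family,
    feature = feature, layer = layer, contrast = contrast,
    effect = effect, se = se, p = p, n = n, model_tag = model_tag
  )
  if (!is.null(significant)) out$significant <- significant
  out
}

# Brute-force BH step-up oracle: q_(i) = min_{j >= i} p_(j) * m / j.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(pmin(ps[i:m] * m / (i:m), 1))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# Floyd-Warshall all-pairs shortest paths on an unweighted edge list.
floyd_warshall <- function(nodes, from, to) {
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  d[cbind(from, to)] <- 1
  d[cbind(to, from)] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# Modularity of a partition by the definition Q = sum_c (e_c/m - (d_c/2m)^2).
modularity_oracle <- function(from, to, membership) {
  m <- length(from)
  comms <- unique(membership)
  q <- 0
  deg <- table(c(from, to))
  for (cc in comms) {
    members <- names(membership)[membership == cc]
    e_c <- sum(from %in% members & to %in% members)
    d_c <- sum(deg[names(deg) %in% members])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}
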