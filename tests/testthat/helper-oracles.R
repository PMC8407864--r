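# Independently coded brute-force oracles. These deliberately use naive
# loop-based formulations (and base R primitives only) so they share no code
# path with the package implementations they check.

oracle_pool <- function(b, s) {
  w <- numeric(length(b)); num <- 0
  for (i in seq_along(b)) { w[i] <- 1 / (s[i] * s[i]); num <- num + w[i] * b[i] }
  pooled <- num / sum(w)
  q <- 0
  for (i in seq_along(b)) q <- q + w[i] * (b[i] - pooled)^2
  k <- length(b)
  i2 <- if (k <= 1 || q <= 0) 0 else max(0, (q - (k - 1)) / q) * 100
  se <- sqrt(1 / sum(w))
  z <- pooled / se
  list(beta = pooled, se = se, z = z, p = 2 * pnorm(-abs(z)),
       q = q, df = k - 1, i2 = i2)
}

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (r in m:1) {
    val <- min(prev, p[o[r]] * m / r)
    adj[o[r]] <- val
    prev <- val
  }
  adj
}

oracle_lambda <- function(p) {
  chis <- qchisq(1 - p, df = 1)
  median(chis) / qchisq(0.5, df = 1)
}

oracle_het_q <- function(bp, sp, bm, sm) {
  q <- (bp - bm)^2 / (sp^2 + sm^2)
  # upper-tail form: the complement 1 - pchisq(q, 1) underflows for large q
  list(q = q, p = pchisq(q, 1, lower.tail = FALSE),
       i2 = max(0, (q - 1) / q) * 100)
}

# small consortium used by several tests; fixed structure, configurable seed
tiny_config <- function(seed = 1L, n_cohorts = 3L, n = 150L, n_probes = 60L,
                        effect_specs = NULL, ...) {
  simulation_config(n_cohorts = n_cohorts, cohort_sizes = rep(n, n_cohorts),
                    n_probes = n_probes, n_cell_types = 4L,
                    n_batch_factors = 5L, effect_specs = effect_specs,
                    seed = seed, ...)
}
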