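# Shared fixtures and independent oracles.

# signal table builder: one row per (id, strain, condition, assay)
make_signals <- function(ids, strain, h_b, h_s, p_b, p_s,
                         conditions = c("basal", "il4")) {
  rbind(
    data.frame(element_id = ids, strain = strain, condition = conditions[1],
               assay = "H3K27ac", value = h_b, stringsAsFactors = FALSE),
    data.frame(element_id = ids, strain = strain, condition = conditions[2],
               assay = "H3K27ac", value = h_s, stringsAsFactors = FALSE),
    data.frame(element_id = ids, strain = strain, condition = conditions[1],
               assay = "PolII", value = p_b, stringsAsFactors = FALSE),
    data.frame(element_id = ids, strain = strain, condition = conditions[2],
               assay = "PolII", value = p_s, stringsAsFactors = FALSE))
}

# brute-force re-statement of the element classification rules, written as a
# literal per-element rule table (independent of the vectorized code path)
oracle_classify <- function(h_b, h_s, p_b, p_s, cfg = pipeline_config()) {
  out <- character(length(h_b))
  for (i in seq_along(h_b)) {
    if (max(h_b[i], h_s[i]) < cfg$min_h3k27ac ||
        max(p_b[i], p_s[i]) < cfg$min_polii) {
      out[i] <- "below_minimum"
      next
    }
    fh <- (h_s[i] + 1) / (h_b[i] + 1)
    fp <- (p_s[i] + 1) / (p_b[i] + 1)
    if (fh >= cfg$induce_fc && fp >= cfg$induce_fc) out[i] <- "induced"
    else if (fh <= 1 / cfg$induce_fc && fp <= 1 / cfg$induce_fc) out[i] <- "repressed"
    else if (fh < cfg$neutral_fc && fh > 1 / cfg$neutral_fc &&
             fp < cfg$neutral_fc && fp > 1 / cfg$neutral_fc) out[i] <- "neutral"
    else out[i] <- "ambiguous"
  }
  out
}

# exact two-sided Fisher p by hypergeometric enumeration (with the
# conventional relative tolerance for floating-point probability ties)
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0L, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  sum(probs[probs <= dhyper(a, m, n, k) * (1 + 1e-7)])
}

# exact signed-rank two-sided p by full sign enumeration (n <= ~15)
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  mean(abs(W_all - mu) >= abs(W_obs - mu) - 1e-9)
}

tiny_params <- function(seed = 1, n_elements = 80, ...) {
  generator_params(seed = seed, n_elements = n_elements, n_genes = 40, ...)
}
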