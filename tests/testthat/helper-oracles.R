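# Independent oracles used by the unit and acceptance tests. These are
# deliberately written from first principles, not via the package's own
# code paths.

# territory attributes, restated literally (canonical column order)
oracle_side <- c("left", "right", "left", "right", "left", "right",
                 "left", "right", "midline")
oracle_compartment <- c(rep("supratentorial", 6), rep("infratentorial", 3))
oracle_circulation <- c(rep("anterior", 4), rep("posterior", 5))

# brute-force lesion-constellation flag computer over a length-9 count vector
oracle_flags <- function(cnt) {
  inv <- which(cnt >= 1)
  sides <- oracle_side[inv]
  sides <- sides[sides != "midline"]
  list(mal = sum(cnt) > 1,
       n_territories = length(inv),
       bilateral = ("left" %in% sides) && ("right" %in% sides),
       supra_and_infra = ("supratentorial" %in% oracle_compartment[inv]) &&
         ("infratentorial" %in% oracle_compartment[inv]),
       ant_and_post = ("anterior" %in% oracle_circulation[inv]) &&
         ("posterior" %in% oracle_circulation[inv]))
}

# two-sided Fisher p by full enumeration of tables with fixed margins
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(a) {
    stats::dhyper(a, r1, r2, c1)
  }, numeric(1))
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# direct BH step-up computation
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# brute-force HPDI: scan every window of ceiling(mass * n) sorted draws
oracle_hpdi <- function(draws, mass) {
  s <- sort(draws)
  n <- length(s)
  m <- ceiling(mass * n)
  if (m >= n) return(c(s[1], s[n]))
  best <- c(s[1], s[m])
  for (i in seq_len(n - m + 1)) {
    if (s[i + m - 1] - s[i] < best[2] - best[1] - 1e-15)
      best <- c(s[i], s[i + m - 1])
  }
  best
}

# closed-form log-normal scale from median and IQR (quantile identity)
oracle_lognormal_scale <- function(median, iqr) {
  r <- iqr / median
  log((r + sqrt(r^2 + 4)) / 2) / stats::qnorm(0.75)
}

# enumerate involvement patterns: all 2^9 subsets, with counts filled by
# `fill` (a function of the subset index giving 1s and 2s)
involvement_patterns <- function() {
  pats <- list()
  for (mask in 1:511) {
    inv <- which(bitwAnd(mask, 2^(0:8)) > 0)
    ones <- integer(9); ones[inv] <- 1L
    pats[[length(pats) + 1L]] <- ones
    mixed <- integer(9)
    mixed[inv] <- 1L + (seq_along(inv) + mask) %% 2L  # deterministic 1/2 mix
    if (!identical(mixed, ones)) pats[[length(pats) + 1L]] <- mixed
  }
  pats
}
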