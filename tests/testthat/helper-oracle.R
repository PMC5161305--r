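# Brute-force per-object Bernoulli oracles for the cascade sub-steps.
# These deliberately loop over individual objects (one uniform draw per
# object) so they are an independent implementation of the per-object
# event semantics the binomial-count kernels must reproduce.

oracle_bernoulli <- function(n, p) {
  if (n == 0L) return(0L)
  sum(stats::runif(n) < p)
}

# metabolism: each APAP metabolized w.p. p_met; metabolite NAPQI w.p. p_nap
oracle_metabolism <- function(apap, p_met, p_nap) {
  met <- 0L; nap <- 0L
  for (i in seq_len(apap)) {
    if (stats::runif(1) < p_met) {
      met <- met + 1L
      if (stats::runif(1) < p_nap) nap <- nap + 1L
    }
  }
  c(met = met, napqi = nap)
}

# NAPQI fate below threshold: depletion events; above: damage products
oracle_napqi_fate <- function(napqi, below_threshold, p_dep, p_react,
                              p_split) {
  if (below_threshold) {
    c(depleted = oracle_bernoulli(napqi, p_dep), mitod = 0L, nonmd = 0L)
  } else {
    r <- oracle_bernoulli(napqi, p_react)
    md <- oracle_bernoulli(r, p_split)
    c(depleted = 0L, mitod = md, nonmd = r - md)
  }
}

# amplification: each unamplified mitoD gains n ~ DU{1..6}
oracle_amplification <- function(unamp) {
  total <- 0L
  for (i in seq_len(unamp)) {
    total <- total + 1L + sample(1:6, 1L)
  }
  total
}

oracle_mitigation <- function(mitod, nonmd, p_mit, p_nonmd) {
  c(mitod_destroyed = oracle_bernoulli(mitod, p_mit),
    nonmd_destroyed = oracle_bernoulli(nonmd, p_nonmd))
}

# two-sample chi-squared comparison of integer samples, pooling sparse
# cells so expected counts stay reasonable
chisq_two_sample <- function(x, y, min_expected = 5) {
  lev <- sort(unique(c(x, y)))
  tx <- tabulate(match(x, lev), length(lev))
  ty <- tabulate(match(y, lev), length(lev))
  keep <- (tx + ty) / 2 >= min_expected
  if (sum(keep) < length(lev)) {
    tx <- c(tx[keep], sum(tx[!keep]))
    ty <- c(ty[keep], sum(ty[!keep]))
  }
  suppressWarnings(stats::chisq.test(rbind(tx, ty)))$p.value
}
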