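# Independent oracles used across the suite.  These never call the engine.

# Exact SSA for a birth-death process (birth rate b, per-molecule death
# rate d): returns the count at time t_end.
ssa_birth_death <- function(b, d, t_end, x0 = 0) {
  t <- 0; x <- x0
  repeat {
    a <- b + d * x
    if (a <= 0) return(x)
    t <- t + rexp(1, a)
    if (t > t_end) return(x)
    x <- if (runif(1) < b / a) x + 1 else max(0, x - 1)
  }
}

# Stationary occupancy of a 2-allele gene with constant activation a per
# inactive allele and deactivation d per active allele: alleles switch
# independently, so occupancy of {0,1,2} is Binomial(2, a/(a+d)).
toggle_stationary <- function(a, d) {
  dbinom(0:2, 2, a / (a + d))
}

# Brute-force two-sample chi-squared on a 2 x k count table.
chi2_brute <- function(obs, sim) {
  tab <- rbind(obs, sim)
  rowtot <- rowSums(tab); coltot <- colSums(tab); n <- sum(tab)
  E <- outer(rowtot, coltot) / n
  stat <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, p_value = pchisq(stat, df, lower.tail = FALSE))
}

# Hand-built trajectory for fate tests: constant or piecewise series.
synth_traj <- function(times, p53a, bax, p21) {
  Y <- cbind(P53a_nuc = p53a, BAX = bax, P21 = p21)
  structure(list(times = times, Y = Y,
                 G = matrix(0L, length(times), 0),
                 dsb = numeric(length(times)),
                 receptors = integer(length(times))),
            class = "cell_trajectory")
}
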