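# Shared fixtures, all generated in code from the simulator.

# calibrate gate + threshold from simulated reference-strain runs,
# consuming the current RNG stream
make_calibration <- function(n = 3000) {
  veh <- exposure_preset("DMSO")
  neg <- simulate_biosort_run(strain_preset("col-121"), veh, n)
  pos <- simulate_biosort_run(strain_preset("him-8"), veh, n)
  gate <- fit_adult_gate(neg)
  in_gate <- function(ev) ev[ev$tof >= gate$tof_min & ev$tof <= gate$tof_max, ]
  thr <- fit_gfp_threshold(in_gate(neg)$gfp_peak, in_gate(pos)$gfp_peak)
  list(gate = gate, threshold = thr)
}

# brute-force exact two-tailed Mann-Whitney over all group labelings,
# independent of the package's rank-sum counting implementation
brute_force_mw_p <- function(x, y) {
  n1 <- length(x)
  pool <- c(x, y)
  r <- rank(pool)
  mu <- n1 * length(y) / 2
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(length(pool), n1)
  us <- apply(idx, 2, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# brute-force two-sided Fisher p by explicit table enumeration with
# choose() products (probability-mass rule)
brute_force_fisher_p <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c; n <- m1 + m2
  xs <- max(0, k - m2):min(k, m1)
  pr <- choose(m1, xs) * choose(m2, k - xs) / choose(n, k)
  p_obs <- pr[xs == a]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# exhaustive-scan threshold oracle over the same candidate set
brute_force_threshold <- function(neg, pos) {
  vals <- sort(unique(c(neg, pos)))
  cands <- c(vals[1] - 1, (vals[-1] + vals[-length(vals)]) / 2,
             vals[length(vals)] + 1)
  best_tau <- NA; best <- Inf
  for (tau in cands) {
    s <- mean(neg > tau) + mean(pos <= tau)
    if (s < best - 1e-12 || (abs(s - best) <= 1e-12 && tau > best_tau)) {
      best <- s; best_tau <- tau
    }
  }
  best_tau
}
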