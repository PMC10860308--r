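# independent oracles: these never call the code paths they check

# Bartlett via base R
oracle_bartlett <- function(groups) {
  b <- stats::bartlett.test(groups)
  list(K2 = unname(b$statistic), df = unname(b$parameter), p = b$p.value)
}

# Monte-Carlo oracle for the Gamma-Poisson clutch model: expected value
# (and replicate sd) of the mean-over-genes log10 ratio of sample CV^2
# between an H clutch (phi * inflation) and a C clutch, at the given
# sample sizes and per-gene expected depth. Draws straight from rgamma /
# rpois, independent of the simulator.
oracle_mean_log_ratio <- function(mu, phi, inflation, nH, nC, depth_per_mu,
                                  reps = 200) {
  G <- length(mu)
  rep_means <- vapply(seq_len(reps), function(r) {
    lr <- vapply(seq_len(G), function(g) {
      draw_cv2 <- function(n, ph) {
        x <- stats::rgamma(n, shape = 1 / ph, scale = mu[g] * ph)
        k <- stats::rpois(n, depth_per_mu * x)
        stats::var(k) / mean(k)^2
      }
      log10(draw_cv2(nH, phi[g] * inflation) / draw_cv2(nC, phi[g]))
    }, 0)
    mean(lr[is.finite(lr)])
  }, 0)
  list(mean = mean(rep_means), sd = stats::sd(rep_means))
}

# per-gene expected total CV^2 of counts under the Gamma-Poisson model,
# by plain Monte Carlo
oracle_expected_cv2 <- function(mu, phi, depth_per_mu, ndraw = 1e5) {
  x <- stats::rgamma(ndraw, shape = 1 / phi, scale = mu * phi)
  k <- stats::rpois(ndraw, depth_per_mu * x)
  stats::var(k) / mean(k)^2
}
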