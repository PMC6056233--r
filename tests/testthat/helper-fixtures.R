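# Shared fixture builders; everything is generated in code at test time.

# densely sampled rectangular spectrum: `value` on [lo, hi], zero outside
rect_spectrum <- function(lo, hi, value, kind, step = 0.5) {
  wl <- seq(lo, hi, by = step)
  spectrum(wl, rep(value, length(wl)), kind = kind)
}

# noiseless stepped quench trace: plateau `pre`, then `post`, 10-s sampling
step_trace <- function(pre = 100, post = 40, n = 10,
                       construct = "test", condition = "apo") {
  times <- seq(0, by = 10, length.out = 2 * n)
  f <- c(rep(pre, n), rep(post, n))
  quench_experiment(times, f,
                    events = data.frame(time = times[n] + 5,
                                        label = "add_acceptor"),
                    construct = construct, condition = condition)
}

# Monte-Carlo oracle for the FCG forward model: mean Forster efficiency
# over draws from the zero-truncated Gaussian, with its standard error
fcg_mc_oracle <- function(mu, sigma, R0, n = 1e6) {
  r <- rnorm(n, mu, sigma)
  r <- r[r > 0]
  e <- 1 / (1 + (r / R0)^6)
  list(mean = mean(e), se = sd(e) / sqrt(length(e)))
}
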