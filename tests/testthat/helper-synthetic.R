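# construct a synthetic result with a prescribed constant sensory weight:
# r_out = alpha * s + (1 - alpha) * mu_bar with s constant within trials
synthetic_alpha_result <- function(alpha, mus, n_steps = 10) {
  nt <- length(mus)
  mu_bar <- mean(mus)
  s <- rep(mus, each = n_steps)
  sc <- data.frame(t = seq_along(s), s = s,
                   trial = rep(seq_len(nt), each = n_steps),
                   rM_low = mu_bar, rV_low = NA, rM_high = NA, rV_high = NA,
                   alpha = alpha,
                   r_out = alpha * s + (1 - alpha) * mu_bar)
  structure(list(scalars = sc, trial_means = mus,
                 protocol = stimulus_protocol(nt, 1, n_steps, c(min(mus),
                                              max(mus)), 0)),
            class = "pe_sim")
}
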