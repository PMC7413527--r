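# Shared small fixtures, built in code at test time.

small_config <- function(...) {
  generator_config(n_trials = 4, blocks_per_trial = 3,
                   treatments_per_trial = 5, trial_type = "N", seed = 1, ...)
}

# mixed-type trial set used for fitting tests
recovery_config <- function(noise_sd = 0, block_sd = 0, seed = 7, n_trials = 20) {
  generator_config(n_trials = n_trials, blocks_per_trial = 3,
                   treatments_per_trial = 5,
                   trial_type = rep_len(c("N", "P", "K", "factorial"), n_trials),
                   noise_sd = noise_sd, block_sd = block_sd, seed = seed)
}

# random compositions (rows close to 1)
random_composition <- function(n, D) {
  x <- matrix(stats::rexp(n * D), n, D)
  x / rowSums(x)
}

# literal arithmetic of the balance definition, as an independent oracle:
# loops over contrasts, geometric means computed explicitly
ilr_oracle <- function(x, scheme) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  colnames(x) <- scheme$parts
  out <- matrix(NA_real_, nrow(x), length(scheme$contrasts))
  for (i in seq_len(nrow(x))) {
    for (j in seq_along(scheme$contrasts)) {
      den <- scheme$contrasts[[j]]$den
      num <- scheme$contrasts[[j]]$num
      r <- length(den); s <- length(num)
      g_num <- prod(x[i, num])^(1 / s)
      g_den <- prod(x[i, den])^(1 / r)
      out[i, j] <- sqrt(r * s / (r + s)) * log(g_num / g_den)
    }
  }
  out
}
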