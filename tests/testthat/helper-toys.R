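# Shared toy fixtures: tiny alphabets and enumerable sequence spaces used by
# the sampler and energy-model tests.

toy_ab3 <- c("A", "C", "G")
toy_ab4 <- c("A", "C", "G", "T")

# All sequences of length L over an alphabet, lexicographic in position order.
enumerate_space <- function(L, alphabet) {
  grid <- do.call(expand.grid,
                  c(rep(list(alphabet), L), stringsAsFactors = FALSE))
  apply(grid[, rev(seq_len(L)), drop = FALSE], 1L, paste, collapse = "")
}

# Deterministic toy energy: weighted sum of alphabet ranks plus a small
# interaction, so the landscape is neither flat nor additive.
toy_energy_fn <- function(alphabet, coefs) {
  force(alphabet); force(coefs)
  function(x) {
    m <- match(seq_chars_test(x), alphabet)
    sum(coefs[seq_along(m)] * m) + 0.25 * (m[1] == m[length(m)])
  }
}

seq_chars_test <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Uniform prior over a reduced alphabet (normalized, unlike uniform_prior()
# which is fixed to the 20-letter alphabet).
toy_uniform_prior <- function(L, a) {
  ar_prior(function(x) L * log(1 / a),
           function(x) rep(log(1 / a), L), name = "toy-uniform")
}

# Boltzmann target over a toy space: maximize -efun, inverse temperature
# T_inv, uniform prior.
toy_target <- function(efun, L, alphabet, T_inv = 2) {
  energy_model(list(f = function(x) -efun(x)), weights = 1, T_inv = T_inv,
               prior = toy_uniform_prior(L, length(alphabet)))
}

# Exact Boltzmann probabilities of a target restricted to `space`.
exact_boltzmann <- function(target, space) {
  lp <- vapply(space, function(s) log_unnorm_density(target, s), numeric(1))
  p <- exp(lp - max(lp))
  p / sum(p)
}

total_variation <- function(p, q) 0.5 * sum(abs(p - q))
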