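# Independent numerical oracles used across test files.

# Trapezoid-rule causal convolution of two sampled signals on a common grid:
# the independent numerical oracle for the symbolic kernel algebra.
trap_conv <- function(a, b, dt) {
  n <- length(a)
  cv <- stats::convolve(a, rev(b), type = "open")[seq_len(n)]
  (cv - 0.5 * (a[1] * b + a * b[1])) * dt
}

# Numerically convolve the (unnormalized) exponential factors of one chain.
chain_conv_oracle <- function(cc, rates, t, dt) {
  out <- cc * exp(-rates[1] * t)
  for (g in rates[-1]) out <- trap_conv(out, exp(-g * t), dt)
  out
}

# Evaluate a whole kernel by numerically convolving each chain's factors.
kernel_conv_oracle <- function(k, t, dt) {
  out <- numeric(length(t))
  for (ch in k$chains) out <- out + chain_conv_oracle(ch$c, ch$rates, t, dt)
  out
}

# Random kernel with 1-2 chains of length 1-3, used by property tests.
random_kernel <- function() {
  n_chain <- sample(1:2, 1)
  chains <- lapply(seq_len(n_chain), function(i) {
    len <- sample(1:3, 1)
    list(c = stats::runif(1, -2, 2), rates = exp(stats::runif(len, log(0.05), log(2))))
  })
  prop_kernel(chains)
}

# Tiny network fixtures ------------------------------------------------------

toy_single_edge_net <- function(kernel, n = 3, from = 1, to = 2,
                                inhibitory = FALSE) {
  structure(list(
    n_neurons = n, labels = sprintf("N%03d", seq_len(n)),
    edges = data.frame(from = from, to = to, inhibitory = inhibitory,
                       extrasynaptic = FALSE),
    kernels = list(kernel)), class = "ground_truth_network")
}

quiet_screen <- function(...) suppressMessages(apply_inclusion(...))
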