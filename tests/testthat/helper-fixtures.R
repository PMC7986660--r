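# Shared fixtures: everything is generated in code at test time.

# Widely separated two-component data: clustering recovers the classes
# perfectly, which pins down label alignment in tests.
separated_sim <- function(n = 300, seed = 1) {
  mix <- mixture_model(c(0.5, 0.5), rbind(c(-10, 0), c(10, 0)))
  simulate_mixture(mix, n, seed = seed)
}

# The balanced two-class study scenario with a logistic outcome.
balanced_logistic_sim <- function(n = 1000, seed = 1) {
  simulate_mixture(two_class_mixture(0.5), n, seed = seed) |>
    add_logistic_outcome(c(-1, 2), seed = seed + 1000L)
}

# Symmetric two-class flip matrix.
flip_matrix <- function(p) {
  misclass_matrix(matrix(c(1 - p, p, p, 1 - p), 2))
}

# All permutations of 1..k, independent of the package internals (used as a
# brute-force oracle for label alignment).
perms_oracle <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- perms_oracle(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(pos) {
    t(apply(sub, 1L, append, values = k, after = pos - 1L))
  }))
}
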