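# Small fixtures used across the suite; everything is generated in code.

small_net_params <- function(...) {
  network_params(n_excitatory = 80L, n_inhibitory = 20L, group_size = 10L, ...)
}

# a 100-neuron network with two input groups and one output group
small_network <- function(seed = 1, ...) {
  build_network(small_net_params(...),
                group_spec(inputs = c("S1", "S2"), outputs = "A0"),
                seed = seed)
}

# drive the R reference path step by step from a stimulus raster and reward
# vector (mirrors what the compiled schedule engine consumes)
run_reference <- function(network, plasticity, stim_on, r_step) {
  in_labels <- names(network$groups)[
    vapply(network$groups, function(g) g$role, "") == "input"]
  for (t in seq_len(ncol(stim_on))) {
    active <- in_labels[stim_on[, t] == 1L]
    network <- step_rchp(network, plasticity, active = active, r = r_step[t])
  }
  network
}

# quantile oracle: type-7 by explicit sort-based interpolation
sort_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
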