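# Small shared fixtures. Everything is generated in code; sizes are kept
# tiny so the unit suite stays fast.

tiny_reservoir <- function(N = 40, num_inputs = 3, seed = 1, ...) {
  build_reservoir(reservoir_params(N = N, ...), num_inputs, seed)
}

# a boxcar schedule on the given rows
boxcar_schedule <- function(n_inputs, rows, duration = 100, on = 20,
                            off = 70, decision_time = duration) {
  inputs <- matrix(0, n_inputs, duration)
  inputs[rows, (on + 1):off] <- 1
  trial_schedule(inputs, decision_time)
}

# reference transfer function, written independently of the package path
ref_transfer <- function(x, y0 = 0.1, ymax = 1) {
  ifelse(x <= 0, y0 + y0 * tanh(x / y0), y0 + (ymax - y0) * tanh(x / (ymax - y0)))
}
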