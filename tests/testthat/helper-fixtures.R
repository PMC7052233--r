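# small in-code fixtures shared across the suite

tiny_pool <- function(m = 5, epsilon = 1) {
  build_pool(m, trait_ranges(epsilon = epsilon))
}

tiny_params <- function(m = 5, n = 2, epsilon = 1, ...) {
  model_params(pool = tiny_pool(m, epsilon), n_terraces = n, ...)
}

# constant-rate forcing avoids square-wave discontinuities in oracle tests
const_series <- function(P, end) {
  precip_series(times = 0, P = P, end = end)
}
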