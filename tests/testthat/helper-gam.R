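# shared builder for additive-model test data
gam_test_data <- function(n = 200, seed = 51) {
  set.seed(seed)
  st <- make_stations(24, c(10, 90), seed)
  d <- st[sample(24, n, replace = TRUE), ]
  d$noise <- rnorm(n)
  d
}
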