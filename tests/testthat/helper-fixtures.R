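# shared small fixtures, built in code

# 1-D strip domain: ny = 3 (no-flux top/bottom), source column at x = 0
strip_domain <- function(nx, dx) {
  src <- matrix(FALSE, 3, nx)
  src[, 1] <- TRUE
  grid_domain(nx, 3, dx, source_mask = src)
}

# analytic semi-infinite steady state of phi P'' = lambda P, P(0) = 1
strip_oracle <- function(x, phi, lambda) exp(-x * sqrt(lambda / phi))

test_community <- function() herbivore_community(c(100, 1000, 8000), c(5, 1, 0.1))
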