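# shared fixtures and tiny independent oracles used across test files

default_params <- fitness_params()

# independent closed-form oracle for the growth-rate model, written directly
# from the benefit/cost definitions (kept separate from the package path)
oracle_W <- function(x, y, p = default_params) {
  if (y > p$h) return(0)
  B <- p$a * y * x / (p$k + x)
  C <- p$b * y / (p$h - y)
  max(p$W0 * (1 + B - C), 0)
}

# central-difference derivative
num_deriv <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)

log_grid <- function(from, to, n) exp(seq(log(from), log(to), length.out = n))
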