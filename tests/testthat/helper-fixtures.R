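# Shared fixtures: tissue defaults and the standard study sources.

tp_default <- tissue_params()                                  # ambient 27 degC
tp_266 <- tissue_params(T_env = celsius_to_kelvin(26.6))       # sensitivity study ambient
src_sensitivity <- heat_source(Q = 0.045, d = 0.0105, R = 0.005)
src_point <- heat_source(Q = 0.1, d = 0.014, R = 0)            # point-source fixture

# Forward closed form written out independently of the package internals,
# used as the oracle for round-trip and regression checks.
oracle_surface_temp <- function(Q, d, R, h0, T_env_C, a) {
  T_env_C + Q / (4 * pi * h0 * ((d + R)^2 + a^2))
}

random_sources <- function(n, seed, R_zero = TRUE) {
  withr_seed <- function(expr) thermoloc:::with_seed(seed, expr)
  withr_seed(data.frame(
    Q = runif(n, 0.005, 0.5),
    d = runif(n, 0.004, 0.05),
    R = if (R_zero) 0 else runif(n, 0.0005, 0.01),
    a = runif(n, 0.002, 0.08)))
}
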