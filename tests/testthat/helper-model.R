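# shared fixtures: all built in code, nothing read from disk

default_phys <- build_physiology()
us_sys <- us_systemic_params()
cn_sys <- cn_systemic_params()
default_frac <- deposition_fractions()

# one-compartment first-order absorption closed form (amounts ng, mL, h)
bateman <- function(t, dose, FA, ka, Vc, CL, tlag = 0) {
  k <- CL / Vc
  tt <- pmax(t - tlag, 0)
  FA * dose * ka / (Vc * (ka - k)) * (exp(-k * tt) - exp(-ka * tt))
}

# first-order-absorption superposition train (continuous at dose times,
# like the PBPK model's plasma profile)
bateman_train <- function(t, dose, FA, ka, Vc, CL, dose_times) {
  vapply(t, function(ti) {
    past <- dose_times[dose_times <= ti]
    if (!length(past)) return(0)
    sum(vapply(past, function(tj) bateman(ti - tj, dose, FA, ka, Vc, CL),
               numeric(1)))
  }, numeric(1))
}

# fraction of a single dose's AUC lying within [0, T] for the Bateman form
bateman_auc_frac <- function(T, ka, k) {
  1 - (ka * exp(-k * T) - k * exp(-ka * T)) / (ka - k)
}

fake_nca <- function(...) {
  fields <- list(...)
  res <- nasalpbpk:::new_nca_result(fields)
  res
}

noise_free <- function(seed = 1) {
  noise_spec(proportional_sd = 0, additive_sd = 0, lloq = 0, seed = seed)
}
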