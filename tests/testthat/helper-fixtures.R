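# Shared fixtures: the injection-solution parameter set and coarse drive
# grids used across test files. Everything is generated in code.

solution_params <- function() {
  ensemble_params(M_tilde = 3.633e-6, M_C = 31580, sigma = 0.734,
                  alpha = 0.2057, E_A = 8.3)
}

coarse_drive <- function(by = 20) {
  drive_conditions(H_grid = seq(-300, 300, by = by))
}

# simulate a direct/reverse pair at both scan frequencies and preprocess
make_curve <- function(params = solution_params(), drive = coarse_drive(),
                       sigma_abs = 0, seed = 1) {
  nm <- noise_model(sigma_abs = sigma_abs, seed = seed)
  fast <- simulate_sweep(params, drive, F_sc = 8, noise = nm)
  slow <- simulate_sweep(params, drive, F_sc = 0.25, noise = nm)
  preprocess_sweeps(fast[c("direct", "reverse")],
                    slow[c("direct", "reverse")])
}

# printed reference rows with complete magnetics (used by several files)
processed_reference_rows <- function() {
  ref <- reference_biodistribution()
  ref[!is.na(ref$M_C), ]
}
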