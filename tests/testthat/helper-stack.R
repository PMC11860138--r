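# shared model stack for tests; 0.1 h grid keeps single tests fast while
# still resolving a 1.1-1.6 h half-life
default_stack <- function() {
  list(compound = default_compound(),
       physiology = build_physiology(),
       partition = default_partition_coefficients(),
       params = pbpk_parameters())
}

quick_profile <- function(regimen = dose_regimen(1000, "OD", 1),
                          grid_step = 0.1, t_end = 24,
                          params = pbpk_parameters(),
                          compound = default_compound()) {
  s <- default_stack()
  simulate_pbpk(compound, s$physiology, s$partition, params, regimen,
                grid_step = grid_step, t_end = t_end)
}

# hand-built constant-concentration profile for toxicity unit tests
constant_profile <- function(conc = 10, t_end = 24, liver_conc = conc) {
  n <- t_end / 0.5
  tissue <- matrix(liver_conc, nrow = n + 1, ncol = 1,
                   dimnames = list(NULL, "liver"))
  structure(list(time = seq(0, t_end, by = 0.5),
                 plasma = rep(conc, n + 1),
                 tissue = tissue,
                 dose_events = data.frame(time = 0, amount_umol = 1)),
            class = "concentration_profile", grid_step = 0.5)
}
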