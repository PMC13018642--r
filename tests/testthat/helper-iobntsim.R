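# coarser reporting grid for unit tests that only need summary quantities
fast_opts <- function(grid_dt = 5) solver_options(grid_dt = grid_dt)

# all-zero-rate parameter set (volume fractions must stay in (0, 1))
zero_pk <- function() {
  pk_parameters(k12 = 0, k21 = 0, k10 = 0, ps = 0, Fpv_t = 0,
                U_Dox = 0, U_Dox_e = 0, k1wi = 0, k2wi = 0, k3wi = 0,
                k5wi = 0, kiwi = 1e-3)
}

# relative error with a floor to avoid 0/0 at empty compartments
rel_err <- function(a, b, floor = 1e-12) abs(a - b) / pmax(abs(b), floor)
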