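# Shared miniature fixtures, built in code.

# uniform all-gray square domain, mm-sized
gray_domain <- function(size_mm = 2, px = 20) {
  n <- as.integer(size_mm * 1000 / px)
  tissue_domain(matrix(TISSUE["GRAY"], n, n), px)
}

# gray with a horizontal white band through the middle
banded_domain <- function(size_mm = 2, band_mm = 0.5, px = 20) {
  make_synthetic_brain(size_mm, size_mm,
                       tract = list(y_mm = size_mm / 2, thickness_mm = band_mm),
                       px_size = px, seed = 99)
}

# small, fast parameter set used across engine tests
quick_params <- function(...) {
  args <- utils::modifyList(
    list(tau_mean = 40, sigma_tau = 10, v_mean = 20, sigma_v = 5,
         p0 = 300, D_p = 1e-4, r_d = 0.1, r_s = 200, r_c = 0.05,
         K_p = 50, K_m = 50, beta_p = 0.5, beta_m = 0.5, p_a = 10,
         rho_R = 2, sigma_theta = 20,
         kappa = 50, dt = 0.5, end_day = 2),
    list(...))
  do.call(parameter_set, args)
}

# population of k identical cells at given positions
fixed_pop <- function(x, y, tau = 40, v = 20, lineage = LINEAGE["INFECTED"],
                      ...) {
  pop <- new_population()
  pop_add(pop, x, y, tau, v, lineage, ...)
  pop
}
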