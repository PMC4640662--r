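# small populations used across tests; built in code, deterministic
small_human <- function(n = 500, seed = 42) {
  d <- load_defaults("human", n = n)
  list(meta = d$meta, env = d$env, units = sample_population(d$meta, seed = seed))
}

small_rat <- function(n = 500, seed = 42) {
  d <- load_defaults("rat", n = n)
  list(meta = d$meta, env = d$env, units = sample_population(d$meta, seed = seed))
}

# a single deterministic unit with chosen parameters (sd = 0 draws)
one_unit <- function(G_n = 4, R_n = 1000, alpha_n = 0.3, k_n = 0.1,
                     Dbar_n = 3e-3, rho_n = 6.5e-3, Gamma_n = 9,
                     gamma_n = 10, zeta_n = 0.1) {
  tibble::tibble(G_n = G_n, R_n = R_n, alpha_n = alpha_n, k_n = k_n,
                 Dbar_n = Dbar_n, rho_n = rho_n, Gamma_n = Gamma_n,
                 gamma_n = gamma_n, zeta_n = zeta_n)
}
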