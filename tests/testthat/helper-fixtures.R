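# Shared fixtures: the reference parameter sets the generators emulate and
# small concentration grids used across tests.

pe_o2 <- list(kcat = 201, Km_alcohol = 50, Km_acceptor = 176)
ba_red <- list(kred = 117, Kd = 765)
ba_acid <- list(kon = 47, koff = 13)     # 3-Cl-4-methoxybenzoic acid
ba_acid4 <- list(kon = 10, koff = 18)    # 4-methoxybenzoic acid
ba_itc <- list(Kd_uM = 0.05, dH = -21.4)
pe_itc <- list(Kd_uM = 27.1, dH = -25.1)

grid_A <- function(Km = pe_o2$Km_alcohol) c(0.2, 0.5, 1, 3, 10) * Km
grid_B <- function(Km = pe_o2$Km_acceptor) c(0.2, 0.5, 1, 3, 10) * Km

pe_o2_grid <- function(noise_sd = 0, seed = NULL) {
  gen_bisubstrate(pe_o2$kcat, pe_o2$Km_alcohol, pe_o2$Km_acceptor,
                  A = grid_A(), B = grid_B(), noise_sd = noise_sd,
                  seed = seed)
}

red_series <- function(noise_sd = 0, seed = NULL) {
  gen_kobs(seq(ba_red$Kd * 0.75, ba_red$Kd * 6, length.out = 8),
           "reductant", kred = ba_red$kred, Kd = ba_red$Kd,
           noise_sd = noise_sd, seed = seed)
}
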