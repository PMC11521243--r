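# Frozen published values used as golden expectations across tests.
# All were transcribed from the bundled study's summary tables and
# independently re-verified by hand arithmetic before freezing.

# 12-parameter indices (IP, IPP, IGC at f = 0.952)
printed_classic <- list(
  flurbiprofen = c(ip = 0.42, ipp = 4.73, igc = 4.50),
  ludipress    = c(ip = 0.75, ipp = 6.72, igc = 6.40)
)

# 12-parameter incidence means, canonical group order
printed_incidences_classic <- rbind(
  flurbiprofen = c(5.50, 3.00, 4.85, 5.85, 5.24),
  ludipress    = c(5.45, 7.07, 5.19, 8.57, 7.95)
)
colnames(printed_incidences_classic) <-
  c("dimension", "compressibility", "flowability",
    "lubricity_stability", "lubricity_dosage")

# 15-parameter blend indices (IPP; IGCB at f = 0.950; IP)
printed_blends <- data.frame(
  run  = paste0("F", 1:9),
  ip   = c(0.67, 0.73, 0.67, 0.67, 0.67, 0.67, 0.67, 0.67, 0.67),
  ipp  = c(6.64, 6.26, 6.38, 6.13, 6.45, 6.26, 6.39, 6.28, 6.05),
  igcb = c(6.31, 5.95, 6.06, 5.83, 6.13, 5.95, 6.07, 5.96, 5.75)
)

# blend incidence means excluding disgregability (the published
# disgregability column disagrees with the mean of its three radii and is
# not asserted)
printed_incidences_blends <- rbind(
  F1 = c(5.08, 6.48, 4.72, 8.62, 5.16),
  F2 = c(4.25, 5.44, 5.18, 7.53, 5.17),
  F3 = c(4.36, 6.37, 4.99, 7.09, 5.20),
  F4 = c(4.15, 5.63, 4.63, 7.08, 5.22),
  F5 = c(4.88, 6.58, 4.50, 7.64, 5.17),
  F6 = c(4.50, 5.83, 4.34, 7.93, 5.22),
  F7 = c(4.71, 6.28, 4.53, 7.82, 5.13),
  F8 = c(4.50, 5.82, 4.43, 8.01, 5.15),
  F9 = c(4.30, 5.66, 4.15, 7.15, 5.14)
)
colnames(printed_incidences_blends) <- colnames(printed_incidences_classic)

# published composition table: tablet weight and mg per ingredient,
# 3-decimal display values
printed_compositions <- data.frame(
  run = paste0("F", 1:9),
  tablet_weight = c(219.780, 275.805, 240.963, 246.913, 265.392,
                    223.463, 230.792, 253.164, 281.690),
  ludipress_mg = c(107.692, 155.120, 118.072, 128.395, 138.004,
                   106.703, 120.012, 139.240, 154.929),
  croscarmellose_mg = c(2.197, 8.274, 12.048, 7.407, 15.445,
                        6.703, 0.394, 2.531, 14.084),
  aerosil_mg = c(0.307, 0.386, 0.337, 0.345, 0.371, 0.312, 0.323, 0.354, 0.394),
  talc_mg = c(5.186, 6.509, 5.686, 5.827, 6.263, 5.273, 5.446, 5.974, 6.647),
  aspartame_mg = c(2.197, 2.758, 2.409, 2.469, 2.653, 2.234, 2.307, 2.531, 2.816),
  magnesium_stearate_mg = c(2.197, 2.758, 2.409, 2.469, 2.653, 2.234, 2.307, 2.531, 2.816)
)

# published axial factor levels with the decimal precision they were
# printed at (the generated exact levels must truncate to these)
printed_axials <- data.frame(
  factor = c("ludipress", "ludipress", "croscarmellose", "croscarmellose"),
  coded = c(sqrt(2), -sqrt(2), sqrt(2), -sqrt(2)),
  printed = c(56.242, 47.75, 5.82, 0.171),
  digits = c(3, 2, 2, 3)
)

# canonical 7-point dissolution sampling grid (minutes)
grid7 <- c(2, 4, 6, 8, 10, 12, 15)

# r-squared fixture as a named-vector list for the model selector
printed_r2_sets <- function() {
  rk <- flurbiprofen_release_kinetics()
  lapply(seq_len(nrow(rk)), function(i) {
    c(first_order = rk$r2_first_order[i], higuchi = rk$r2_higuchi[i],
      hixson_crowell = rk$r2_hixson_crowell[i], weibull = rk$r2_weibull[i])
  })
}
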