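# deterministic in-code fixtures shared across test files

flat_cell_records <- function(n = 400L, area = 100) {
  data.frame(stage = "S1", replicate = 1L,
             pos_pd = seq(0.0025, 0.9975, length.out = n),
             pos_lat = rep(0.5, n),
             area = rep(area, n))
}

# exact division-decay points k = r_d * exp(-L / L0)
decay_points <- function(r_d = 1.1, L0 = 30,
                         L = c(5, 15, 30, 60, 120, 200, 280)) {
  list(L = L, k = r_d * exp(-L / L0))
}
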