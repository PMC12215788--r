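# In-code fixtures shared across test files.

# A hand-built long panel from named series: series[[video]][[region]] is a
# named list subject -> numeric vector.
build_panel <- function(series) {
  rows <- list()
  for (v in names(series)) {
    for (rg in names(series[[v]])) {
      for (s in names(series[[v]][[rg]])) {
        val <- series[[v]][[rg]][[s]]
        rows[[length(rows) + 1]] <- data.frame(
          subject = s, video = v, region = rg,
          timepoint = seq_along(val), value = val,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# Simulated panel -> ISC -> design chain at the test-preset geometry.
sim_chain <- function(seed, ...) {
  sim <- simulate_neural_panel(neural_sim_config(seed = seed, ...))
  isc <- compute_dyadic_isc(sim$panel)
  design <- build_dyad_design(sim$ratings, sim$attributes)
  list(sim = sim, isc = isc, design = design)
}
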