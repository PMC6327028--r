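#!/usr/bin/env Rscript
# Stage 1: generate the canonical synthetic datasets.
#
# Emulates the pulse-radiolysis campaign: a neat-solvent picosecond matrix
# (bilinear and shifting renderings), a 0.3 M solution matrix, the
# three-species deconvolution matrix (300 ps - 300 ns), a neat microsecond
# matrix, and the six-point concentration series. All matrices are written
# as CSV + metadata sidecars under results/data/ for the later stages.

suppressPackageStartupMessages(library(tasolv))
seed <- as.integer(Sys.getenv("TASOLV_SEED", "1"))
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("simulating with base seed ", seed)

write_ta_matrix(simulate_default_matrix(0, "ps", seed = seed),
                file.path(out, "neat_ps.csv"))
write_ta_matrix(simulate_default_matrix(0, "ps", seed = seed + 1,
                                        render = "shifting"),
                file.path(out, "neat_ps_shifting.csv"))
write_ta_matrix(simulate_default_matrix(0.3, "ps", seed = seed + 4),
                file.path(out, "solution_0p3M_ps.csv"))
write_ta_matrix(simulate_deconvolution_matrix(0.3, seed = seed + 2),
                file.path(out, "deconvolution_0p3M.csv"))
write_ta_matrix(simulate_default_matrix(0, "us", seed = seed + 3),
                file.path(out, "neat_us.csv"))

concs <- c(0, 0.05, 0.1, 0.2, 0.3, 0.5)
for (i in seq_along(concs)) {
  write_ta_matrix(
    simulate_default_matrix(concs[i], "ps", seed = seed + 10 + i),
    file.path(out, sprintf("series_%04.0fmM.csv", 1000 * concs[i])))
}

message("wrote ", length(list.files(out, pattern = "\\.csv$")),
        " matrices to ", out)
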