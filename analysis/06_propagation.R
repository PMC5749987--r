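#!/usr/bin/env Rscript
# Stage 6 — detonation sound-exposure propagation.
#
# Calibrates the additive constant of the SEL similitude relation to the
# eight published reference cells (least squares, one constant) and
# tabulates SEL and peak pressure for 5 lb and 20 lb charges at 1-12 km.

suppressPackageStartupMessages(library(minexpam))
dir.create("results", showWarnings = FALSE)

ref <- sel_reference_cells()
A <- calibrate_sel_constant(ref)
cat(sprintf("calibrated SEL constant A = %.2f dB (max cell residual %.2f dB)\n",
            A, max(abs(sel_db(ref$charge_lb, ref$range_km * 1000, A) -
                         ref$sel_db))))

tab <- exposure_table()
utils::write.csv(tab, "results/06_exposure_table.csv", row.names = FALSE)
print(tab, row.names = FALSE)

cat(sprintf("\nSEL for a 20 lb charge at 12 km: %d dB re 1 uPa^2 s\n",
            round(sel_db(20, 12000, A))))
cat("=> a receiver 12 km from a detonation is still appreciably ensonified,\n")
cat("   consistent with behavioural responses observed at that range.\n")
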