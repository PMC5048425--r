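#!/usr/bin/env Rscript
# Calibration audit for the default oscillator parameters.
#
# The package's defaults are required to satisfy, in order:
#   1. tau read back through the dynamics (limit cycle consistent);
#   2. a weak type-1 PRC to the 1-h, 1,000-lux pulse: max |shift| ~ 1-2 h,
#      dead zone in mid subjective day, delays early / advances late night;
#   3. entrainment of >= 9/10 seeded replicates at a 15-h dispersion window
#      at 1,000 lux, but < 10/10 at a 20-h window;
#   4. loss of entrainment at the 15-h window when pulses are 100 lux.
# This script recomputes all four from scratch so any parameter change can
# be audited with one run.

suppressPackageStartupMessages(library(circapulse))

p <- oscillator_params()
print(p)

cat(sprintf("free-running period: %.4f h (tau = %g)\n",
            free_running_period(p), p$tau))

prc <- phase_response_curve(p, pulse_duration = 1, lux = 1000, n_phases = 24)
cat(sprintf("PRC: max |shift| %.2f h; mid-day (CT6) shift %.3f h\n",
            max(abs(prc$shift_h)), prc$shift_h[prc$ct_h == 6]))
cat(sprintf("     delays CT13-16: %s\n",
            paste(sprintf("%.2f", prc$shift_h[prc$ct_h %in% 13:16]), collapse = " ")))
cat(sprintf("     advances CT19-22: %s\n",
            paste(sprintf("%.2f", prc$shift_h[prc$ct_h %in% 19:22]), collapse = " ")))

sweep <- entrainment_range(p, lux = 1000, I_grid = c(8, 14, 15, 16, 18, 20),
                           days = 40, replicates = 10, seed = 1)
cat("entrained fraction at 1,000 lux:\n")
print(sweep)

weak <- entrainment_range(p, lux = 100, I_grid = 15, days = 40,
                          replicates = 10, seed = 1)
cat(sprintf("I = 15 h at 100 lux (Lambda = %.3f): %d/10 entrained\n",
            lux_to_forcing(100, p), weak$entrained))
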