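#!/usr/bin/env Rscript
# Tunability of the feedforward controller: sweeps of the excisionase
# turnover d_X and the integrase synthesis rate k_I, and root-finding for
# the decoupling optimum of each.

suppressPackageStartupMessages(library(recflip))
dir.create("results", showWarnings = FALSE)

params <- circuit_parameters()

cat("== Excisionase turnover sweep (Re-NF-FF controller) ==\n")
sw_dx <- parameter_sweep(params, "RE_NF_FF", "d_X")
write_sweep(sw_dx, "results/dx_sweep.csv", params = params)
write.csv(data.frame(d_X = sw_dx$swept_values, ci = sw_dx$ci_per_value),
          "results/dx_ci_curve.csv", row.names = FALSE)
ci <- sw_dx$ci_per_value
cat(sprintf("  CI runs from %+.4f (slow turnover: overcompensation) to %+.4f\n",
            ci[1], ci[length(ci)]))
cat(sprintf("  sign changes across the grid: %d\n",
            sum(diff(sign(ci)) != 0)))

tuned_dx <- find_decoupling_value(params, "RE_NF_FF", "d_X",
                                  bracket = c(1e-2, 1e2), ci_tol = 1e-3)
cat(sprintf("  decoupling optimum: d_X* = %.3f 1/h (|CI| = %.2g, %d iterations)\n",
            tuned_dx$tuned_value, abs(tuned_dx$ci_at_value),
            tuned_dx$iterations))
jsonlite::write_json(tuned_dx[c("tuned_name", "tuned_value", "ci_at_value",
                                "iterations")],
                     "results/tuned_dx.json", auto_unbox = TRUE, digits = NA)

# dose response at the tuned optimum vs the open loop
opt <- dose_response_scan(update_parameters(params, d_X = tuned_dx$tuned_value),
                          "RE_NF_FF")
open_loop <- dose_response_scan(params, "OPEN_LOOP_MUT")
comp <- rbind(
  data.frame(system = "re_nf_ff_tuned", dose = opt$dose, G_ss = opt$G_ss,
             R_ss = opt$R_ss),
  data.frame(system = "open_loop", dose = open_loop$dose,
             G_ss = open_loop$G_ss, R_ss = open_loop$R_ss))
write.csv(comp, "results/gfp_rfp_tuned_vs_openloop.csv", row.names = FALSE)
cat(sprintf("  at d_X*: GFP stays within [%.2f, %.2f] a.u. across the ladder (open loop: [%.2f, %.2f])\n",
            min(opt$G_ss), max(opt$G_ss), min(open_loop$G_ss),
            max(open_loop$G_ss)))

cat("\n== Integrase synthesis-rate sweep ==\n")
sw_ki <- parameter_sweep(params, "RE_NF_FF", "k_I")
write_sweep(sw_ki, "results/ki_sweep.csv", params = params)
write.csv(data.frame(k_I = sw_ki$swept_values, ci = sw_ki$ci_per_value),
          "results/ki_ci_curve.csv", row.names = FALSE)
cik <- sw_ki$ci_per_value
cat(sprintf("  CI runs from %+.4f to %+.4f with %d sign change(s)\n",
            cik[1], cik[length(cik)], sum(diff(sign(cik)) != 0)))
tuned_ki <- find_decoupling_value(params, "RE_NF_FF", "k_I",
                                  bracket = range(sw_ki$swept_values),
                                  ci_tol = 1e-3)
cat(sprintf("  decoupling optimum: k_I* = %.3f a.u./h (|CI| = %.2g)\n",
            tuned_ki$tuned_value, abs(tuned_ki$ci_at_value)))
jsonlite::write_json(tuned_ki[c("tuned_name", "tuned_value", "ci_at_value",
                                "iterations")],
                     "results/tuned_ki.json", auto_unbox = TRUE, digits = NA)

cat("\nFindings: both recombinase knobs tune the controller through zero\n")
cat("coupling exactly once; either excisionase turnover or integrase\n")
cat("expression can balance feedforward overcompensation against residual\n")
cat("negative coupling.\n")
cat("Tables: results/dx_sweep.csv, dx_ci_curve.csv, ki_sweep.csv, ki_ci_curve.csv\n")
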