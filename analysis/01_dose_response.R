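#!/usr/bin/env Rscript
# Steady-state dose responses of the four circuit variants over the plate
# induction ladder, and their Coupling Indices.

suppressPackageStartupMessages(library(recflip))
dir.create("results", showWarnings = FALSE)

params <- circuit_parameters()
write_parameters(params, "results/default_parameters.yaml")

cat("== Dose responses over the L-ara ladder (default parameters) ==\n")
summary_rows <- list()
for (topo in CIRCUIT_TOPOLOGIES) {
  tab <- dose_response_scan(params, topo)
  write_dose_response(tab, sprintf("results/dose_response_%s.csv", topo),
                      params = params)
  ci <- tryCatch(compute_ci(normalize_responses(tab)),
                 error = function(e) NULL)
  ci_val <- if (is.null(ci)) NA_real_ else ci$ci
  sign <- if (is.null(ci)) "degenerate" else ci$sign
  summary_rows[[topo]] <- data.frame(
    topology = topo,
    G_baseline = tab$G_ss[1], G_top_dose = tab$G_ss[nrow(tab)],
    R_top_dose = tab$R_ss[nrow(tab)],
    P_LR_top_dose = tab$P_LR_ss[nrow(tab)],
    ci = ci_val, sign = sign)
  cat(sprintf("  %-14s GFP %6.2f -> %6.2f a.u. across the ladder, CI = %+.4f (%s)\n",
              topo, tab$G_ss[1], tab$G_ss[nrow(tab)], ci_val, sign))
}
summary <- do.call(rbind, summary_rows)
write.csv(summary, "results/dose_response_summary.csv", row.names = FALSE)

cat("\nFindings:\n")
cat(" - The flip-disabled open loop loses",
    sprintf("%.0f%%", 100 * (1 - summary["OPEN_LOOP_MUT", "G_top_dose"] /
                               summary["OPEN_LOOP_MUT", "G_baseline"])),
    "of its GFP at full induction: resource competition couples the modules.\n")
cat(" - The negative-feedback controller flips the RFP promoter down to",
    sprintf("P_LR = %.2f", summary["RE_NF", "P_LR_top_dose"]),
    "and retains most of the GFP baseline (CI closer to 0).\n")
cat(" - The feedforward variant overcompensates at the default excisionase",
    "turnover (positive CI); script 03 tunes it.\n")
cat(" - Recombinase expression itself costs GFP even uninduced:",
    sprintf("%.2f vs %.2f a.u.\n", summary["NO_CONTROLLER", "G_baseline"],
            summary["OPEN_LOOP_MUT", "G_baseline"]))
cat("Tables under results/dose_response_*.csv\n")
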