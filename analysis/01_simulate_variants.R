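#!/usr/bin/env Rscript
# Monte Carlo ensembles of the routing model, three variants (deterministic,
# velocity noise only, full), over N = 1..30 at 1e4 realizations per count.
# Writes long-format conditional occupancy laws and a JSON summary under
# results/simulation/.

suppressPackageStartupMessages(library(pedroute))

cfg <- default_config()
out_dir <- "results/simulation"
stats <- run_simulate(cfg, out_dir)

cat("\n== Ensemble summary (tuned perception EMG, fixed ratio ",
    config_lambda_fixed(cfg), " for non-full variants) ==\n", sep = "")
for (v in names(stats)) {
  st <- stats[[v]]
  act <- tryCatch(estimate_activation_threshold(st),
                  error = function(e) NA)
  cat(sprintf("%-15s activation N* = %-3s P(N_B=0|20) = %-6.3f mean N_B(20) = %.2f\n",
              st$variant, act, st$p_empty_b[st$n_values == 20],
              st$mean_n_b[st$n_values == 20]))
}
cat("\nThe deterministic variant switches sharply from an empty detour to",
    "systematic use; velocity noise alone activates the detour slightly",
    "earlier but keeps herding almost deterministic; only the stochastic",
    "perceived ratio produces the persistent bimodality (empty detour at",
    "high N) seen in tracking data.\n")
cat("Tables in", out_dir, "\n")
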