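#!/usr/bin/env Rscript
# Is using discriminability evidence a heuristic or optimal? Compare the
# conditional entropy of accuracy given confidence, H(A|c), when the same
# trials are scored with the full general-model posterior (e_I and e_d)
# versus the identity-only standard posterior. Lower H(A|c) means confidence
# predicts accuracy better. Reads the grid summary written by
# analysis/02_general_grid.R when present, otherwise recomputes it.

suppressPackageStartupMessages({
  library(confsig)
  library(dplyr)
})

summary_path <- file.path("results", "general_grid", "general_grid_summary.json")
if (file.exists(summary_path)) {
  res <- tibble::as_tibble(jsonlite::fromJSON(summary_path))
} else {
  res <- run_campaign(campaign("general_grid", scale = 0.025), seed = 1L,
                      out_dir = file.path("results", "general_grid"))
}

ent <- res |>
  mutate(prior = sub("_sd=.*$", "", config),
         benefit = H_identity_only - H_with_discriminability) |>
  select(prior, sigma_d, H_identity_only, H_with_discriminability, benefit, se_diff)

dir.create("results", showWarnings = FALSE)
readr::write_csv(ent, file.path("results", "entropy_sweep.csv"))
print(as.data.frame(ent), digits = 4)

worse <- sum(ent$benefit < -3 * ent$se_diff)
strict <- ent |> filter(sigma_d == 0.1) |> summarise(all(benefit > 3 * se_diff))
message(sprintf("\nFinding: confidence using e_d is never worse (%d/36 cells worse beyond MC error);", worse))
message(sprintf("at sigma_d = 0.1 the entropy reduction is strict for all nine priors: %s.",
                strict[[1]]))
message("Table written to results/entropy_sweep.csv (entropies in nats).")
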