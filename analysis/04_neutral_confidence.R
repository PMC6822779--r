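#!/usr/bin/env Rscript
# Confidence for exactly neutral stimuli (d = 0). The folded X-pattern
# predicts 0.75 there, but that value hinges on a continuous uniform
# discriminability prior reaching high discriminability; coarse discrete
# priors pull it below 0.75, and reliable discriminability evidence pulls it
# to 0.5.

suppressPackageStartupMessages(library(confsig))

`%||%` <- function(a, b) if (is.null(a)) b else a

n_eval <- 1e5
seed <- 1L

cases <- list(
  list(prior = prior_cunif(0, 4), sigma_d = NULL),
  list(prior = prior_cunif(0, 1), sigma_d = NULL),
  list(prior = prior_discrete(c(0, 2, 4)), sigma_d = NULL),
  list(prior = prior_discrete(c(0, 1)), sigma_d = NULL),
  list(prior = prior_gamma(2, 1), sigma_d = NULL),
  list(prior = prior_discrete(0:2), sigma_d = 0.1),
  list(prior = prior_discrete(0:2), sigma_d = 10)
)

rows <- lapply(cases, function(cs) {
  cfg <- experiment_config(cs$prior, sigma_I = 1, sigma_d = cs$sigma_d, n_trials = 2)
  tibble::tibble(
    prior = prior_label(cs$prior),
    model = cfg$model,
    sigma_d = cs$sigma_d %||% NA_real_,
    neutral_confidence = neutral_confidence(cfg, n_eval = n_eval, seed = seed)
  )
})
out <- dplyr::bind_rows(rows)

dir.create("results", showWarnings = FALSE)
readr::write_csv(out, file.path("results", "neutral_confidence.csv"))
print(as.data.frame(out), digits = 4)

message("\nFinding: 0.75 at d = 0 holds only for a wide continuous uniform prior; ")
message("discrete or narrow priors depress it, and reliable e_d drives it to 0.5.")
message("Table written to results/neutral_confidence.csv.")
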