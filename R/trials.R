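# Trial-level simulator for two-alternative forced-choice experiments.
# Generative structure per trial: identity I in {-1, 1} (balanced across the
# experiment), discriminability d ~ prior, identity evidence
# e_I ~ Normal(d * I, sigma_I), optionally discriminability evidence
# e_d ~ Normal(d, sigma_d), deterministic choice by the sign of e_I.

#' Configuration of one simulated experiment
#'
#' @param prior A [disc_prior][prior_discrete] over discriminability.
#' @param sigma_I Positive SD of identity evidence (default 1).
#' @param sigma_d Positive SD of discriminability evidence, or `NULL` for the
#'   standard model (no trial-level discriminability evidence).
#' @param n_trials Even positive trial count (full-scale experiments use
#'   4e6).
#' @param seed Integer seed; simulation is bit-reproducible given the config.
#' @param model `"standard"` or `"general"`; derived from `sigma_d` when
#'   omitted, and must be consistent with it when given.
#' @param name Optional label used in campaign output files.
#' @return An `experiment_config` object.
#' @export
experiment_config <- function(prior, sigma_I = 1, sigma_d = NULL,
                              n_trials = 4e6, seed = 1L, model = NULL,
                              name = NULL) {
  stopifnot(inherits(prior, "disc_prior"))
  if (!is.numeric(sigma_I) || sigma_I <= 0) stop("sigma_I must be positive", call. = FALSE)
  if (!is.null(sigma_d) && (!is.numeric(sigma_d) || sigma_d <= 0)) {
    stop("sigma_d must be positive when present", call. = FALSE)
  }
  n_trials <- as.numeric(n_trials)
  if (n_trials < 2 || n_trials %% 2 != 0) {
    stop("n_trials must be an even positive count (identity is balanced)", call. = FALSE)
  }
  derived <- if (is.null(sigma_d)) "standard" else "general"
  if (is.null(model)) {
    model <- derived
  } else if (!identical(model, derived)) {
    stop("model '", model, "' is inconsistent with sigma_d ",
         if (is.null(sigma_d)) "absent" else "present", call. = FALSE)
  }
  structure(
    list(prior = prior, sigma_I = sigma_I, sigma_d = sigma_d,
         n_trials = n_trials, seed = as.integer(seed), model = model,
         name = name %||% prior_label(prior)),
    class = "experiment_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("experiment_config: %s model, prior %s, sigma_I=%g%s, n=%g, seed=%d\n",
              x$model, prior_label(x$prior), x$sigma_I,
              if (is.null(x$sigma_d)) "" else sprintf(", sigma_d=%g", x$sigma_d),
              x$n_trials, x$seed))
  invisible(x)
}

#' Deterministic choice rule
#'
#' The choice is -1 when the identity evidence is negative and 1 otherwise
#' (a tie at exactly zero maps to 1). Vectorized.
#'
#' @param e_I Numeric vector of identity evidence.
#' @return Vector in \{-1, 1\}.
#' @export
sign_choice <- function(e_I) {
  ifelse(e_I < 0, -1, 1)
}

#' Simulate an experiment trial by trial
#'
#' Seeds the global RNG with `config$seed`, then draws, in this order:
#' discriminability `d` (i.i.d. from the prior), identity evidence
#' `e_I ~ Normal(d * I, sigma_I)`, and for the general model
#' `e_d ~ Normal(d, sigma_d)`. Identity is assigned deterministically:
#' the first half of trials have `I = 1`, the second half `I = -1` (all
#' analyses are exchangeable over trial order).
#'
#' @param config An [experiment_config()].
#' @return A tibble with columns `I`, `d`, `e_I` (and `e_d` for the general
#'   model), `choice`, `accuracy`; one row per trial. Confidence is added
#'   later by [score_table()].
#' @export
simulate_trials <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(config$seed)
  n <- config$n_trials
  I <- rep(c(1, -1), each = n / 2)
  d <- sample_prior(config$prior, n)
  e_I <- stats::rnorm(n, mean = d * I, sd = config$sigma_I)
  choice <- sign_choice(e_I)
  out <- tibble::tibble(I = I, d = d, e_I = e_I)
  if (config$model == "general") {
    out$e_d <- stats::rnorm(n, mean = d, sd = config$sigma_d)
  }
  out$choice <- choice
  out$accuracy <- as.integer(I == choice)
  out
}

#' Write a trial table to CSV
#'
#' Plain CSV with the canonical column order
#' `I,d,e_I,e_d,choice,accuracy,confidence` (`e_d` and `confidence` only when
#' present). A `.gz` path is compressed transparently.
#'
#' @param trials Trial tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  ord <- intersect(c("I", "d", "e_I", "e_d", "choice", "accuracy", "confidence"),
                   names(trials))
  readr::write_csv(trials[ord], path, progress = FALSE)
  invisible(path)
}

#' Read a trial table written by [write_trials()]
#'
#' @param path CSV file path (gzip-transparent).
#' @return A trial tibble.
#' @export
read_trials <- function(path) {
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                  progress = FALSE)
}
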