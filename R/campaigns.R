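# Simulation campaigns: the full experiment grids — three standard-model
# sets, the 9-prior x 4-sigma_d general-model grid, and the entropy sweep —
# run end to end with per-config seeds and file output.

#' The nine canonical discriminability priors
#'
#' Three discrete uniform, three continuous uniform, and three gamma
#' distributions; the gamma parameters are chosen so their means and
#' variances line up with the discrete uniform grids.
#'
#' @return Named list of [disc_prior][prior_discrete] objects.
#' @export
methods_priors <- function() {
  list(
    "dunif(0,1)"       = prior_discrete(c(0, 1)),
    "dunif(0,1,2)"     = prior_discrete(0:2),
    "dunif(0,1,2,3,4)" = prior_discrete(0:4),
    "cunif(0,1)"       = prior_cunif(0, 1),
    "cunif(0,2)"       = prior_cunif(0, 2),
    "cunif(0,4)"       = prior_cunif(0, 4),
    "gamma(1,2)"       = prior_gamma(1, 2),
    "gamma(1.5,1.5)"   = prior_gamma(1.5, 1.5),
    "gamma(2,1)"       = prior_gamma(2, 1)
  )
}

SIGMA_D_GRID <- c(1 / 10, 1 / 3, 1, 10)

scaled_trials <- function(scale) {
  n <- round(4e6 * scale)
  n <- max(2, n + n %% 2)
  n
}

#' Define a simulation campaign
#'
#' A campaign is a named list of experiment configurations at a common trial
#' scale:
#' \describe{
#'   \item{std_distributions}{9 standard-model experiments, one per
#'     canonical prior ([methods_priors()]).}
#'   \item{std_levels}{4 standard-model experiments with discrete uniform
#'     grids \{0,2,4\}, \{0,1,...,4\}, \{0,1/2,...,4\}, \{0,1/4,...,4\} —
#'     finer and finer steps up to the same maximum.}
#'   \item{std_two_values}{4 standard-model experiments with two-point
#'     priors \{0,1\}, \{0,2\}, \{0,3\}, \{0,10\}.}
#'   \item{general_grid}{36 general-model experiments: 9 priors crossed with
#'     sigma_d in \{1/10, 1/3, 1, 10\}.}
#'   \item{entropy_sweep}{the same 36 configs, analysed for the entropy of
#'     accuracy given confidence with and without e_d.}
#' }
#'
#' @param name Campaign name (see above).
#' @param scale Trial-count multiplier relative to the full-scale 4e6 trials
#'   per experiment; the default 0.025 gives 1e5 trials.
#' @return A `campaign` object: list with `name`, `scale`, `n_trials`, and a
#'   `configs` list of `(name, prior, sigma_d)` entries.
#' @export
campaign <- function(name = c("std_distributions", "std_levels",
                              "std_two_values", "general_grid",
                              "entropy_sweep"),
                     scale = 0.025) {
  name <- match.arg(name)
  stopifnot(is.numeric(scale), scale > 0, scale <= 1)
  cfg <- function(label, prior, sigma_d = NULL) {
    list(name = label, prior = prior, sigma_d = sigma_d)
  }
  configs <- switch(name,
    std_distributions = unname(Map(cfg, names(methods_priors()), methods_priors())),
    std_levels = {
      grids <- list(c(0, 2, 4), 0:4, seq(0, 4, by = 0.5), seq(0, 4, by = 0.25))
      lapply(grids, function(v) cfg(prior_label(prior_discrete(v)), prior_discrete(v)))
    },
    std_two_values = lapply(c(1, 2, 3, 10), function(v) {
      p <- prior_discrete(c(0, v))
      cfg(prior_label(p), p)
    }),
    general_grid = ,
    entropy_sweep = {
      out <- list()
      for (pn in names(methods_priors())) {
        for (sd_ in SIGMA_D_GRID) {
          out[[length(out) + 1L]] <- cfg(
            sprintf("%s_sd=%s", pn, format(sd_, digits = 4)),
            methods_priors()[[pn]], sd_)
        }
      }
      out
    }
  )
  structure(list(name = name, scale = scale,
                 n_trials = scaled_trials(scale), configs = configs),
            class = "campaign")
}

#' @export
print.campaign <- function(x, ...) {
  cat(sprintf("campaign '%s': %d configs, %g trials each (scale %g)\n",
              x$name, length(x$configs), x$n_trials, x$scale))
  invisible(x)
}

# stable 31-polynomial string hash so per-config seeds do not shift when
# configs are added or removed
string_hash <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  h
}

#' Derive a per-config seed from a campaign seed
#'
#' @param seed Integer campaign seed.
#' @param name Config name.
#' @return Integer seed below 2^31.
#' @export
config_seed <- function(seed, name) {
  as.integer((as.numeric(seed) + string_hash(name)) %% 2147483647)
}

run_one_config <- function(cmp_name, cfg, n_trials, seed, n_bins, tau) {
  config <- experiment_config(cfg$prior, sigma_I = 1, sigma_d = cfg$sigma_d,
                              n_trials = n_trials, seed = seed,
                              name = cfg$name)
  trials <- simulate_trials(config)
  engine <- posterior_engine(config$prior, config$sigma_I, config$sigma_d)
  trials <- score_table(engine, trials)
  bins <- if (config$prior$kind == "discrete_uniform") NULL else n_bins
  curve <- confidence_curve(trials, bins)
  pattern <- withCallingHandlers(
    classify_pattern(curve, tau),
    warning = function(w) {
      message("[", cfg$name, "] ", conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  res <- list(config = config, curve = curve, pattern = pattern)
  if (config$model == "general") {
    eng_std <- posterior_engine(config$prior, config$sigma_I)
    nll_gen <- -log(ifelse(trials$accuracy == 1, trials$confidence, 1 - trials$confidence))
    t_std <- score_table(eng_std, trials)
    nll_std <- -log(ifelse(t_std$accuracy == 1, t_std$confidence, 1 - t_std$confidence))
    res$entropy <- tibble::tibble(
      sigma_d = config$sigma_d,
      H_identity_only = mean(nll_std),
      H_with_discriminability = mean(nll_gen),
      se_diff = stats::sd(nll_gen - nll_std) / sqrt(length(nll_gen)),
      n = length(nll_gen)
    )
  }
  res
}

curve_tidy <- function(curve) {
  tibble::tibble(
    level = rep(curve$level, 2L),
    accuracy_class = rep(c("correct", "incorrect"), each = nrow(curve)),
    mean_confidence = c(curve$mean_conf_correct, curve$mean_conf_incorrect),
    n = c(curve$n_correct, curve$n_incorrect)
  )
}

#' Run a campaign and write per-config results
#'
#' For each configuration: simulate, score with the matching posterior
#' engine, build the confidence curve, classify its pattern, and (general
#' model only) compute the entropy of accuracy given confidence with and
#' without discriminability evidence. Writes one tidy curve CSV
#' (`curve_<config>.csv`) and one JSON summary per config plus a
#' campaign-level JSON table, all under `out_dir`. Deterministic given
#' `seed` and the campaign scale; a failing config is logged and skipped.
#'
#' @param cmp A [campaign()].
#' @param seed Integer campaign seed; per-config seeds derive from it via
#'   [config_seed()].
#' @param out_dir Output directory (created if missing), or `NULL` to skip
#'   file output.
#' @param n_bins Bins for continuous-prior curves (default 10).
#' @param tau Pattern slope threshold, see [classify_pattern()].
#' @return Tibble with one row per config: name, sigma_d, slopes, pattern
#'   label, and (general model) the two entropies; invisibly.
#' @export
run_campaign <- function(cmp, seed = 1L, out_dir = NULL, n_bins = 10L,
                         tau = 0.005) {
  stopifnot(inherits(cmp, "campaign"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  rows <- vector("list", length(cmp$configs))
  for (i in seq_along(cmp$configs)) {
    cfg <- cmp$configs[[i]]
    cseed <- config_seed(seed, cfg$name)
    res <- tryCatch(
      run_one_config(cmp$name, cfg, cmp$n_trials, cseed, n_bins, tau),
      error = function(e) {
        message("[", cfg$name, "] failed: ", conditionMessage(e))
        NULL
      }
    )
    if (is.null(res)) {
      rows[[i]] <- tibble::tibble(config = cfg$name, sigma_d = cfg$sigma_d %||% NA_real_,
                                  slope_correct = NA_real_, slope_incorrect = NA_real_,
                                  label = NA_character_)
      next
    }
    row <- tibble::tibble(
      config = cfg$name,
      sigma_d = cfg$sigma_d %||% NA_real_,
      slope_correct = res$pattern$slope_correct,
      slope_incorrect = res$pattern$slope_incorrect,
      label = res$pattern$label
    )
    if (!is.null(res$entropy)) {
      row$H_identity_only <- res$entropy$H_identity_only
      row$H_with_discriminability <- res$entropy$H_with_discriminability
      row$se_diff <- res$entropy$se_diff
    }
    rows[[i]] <- row
    if (!is.null(out_dir)) {
      slug <- gsub("[^A-Za-z0-9._-]+", "_", cfg$name)
      readr::write_csv(curve_tidy(res$curve),
                       file.path(out_dir, paste0("curve_", slug, ".csv")),
                       progress = FALSE)
      summary <- list(
        campaign = cmp$name, config = cfg$name,
        prior = prior_label(cfg$prior), sigma_I = 1,
        sigma_d = cfg$sigma_d, n_trials = cmp$n_trials, seed = cseed,
        slope_correct = res$pattern$slope_correct,
        slope_incorrect = res$pattern$slope_incorrect,
        label = res$pattern$label,
        entropy = if (is.null(res$entropy)) NULL else as.list(res$entropy),
        log_base = "nats"
      )
      jsonlite::write_json(summary, file.path(out_dir, paste0("summary_", slug, ".json")),
                           auto_unbox = TRUE, digits = NA, null = "null")
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!is.null(out_dir)) {
    jsonlite::write_json(out, file.path(out_dir, paste0(cmp$name, "_summary.json")),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}

#' Mean objective confidence for exactly neutral stimuli
#'
#' Holds discriminability at zero — the stimulus carries no information
#' about identity — while scoring with the experiment's full prior. Identity
#' evidence is drawn from `Normal(0, sigma_I)` (and `e_d` from
#' `Normal(0, sigma_d)` for the general model), the sign rule picks the
#' choice, and the mean posterior confidence is returned. This evaluates the
#' d = 0 point of the confidence curves directly, without binning artifacts;
#' for continuous priors a simulated experiment contains no exactly-neutral
#' trials at all.
#'
#' @param config An [experiment_config()] whose prior includes d = 0 in (or
#'   on the boundary of) its support.
#' @param n_eval Number of evaluation draws.
#' @param seed Integer seed for the evaluation draws.
#' @return Mean confidence, a scalar in `[0.5, 1]`.
#' @export
neutral_confidence <- function(config, n_eval = 1e5, seed = 1L) {
  stopifnot(inherits(config, "experiment_config"), n_eval >= 1)
  p <- config$prior
  supports_zero <- switch(p$kind,
    discrete_uniform = 0 %in% p$values,
    continuous_uniform = p$lo == 0,
    gamma = TRUE
  )
  if (!supports_zero) {
    stop("prior does not place d = 0 in or at the boundary of its support",
         call. = FALSE)
  }
  set.seed(seed)
  e_I <- stats::rnorm(n_eval, 0, config$sigma_I)
  e_d <- if (config$model == "general") stats::rnorm(n_eval, 0, config$sigma_d) else NULL
  engine <- posterior_engine(p, config$sigma_I, config$sigma_d)
  mean(confidence(engine, e_I, e_d, sign_choice(e_I)))
}
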