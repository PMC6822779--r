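# Condensing scored trial tables into the study's result objects:
# conditional confidence curves, their qualitative pattern (folded-X versus
# double increase), and the conditional entropy of accuracy given confidence.

#' Mean confidence by discriminability level and accuracy
#'
#' Groups trials by discriminability — exactly by support value for discrete
#' priors (`bins = NULL`), or into equal-width bins over `[0, max(d)]`
#' labelled by midpoints for continuous priors — and averages confidence
#' separately over correct and incorrect trials. A level with no trials of a
#' given accuracy carries `NA`, not zero.
#'
#' @param trials Scored trial tibble (confidence column filled).
#' @param bins `NULL` for exact discrete levels, or an integer number of
#'   equal-width bins.
#' @return A `confidence_curve` tibble with columns `level`,
#'   `mean_conf_correct`, `mean_conf_incorrect`, `n_correct`, `n_incorrect`,
#'   sorted by level.
#' @export
confidence_curve <- function(trials, bins = NULL) {
  if (!"confidence" %in% names(trials) || anyNA(trials$confidence)) {
    stop("trial table must be scored (see score_table()) before summarising",
         call. = FALSE)
  }
  if (is.null(bins)) {
    level <- trials$d
  } else {
    stopifnot(is.numeric(bins), bins >= 1)
    brk <- seq(0, max(trials$d), length.out = bins + 1)
    idx <- pmin(pmax(findInterval(trials$d, brk, rightmost.closed = TRUE), 1L), bins)
    level <- (brk[idx] + brk[idx + 1L]) / 2
  }
  df <- tibble::tibble(level = level,
                       accuracy = trials$accuracy,
                       confidence = trials$confidence)
  agg <- df |>
    dplyr::group_by(level, accuracy) |>
    dplyr::summarise(m = mean(confidence), n = dplyr::n(), .groups = "drop")
  wide <- tidyr::pivot_wider(
    agg, names_from = "accuracy", values_from = c("m", "n"),
    names_sep = "_", values_fill = list(n = 0L)
  )
  for (col in c("m_1", "m_0", "n_1", "n_0")) {
    if (!col %in% names(wide)) wide[[col]] <- if (startsWith(col, "n")) 0L else NA_real_
  }
  out <- tibble::tibble(
    level = wide$level,
    mean_conf_correct = wide$m_1,
    mean_conf_incorrect = wide$m_0,
    n_correct = as.integer(wide$n_1),
    n_incorrect = as.integer(wide$n_0)
  )
  out <- out[order(out$level), ]
  class(out) <- c("confidence_curve", class(out))
  out
}

weighted_slope <- function(x, y, w) {
  keep <- !is.na(y) & w > 0
  if (sum(keep) < 2L) return(NA_real_)
  fit <- stats::lm.wfit(cbind(1, x[keep]), y[keep], w[keep])
  unname(fit$coefficients[2L])
}

#' Classify a confidence curve as folded-X, double increase, or flat
#'
#' Fits count-weighted least-squares slopes of mean confidence on
#' discriminability level, separately for correct and incorrect trials.
#' `folded_X` means confidence rises with discriminability when correct and
#' falls when incorrect; `double_increase` means it rises in both; slopes
#' within `tau` of zero count as flat. Levels where an accuracy class is
#' empty are dropped from that class's fit with a warning.
#'
#' @param curve A [confidence_curve()].
#' @param tau Slope magnitude below which an association is treated as zero
#'   (confidence units per discriminability unit; default 0.005).
#' @return A `pattern_call` list with `slope_correct`, `slope_incorrect` and
#'   `label` (one of `"folded_X"`, `"double_increase"`, `"flat"`, or `NA`
#'   when a class has fewer than two populated levels).
#' @export
classify_pattern <- function(curve, tau = 0.005) {
  stopifnot(inherits(curve, "confidence_curve"))
  if (nrow(curve) < 2L) stop("need at least two discriminability levels", call. = FALSE)
  dropped <- sum(is.na(curve$mean_conf_correct) | curve$n_correct == 0L) +
    sum(is.na(curve$mean_conf_incorrect) | curve$n_incorrect == 0L)
  if (dropped > 0L) {
    warning(dropped, " empty level-by-accuracy cell(s) dropped from slope fitting",
            call. = FALSE)
  }
  s_c <- weighted_slope(curve$level, curve$mean_conf_correct, curve$n_correct)
  s_i <- weighted_slope(curve$level, curve$mean_conf_incorrect, curve$n_incorrect)
  label <- if (is.na(s_c) || is.na(s_i)) {
    NA_character_
  } else if (s_c > tau && s_i < -tau) {
    "folded_X"
  } else if (s_c > tau && s_i > tau) {
    "double_increase"
  } else {
    "flat"
  }
  structure(list(slope_correct = s_c, slope_incorrect = s_i, label = label),
            class = "pattern_call")
}

#' @export
print.pattern_call <- function(x, ...) {
  cat(sprintf("pattern: %s (slope correct %.4f, incorrect %.4f)\n",
              x$label, x$slope_correct, x$slope_incorrect))
  invisible(x)
}

#' Conditional entropy of accuracy given confidence
#'
#' The per-trial mean negative log probability that confidence assigned to
#' the realized accuracy,
#' \deqn{H(A|c) = -\frac{1}{n} \sum_j \log(A_j c_j + (1 - A_j)(1 - c_j)),}
#' in nats. Zero when confidence perfectly predicts accuracy; `log(2)` when
#' confidence is uninformative at 0.5. Lower values mean confidence is a
#' better predictor of accuracy.
#'
#' @param trials Scored trial tibble with `accuracy` and `confidence`.
#' @return Nonnegative scalar (nats).
#' @export
accuracy_entropy <- function(trials) {
  if (!all(c("confidence", "accuracy") %in% names(trials))) {
    stop("trial table needs accuracy and confidence columns", call. = FALSE)
  }
  p <- ifelse(trials$accuracy == 1, trials$confidence, 1 - trials$confidence)
  bad <- which(p <= 0)
  if (length(bad) > 0L) {
    stop("confidence assigns zero probability to the realized accuracy in trial(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  -mean(log(p))
}

#' Entropy of accuracy given confidence, with and without e_d
#'
#' Simulates one general-model experiment, scores the same trials twice —
#' once with the full general-model posterior (using `e_I` and `e_d`) and
#' once with the standard-model posterior over the same prior and `sigma_I`
#' (using `e_I` only) — and returns both conditional entropies. Because both
#' scorings share the trials, the Monte Carlo error of the difference is the
#' paired standard error reported as `se_diff`.
#'
#' @param config A general-model [experiment_config()].
#' @return One-row tibble: `sigma_d`, `H_identity_only`,
#'   `H_with_discriminability`, `se_diff`, `n`.
#' @export
entropy_comparison <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  if (config$model != "general") {
    stop("entropy comparison requires a general-model config", call. = FALSE)
  }
  trials <- simulate_trials(config)
  eng_gen <- posterior_engine(config$prior, config$sigma_I, config$sigma_d)
  eng_std <- posterior_engine(config$prior, config$sigma_I)
  nll <- function(tab) {
    p <- ifelse(tab$accuracy == 1, tab$confidence, 1 - tab$confidence)
    -log(p)
  }
  t_gen <- nll(score_table(eng_gen, trials))
  t_std <- nll(score_table(eng_std, trials))
  diff <- t_gen - t_std
  tibble::tibble(
    sigma_d = config$sigma_d,
    H_identity_only = mean(t_std),
    H_with_discriminability = mean(t_gen),
    se_diff = stats::sd(diff) / sqrt(length(diff)),
    n = length(diff)
  )
}
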