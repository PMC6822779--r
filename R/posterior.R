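# Objective confidence: the Bayesian posterior probability that the choice
# was correct given the evidence. For a symmetric identity prior,
#
#   p(I = 1 | e_I, e_d) =
#     sum_k w_k N(e_I; d_k, sigma_I) N(e_d; d_k, sigma_d)
#     -----------------------------------------------------------------
#     sum_{i in {-1,1}} sum_k w_k N(e_I; d_k i, sigma_I) N(e_d; d_k, sigma_d)
#
# with (d_k, w_k) the prior's quadrature representation. The standard model
# is the same computation with the e_d factor identically 1 (no trial-level
# discriminability evidence). Confidence is the posterior of the chosen
# identity; with choice = sign(e_I) it never falls below 0.5.
#
# All likelihood sums run in log space with a max-subtraction normalization:
# at d = 10 and sigma_I = 1 the raw Gaussian densities underflow.

#' Posterior engine for objective confidence
#'
#' Caches the quadrature representation of a discriminability prior and the
#' evidence noise levels so trial tables can be scored vectorized.
#'
#' @param prior A [disc_prior][prior_discrete].
#' @param sigma_I Positive SD of identity evidence.
#' @param sigma_d Positive SD of discriminability evidence, or `NULL` for a
#'   standard-model engine (confidence from `e_I` and the choice alone).
#' @param n_nodes Gauss--Legendre order for continuous priors; see
#'   [quadrature_nodes()].
#' @return A `posterior_engine` object.
#' @export
posterior_engine <- function(prior, sigma_I = 1, sigma_d = NULL, n_nodes = 256L) {
  stopifnot(inherits(prior, "disc_prior"))
  if (!is.numeric(sigma_I) || sigma_I <= 0) stop("sigma_I must be positive", call. = FALSE)
  if (!is.null(sigma_d) && (!is.numeric(sigma_d) || sigma_d <= 0)) {
    stop("sigma_d must be positive when present", call. = FALSE)
  }
  q <- quadrature_nodes(prior, n_nodes)
  structure(
    list(prior = prior, sigma_I = sigma_I, sigma_d = sigma_d,
         nodes = q$nodes, weights = q$weights, log_weights = log(q$weights),
         model = if (is.null(sigma_d)) "standard" else "general"),
    class = "posterior_engine"
  )
}

#' @export
print.posterior_engine <- function(x, ...) {
  cat(sprintf("posterior_engine: %s model, prior %s, sigma_I=%g%s, %d nodes\n",
              x$model, prior_label(x$prior), x$sigma_I,
              if (is.null(x$sigma_d)) "" else sprintf(", sigma_d=%g", x$sigma_d),
              length(x$nodes)))
  invisible(x)
}

# log sum_k exp(M[, k]) per row, stable under large negative entries
row_logsumexp <- function(M) {
  m <- M[, 1L]
  K <- ncol(M)
  if (K > 1L) for (k in 2:K) m <- pmax(m, M[, k])
  m + log(rowSums(exp(M - m)))
}

# log-posterior-odds of I = 1 vs I = -1, vectorized over trials; chunked so
# the n-by-K likelihood matrices stay modest at millions of trials
posterior_log_odds <- function(engine, e_I, e_d = NULL) {
  nodes <- engine$nodes
  lw <- engine$log_weights
  K <- length(nodes)
  n <- length(e_I)
  out <- numeric(n)
  chunk <- max(1L, as.integer(floor(4e6 / K)))
  for (start in seq.int(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    ei <- e_I[idx]
    m <- length(idx)
    LW <- matrix(lw, m, K, byrow = TRUE)
    # N(e_I; -d_k, s) = N(-e_I; d_k, s), so the I = -1 branch reuses +nodes
    A <- stats::dnorm(outer(ei, nodes, "-"), sd = engine$sigma_I, log = TRUE) + LW
    B <- stats::dnorm(outer(ei, nodes, "+"), sd = engine$sigma_I, log = TRUE) + LW
    if (!is.null(e_d)) {
      D <- stats::dnorm(outer(e_d[idx], nodes, "-"), sd = engine$sigma_d, log = TRUE)
      A <- A + D
      B <- B + D
    }
    out[idx] <- row_logsumexp(A) - row_logsumexp(B)
  }
  out
}

check_evidence_args <- function(engine, e_d) {
  if (engine$model == "standard" && !is.null(e_d)) {
    stop("e_d supplied to a standard-model engine", call. = FALSE)
  }
  if (engine$model == "general" && is.null(e_d)) {
    stop("a general-model engine requires e_d", call. = FALSE)
  }
}

#' Posterior probability that the stimulus identity is 1
#'
#' Evaluates the Bayesian posterior of `I = 1` given the evidence, under the
#' engine's prior and noise model. Vectorized over trials.
#'
#' @param engine A [posterior_engine()].
#' @param e_I Numeric vector of identity evidence.
#' @param e_d Numeric vector of discriminability evidence; required for a
#'   general-model engine and forbidden for a standard one.
#' @return Probabilities in (0, 1).
#' @export
posterior_identity <- function(engine, e_I, e_d = NULL) {
  stopifnot(inherits(engine, "posterior_engine"))
  check_evidence_args(engine, e_d)
  stats::plogis(posterior_log_odds(engine, e_I, e_d))
}

#' Objective confidence in a choice
#'
#' The posterior probability that `choice` matches the stimulus identity:
#' [posterior_identity()] when `choice = 1`, its complement when
#' `choice = -1`. Because the choice is the sign of `e_I` and the identity
#' prior is symmetric, confidence lies in `[0.5, 1]`.
#'
#' @inheritParams posterior_identity
#' @param choice Vector in \{-1, 1\}.
#' @return Confidence values in `[0.5, 1]` (up to numerical round-off).
#' @export
confidence <- function(engine, e_I, e_d = NULL, choice) {
  stopifnot(inherits(engine, "posterior_engine"))
  check_evidence_args(engine, e_d)
  if (!all(choice %in% c(-1, 1))) stop("choice must be -1 or 1", call. = FALSE)
  stats::plogis(choice * posterior_log_odds(engine, e_I, e_d))
}

#' Score a trial table with objective confidence
#'
#' Fills (or overwrites) the `confidence` column; semantics are identical to
#' calling [confidence()] per trial. A standard-model engine ignores an
#' `e_d` column if one is present — that is the deliberate "identity-only"
#' scoring used when comparing confidence with and without discriminability
#' evidence on the same trials.
#'
#' @param engine A [posterior_engine()].
#' @param trials A trial tibble from [simulate_trials()].
#' @return `trials` with the `confidence` column filled.
#' @export
score_table <- function(engine, trials) {
  stopifnot(inherits(engine, "posterior_engine"))
  if (engine$model == "general" && !"e_d" %in% names(trials)) {
    stop("trial table has no e_d column but the engine is general-model", call. = FALSE)
  }
  e_d <- if (engine$model == "general") trials$e_d else NULL
  trials$confidence <- confidence(engine, trials$e_I, e_d, trials$choice)
  trials
}
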