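# Discriminability priors: the distributions from which task difficulty |d|
# is drawn across an experiment. Three families are supported (discrete
# uniform, continuous uniform on [lo, hi], gamma), which is what orthogonal
# difficulty manipulations in psychophysics typically look like.

new_disc_prior <- function(kind, fields) {
  structure(c(list(kind = kind), fields), class = "disc_prior")
}

#' Discrete uniform prior over discriminability values
#'
#' Equiprobable nonnegative difficulty levels, as when an experiment
#' manipulates contrast or coherence in a fixed set of steps.
#'
#' @param values Numeric vector of distinct nonnegative discriminability
#'   levels. Stored sorted ascending.
#' @return A `disc_prior` object.
#' @export
#' @examples
#' prior_discrete(c(0, 1, 2))
prior_discrete <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L || anyNA(values)) {
    stop("`values` must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("discriminability values must be nonnegative", call. = FALSE)
  }
  values <- sort(values)
  if (anyDuplicated(values)) {
    stop("discriminability values must be distinct", call. = FALSE)
  }
  new_disc_prior("discrete_uniform", list(values = values))
}

#' Continuous uniform prior over discriminability
#'
#' @param lo,hi Nonnegative bounds with `lo < hi`. Difficulty is uniform on
#'   `[lo, hi]`; experiments here always use `lo = 0`.
#' @return A `disc_prior` object.
#' @export
prior_cunif <- function(lo = 0, hi) {
  if (!is.numeric(lo) || !is.numeric(hi) || lo < 0 || hi <= lo) {
    stop("need 0 <= lo < hi", call. = FALSE)
  }
  new_disc_prior("continuous_uniform", list(lo = as.numeric(lo), hi = as.numeric(hi)))
}

#' Gamma prior over discriminability
#'
#' @param shape,rate Positive gamma parameters (shape \eqn{\alpha}, rate
#'   \eqn{\beta}); the mean is \eqn{\alpha/\beta}.
#' @return A `disc_prior` object.
#' @export
prior_gamma <- function(shape, rate) {
  if (!is.numeric(shape) || !is.numeric(rate) || shape <= 0 || rate <= 0) {
    stop("gamma shape and rate must be positive", call. = FALSE)
  }
  new_disc_prior("gamma", list(shape = as.numeric(shape), rate = as.numeric(rate)))
}

#' Parse a prior from string shorthand
#'
#' Accepts `"dunif:0,1,2"`, `"cunif:0,4"` and `"gamma:1.5,1.5"`.
#'
#' @param spec Character scalar.
#' @return A `disc_prior` object.
#' @export
parse_prior <- function(spec) {
  stopifnot(is.character(spec), length(spec) == 1L)
  parts <- strsplit(spec, ":", fixed = TRUE)[[1L]]
  if (length(parts) != 2L) stop("prior spec must look like 'family:a,b,...'", call. = FALSE)
  args <- as.numeric(strsplit(parts[2L], ",", fixed = TRUE)[[1L]])
  switch(parts[1L],
    dunif = prior_discrete(args),
    cunif = { stopifnot(length(args) == 2L); prior_cunif(args[1L], args[2L]) },
    gamma = { stopifnot(length(args) == 2L); prior_gamma(args[1L], args[2L]) },
    stop("unknown prior family: ", parts[1L], call. = FALSE)
  )
}

#' @export
print.disc_prior <- function(x, ...) {
  cat(prior_label(x), "\n")
  invisible(x)
}

#' Compact label for a prior
#'
#' @param prior A `disc_prior`.
#' @return Character scalar such as `"dunif(0,1,2)"`.
#' @export
prior_label <- function(prior) {
  stopifnot(inherits(prior, "disc_prior"))
  switch(prior$kind,
    discrete_uniform = paste0("dunif(", paste(prior$values, collapse = ","), ")"),
    continuous_uniform = paste0("cunif(", prior$lo, ",", prior$hi, ")"),
    gamma = paste0("gamma(", prior$shape, ",", prior$rate, ")")
  )
}

#' Draw discriminability values from a prior
#'
#' Uses the current RNG stream; callers seed it (experiment configs carry the
#' seed).
#'
#' @param prior A `disc_prior`.
#' @param n Number of draws.
#' @return Numeric vector of `n` nonnegative values.
#' @export
sample_prior <- function(prior, n) {
  stopifnot(inherits(prior, "disc_prior"), n >= 1)
  switch(prior$kind,
    discrete_uniform =
      if (length(prior$values) == 1L) rep(prior$values, n)
      else sample(prior$values, n, replace = TRUE),
    continuous_uniform = stats::runif(n, prior$lo, prior$hi),
    gamma = stats::rgamma(n, shape = prior$shape, rate = prior$rate)
  )
}

#' Prior mass or density at a discriminability value
#'
#' Probability mass for discrete priors, density for continuous ones; zero
#' outside the support. Vectorized over `d`.
#'
#' @param prior A `disc_prior`.
#' @param d Numeric vector of discriminability values.
#' @return Nonnegative numeric vector.
#' @export
prior_weight <- function(prior, d) {
  stopifnot(inherits(prior, "disc_prior"))
  switch(prior$kind,
    discrete_uniform = ifelse(d %in% prior$values, 1 / length(prior$values), 0),
    continuous_uniform = stats::dunif(d, prior$lo, prior$hi),
    gamma = stats::dgamma(d, shape = prior$shape, rate = prior$rate)
  )
}

#' Quadrature representation of a prior
#'
#' Nodes and weights such that `sum(weights) == 1` and
#' `sum(weights * f(nodes))` approximates `E[f(|d|)]`. Discrete priors pass
#' through exactly. Continuous priors use fixed-order Gauss--Legendre on the
#' support, with gamma support truncated at the `1 - 1e-10` quantile (the
#' discarded tail mass is negligible) and weights renormalized to sum to one.
#'
#' @param prior A `disc_prior`.
#' @param n_nodes Number of Gauss--Legendre nodes for continuous priors
#'   (default 256; ignored for discrete priors).
#' @return List with numeric `nodes` and `weights`.
#' @export
quadrature_nodes <- function(prior, n_nodes = 256L) {
  stopifnot(inherits(prior, "disc_prior"))
  if (prior$kind == "discrete_uniform") {
    k <- length(prior$values)
    return(list(nodes = prior$values, weights = rep(1 / k, k)))
  }
  bounds <- if (prior$kind == "continuous_uniform") {
    c(prior$lo, prior$hi)
  } else {
    c(0, stats::qgamma(1 - 1e-10, shape = prior$shape, rate = prior$rate))
  }
  gl <- pracma::gaussLegendre(n_nodes, bounds[1L], bounds[2L])
  w <- gl$w * prior_weight(prior, gl$x)
  list(nodes = gl$x, weights = w / sum(w))
}
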