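# Site-rate heterogeneity: invariant sites, discrete/continuous Gamma,
# free rates. Every model has mean rate 1, so branch lengths keep their
# substitutions-per-site interpretation.

#' Discrete Gamma category rates
#'
#' Splits the Gamma(shape `alpha`, mean 1) density into `k` equal-probability
#' categories and returns the mean of the density over each inter-quantile
#' interval (the "mean" discretization, the convention of most likelihood
#' software), renormalized so the category mean is exactly 1.
#'
#' @param alpha Gamma shape, `> 0`.
#' @param k Number of categories, `>= 1`.
#' @return Numeric vector of `k` strictly increasing rates with mean 1.
#' @examples
#' discrete_gamma_rates(0.5, 4)
#' @export
discrete_gamma_rates <- function(alpha, k) {
  if (!is.finite(alpha) || alpha <= 0) stop("gamma shape alpha must be > 0")
  if (!is.numeric(k) || k < 1) stop("need at least one category")
  k <- as.integer(k)
  if (k == 1L) return(1)
  qb <- stats::qgamma((0:k) / k, shape = alpha, rate = alpha)
  # mean of Gamma(a, rate a) over (qb[j], qb[j+1]] via the incomplete-gamma
  # identity: \int x f_a(x) dx = F_{a+1}(b) - F_{a+1}(a) (mean-1 scaling)
  cdf1 <- stats::pgamma(qb, shape = alpha + 1, rate = alpha)
  rates <- k * diff(cdf1)
  rates / mean(rates)
}

#' Specify a site-rate heterogeneity model
#'
#' Exactly one variable-rate component may be active — discrete Gamma
#' (`gamma_shape` + `n_categories`), continuous Gamma (`gamma_shape` +
#' `continuous = TRUE`) or free rates (`free_rates`) — optionally combined
#' with a proportion of invariant sites. Non-invariant rates are scaled by
#' `1/(1 - p_inv)` so the mean rate over all sites is 1.
#'
#' @param p_inv Proportion of invariant (rate-0) sites, in `[0, 1)`.
#' @param gamma_shape Gamma shape `alpha > 0`, or `NULL` for no Gamma.
#' @param n_categories Number of discrete Gamma categories (default 4 when a
#'   shape is given and `continuous = FALSE`).
#' @param continuous If `TRUE`, draw one Gamma variate per site instead of
#'   discretizing.
#' @param free_rates Optional 2-column matrix or data.frame of
#'   `(weight, rate)` pairs; weights are renormalized to sum to 1 and rates
#'   rescaled to mean 1 (with a warning if they were off).
#' @return An object of class `"rate_model"` with precomputed category rates
#'   already scaled by `1/(1 - p_inv)`.
#' @export
rate_model <- function(p_inv = 0, gamma_shape = NULL, n_categories = NULL,
                       continuous = FALSE, free_rates = NULL) {
  if (!is.finite(p_inv) || p_inv < 0 || p_inv >= 1) {
    stop("p_inv must lie in [0, 1)")
  }
  has_gamma <- !is.null(gamma_shape)
  has_free <- !is.null(free_rates)
  if (has_gamma && has_free) stop("Gamma and free-rate models are exclusive")
  if (continuous && !has_gamma) stop("continuous = TRUE needs a gamma_shape")
  kind <- "none"; cat_rates <- 1; cat_weights <- 1; alpha <- NULL; k <- 1L
  if (has_gamma) {
    alpha <- gamma_shape
    if (!is.finite(alpha) || alpha <= 0) stop("gamma shape must be > 0")
    if (continuous) {
      kind <- "gamma_continuous"
      cat_rates <- numeric(0); cat_weights <- numeric(0)
    } else {
      k <- as.integer(if (is.null(n_categories)) 4L else n_categories)
      if (k < 1L) stop("need at least one Gamma category")
      kind <- "gamma_discrete"
      cat_rates <- discrete_gamma_rates(alpha, k)
      cat_weights <- rep(1 / k, k)
    }
  } else if (has_free) {
    fr <- as.matrix(free_rates)
    if (ncol(fr) != 2L || nrow(fr) < 1L) {
      stop("free_rates must be (weight, rate) pairs")
    }
    w <- fr[, 1]; r <- fr[, 2]
    if (any(w <= 0) || any(r < 0)) stop("free-rate weights/rates invalid")
    w <- w / sum(w)
    m <- sum(w * r)
    if (abs(m - 1) > 1e-9) {
      warning("free rates renormalized to mean 1 (was ", signif(m, 6), ")")
      r <- r / m
    }
    kind <- "free"
    k <- length(r)
    cat_rates <- r; cat_weights <- w
  }
  structure(
    list(kind = kind, p_inv = p_inv, alpha = alpha, k = k,
         # variable-part rates pre-scaled so the full-model mean is 1
         cat_rates = cat_rates / (1 - p_inv),
         cat_weights = cat_weights),
    class = "rate_model"
  )
}

#' Sample per-site rate multipliers
#'
#' Each site independently becomes invariant (rate exactly 0) with
#' probability `p_inv`, and otherwise draws from the variable part of the
#' model, pre-scaled by `1/(1 - p_inv)` so `E[rate] = 1`.
#'
#' @param model A [rate_model()] (or `NULL` for the homogeneous model).
#' @param L Number of sites, `>= 1`.
#' @return An object of class `"site_rates"`: list with `rates` (length-`L`
#'   numeric) and `categories` (length-`L` integer; 0 marks invariant sites,
#'   `NA` for continuous draws).
#' @export
sample_site_rates <- function(model, L) {
  if (is.null(model)) model <- rate_model()
  stopifnot(inherits(model, "rate_model"))
  if (!is.numeric(L) || L < 1) stop("L must be >= 1")
  L <- as.integer(L)
  variable <- if (model$p_inv > 0) stats::runif(L) >= model$p_inv
              else rep(TRUE, L)
  rates <- numeric(L)
  cats <- integer(L)
  nv <- sum(variable)
  if (nv > 0) {
    if (model$kind == "gamma_continuous") {
      rates[variable] <- stats::rgamma(nv, shape = model$alpha,
                                       rate = model$alpha) /
        (1 - model$p_inv)
      cats[variable] <- NA_integer_
    } else if (model$kind == "none") {
      rates[variable] <- 1 / (1 - model$p_inv)
      cats[variable] <- 1L
    } else {
      idx <- sample.int(model$k, nv, replace = TRUE,
                        prob = model$cat_weights)
      rates[variable] <- model$cat_rates[idx]
      cats[variable] <- idx
    }
  }
  structure(list(rates = rates, categories = cats), class = "site_rates")
}

#' Analytic mean rate of a rate model
#'
#' Equals 1 for every valid model by construction; exposed for property
#' checks.
#' @param model A [rate_model()].
#' @return The expected per-site rate.
#' @export
mean_rate <- function(model) {
  stopifnot(inherits(model, "rate_model"))
  if (model$kind == "gamma_continuous") {
    # E[Gamma(a, rate a)] = 1, scaled by 1/(1-p) with prob (1-p)
    return(1)
  }
  (1 - model$p_inv) * sum(model$cat_weights * model$cat_rates)
}

# Compact description passed to the C++ Gillespie core so rates for inserted
# sites are drawn from the same model (mode 0 = none, 1 = categorical,
# 2 = continuous Gamma).
rate_spec_for_cpp <- function(model) {
  if (is.null(model)) model <- rate_model()
  if (model$kind == "gamma_continuous") {
    list(mode = 2L, p_inv = model$p_inv, alpha = model$alpha,
         scale = 1 / (1 - model$p_inv),
         cat_cdf = numeric(0), cat_rates = numeric(0))
  } else {
    list(mode = 1L, p_inv = model$p_inv, alpha = 0,
         scale = 1,
         cat_cdf = cumsum(model$cat_weights),
         cat_rates = model$cat_rates)
  }
}
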