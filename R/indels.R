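# Indel machinery: length distributions on {1, 2, ...}, their exact means,
# and the total-rate bookkeeping S, I, D, M used by the Gillespie engine.

#' Indel-length distribution
#'
#' Built-in length distributions on the positive integers:
#' \describe{
#'   \item{geometric(p)}{`P(k) = p (1-p)^{k-1}`, `k >= 1`.}
#'   \item{negative_binomial(r, p)}{number of failures before the `r`-th
#'     success, shifted to support `>= 1`: `k = 1 + NB(r, p)`.}
#'   \item{zipfian(a, max)}{`P(k) \propto k^{-a}` truncated at `max`.}
#'   \item{lavalette(a, max)}{`P(k) \propto ((k max)/(max - k + 1))^{-a}`
#'     truncated at `max`.}
#' }
#' Zipfian and Lavalette are tabulated exactly over `1..max`; the unbounded
#' geometric/negative-binomial samplers are tabulated to the `1 - 1e-12`
#' quantile (mean computation still uses the closed form).
#'
#' @param kind One of `"geometric"`, `"negative_binomial"`, `"zipfian"`,
#'   `"lavalette"`.
#' @param a Exponent for zipfian/lavalette (`> 0`). The field's default for
#'   indel lengths is a Zipfian exponent of 1.7.
#' @param max Truncation point for zipfian/lavalette, `>= 1`.
#' @param p Success probability in `(0, 1]` for geometric/negative binomial.
#' @param r Size parameter (`> 0`) for the negative binomial.
#' @return A `"length_distribution"` with a cumulative sampling table.
#' @examples
#' mean_length(length_distribution("zipfian", a = 1.7, max = 50))
#' @export
length_distribution <- function(kind = c("zipfian", "geometric",
                                         "negative_binomial", "lavalette"),
                                a = 1.7, max = 50, p = NULL, r = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("zipfian", "lavalette")) {
    if (!is.finite(a) || a <= 0) stop("exponent a must be > 0")
    if (!is.numeric(max) || max < 1) stop("max must be >= 1")
    max <- as.integer(max)
    k <- seq_len(max)
    pmf <- if (kind == "zipfian") k^(-a)
           else ((k * max) / (max - k + 1))^(-a)
    pmf <- pmf / sum(pmf)
    mean_exact <- sum(k * pmf)
  } else {
    if (is.null(p) || !is.finite(p) || p <= 0 || p > 1) {
      stop("need success probability p in (0, 1]")
    }
    if (kind == "negative_binomial") {
      if (is.null(r) || !is.finite(r) || r <= 0) stop("need size r > 0")
      mean_exact <- 1 + r * (1 - p) / p
      kmax <- if (p == 1) 1L else
        as.integer(1 + stats::qnbinom(1 - 1e-12, size = r, prob = p))
      pmf <- stats::dnbinom(seq_len(kmax) - 1L, size = r, prob = p)
    } else {
      mean_exact <- 1 / p
      kmax <- if (p == 1) 1L else
        as.integer(1 + stats::qgeom(1 - 1e-12, prob = p))
      pmf <- stats::dgeom(seq_len(kmax) - 1L, prob = p)
    }
    pmf <- pmf / sum(pmf)
  }
  structure(
    list(kind = kind, a = a, max = max, p = p, r = r,
         pmf = pmf, cdf = cumsum(pmf), mean = mean_exact),
    class = "length_distribution"
  )
}

#' Exact mean of an indel-length distribution
#'
#' Truncated distributions by direct summation over their support;
#' geometric/negative binomial by closed form (`1/p` and `1 + r(1-p)/p`).
#'
#' @param dist A [length_distribution()].
#' @return The mean length, `>= 1`.
#' @export
mean_length <- function(dist) {
  stopifnot(inherits(dist, "length_distribution"))
  dist$mean
}

#' Sample indel lengths
#'
#' Inverse-CDF sampling from the precomputed cumulative table (exact for the
#' truncated distributions).
#'
#' @param dist A [length_distribution()].
#' @param n Number of draws.
#' @return Integer vector of lengths `>= 1`.
#' @export
sample_length <- function(dist, n = 1) {
  stopifnot(inherits(dist, "length_distribution"))
  findInterval(stats::runif(n), dist$cdf) + 1L
}

#' Indel model
#'
#' Insertion and deletion rates are expressed relative to the substitution
#' rate (the rate matrix is normalized to one substitution per site per unit
#' time), with separate insertion- and deletion-length distributions.
#'
#' @param r_ins Insertion rate `>= 0`.
#' @param r_del Deletion rate `>= 0`.
#' @param ins_dist,del_dist [length_distribution()]s; default Zipfian with
#'   exponent 1.7 truncated at 50.
#' @return An `"indel_model"`; `u_del` caches the deletion-length mean used
#'   in the total deletion rate `D = r_del (L - 1 + u_del)`.
#' @export
indel_model <- function(r_ins, r_del,
                        ins_dist = length_distribution("zipfian", 1.7, 50),
                        del_dist = length_distribution("zipfian", 1.7, 50)) {
  if (!is.finite(r_ins) || r_ins < 0 || !is.finite(r_del) || r_del < 0) {
    stop("indel rates must be finite and >= 0")
  }
  stopifnot(inherits(ins_dist, "length_distribution"),
            inherits(del_dist, "length_distribution"))
  structure(
    list(r_ins = r_ins, r_del = r_del,
         ins_dist = ins_dist, del_dist = del_dist,
         u_del = mean_length(del_dist)),
    class = "indel_model"
  )
}

#' Total event rates of a sequence state
#'
#' Returns the running totals used by the Gillespie algorithm:
#' `S = -sum_i q_{x_i x_i} r_i` over non-gap sites, `I = r_ins (L + 1)`,
#' `D = r_del (L - 1 + u_del)` and `M = S + I + D`, where `L` is the
#' number of non-gap characters.
#'
#' @param state A [sequence_state()].
#' @param model A `"substitution_model"`.
#' @param indel An [indel_model()], or `NULL` for no indels.
#' @return List with `S`, `I`, `D`, `M` and `L`.
#' @export
total_event_rates <- function(state, model, indel = NULL) {
  stopifnot(inherits(state, "sequence_state"),
            inherits(model, "substitution_model"))
  code <- state$code
  ng <- code != 0L
  L <- sum(ng)
  if (any(state$rates[!ng] != 0)) stop("gap positions must carry rate 0")
  S <- -sum(diag(model$Q)[code[ng]] * state$rates[ng])
  if (is.null(indel)) {
    I <- 0; D <- 0
  } else {
    I <- indel$r_ins * (L + 1)
    D <- indel$r_del * (L - 1 + indel$u_del)
  }
  list(S = S, I = I, D = D, M = S + I + D, L = L)
}
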