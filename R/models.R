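# Substitution models: rate-matrix construction, normalization, exponentiation.

#' Define a state alphabet
#'
#' An alphabet is an ordered set of single-character state symbols plus the
#' gap symbol `"-"`, which is never a state.
#'
#' @param states Character vector of unique single-character state symbols
#'   (at least two).
#' @return An object of class `"msa_alphabet"`.
#' @examples
#' alphabet(c("A", "C", "G", "T"))
#' @export
alphabet <- function(states = c("A", "C", "G", "T")) {
  states <- as.character(states)
  if (length(states) < 2L) stop("an alphabet needs at least 2 states")
  if (anyDuplicated(states)) stop("alphabet states must be unique")
  if (any(nchar(states) != 1L)) stop("states must be single characters")
  if ("-" %in% states) stop("the gap symbol '-' cannot be a state")
  structure(list(states = states, gap = "-"), class = "msa_alphabet")
}

#' @export
print.msa_alphabet <- function(x, ...) {
  cat("Alphabet:", paste(x$states, collapse = " "), "(gap '-')\n")
  invisible(x)
}

dna_alphabet <- function() alphabet(c("A", "C", "G", "T"))

# Order of the 6 GTR exchangeabilities, as in most phylogenetic software:
# AC, AG, AT, CG, CT, GT.
gtr_exchange_matrix <- function(ex) {
  R <- matrix(0, 4, 4)
  R[1, 2] <- R[2, 1] <- ex[1] # A-C
  R[1, 3] <- R[3, 1] <- ex[2] # A-G
  R[1, 4] <- R[4, 1] <- ex[3] # A-T
  R[2, 3] <- R[3, 2] <- ex[4] # C-G
  R[2, 4] <- R[4, 2] <- ex[5] # C-T
  R[3, 4] <- R[4, 3] <- ex[6] # G-T
  R
}

check_freqs <- function(freqs, n, strict_positive = FALSE) {
  if (length(freqs) != n) stop("frequency vector has wrong length")
  if (any(!is.finite(freqs)) || any(freqs < 0)) {
    stop("frequencies must be finite and non-negative")
  }
  if (strict_positive && any(freqs <= 0)) stop("non-positive frequency")
  s <- sum(freqs)
  if (abs(s - 1) > 1e-6) stop("frequencies must sum to 1 (within 1e-6)")
  freqs / s
}

#' Normalize a raw rate matrix into a substitution model
#'
#' Sets the diagonal so every row sums to zero, then rescales the whole
#' matrix so that the expected number of substitutions per site per unit
#' time equals one: \eqn{\sum_x \pi_x q_{xx} = -1}. With this convention
#' branch lengths are interpretable as substitutions per site.
#'
#' @param raw_rates Square matrix of non-negative off-diagonal instantaneous
#'   rates (the diagonal is ignored).
#' @param freqs Stationary state frequencies (probability vector).
#' @param alph An [alphabet()]; defaults to nucleotides for 4x4 input,
#'   otherwise taken from the matrix column names.
#' @return A `"substitution_model"` with elements `alphabet`, `freqs`, `Q`,
#'   `reversible` and (for reversible models) a cached spectral
#'   decomposition used by [transition_matrix()].
#' @export
normalize_rate_matrix <- function(raw_rates, freqs, alph = NULL) {
  raw_rates <- as.matrix(raw_rates)
  n <- nrow(raw_rates)
  if (ncol(raw_rates) != n) stop("rate matrix must be square")
  if (is.null(alph)) {
    alph <- if (!is.null(colnames(raw_rates))) {
      alphabet(colnames(raw_rates))
    } else if (n == 4L) dna_alphabet() else {
      stop("supply an alphabet for non-nucleotide matrices without names")
    }
  }
  if (length(alph$states) != n) stop("alphabet/matrix dimension mismatch")
  freqs <- check_freqs(freqs, n)
  Q <- raw_rates
  diag(Q) <- 0
  if (any(!is.finite(Q)) || any(Q < 0)) {
    stop("off-diagonal rates must be finite and non-negative")
  }
  if (any(rowSums(Q) == 0)) stop("absorbing state: a row has no positive rate")
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q)) # expected substitutions/site/unit time
  if (mu <= 0) stop("total substitution rate must be positive")
  Q <- Q / mu
  dimnames(Q) <- list(alph$states, alph$states)
  reversible <- max(abs(freqs * Q - t(freqs * Q))) < 1e-9 * max(abs(Q))
  decomposition <- if (reversible) rev_decomposition(Q, freqs) else NULL
  structure(
    list(alphabet = alph, freqs = freqs, Q = Q,
         reversible = reversible, decomposition = decomposition),
    class = "substitution_model"
  )
}

# Spectral factorization of a reversible Q via the similar symmetric matrix
# B = D^{1/2} Q D^{-1/2}, D = diag(pi). Guarantees real eigenvalues.
# Zero-frequency states are handled by restricting to the support of pi is
# not needed here: reversibility with pi_x = 0 forces q_xy terms symmetric
# anyway; we guard the sqrt with a tiny floor only for exact zeros.
rev_decomposition <- function(Q, freqs) {
  if (any(freqs == 0)) return(NULL) # fall back to dense expm
  s <- sqrt(freqs)
  B <- (s * Q) %*% diag(1 / s)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  # Q = diag(1/s) U L U' diag(s);  exp(Qt) = A exp(Lt) Ainv
  list(values = e$values,
       A = diag(1 / s) %*% e$vectors,
       Ainv = t(e$vectors) %*% diag(s))
}

#' Build a named substitution model
#'
#' Supported model families: `JC` (equal rates, equal frequencies), `K2P`
#' (one transition/transversion ratio, equal frequencies), `HKY` (ratio plus
#' free frequencies), `GTR` (6 exchangeabilities plus frequencies) and `USER`
#' (a full instantaneous rate matrix over any alphabet). The returned matrix
#' is always normalized (see [normalize_rate_matrix()]).
#'
#' @param name One of `"JC"`, `"K2P"`, `"HKY"`, `"GTR"`, `"USER"`.
#' @param params Numeric parameter vector: none for JC, `kappa` for K2P/HKY,
#'   the six exchangeabilities (AC, AG, AT, CG, CT, GT) for GTR.
#' @param freqs Stationary frequencies; defaults to uniform where the model
#'   allows them to be free (HKY, GTR, USER).
#' @param rate_matrix For `USER`: a square matrix of non-negative
#'   off-diagonal rates, with state symbols as column names (or supply
#'   `alph`).
#' @param alph Optional [alphabet()] for `USER` models.
#' @return A `"substitution_model"`.
#' @examples
#' m <- build_model("GTR", params = c(1, 2, 1, 1, 2, 1),
#'                  freqs = c(0.1, 0.2, 0.3, 0.4))
#' rowSums(m$Q) # all zero
#' @export
build_model <- function(name, params = NULL, freqs = NULL,
                        rate_matrix = NULL, alph = NULL) {
  name <- toupper(name)
  if (!is.null(params) && (any(!is.finite(params)) || any(params <= 0))) {
    stop("model parameters must be strictly positive")
  }
  switch(name,
    JC = {
      if (length(params)) stop("JC takes no parameters")
      if (!is.null(freqs)) stop("JC frequencies are fixed at 1/4")
      normalize_rate_matrix(gtr_exchange_matrix(rep(1, 6)), rep(0.25, 4))
    },
    K2P = {
      if (length(params) != 1L) stop("K2P takes a single kappa parameter")
      if (!is.null(freqs)) stop("K2P frequencies are fixed at 1/4")
      k <- params[1]
      normalize_rate_matrix(gtr_exchange_matrix(c(1, k, 1, 1, k, 1)),
                            rep(0.25, 4))
    },
    HKY = {
      if (length(params) != 1L) stop("HKY takes a single kappa parameter")
      if (is.null(freqs)) freqs <- rep(0.25, 4)
      freqs <- check_freqs(freqs, 4, strict_positive = TRUE)
      k <- params[1]
      R <- gtr_exchange_matrix(c(1, k, 1, 1, k, 1))
      normalize_rate_matrix(R %*% diag(freqs), freqs)
    },
    GTR = {
      if (length(params) != 6L) {
        stop("GTR takes 6 exchangeabilities (AC, AG, AT, CG, CT, GT)")
      }
      if (is.null(freqs)) freqs <- rep(0.25, 4)
      freqs <- check_freqs(freqs, 4, strict_positive = TRUE)
      R <- gtr_exchange_matrix(params)
      normalize_rate_matrix(R %*% diag(freqs), freqs)
    },
    USER = {
      if (is.null(rate_matrix)) stop("USER model needs a rate matrix")
      if (is.null(freqs)) freqs <- stationary_freqs(rate_matrix)
      normalize_rate_matrix(rate_matrix, freqs, alph = alph)
    },
    stop("unknown model name: ", name)
  )
}

# Stationary distribution of an (un-normalized) rate matrix: left null
# vector of Q, i.e. pi Q = 0 with sum(pi) = 1.
stationary_freqs <- function(raw_rates) {
  Q <- as.matrix(raw_rates)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  n <- nrow(Q)
  # solve t(Q) v = 0 with the constraint sum v = 1
  A <- rbind(t(Q), rep(1, n))
  b <- c(rep(0, n), 1)
  v <- qr.solve(A, b)
  if (any(v < -1e-10)) stop("rate matrix has no valid stationary distribution")
  v <- pmax(v, 0)
  v / sum(v)
}

#' Read a USER rate matrix from a plain-text file
#'
#' The file holds a whitespace-separated square matrix of non-negative
#' off-diagonal instantaneous rates with a header row of state symbols.
#'
#' @param path File path.
#' @return A numeric matrix with state symbols as dimnames.
#' @export
read_rate_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, check.names = FALSE))
  if (nrow(m) != ncol(m)) stop("non-square user matrix in ", path)
  rownames(m) <- colnames(m)
  m
}

#' Transition probability matrix P(t, r) = exp(Q t r)
#'
#' For reversible models the cached spectral decomposition is reused, so
#' repeated calls with different effective distances cost one matrix rebuild
#' each; general matrices use dense scaling-and-squaring exponentiation.
#' Tiny negative entries from round-off (above `-1e-12`) are clamped to zero
#' and the row renormalized.
#'
#' @param model A `"substitution_model"`.
#' @param t Branch length (substitutions per site), `>= 0`.
#' @param r Site-rate multiplier, `>= 0` (default 1).
#' @return A row-stochastic matrix with attribute `t_eff = t * r`.
#' @export
transition_matrix <- function(model, t, r = 1) {
  stopifnot(inherits(model, "substitution_model"))
  if (!is.finite(t) || t < 0) stop("branch length t must be finite and >= 0")
  if (!is.finite(r) || r < 0) stop("site rate r must be finite and >= 0")
  s <- t * r
  P <- if (!is.null(model$decomposition)) {
    d <- model$decomposition
    d$A %*% (exp(d$values * s) * d$Ainv)
  } else {
    as.matrix(Matrix::expm(model$Q * s))
  }
  if (min(P) < -1e-12) stop("transition matrix has a large negative entry")
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(model$Q)
  attr(P, "t_eff") <- s
  P
}

#' Sample a root sequence from the stationary distribution
#'
#' Draws `L` i.i.d. states from the model's stationary frequencies. Uses the
#' current R random stream, so results are reproducible with [set.seed()].
#'
#' @param model A `"substitution_model"`.
#' @param L Sequence length, `>= 1`.
#' @return Character vector of length `L` over the model's alphabet (no
#'   gaps).
#' @export
sample_root_sequence <- function(model, L) {
  stopifnot(inherits(model, "substitution_model"))
  if (!is.numeric(L) || length(L) != 1L || L < 1) stop("L must be >= 1")
  L <- as.integer(L)
  idx <- sample.int(length(model$freqs), L, replace = TRUE,
                    prob = model$freqs)
  model$alphabet$states[idx]
}

#' @export
print.substitution_model <- function(x, ...) {
  cat("Substitution model over {", paste(x$alphabet$states, collapse = ","),
      "}", if (x$reversible) "(reversible)" else "(general)", "\n")
  cat("pi:", signif(x$freqs, 4), "\n")
  print(signif(x$Q, 4))
  invisible(x)
}

# Integer encoding used by the engine: 1..K states, 0 = gap.
encode_seq <- function(chars, alph) {
  code <- match(chars, alph$states)
  code[chars == alph$gap] <- 0L
  if (anyNA(code)) stop("sequence contains symbols outside the alphabet")
  as.integer(code)
}

decode_seq <- function(code, alph) {
  out <- character(length(code))
  out[code == 0L] <- alph$gap
  out[code != 0L] <- alph$states[code[code != 0L]]
  out
}
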