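# Rate-matrix construction, normalization, exponentiation, root sampling.

test_that("JC and degenerate GTR give the canonical equal-rates matrix", {
  m <- build_model("JC")
  expect_equal(unname(diag(m$Q)), rep(-1, 4), tolerance = 1e-12)
  off <- m$Q[row(m$Q) != col(m$Q)]
  expect_equal(unname(off), rep(1 / 3, 12), tolerance = 1e-12)
  g <- build_model("GTR", params = rep(1, 6), freqs = rep(0.25, 4))
  expect_equal(g$Q, m$Q, tolerance = 1e-12)
})

test_that("normalization invariants hold on random GTR instances", {
  set.seed(101)
  for (i in 1:200) {
    m <- random_gtr()
    expect_lt(max(abs(rowSums(m$Q))), 1e-12)
    expect_lt(abs(sum(m$freqs * diag(m$Q)) + 1), 1e-12)
    expect_true(m$reversible)
    # detailed balance of the construction
    expect_lt(max(abs(m$freqs * m$Q - t(m$freqs * m$Q))), 1e-12)
  }
})

test_that("normalize_rate_matrix handles the stated cases", {
  raw <- matrix(1, 4, 4)
  m <- normalize_rate_matrix(raw, rep(0.25, 4))
  expect_equal(unname(diag(m$Q)), rep(-1, 4))
  expect_equal(m$Q[1, 2], 1 / 3)
  # scale invariance
  m100 <- normalize_rate_matrix(raw * 100, rep(0.25, 4))
  expect_equal(m100$Q, m$Q, tolerance = 1e-14)
  # absorbing state rejected
  bad <- raw; bad[2, ] <- 0
  expect_error(normalize_rate_matrix(bad, rep(0.25, 4)), "absorbing")
  expect_error(normalize_rate_matrix(raw, rep(0.5, 2)), "length")
  expect_error(normalize_rate_matrix(matrix(1, 3, 4), rep(0.25, 4)),
               "square")
})

test_that("frequency validation renormalizes small error, rejects large", {
  f <- c(0.25, 0.25, 0.25, 0.25 + 5e-7)
  m <- build_model("GTR", params = rep(1, 6), freqs = f)
  expect_equal(sum(m$freqs), 1, tolerance = 1e-15)
  expect_error(build_model("GTR", params = rep(1, 6),
                           freqs = c(0.3, 0.3, 0.3, 0.2)), "sum to 1")
  expect_error(build_model("GTR", params = rep(1, 6),
                           freqs = c(0.5, 0.5, 0, 0)), "positive")
  expect_error(build_model("GTR", params = rep(1, 5)), "6 exchangeabilities")
  expect_error(build_model("NOSUCH"), "unknown model")
})

test_that("transition matrices: identity, closed form, ergodic limit", {
  m <- build_model("JC")
  expect_equal(transition_matrix(m, 0), diag(4), ignore_attr = TRUE,
               tolerance = 1e-12)
  P <- transition_matrix(m, 0.1)
  expect_equal(P[1, 1], 1 / 4 + (3 / 4) * exp(-4 * 0.1 / 3),
               tolerance = 1e-9)
  expect_error(transition_matrix(m, -1), ">= 0")
  expect_error(transition_matrix(m, 1, -0.5), ">= 0")
  set.seed(7)
  g <- random_gtr()
  # ergodic limit checked against the repeated-squaring oracle of P(1)
  P1 <- transition_matrix(g, 1)
  Pbig <- P1
  for (i in 1:7) Pbig <- Pbig %*% Pbig  # P(128)
  expect_lt(max(abs(sweep(Pbig, 2, g$freqs))), 1e-8)
  P128 <- transition_matrix(g, 128)
  expect_lt(max(abs(sweep(P128, 2, g$freqs))), 1e-6)
})

test_that("stochasticity, stationarity and Chapman-Kolmogorov", {
  set.seed(42)
  for (i in 1:25) {
    m <- random_gtr()
    t1 <- stats::runif(1, 0.01, 2)
    t2 <- stats::runif(1, 0.01, 2)
    P1 <- transition_matrix(m, t1)
    P2 <- transition_matrix(m, t2)
    expect_lt(max(abs(rowSums(P1) - 1)), 1e-10)
    expect_true(all(P1 >= 0))
    expect_lt(max(abs(m$freqs %*% P1 - m$freqs)), 1e-8)
    expect_lt(max(abs(P1 %*% P2 - transition_matrix(m, t1 + t2))), 1e-8)
  }
})

test_that("eigendecomposition path agrees with dense expm oracle", {
  set.seed(11)
  for (i in 1:100) {
    m <- random_gtr()
    t <- stats::runif(1, 0.01, 3)
    expect_false(is.null(m$decomposition))
    P_eig <- transition_matrix(m, t)
    P_expm <- as.matrix(Matrix::expm(m$Q * t))
    expect_lt(max(abs(P_eig - P_expm)), 1e-9)
  }
})

test_that("USER models work over arbitrary alphabets", {
  raw <- matrix(c(0, 2, 1,
                  1, 0, 3,
                  2, 1, 0), 3, 3, byrow = TRUE,
                dimnames = list(NULL, c("a", "b", "c")))
  m <- build_model("USER", rate_matrix = raw)
  expect_equal(length(m$freqs), 3L)
  expect_lt(max(abs(rowSums(m$Q))), 1e-12)
  expect_lt(abs(sum(m$freqs * diag(m$Q)) + 1), 1e-12)
  # stationarity of the derived frequencies
  expect_lt(max(abs(m$freqs %*% m$Q)), 1e-10)
  # file round trip
  f <- tempfile()
  write.table(raw, f, row.names = FALSE, quote = FALSE)
  m2 <- build_model("USER", rate_matrix = read_rate_matrix(f))
  expect_equal(m2$Q, m$Q)
})

test_that("root sequences follow the stationary distribution", {
  m <- build_model("JC")
  set.seed(5)
  s1 <- sample_root_sequence(m, 1e5)
  set.seed(5)
  s2 <- sample_root_sequence(m, 1e5)
  expect_identical(s1, s2)
  fr <- table(factor(s1, m$alphabet$states)) / 1e5
  se <- sqrt(0.25 * 0.75 / 1e5)
  expect_true(all(abs(fr - 0.25) < 4 * se))
  expect_error(sample_root_sequence(m, 0), ">= 1")
  # degenerate distribution through a USER matrix (zero frequencies are
  # legal in normalize_rate_matrix, only build_model's named path rejects
  # them)
  md <- normalize_rate_matrix(matrix(1, 4, 4), c(1, 0, 0, 0))
  expect_true(all(sample_root_sequence(md, 500) == "A"))
})

test_that("alphabet validation", {
  expect_error(alphabet(c("A", "A")), "unique")
  expect_error(alphabet("A"), "2 states")
  expect_error(alphabet(c("A", "-")), "gap")
  expect_error(sequence_state(c("A", "X"), model = build_model("JC")),
               "outside the alphabet")
})
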