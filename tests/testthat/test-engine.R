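# Branch evolution, adaptive selection, traversal, assembly.

jc <- build_model("JC")

test_that("zero-length branches are identity for both methods", {
  set.seed(12)
  st <- sequence_state(sample_root_sequence(jc, 200), rep(1, 200), jc)
  g <- gillespie_branch(st, 0, jc)
  expect_identical(g$state$code, st$code)
  expect_equal(nrow(g$events), 0L)
  expect_equal(sum(g$counts), 0L)
  p <- probmatrix_branch(st, 0, jc)
  expect_identical(p$state$code, st$code)
  expect_error(gillespie_branch(st, -1, jc), ">= 0")
})

test_that("Gillespie substitution counts are Poisson(L t)", {
  # under a normalized Q at stationarity the total leave rate is L, so the
  # event count is Poisson(L * t); scaled-down version of the acceptance run
  set.seed(13)
  L <- 500; t <- 0.2; nrep <- 2000
  st <- sequence_state(sample_root_sequence(jc, L), rep(1, L), jc)
  cnt <- vapply(seq_len(nrep), function(i) {
    gillespie_branch(st, t, jc)$counts[["n_sub"]]
  }, 0L)
  lambda <- L * t
  expect_lt(abs(mean(cnt) - lambda), 4 * sqrt(lambda / nrep))
  se_var <- sqrt((2 * lambda^2 + lambda) / nrep)
  expect_lt(abs(stats::var(cnt) - lambda), 4 * se_var)
})

test_that("insertion events appear at rate r_I (L + 1) for small t", {
  set.seed(14)
  L <- 100; t <- 0.01; nrep <- 2e4
  z <- length_distribution("zipfian", 1.7, 50)
  im <- indel_model(0.03, 0, z, z)
  st <- sequence_state(sample_root_sequence(jc, L), rep(1, L), jc)
  cnt <- vapply(seq_len(nrep), function(i) {
    gillespie_branch(st, t, jc, indel = im,
                     substitutions = FALSE)$counts[["n_ins"]]
  }, 0L)
  lambda <- 0.03 * (L + 1) * t
  expect_lt(abs(mean(cnt) - lambda), 4 * sqrt(lambda / nrep))
})

test_that("probability-matrix sampling matches the JC closed form", {
  set.seed(15)
  L <- 1e5
  st <- sequence_state(rep("A", L), rep(1, L), jc)
  p <- probmatrix_branch(st, 0.5, jc)
  frac <- mean(p$state$code == 1L)
  exact <- 1 / 4 + (3 / 4) * exp(-2 / 3)
  expect_lt(abs(frac - exact), 4 * sqrt(exact * (1 - exact) / L))
})

test_that("discrete +G4 branches build exactly 4 transition matrices", {
  set.seed(16)
  rm4 <- rate_model(gamma_shape = 0.5)
  st <- sequence_state(sample_root_sequence(jc, 400),
                       sample_site_rates(rm4, 400)$rates, jc)
  res <- probmatrix_branch(st, 0.3, jc, rm4)
  expect_equal(res$n_matrix_builds, 4L)
  # +I sites cannot change and cost no matrix build
  rmI <- rate_model(p_inv = 0.5)
  stI <- sequence_state(sample_root_sequence(jc, 400),
                        sample_site_rates(rmI, 400)$rates, jc)
  resI <- probmatrix_branch(stI, 0.3, jc, rmI)
  expect_equal(resI$n_matrix_builds, 1L)
  inv <- stI$rates == 0
  expect_identical(resI$state$code[inv], stI$code[inv])
})

test_that("choose_approach flips exactly at the printed constants", {
  expect_equal(unname(default_thresholds()),  c(2.226, 17.307))
  disc <- rate_model(gamma_shape = 0.5)          # 4-category discrete
  cont <- rate_model(gamma_shape = 0.5, continuous = TRUE)
  expect_equal(choose_approach(1000, 0.001, disc), "RATE_MATRIX")
  expect_equal(choose_approach(30000, 0.1, disc), "PROB_MATRIX")
  expect_equal(choose_approach(100, 0.17, cont), "RATE_MATRIX")
  # no-heterogeneity uses the discrete constant; ties go to PROB_MATRIX
  expect_equal(choose_approach(2226, 0.001, NULL), "PROB_MATRIX")
  expect_equal(choose_approach(2225, 0.001, NULL), "RATE_MATRIX")
  expect_equal(choose_approach(17307, 0.001, cont), "PROB_MATRIX")
  expect_equal(choose_approach(17306, 0.001, cont), "RATE_MATRIX")
  expect_equal(choose_approach(10, 1, NULL,
                               thresholds = c(discrete = 100,
                                              continuous = 100)),
               "RATE_MATRIX")
})

test_that("two-tip stationarity at large t for both approaches", {
  set.seed(17)
  m <- build_model("GTR", params = c(1, 2, 1.5, 0.8, 3, 1),
                   freqs = c(0.1, 0.2, 0.3, 0.4))
  tr <- parse_newick("(A:5,B:5);")
  L <- 2e4
  for (appr in c("rate", "prob")) {
    res <- simulate_alignment(tr, m, config = sim_config(
      length = L, seed = 18, approach = appr))
    chars <- unlist(strsplit(res$alignment, ""))
    fr <- as.numeric(table(factor(chars, m$alphabet$states))) /
      length(chars)
    se <- sqrt(m$freqs * (1 - m$freqs) / length(chars))
    expect_true(all(abs(fr - m$freqs) < 4 * se),
                label = paste("stationary frequencies,", appr))
  }
})

test_that("equivalence check passes, and rejects a corrupted arm", {
  set.seed(19)
  m <- build_model("HKY", 2, freqs = c(0.3, 0.2, 0.2, 0.3))
  ec <- equivalence_check(m, rate_model(gamma_shape = 0.5),
                          L = 500, t = 0.3, n_reps = 100)
  expect_gt(ec$p_value, 0.001)
  bad <- build_model("HKY", 8, freqs = c(0.3, 0.2, 0.2, 0.3))
  ecn <- equivalence_check(m, NULL, L = 500, t = 0.3, n_reps = 100,
                           model_prob = bad)
  expect_lt(ecn$p_value, 1e-6)
  expect_error(equivalence_check(m, NULL, L = 60, t = 0.3, n_reps = 1),
               "too small")
})

test_that("simulate_alignment conserves shape and honours zero branches", {
  set.seed(21)
  tr <- parse_newick("((A:0,B:0):0,C:0);")
  cfg <- sim_config(length = 80, seed = 5, write_ancestral = TRUE)
  res <- simulate_alignment(tr, jc, config = cfg)
  expect_true(all(nchar(res$alignment) == 80))
  root <- res$ancestral[["Root"]]
  expect_true(all(res$alignment == root))
  # without indels the alignment length always equals the root length
  tr2 <- assign_branch_lengths(yule_harding_tree(12))
  res2 <- simulate_alignment(tr2, jc, config = sim_config(length = 133,
                                                          seed = 6))
  expect_true(all(nchar(res2$alignment) == 133))
  expect_equal(length(res2$alignment), 12L)
})

test_that("missing branch lengths need a distribution", {
  set.seed(22)
  tr <- yule_harding_tree(5)
  expect_error(simulate_alignment(tr, jc,
                                  config = sim_config(length = 10, seed = 1)),
               "without lengths")
  res <- simulate_alignment(tr, jc,
                            config = sim_config(length = 10, seed = 1),
                            branch_dist = branch_length_distribution())
  expect_equal(length(res$alignment), 5L)
})

test_that("rows have equal length with indels and assemblers agree", {
  set.seed(23)
  z <- length_distribution("zipfian", 1.7, 10)
  im <- indel_model(0.08, 0.08, z, z)
  for (i in 1:30) {
    ntip <- sample(3:8, 1)
    L <- sample(10:50, 1)
    tr <- assign_branch_lengths(yule_harding_tree(ntip),
                                branch_length_distribution(mean = 0.3))
    seed <- sample.int(1e6, 1)
    a <- simulate_alignment(tr, jc, indel = im,
                            config = sim_config(length = L, seed = seed,
                                                assembler = "events"))
    b <- simulate_alignment(tr, jc, indel = im,
                            config = sim_config(length = L, seed = seed,
                                                assembler = "naive"))
    expect_identical(a$alignment, b$alignment)
    expect_equal(length(unique(nchar(a$alignment))), 1L)
  }
})

test_that("deletion-only simulations have monotone gap inheritance", {
  set.seed(24)
  z <- length_distribution("zipfian", 1.7, 5)
  im <- indel_model(0, 0.3, z, z)
  for (i in 1:10) {
    tr <- assign_branch_lengths(yule_harding_tree(6),
                                branch_length_distribution(mean = 0.4))
    cfg <- sim_config(length = 40, seed = i, write_ancestral = TRUE)
    res <- simulate_alignment(tr, jc, indel = im, config = cfg)
    rows <- c(res$alignment, res$ancestral)
    # every ancestor gap column must be a gap in every tip below it:
    # walk tip -> root through internal labels
    gapmat <- do.call(rbind, strsplit(rows, "")) == "-"
    rownames(gapmat) <- names(rows)
    for (v in which(tr$is_tip)) {
      u <- tr$parent[v]
      tipgaps <- gapmat[tr$label[v], ]
      while (!is.na(u)) {
        nm <- if (is.na(tr$parent[u])) "Root" else paste0("Node", u)
        expect_true(all(tipgaps[gapmat[nm, ]]),
                    label = "ancestor gaps persist in descendants")
        u <- tr$parent[u]
      }
    }
  }
})

test_that("memory contract: peak storage bounded by tree depth", {
  set.seed(25)
  bal <- balanced_newick(6)  # 64 tips
  sink_rows <- character(0)
  res <- simulate_alignment(bal, jc,
                            config = sim_config(length = 30, seed = 1),
                            sink = function(nm, s) sink_rows[[nm]] <<- s)
  expect_lte(res$summary$peak_stored, 7L) # log2(64) + 1
  expect_equal(res$summary$n_streamed, 64L)
  expect_equal(length(sink_rows), 64L)
  expect_true(all(nchar(sink_rows) == 30))
  # streamed rows equal the buffered result for the same seed
  res2 <- simulate_alignment(bal, jc,
                             config = sim_config(length = 30, seed = 1,
                                                 streaming = FALSE))
  expect_identical(sink_rows[names(res2$alignment)], res2$alignment)
})

test_that("simulation is deterministic and adaptive tally is recorded", {
  set.seed(26)
  m <- build_model("HKY", 2)
  tr <- assign_branch_lengths(yule_harding_tree(10))
  cfg <- sim_config(length = 50, seed = 314)
  a <- simulate_alignment(tr, m, config = cfg)
  b <- simulate_alignment(tr, m, config = cfg)
  expect_identical(a$alignment, b$alignment)
  expect_equal(sum(a$summary$approach_tally), 18L) # 2n - 2 branches
  # forcing one method shifts the tally wholesale
  r <- simulate_alignment(tr, m, config = sim_config(length = 50, seed = 314,
                                                     approach = "rate"))
  expect_equal(unname(r$summary$approach_tally["PROB_MATRIX"]), 0L)
})

test_that("calibrate_switching recovers an injected crossover law", {
  # synthetic cost oracle: Gillespie work ~ c1 * (L t), probability-matrix
  # work constant per branch, c2/c1 = 3  =>  crossover at L t = 3
  cost <- list(rate = function(L, t) 1.0 * L * t,
               prob = function(L, t) 3.0)
  fit <- calibrate_switching(jc, lengths = c(1000, 5000, 20000),
                             t_range = c(1e-6, 10), iters = 40,
                             cost_fns = cost)
  expect_equal(fit$constant, 3, tolerance = 0.01)
  one <- calibrate_switching(jc, lengths = 500, t_range = c(1e-6, 10),
                             iters = 40, cost_fns = cost)
  expect_equal(one$constant, one$crossovers$t_star[1] * 500,
               tolerance = 1e-6)
})
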