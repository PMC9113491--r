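# Branch evolution engine: Gillespie (rate matrix) and probability-matrix
# methods, per-branch adaptive choice, depth-bounded tree traversal, and
# assembly of the final gapped alignment.

#' Sequence state
#'
#' A (possibly gapped) sequence plus its parallel per-site rate vector; gap
#' positions carry rate 0.
#'
#' @param chars Character vector over the model alphabet plus `"-"`, or an
#'   integer code vector (1..K states, 0 gap).
#' @param rates Per-site rate multipliers; defaults to 1 at non-gap sites.
#' @param model A `"substitution_model"` (supplies the alphabet).
#' @return A `"sequence_state"` with elements `code` and `rates`.
#' @export
sequence_state <- function(chars, rates = NULL, model) {
  stopifnot(inherits(model, "substitution_model"))
  code <- if (is.character(chars)) encode_seq(chars, model$alphabet)
          else as.integer(chars)
  if (any(code < 0L) || any(code > length(model$alphabet$states))) {
    stop("invalid state codes")
  }
  if (is.null(rates)) rates <- as.numeric(code != 0L)
  if (length(rates) != length(code)) stop("|chars| must equal |rates|")
  if (any(rates < 0)) stop("site rates must be >= 0")
  if (any(rates[code == 0L] != 0)) stop("gap positions must carry rate 0")
  structure(list(code = code, rates = as.numeric(rates)),
            class = "sequence_state")
}

#' @export
print.sequence_state <- function(x, ...) {
  ng <- sum(x$code != 0L)
  cat("Sequence state:", length(x$code), "columns,", ng, "residues\n")
  invisible(x)
}

empty_events <- function() {
  matrix(integer(0), 0, 2, dimnames = list(NULL, c("pos", "len")))
}

#' Evolve a sequence along one branch with the Gillespie algorithm
#'
#' Event-based simulation driven by the instantaneous rate matrix: waiting
#' times are exponential with mean `1/M` where `M = S + I + D` is the total
#' mutation rate; each event is a substitution, insertion or deletion with
#' probabilities `S/M`, `I/M`, `D/M`. Substitution sites are chosen
#' proportionally to `-q_{xx} r_i`, insertion slots uniformly among the
#' `L + 1` positions around the `L` non-gap residues, deletion starts
#' uniformly among the `L` non-gap residues (deletions overrunning the end
#' are truncated).
#'
#' @param state A [sequence_state()].
#' @param t Branch length `>= 0` (substitutions per site).
#' @param model A `"substitution_model"`.
#' @param rates_model A [rate_model()] used to draw rates for inserted
#'   sites; `NULL` means the homogeneous model.
#' @param indel An [indel_model()] or `NULL` (substitutions only).
#' @param substitutions Set `FALSE` to pin the total substitution rate `S`
#'   at zero (used for the indel phase of the probability-matrix method).
#' @return List with `state` (the evolved [sequence_state()]), `events`
#'   (integer matrix of insertion events: alignment `pos` of the new block
#'   and its `len`) and `counts` (named vector `n_sub`, `n_ins`, `n_del`).
#' @export
gillespie_branch <- function(state, t, model, rates_model = NULL,
                             indel = NULL, substitutions = TRUE) {
  stopifnot(inherits(state, "sequence_state"),
            inherits(model, "substitution_model"))
  if (!is.finite(t) || t < 0) stop("branch length t must be finite and >= 0")
  rs <- rate_spec_for_cpp(rates_model)
  if (is.null(indel)) {
    r_ins <- 0; r_del <- 0; u_del <- 1; icdf <- 1; dcdf <- 1
  } else {
    r_ins <- indel$r_ins; r_del <- indel$r_del; u_del <- indel$u_del
    icdf <- indel$ins_dist$cdf; dcdf <- indel$del_dist$cdf
  }
  res <- gillespie_branch_cpp(state$code, state$rates, t, model$Q,
                              model$freqs, r_ins, r_del, u_del,
                              icdf, dcdf,
                              rs$mode, rs$p_inv,
                              if (is.null(rs$alpha)) 0 else rs$alpha,
                              rs$scale, rs$cat_cdf, rs$cat_rates,
                              substitutions)
  out_state <- structure(list(code = res$code, rates = res$rates),
                         class = "sequence_state")
  list(state = out_state, events = res$events, counts = res$counts)
}

#' Evolve a sequence along one branch with the probability-matrix method
#'
#' Each non-gap site draws its child state from row `x_i` of
#' `P(t, r_i) = exp(Q t r_i)`. With a discrete rate model only one transition
#' matrix per distinct site rate is built (at most `k`, plus none for
#' invariant sites, which cannot change); with continuous Gamma rates the
#' cached eigendecomposition is applied to all per-site effective distances
#' at once. Indels, if any, are then simulated by [gillespie_branch()] with
#' the substitution rate pinned at zero.
#'
#' @inheritParams gillespie_branch
#' @return As [gillespie_branch()], plus `n_matrix_builds`, the number of
#'   transition-matrix constructions performed.
#' @export
probmatrix_branch <- function(state, t, model, rates_model = NULL,
                              indel = NULL) {
  stopifnot(inherits(state, "sequence_state"),
            inherits(model, "substitution_model"))
  if (!is.finite(t) || t < 0) stop("branch length t must be finite and >= 0")
  code <- state$code
  rates <- state$rates
  K <- length(model$freqs)
  ng <- which(code != 0L & rates > 0)
  n_builds <- 0L
  if (length(ng) > 0 && t > 0) {
    continuous <- !is.null(rates_model) &&
      rates_model$kind == "gamma_continuous"
    if (!continuous) {
      parent_code <- code # snapshot: groups are defined by parent states
      ur <- unique(rates[ng])
      for (rr in ur) {
        P <- transition_matrix(model, t, rr)
        n_builds <- n_builds + 1L
        idx <- ng[rates[ng] == rr]
        for (x in unique(parent_code[idx])) {
          sites <- idx[parent_code[idx] == x]
          code[sites] <- sample.int(K, length(sites), replace = TRUE,
                                    prob = P[x, ])
        }
      }
    } else if (!is.null(model$decomposition)) {
      d <- model$decomposition
      s <- t * rates[ng]
      E <- exp(outer(s, d$values))            # n x K
      probs <- (d$A[code[ng], , drop = FALSE] * E) %*% d$Ainv
      probs[probs < 0] <- 0
      probs <- probs / rowSums(probs)
      cum <- probs
      for (j in 2:K) cum[, j] <- cum[, j - 1] + cum[, j]
      u <- stats::runif(length(ng))
      code[ng] <- as.integer(rowSums(u > cum) + 1L)
      n_builds <- length(ng)
    } else {
      # general (non-reversible) matrix: dense expm per site
      for (i in ng) {
        P <- transition_matrix(model, t, rates[i])
        n_builds <- n_builds + 1L
        code[i] <- sample.int(K, 1L, prob = P[code[i], ])
      }
    }
  }
  out <- structure(list(code = code, rates = rates),
                   class = "sequence_state")
  if (!is.null(indel)) {
    res <- gillespie_branch(out, t, model, rates_model, indel,
                            substitutions = FALSE)
    res$n_matrix_builds <- n_builds
    res
  } else {
    list(state = out, events = empty_events(),
         counts = c(n_sub = NA_integer_, n_ins = 0L, n_del = 0L),
         n_matrix_builds = n_builds)
  }
}

#' Default switching thresholds of the adaptive method
#'
#' The rate-matrix (Gillespie) method is used on a branch when the product
#' of sequence length and branch length falls below the threshold: 2.226
#' for homogeneous/discrete rate models and 17.307 for continuous Gamma.
#' @return Named numeric vector with elements `discrete` and `continuous`.
#' @export
default_thresholds <- function() c(discrete = 2.226, continuous = 17.307)

#' Choose the simulation method for one branch
#'
#' Returns `"RATE_MATRIX"` iff `L * t` is strictly below the applicable
#' threshold (ties go to the probability-matrix method).
#'
#' @param L Current (non-gap) sequence length, `>= 1`.
#' @param t Branch length `>= 0`.
#' @param rates_model A [rate_model()] or `NULL`; only a continuous-Gamma
#'   model selects the continuous threshold.
#' @param thresholds Named vector as [default_thresholds()].
#' @return `"RATE_MATRIX"` or `"PROB_MATRIX"`.
#' @export
choose_approach <- function(L, t, rates_model = NULL,
                            thresholds = default_thresholds()) {
  stopifnot(L >= 1, t >= 0)
  cont <- !is.null(rates_model) && rates_model$kind == "gamma_continuous"
  thr <- unname(thresholds[if (cont) "continuous" else "discrete"])
  if (L * t < thr) "RATE_MATRIX" else "PROB_MATRIX"
}

#' Simulation configuration
#'
#' @param length Root sequence length (ignored when `root_sequence` given).
#' @param approach `"adaptive"` (per-branch switch), `"rate"` (always
#'   Gillespie) or `"prob"` (always probability matrix).
#' @param thresholds Adaptive switching constants, see
#'   [default_thresholds()].
#' @param seed Integer seed; all randomness derives from it (per-branch
#'   substreams are derived from `(seed, replicate, node id)`).
#' @param n_alignments Number of replicate alignments (used by [run_cli()]).
#' @param write_ancestral Keep internal-node sequences in the result
#'   (forces `streaming = FALSE`).
#' @param streaming Write and free each tip as soon as it is simulated
#'   (automatic only without indels and with a `sink`).
#' @param assembler `"events"` (lazy gap insertion from the event log,
#'   the default) or `"naive"` (gaps physically inserted into every stored
#'   row at event time; reference implementation, same output).
#' @param root_sequence Optional character string/vector used as the root
#'   sequence instead of a stationary draw.
#' @return A `"sim_config"` list.
#' @export
sim_config <- function(length = NULL,
                       approach = c("adaptive", "rate", "prob"),
                       thresholds = default_thresholds(),
                       seed = NULL, n_alignments = 1L,
                       write_ancestral = FALSE, streaming = TRUE,
                       assembler = c("events", "naive"),
                       root_sequence = NULL) {
  approach <- match.arg(approach)
  assembler <- match.arg(assembler)
  if (is.null(root_sequence)) {
    if (is.null(length) || length < 1) stop("need a root length >= 1")
    length <- as.integer(length)
  } else {
    if (is.character(root_sequence) && length(root_sequence) == 1L) {
      root_sequence <- strsplit(root_sequence, "")[[1]]
    }
    length <- length(root_sequence)
  }
  if (any(thresholds <= 0)) stop("thresholds must be > 0")
  if (is.null(seed)) seed <- sample.int(2^31 - 2, 1)
  if (write_ancestral) streaming <- FALSE
  structure(
    list(length = length, approach = approach, thresholds = thresholds,
         seed = as.integer(seed), n_alignments = as.integer(n_alignments),
         write_ancestral = write_ancestral, streaming = streaming,
         assembler = assembler, root_sequence = root_sequence),
    class = "sim_config"
  )
}

# apply global insertion events (ev_from+1 .. nrow) to one row
apply_gap_events <- function(code, rates, events, ev_from) {
  n <- nrow(events)
  if (ev_from >= n) return(list(code = code, rates = rates))
  for (e in (ev_from + 1L):n) {
    pos <- events[e, 1L]
    len <- events[e, 2L]
    gap <- integer(len)
    if (pos == 1L) {
      code <- c(gap, code)
      rates <- c(numeric(len), rates)
    } else if (pos > length(code)) {
      code <- c(code, gap)
      rates <- c(rates, numeric(len))
    } else {
      code <- c(code[seq_len(pos - 1L)], gap,
                code[pos:length(code)])
      rates <- c(rates[seq_len(pos - 1L)], numeric(len),
                 rates[pos:length(rates)])
    }
  }
  list(code = code, rates = rates)
}

#' Simulate one alignment along a tree
#'
#' Draws a root sequence from the stationary distribution (unless supplied),
#' evolves it branch by branch in depth-first order, and assembles the gapped
#' alignment. Each internal node's sequence is freed as soon as all its
#' children are generated; with streaming on (and no indels) each tip row is
#' handed to `sink` and freed immediately, so the peak number of concurrently
#' stored sequences is bounded by the tree depth rather than `2n - 1`.
#'
#' With indels, insertion events at one node open a gap column in every other
#' row. The default assembler records the global insertion-event log and
#' patches rows lazily (when a branch starts from a stale parent copy, and at
#' final materialization); `assembler = "naive"` physically inserts the gap
#' block into every stored row at event time. Both produce byte-identical
#' output.
#'
#' @param tree A `"sim_tree"` with branch lengths (or supply `branch_dist`).
#' @param model A `"substitution_model"`.
#' @param rates_model A [rate_model()] or `NULL`.
#' @param indel An [indel_model()] or `NULL`.
#' @param config A [sim_config()].
#' @param sink Optional `function(name, sequence_string)` called for each
#'   tip as soon as it is final (only used when streaming is possible).
#' @param rep Replicate index (enters the per-branch seed derivation).
#' @param branch_dist Optional [branch_length_distribution()] used to draw
#'   lengths when the tree has none.
#' @return A list of class `"msa_result"`: `alignment` (named character
#'   vector of equal-length rows, tips in depth-first order; `NULL` for rows
#'   already streamed to `sink`), `ancestral` (if requested), and `summary`
#'   (root length, final alignment length, event counts, per-method branch
#'   tally, `peak_stored`, seed).
#' @export
simulate_alignment <- function(tree, model, rates_model = NULL, indel = NULL,
                               config, sink = NULL, rep = 1L,
                               branch_dist = NULL) {
  stopifnot(inherits(tree, "sim_tree"),
            inherits(model, "substitution_model"),
            inherits(config, "sim_config"))
  non_root <- seq_along(tree$parent)[-tree$root]
  if (anyNA(tree$brlen[non_root])) {
    if (is.null(branch_dist)) {
      stop("tree has branches without lengths and no branch-length ",
           "distribution was supplied")
    }
    with_branch_seed(config$seed, rep, 0L,
                     tree <- assign_branch_lengths(tree, branch_dist))
  }
  naive <- config$assembler == "naive"
  has_indel <- !is.null(indel) &&
    (indel$r_ins > 0 || indel$r_del > 0)
  stream <- config$streaming && !has_indel && !is.null(sink) &&
    !config$write_ancestral

  # root sequence + rates
  with_branch_seed(config$seed, rep, tree$root, {
    root_chars <- if (is.null(config$root_sequence)) {
      sample_root_sequence(model, config$length)
    } else config$root_sequence
    root_rates <- sample_site_rates(rates_model, config$length)$rates
  })
  root_state <- sequence_state(root_chars, root_rates, model)
  root_state$rates[root_state$code == 0L] <- 0

  store <- new.env(parent = emptyenv())
  assign(as.character(tree$root),
         list(code = root_state$code, rates = root_state$rates, ev = 0L),
         envir = store)
  n_stored <- 1L
  peak <- 1L
  events <- empty_events()
  tally <- c(RATE_MATRIX = 0L, PROB_MATRIX = 0L)
  counts <- c(n_sub = 0L, n_ins = 0L, n_del = 0L)
  tip_rows <- list()   # finished tips (buffered unless streamed)
  anc_rows <- list()
  n_streamed <- 0L

  patch_all_stored <- function() {
    # naive assembler: gap columns appear in every other row the moment the
    # insertion happens; here every live row and every buffered tip is
    # brought up to the current global event count
    n_ev <- nrow(events)
    for (nm in ls(store)) {
      row <- get(nm, envir = store)
      pr <- apply_gap_events(row$code, row$rates, events, row$ev)
      assign(nm, list(code = pr$code, rates = pr$rates, ev = n_ev),
             envir = store)
    }
    for (nm in names(tip_rows)) {
      row <- tip_rows[[nm]]
      if (!is.list(row)) next # already streamed out
      pr <- apply_gap_events(row$code, numeric(length(row$code)),
                             events, row$ev)
      tip_rows[[nm]] <<- list(code = pr$code, ev = n_ev)
    }
  }

  evolve_child <- function(v, ch) {
      pv <- get(as.character(v), envir = store)
      t_br <- tree$brlen[ch]
      # bring the parent copy up to date with events from other subtrees
      st <- apply_gap_events(pv$code, pv$rates, events, pv$ev)
      parent_state <- structure(list(code = st$code, rates = st$rates),
                                class = "sequence_state")
      Lng <- sum(parent_state$code != 0L)
      meth <- switch(config$approach,
        rate = "RATE_MATRIX",
        prob = "PROB_MATRIX",
        adaptive = if (Lng == 0L) "PROB_MATRIX" else
          choose_approach(Lng, t_br, rates_model, config$thresholds))
      tally[[meth]] <<- tally[[meth]] + 1L
      with_branch_seed(config$seed, rep, ch, {
        res <- if (meth == "RATE_MATRIX") {
          gillespie_branch(parent_state, t_br, model, rates_model, indel)
        } else {
          probmatrix_branch(parent_state, t_br, model, rates_model, indel)
        }
      })
      cc <- res$counts
      if (!is.na(cc[["n_sub"]])) counts[["n_sub"]] <<- counts[["n_sub"]] +
        cc[["n_sub"]]
      counts[["n_ins"]] <<- counts[["n_ins"]] + cc[["n_ins"]]
      counts[["n_del"]] <<- counts[["n_del"]] + cc[["n_del"]]
      if (nrow(res$events) > 0L) {
        events <<- rbind(events, res$events)
        if (naive) patch_all_stored()
      }
      assign(as.character(ch),
             list(code = res$state$code, rates = res$state$rates,
                  ev = nrow(events)),
             envir = store)
      n_stored <<- n_stored + 1L
      if (n_stored > peak) peak <<- n_stored
      if (tree$is_tip[ch]) {
        nm <- tree$label[ch]
        if (stream) {
          sink(nm, paste(decode_seq(res$state$code, model$alphabet),
                         collapse = ""))
          tip_rows[[nm]] <<- NA_character_
          n_streamed <<- n_streamed + 1L
        } else {
          tip_rows[[nm]] <<- list(code = res$state$code, ev = nrow(events))
        }
        rm(list = as.character(ch), envir = store)
        n_stored <<- n_stored - 1L
      }
  }
  free_internal <- function(v) {
    if (config$write_ancestral) {
      nm <- if (nzchar(tree$label[v])) tree$label[v] else paste0("Node", v)
      row <- get(as.character(v), envir = store)
      anc_rows[[nm]] <<- list(code = row$code, ev = row$ev)
    }
    rm(list = as.character(v), envir = store)
    n_stored <<- n_stored - 1L
  }
  # iterative depth-first traversal (an explicit frame stack keeps deep
  # caterpillar trees off the C stack); an internal node is freed as soon as
  # its last child subtree is finished
  frames_v <- tree$root
  frames_i <- 0L
  while (length(frames_v)) {
    top <- length(frames_v)
    v <- frames_v[top]
    i <- frames_i[top] + 1L
    kids <- tree$children[[v]]
    if (i > length(kids)) {
      frames_v <- frames_v[-top]
      frames_i <- frames_i[-top]
      if (v != tree$root) free_internal(v)
      next
    }
    frames_i[top] <- i
    ch <- kids[i]
    evolve_child(v, ch)
    if (!tree$is_tip[ch]) {
      frames_v <- c(frames_v, ch)
      frames_i <- c(frames_i, 0L)
    }
  }
  if (config$write_ancestral) {
    rootrow <- get(as.character(tree$root), envir = store)
    nm <- if (nzchar(tree$label[tree$root])) tree$label[tree$root] else "Root"
    anc_rows[[nm]] <- list(code = rootrow$code, ev = rootrow$ev)
  }

  materialize <- function(rows) {
    out <- character(length(rows))
    names(out) <- names(rows)
    for (i in seq_along(rows)) {
      row <- rows[[i]]
      pr <- apply_gap_events(row$code, numeric(length(row$code)),
                             events, row$ev)
      out[i] <- paste(decode_seq(pr$code, model$alphabet), collapse = "")
    }
    out
  }
  aln <- if (stream) NULL else materialize(tip_rows)
  list(
    alignment = aln,
    ancestral = if (config$write_ancestral) materialize(anc_rows) else NULL,
    summary = list(
      n_tips = sum(tree$is_tip),
      root_length = config$length,
      alignment_length = if (!is.null(aln) && length(aln)) nchar(aln[[1]])
                         else config$length + sum(events[, "len"]),
      counts = counts,
      n_insertion_events = nrow(events),
      approach_tally = tally,
      peak_stored = peak,
      n_streamed = n_streamed,
      seed = config$seed,
      rep = rep
    )
  )
}

#' Chi-square equivalence check between the two branch methods
#'
#' Simulates `n_reps` child sequences from one fixed parent with each method
#' (no indels), tabulates parent-state x child-state counts, and tests
#' homogeneity of the two methods' child-state distributions with a summed
#' chi-square statistic (one 2 x K table per parent state; columns with zero
#' total and parent states with expected counts below 5 are dropped per the
#' usual validity rule).
#'
#' @param model A `"substitution_model"`.
#' @param rates_model A [rate_model()] or `NULL`.
#' @param L Sites per replicate.
#' @param t Branch length.
#' @param n_reps Replicates per method.
#' @param model_prob Model handed to the probability-matrix arm; defaults to
#'   `model`. Passing a deliberately different model is the negative
#'   control: the test must then reject.
#' @return List with `statistic`, `df`, `p_value` and the two count tables.
#' @export
equivalence_check <- function(model, rates_model = NULL, L = 1000, t = 0.3,
                              n_reps = 200, model_prob = model) {
  K <- length(model$freqs)
  parent <- sequence_state(sample_root_sequence(model, L),
                           sample_site_rates(rates_model, L)$rates, model)
  tab <- function(fun) {
    m <- matrix(0L, K, K, dimnames = dimnames(model$Q))
    for (i in seq_len(n_reps)) {
      child <- fun()$state$code
      keep <- parent$rates > 0
      m <- m + table(factor(parent$code[keep], levels = 1:K),
                     factor(child[keep], levels = 1:K))
    }
    m
  }
  t1 <- tab(function() gillespie_branch(parent, t, model, rates_model))
  t2 <- tab(function() probmatrix_branch(parent, t, model_prob, rates_model))
  stat <- 0; df <- 0
  for (x in 1:K) {
    m2 <- rbind(t1[x, ], t2[x, ])
    m2 <- m2[, colSums(m2) > 0, drop = FALSE]
    if (ncol(m2) < 2L) next
    exp_cell <- outer(rowSums(m2), colSums(m2)) / sum(m2)
    if (min(exp_cell) < 5) {
      stop("n_reps too small for chi-square validity (expected cell < 5)")
    }
    stat <- stat + sum((m2 - exp_cell)^2 / exp_cell)
    df <- df + (ncol(m2) - 1L)
  }
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       counts_rate_matrix = t1, counts_prob_matrix = t2)
}

#' Calibrate the adaptive switching constant on this machine
#'
#' For each sequence length, binary-searches the branch length at which the
#' measured cost of the Gillespie method crosses that of the
#' probability-matrix method, then least-square-fits the crossover `t*`
#' against `1/L` through the origin, returning the fitted `L t` constant.
#' Results are hardware-dependent and informational only: the defaults
#' ([default_thresholds()]) are never overridden.
#'
#' @param model A `"substitution_model"`.
#' @param rates_model A [rate_model()] or `NULL`.
#' @param lengths Grid of sequence lengths.
#' @param t_range Branch-length search interval.
#' @param iters Bisection iterations.
#' @param cost_fns Optional list of two functions `rate(L, t)` and
#'   `prob(L, t)` returning a cost; defaults to wall-clock timings of the
#'   two branch operations.
#' @param reps Timing replicates per measurement (default path only).
#' @return List with `crossovers` (data.frame of `L`, `t_star`) and
#'   `constant` (the fitted `L t` value).
#' @export
calibrate_switching <- function(model, rates_model = NULL,
                                lengths = c(1000, 5000, 20000),
                                t_range = c(1e-4, 5), iters = 14,
                                cost_fns = NULL, reps = 3) {
  if (is.null(cost_fns)) {
    time_op <- function(fun, L, t) {
      st <- sequence_state(sample_root_sequence(model, L),
                           sample_site_rates(rates_model, L)$rates, model)
      min(vapply(seq_len(reps), function(i) {
        system.time(fun(st, t, model, rates_model))[["elapsed"]]
      }, 0))
    }
    cost_fns <- list(
      rate = function(L, t) time_op(gillespie_branch, L, t),
      prob = function(L, t) time_op(probmatrix_branch, L, t)
    )
  }
  diff_cost <- function(L, t) cost_fns$rate(L, t) - cost_fns$prob(L, t)
  t_star <- vapply(lengths, function(L) {
    lo <- t_range[1]; hi <- t_range[2]
    dlo <- diff_cost(L, lo); dhi <- diff_cost(L, hi)
    if (dlo >= 0 || dhi <= 0) {
      warning("non-monotone or non-bracketing timings at L = ", L,
              "; widening search")
      lo <- lo / 10; hi <- hi * 10
      dlo <- diff_cost(L, lo); dhi <- diff_cost(L, hi)
      if (dlo >= 0 || dhi <= 0) return(NA_real_)
    }
    for (i in seq_len(iters)) {
      mid <- sqrt(lo * hi)
      if (diff_cost(L, mid) < 0) lo <- mid else hi <- mid
    }
    sqrt(lo * hi)
  }, 0)
  ok <- is.finite(t_star)
  x <- 1 / lengths[ok]
  constant <- sum(t_star[ok] * x) / sum(x^2)
  list(crossovers = data.frame(L = lengths, t_star = t_star),
       constant = constant)
}
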