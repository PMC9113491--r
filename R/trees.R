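# Rooted trees: Newick I/O (parsing via ape), Yule-Harding and birth-death
# random topologies, stochastic branch lengths.
#
# Internal representation ("sim_tree"): parallel vectors indexed by node id —
# parent (NA at root), label, brlen (NA at root), plus a children list.
# Multifurcations are allowed anywhere, including a trifurcating root.

new_sim_tree <- function(parent, label, brlen) {
  n <- length(parent)
  children <- vector("list", n)
  for (v in seq_len(n)) {
    p <- parent[v]
    if (!is.na(p)) children[[p]] <- c(children[[p]], v)
  }
  root <- which(is.na(parent))
  if (length(root) != 1L) stop("tree must have exactly one root")
  is_tip <- lengths(children) == 0L
  tips <- label[is_tip]
  if (anyDuplicated(tips[tips != ""])) stop("duplicate tip names")
  structure(
    list(parent = parent, children = children, label = label,
         brlen = brlen, root = root, is_tip = is_tip),
    class = "sim_tree"
  )
}

#' @export
print.sim_tree <- function(x, ...) {
  cat("Rooted tree:", sum(x$is_tip), "tips,", sum(!x$is_tip),
      "internal nodes\n")
  invisible(x)
}

#' Number of tips of a tree
#' @param tree A `"sim_tree"`.
#' @return Integer tip count.
#' @export
n_tips <- function(tree) sum(tree$is_tip)

#' Parse a Newick tree
#'
#' Accepts rooted or unrooted-style (trifurcating root) Newick with
#' multifurcations; branch lengths may be missing (they can be assigned later
#' with [assign_branch_lengths()]). Parsing is delegated to
#' [ape::read.tree()], with additional validation of parenthesis balance,
#' tip-name uniqueness and branch-length sign.
#'
#' @param text A Newick string, or the path of a file containing one.
#' @return A `"sim_tree"`.
#' @examples
#' tr <- parse_newick("((A:0.1,B:0.2):0.05,C:0.3);")
#' n_tips(tr)
#' @export
parse_newick <- function(text) {
  if (length(text) != 1L || !is.character(text)) {
    stop("expected a single Newick string or file path")
  }
  if (!grepl(";", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  }
  no_q <- gsub("'[^']*'", "", text)
  if (sum(strsplit(no_q, "")[[1]] == "(") !=
      sum(strsplit(no_q, "")[[1]] == ")")) {
    stop("unbalanced parentheses in Newick string")
  }
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) stop("malformed Newick: ",
                                           conditionMessage(e)))
  if (is.null(phy)) stop("malformed Newick string")
  from_phylo(phy)
}

# ape::phylo -> sim_tree
from_phylo <- function(phy) {
  ntip <- length(phy$tip.label)
  n <- ntip + phy$Nnode
  parent <- rep(NA_integer_, n)
  brlen <- rep(NA_real_, n)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  if (!is.null(phy$edge.length)) {
    if (any(phy$edge.length < 0)) stop("negative branch length")
    brlen[phy$edge[, 2]] <- phy$edge.length
  }
  label <- character(n)
  label[seq_len(ntip)] <- phy$tip.label
  if (!is.null(phy$node.label)) {
    label[ntip + seq_len(phy$Nnode)] <- phy$node.label
  }
  new_sim_tree(parent, label, brlen)
}

# sim_tree -> ape::phylo (used by tests and interop, not by the writer)
as_phylo <- function(tree) {
  ape::read.tree(text = write_newick(tree))
}

#' Write a tree as a Newick string
#'
#' Branch lengths are printed with 10 significant digits so that a
#' parse/write round trip is lossless at that precision.
#'
#' @param tree A `"sim_tree"`.
#' @param file Optional path; when given the string is also written there.
#' @return The Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "sim_tree"))
  fmt <- function(v) {
    kids <- tree$children[[v]]
    lab <- tree$label[v]
    core <- if (length(kids) == 0L) lab else {
      paste0("(", paste(vapply(kids, fmt, ""), collapse = ","), ")", lab)
    }
    if (is.na(tree$brlen[v])) core
    else paste0(core, ":", formatC(tree$brlen[v], digits = 10,
                                   format = "g"))
  }
  out <- paste0(fmt(tree$root), ";")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Random topology under the Yule-Harding model
#'
#' Grows a rooted bifurcating topology by repeatedly splitting a uniformly
#' chosen extant lineage until `n` tips exist; tips are labelled `T1..Tn` in
#' random order. Branch lengths are not set (see
#' [assign_branch_lengths()]).
#'
#' @param n Number of tips, `>= 2`.
#' @return A `"sim_tree"` with `2n - 1` nodes and no branch lengths.
#' @export
yule_harding_tree <- function(n) {
  if (!is.numeric(n) || n < 2) stop("need at least 2 tips")
  n <- as.integer(n)
  total <- 2L * n - 1L
  parent <- rep(NA_integer_, total)
  parent[2:3] <- 1L
  extant <- c(2L, 3L)
  nxt <- 4L
  while (length(extant) < n) {
    i <- sample.int(length(extant), 1L)
    v <- extant[i]
    parent[nxt] <- v
    parent[nxt + 1L] <- v
    extant <- c(extant[-i], nxt, nxt + 1L)
    nxt <- nxt + 2L
  }
  label <- character(total)
  label[extant] <- paste0("T", sample.int(n))
  new_sim_tree(parent, label, rep(NA_real_, total))
}

#' Random topology under the birth-death model
#'
#' Forward-time birth-death process conditioned on reaching `n` surviving
#' lineages (the run restarts whenever the process dies out first); extinct
#' lineages are pruned and degree-two nodes collapsed, so the returned
#' topology is bifurcating with exactly `n` tips. With `death_rate = 0` this
#' is the pure-birth (Yule) process.
#'
#' @param n Number of surviving tips, `>= 2`.
#' @param birth_rate Speciation rate `lambda > 0`.
#' @param death_rate Extinction rate `mu`, `0 <= mu < lambda`.
#' @return A `"sim_tree"` with `n` tips and no branch lengths.
#' @export
birth_death_tree <- function(n, birth_rate, death_rate = 0) {
  if (!is.numeric(n) || n < 2) stop("need at least 2 tips")
  if (!is.finite(birth_rate) || birth_rate <= 0) stop("birth rate must be > 0")
  if (!is.finite(death_rate) || death_rate < 0 || death_rate >= birth_rate) {
    stop("need 0 <= death rate < birth rate for tip-count conditioning")
  }
  n <- as.integer(n)
  p_birth <- birth_rate / (birth_rate + death_rate)
  repeat {
    parent <- rep(NA_integer_, 2L * n + 2L)
    alive <- logical(length(parent))
    parent[2:3] <- 1L
    alive[2:3] <- TRUE
    nxt <- 4L
    repeat {
      extant <- which(alive)
      k <- length(extant)
      if (k == 0L) break            # extinct: restart
      if (k == n) break             # reached target
      v <- extant[sample.int(k, 1L)]
      if (stats::runif(1) < p_birth) {
        if (nxt + 1L > length(parent)) {
          parent <- c(parent, rep(NA_integer_, length(parent)))
          alive <- c(alive, logical(length(alive)))
        }
        parent[nxt] <- v; parent[nxt + 1L] <- v
        alive[c(nxt, nxt + 1L)] <- TRUE
        alive[v] <- FALSE
        nxt <- nxt + 2L
      } else {
        alive[v] <- FALSE           # extinction: v becomes a dead tip
      }
    }
    if (sum(alive) == n) {
      return(prune_to_survivors(parent[seq_len(nxt - 1L)],
                                which(alive[seq_len(nxt - 1L)]), n))
    }
  }
}

# Keep only ancestors of the surviving tips; collapse unifurcations
# (including a unifurcating root). Survivors get labels T1..Tn in random
# order.
prune_to_survivors <- function(parent, survivors, n) {
  total <- length(parent)
  keep <- logical(total)
  for (v in survivors) {
    u <- v
    while (!is.na(u) && !keep[u]) { keep[u] <- TRUE; u <- parent[u] }
  }
  nkid <- integer(total)
  for (v in which(keep)) {
    p <- parent[v]
    if (!is.na(p)) nkid[p] <- nkid[p] + 1L
  }
  # collapse kept internal nodes with a single kept child
  up <- function(v) {
    p <- parent[v]
    while (!is.na(p) && nkid[p] == 1L) p <- parent[p]
    p
  }
  is_surv <- logical(total); is_surv[survivors] <- TRUE
  nodes <- which(keep & (is_surv | nkid >= 2L))
  # root = kept node whose collapsed parent is NA
  new_id <- integer(total)
  new_id[nodes] <- seq_along(nodes)
  np <- rep(NA_integer_, length(nodes))
  for (i in seq_along(nodes)) {
    p <- up(nodes[i])
    while (!is.na(p) && !(is_surv[p] || nkid[p] >= 2L)) p <- up(p)
    np[i] <- if (is.na(p)) NA_integer_ else new_id[p]
  }
  label <- character(length(nodes))
  label[new_id[survivors]] <- paste0("T", sample.int(n))
  new_sim_tree(np, label, rep(NA_real_, length(nodes)))
}

#' Branch-length distribution
#'
#' Either exponential with a given mean (the random-tree default is mean
#' 0.1 substitutions/site) or a uniform choice from a user-supplied list of
#' values.
#'
#' @param kind `"exponential"` or `"user_list"`.
#' @param mean Mean of the exponential, `> 0`.
#' @param values Non-empty vector of non-negative lengths for `"user_list"`.
#' @return A `"branch_length_distribution"`.
#' @export
branch_length_distribution <- function(kind = c("exponential", "user_list"),
                                       mean = 0.1, values = NULL) {
  kind <- match.arg(kind)
  if (kind == "exponential") {
    if (!is.finite(mean) || mean <= 0) stop("exponential mean must be > 0")
  } else {
    if (is.null(values) || length(values) == 0L) stop("empty user list")
    if (any(!is.finite(values)) || any(values < 0)) {
      stop("user-list branch lengths must be >= 0")
    }
  }
  structure(list(kind = kind, mean = mean, values = values),
            class = "branch_length_distribution")
}

#' Draw branch lengths from a distribution
#' @param dist A [branch_length_distribution()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
draw_branch_lengths <- function(dist, n) {
  stopifnot(inherits(dist, "branch_length_distribution"))
  if (dist$kind == "exponential") stats::rexp(n, rate = 1 / dist$mean)
  else dist$values[sample.int(length(dist$values), n, replace = TRUE)]
}

#' Assign random branch lengths to every non-root branch
#'
#' Every non-root node receives an i.i.d. draw from `dist` as the length of
#' the branch to its parent. Existing lengths are overwritten.
#'
#' @param tree A `"sim_tree"`.
#' @param dist A [branch_length_distribution()]; default exponential with
#'   mean 0.1.
#' @return The tree with branch lengths set.
#' @export
assign_branch_lengths <- function(tree,
                                  dist = branch_length_distribution()) {
  stopifnot(inherits(tree, "sim_tree"))
  non_root <- seq_along(tree$parent)[-tree$root]
  tree$brlen[non_root] <- draw_branch_lengths(dist, length(non_root))
  tree
}

#' Multiply every branch length by a constant
#' @param tree A `"sim_tree"` with branch lengths.
#' @param factor Positive scaling factor.
#' @return The rescaled tree.
#' @export
scale_branches <- function(tree, factor) {
  stopifnot(inherits(tree, "sim_tree"))
  if (!is.finite(factor) || factor <= 0) stop("scale factor must be > 0")
  tree$brlen <- tree$brlen * factor
  tree
}

#' Structural tree statistics
#'
#' @param tree A `"sim_tree"`.
#' @return A list with `n_tips`, `n_internal_nodes`, `max_depth_in_nodes`
#'   (nodes on the longest root-to-tip path; a balanced bifurcating tree has
#'   `log2(n) + 1`) and `n_internal_branches_unrooted` (internal branches
#'   after suppressing a degree-two root, i.e. `n - 3` for a bifurcating
#'   tree).
#' @export
tree_stats <- function(tree) {
  stopifnot(inherits(tree, "sim_tree"))
  n <- length(tree$parent)
  depth <- integer(n)
  depth[tree$root] <- 1L
  # children always have larger... not guaranteed; traverse explicitly
  stack <- tree$root
  maxd <- 1L
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (c in tree$children[[v]]) {
      depth[c] <- depth[v] + 1L
      if (depth[c] > maxd) maxd <- depth[c]
      stack <- c(stack, c)
    }
  }
  internal <- !tree$is_tip
  # edges with both ends internal, excluding root-incident edges
  cnt <- 0L
  for (v in seq_len(n)) {
    p <- tree$parent[v]
    if (!is.na(p) && p != tree$root && internal[v]) cnt <- cnt + 1L
  }
  rk <- tree$children[[tree$root]]
  if (length(rk) == 2L) {
    # unrooted view merges the two root edges into one branch
    if (all(internal[rk])) cnt <- cnt + 1L
  } else {
    # root of degree >= 3 is itself an internal vertex of the unrooted tree
    cnt <- cnt + sum(internal[rk])
  }
  list(n_tips = sum(tree$is_tip),
       n_internal_nodes = sum(internal),
       max_depth_in_nodes = maxd,
       n_internal_branches_unrooted = cnt)
}
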