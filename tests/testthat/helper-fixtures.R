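# Shared fixtures: random model instances and programmatic tree builders.

# random GTR instance: exchangeabilities ~ U(0.1, 5), Dirichlet(1,1,1,1)
# frequencies
random_gtr <- function() {
  ex <- stats::runif(6, 0.1, 5)
  f <- stats::rgamma(4, 1)
  build_model("GTR", params = ex, freqs = f / sum(f))
}

# perfectly balanced bifurcating tree with 2^depth tips, all branches `bl`
balanced_newick <- function(depth, bl = 0.05) {
  cnt <- 0L
  grow <- function(d) {
    if (d == 0L) {
      cnt <<- cnt + 1L
      paste0("T", cnt, ":", bl)
    } else {
      paste0("(", grow(d - 1L), ",", grow(d - 1L), "):", bl)
    }
  }
  body <- paste0("(", grow(depth - 1L), ",", grow(depth - 1L), ");")
  parse_newick(body)
}

# caterpillar (fully unbalanced) tree with n tips
caterpillar_newick <- function(n, bl = 0.05) {
  s <- paste0("T1:", bl)
  for (i in 2:n) s <- paste0("(", s, ",T", i, ":", bl, "):", bl)
  # outermost node is the root: strip its branch length
  s <- sub(paste0("\\):", bl, "$"), ")", s)
  parse_newick(paste0(s, ";"))
}

# rooted split sizes at the root (sorted), used as a topology statistic
root_split <- function(tree) {
  sizes <- vapply(tree$children[[tree$root]], function(ch) {
    cnt <- 0L
    stack <- ch
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (tree$is_tip[v]) cnt <- cnt + 1L
      else stack <- c(stack, tree$children[[v]])
    }
    cnt
  }, 0L)
  sort(sizes)
}
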