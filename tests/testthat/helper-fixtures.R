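# Shared fixtures and independent oracles, built in code at test time.

# Two disconnected triangles: the classic single-layer modularity toy
# (optimal two-community partition has Q = 0.5 under the Newman-Girvan null).
two_triangles <- function() {
  m <- matrix(0, 6, 6)
  edges <- rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6))
  m[edges] <- 1
  m + t(m)
}

# Random symmetric nonnegative weight matrices, zero diagonal.
random_layers <- function(n_nodes, n_layers, seed) {
  set.seed(seed)
  lapply(seq_len(n_layers), function(l) {
    m <- matrix(stats::runif(n_nodes^2, 0.05, 1), n_nodes)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    m
  })
}

# All set partitions of n items as restricted-growth label vectors
# (Bell-number enumeration); independent of the optimizer.
all_partitions <- function(n) {
  out <- vector("list", 0L)
  rec <- function(prefix, mx) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(mx + 1L)) rec(c(prefix, v), max(mx, v))
  }
  rec(integer(0), 0L)
  out
}

# Naive double-loop evaluation of the multilayer modularity quality
# function, written directly from its definition: sum over all ordered
# node-layer pairs of the intra-layer term (same layer) plus the coupling
# term (same node, adjacent layers), each gated by community agreement.
naive_modularity_Q <- function(net, part) {
  n <- net$n_nodes
  w <- net$n_layers
  total <- 0
  for (l in seq_len(w)) {
    for (r in seq_len(w)) {
      for (i in seq_len(n)) {
        for (j in seq_len(n)) {
          if (part[i, l] != part[j, r]) next
          if (l == r) {
            total <- total + net$intra[[l]][i, j] - net$gamma[l] * net$null[[l]][i, j]
          }
          if (i == j && abs(l - r) == 1L) {
            total <- total + net$omega
          }
        }
      }
    }
  }
  total / (2 * net$mu)
}

# Exhaustive-search optimum of multilayer modularity over all partitions of
# the node-layer copies (feasible up to 9 copies).
brute_force_optimum <- function(net) {
  n_copies <- net$n_nodes * net$n_layers
  parts <- all_partitions(n_copies)
  best <- -Inf
  for (g in parts) {
    q <- modularity_Q(net, matrix(g, net$n_nodes, net$n_layers))
    if (q > best) best <- q
  }
  best
}

# Best label-permutation agreement between two labelings (matching oracle
# for cluster recovery; exact over all permutations, fine for small k).
matched_agreement <- function(truth, labels, k) {
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best <- 0
  for (p in perms(seq_len(k))) {
    best <- max(best, mean(p[labels] == truth))
  }
  best
}

# Small, fully deterministic time-course fixture.
toy_timecourse <- function(T_len = 60L, n = 3L, seed = 1L, TR = 2) {
  set.seed(seed)
  x <- matrix(stats::rnorm(T_len * n), T_len, n)
  colnames(x) <- c("PCC", "LECN", "insula")[seq_len(n)]
  timecourse_set(x, TR = TR,
                 membership = c(PCC = "DMN", LECN = "ECN", insula = "SAN"),
                 subject_id = sprintf("toy%d", seed))
}
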