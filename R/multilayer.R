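# --- multilayer modularity: supra-adjacency construction, quality function,
# --- generalized Louvain optimization, allegiance and integration summaries.

as_layer_list <- function(wc) {
  if (inherits(wc, "windowed_connectivity")) {
    w_dim <- dim(wc$layers)[3L]
    return(lapply(seq_len(w_dim), function(l) wc$layers[, , l]))
  }
  if (is.list(wc) && all(vapply(wc, is.matrix, logical(1L)))) return(wc)
  stopf("'wc' must be a windowed_connectivity object or a list of matrices")
}

#' Build a multilayer network from windowed connectivity
#'
#' Each window becomes one layer: intra-layer edge weights are the window's
#' connectivity values after applying the negative-weight policy
#' (\code{clip_zero} discards negative correlations, \code{absolute} takes
#' magnitudes); copies of the same node in temporally adjacent layers are
#' joined by coupling edges of weight \code{omega} (ordinal coupling). The
#' per-layer null model is Newman-Girvan:
#' \code{P[i,j] = k_i k_j / (2 m_l)} with node strengths k and total layer
#' weight m_l.
#'
#' @param wc a \code{\link{windowed_connectivity}} object, or a plain list of
#'   symmetric nonnegative weight matrices (one per layer).
#' @param omega inter-layer coupling weight (>= 0, default 1).
#' @param gamma resolution parameter, scalar or per-layer vector (default 1).
#' @param negative_policy how to map signed connectivity to weights:
#'   \code{"clip_zero"} (default) or \code{"absolute"}.
#' @return object of class \code{multilayer_network}: list with \code{intra}
#'   (list of layer weight matrices), \code{null} (Newman-Girvan matrices),
#'   \code{gamma} (per layer), \code{omega}, \code{mu} (normalization: total
#'   intra-layer strength halved plus total coupling weight),
#'   \code{node_labels}, \code{membership}, \code{n_nodes}, \code{n_layers},
#'   \code{negative_policy}.
#' @export
build_supra <- function(wc, omega = 1, gamma = 1,
                        negative_policy = c("clip_zero", "absolute")) {
  negative_policy <- match.arg(negative_policy)
  layers <- as_layer_list(wc)
  n_layers <- length(layers)
  if (n_layers < 1L) stopf("need at least 1 layer")
  if (!is_number(omega) || omega < 0) stopf("'omega' must be >= 0")
  n <- nrow(layers[[1L]])
  gamma <- rep_len(gamma, n_layers)
  intra <- vector("list", n_layers)
  null <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    a <- layers[[l]]
    if (nrow(a) != n || ncol(a) != n) stopf("layer %d has inconsistent dimensions", l)
    a <- (a + t(a)) / 2
    a <- switch(negative_policy, clip_zero = pmax(a, 0), absolute = abs(a))
    diag(a) <- 0
    total <- sum(a) / 2
    if (total <= 0) stopf("layer %d has total weight 0", l)
    strength <- rowSums(a)
    intra[[l]] <- a
    null[[l]] <- tcrossprod(strength) / (2 * total)
  }
  mu <- sum(vapply(intra, sum, numeric(1L))) / 2 + omega * n * (n_layers - 1L)
  labels <- rownames(layers[[1L]]) %||% paste0("node", seq_len(n))
  membership <- if (inherits(wc, "windowed_connectivity")) wc$membership else NULL
  structure(list(intra = intra, null = null, gamma = gamma, omega = omega,
                 mu = mu, node_labels = labels, membership = membership,
                 n_nodes = n, n_layers = n_layers,
                 negative_policy = negative_policy),
            class = "multilayer_network")
}

#' @export
print.multilayer_network <- function(x, ...) {
  cat(sprintf(
    "<multilayer_network> %d nodes x %d layers, omega = %g, gamma = %g, mu = %.4g (%s)\n",
    x$n_nodes, x$n_layers, x$omega, x$gamma[1L], x$mu, x$negative_policy))
  invisible(x)
}

# Dense supra modularity matrix B[(l-1)N+i, (r-1)N+j]:
#   same layer: A_ijl - gamma_l P_ijl; adjacent layers, same node: omega.
modularity_matrix <- function(net) {
  n <- net$n_nodes
  w <- net$n_layers
  b <- matrix(0, n * w, n * w)
  for (l in seq_len(w)) {
    idx <- (l - 1L) * n + seq_len(n)
    b[idx, idx] <- net$intra[[l]] - net$gamma[l] * net$null[[l]]
    if (l < w && net$omega > 0) {
      nxt <- l * n + seq_len(n)
      b[cbind(idx, nxt)] <- b[cbind(idx, nxt)] + net$omega
      b[cbind(nxt, idx)] <- b[cbind(nxt, idx)] + net$omega
    }
  }
  b
}

check_partition <- function(net, part) {
  part <- as.matrix(part)
  if (nrow(part) != net$n_nodes || ncol(part) != net$n_layers) {
    stopf("partition is %d x %d but the network has %d nodes x %d layers",
          nrow(part), ncol(part), net$n_nodes, net$n_layers)
  }
  if (any(part < 1) || any(part != round(part))) stopf("community labels must be positive integers")
  part
}

#' Multilayer modularity of a partition
#'
#' Evaluates the multilayer modularity quality function: the sum over
#' same-layer node pairs sharing a community of the intra-layer weight minus
#' the resolution-scaled null expectation, plus the coupling weight for every
#' same-node adjacent-layer pair sharing a community, normalized by twice the
#' total strength \code{mu}.
#'
#' @param net a \code{\link{build_supra}} network.
#' @param part N x W integer matrix of community labels (node i, layer l).
#' @return modularity Q (numeric scalar).
#' @export
modularity_Q <- function(net, part) {
  part <- check_partition(net, part)
  total <- 0
  for (l in seq_len(net$n_layers)) {
    same <- outer(part[, l], part[, l], "==")
    total <- total + sum((net$intra[[l]] - net$gamma[l] * net$null[[l]]) * same)
  }
  if (net$n_layers > 1L && net$omega > 0) {
    agree <- part[, -net$n_layers, drop = FALSE] == part[, -1L, drop = FALSE]
    total <- total + 2 * net$omega * sum(agree)
  }
  total / (2 * net$mu)
}

# One Louvain pass over a (possibly aggregated) modularity matrix: greedy
# node sweeps in seeded random order until no single move improves the
# quality; returns consecutive labels and whether anything moved.
louvain_phase1 <- function(b, tol = 1e-10) {
  n <- nrow(b)
  labels <- seq_len(n)
  moved_any <- FALSE
  repeat {
    moved <- FALSE
    for (i in sample.int(n)) {
      bi <- b[i, ]
      comm_sums <- vapply(split(bi, labels), sum, numeric(1L))
      cur <- as.character(labels[i])
      stay <- comm_sums[[cur]] - b[i, i]
      comm_sums[[cur]] <- -Inf  # candidate moves exclude the current community
      best <- which.max(comm_sums)
      if (comm_sums[[best]] > stay + tol) {
        labels[i] <- as.integer(names(comm_sums)[best])
        moved <- TRUE
        moved_any <- TRUE
      }
    }
    if (!moved) break
  }
  list(labels = match(labels, unique(labels)), moved = moved_any)
}

#' Generalized Louvain optimization of multilayer modularity
#'
#' Louvain-style greedy maximization over node-layer copies: phase 1 sweeps
#' copies in seeded random order, moving each to the community with the
#' largest modularity gain (> 1e-10; ties keep the current community);
#' phase 2 aggregates communities into super-nodes, preserving intra-layer
#' and coupling structure; the two phases repeat until no improving move
#' exists. Q is non-decreasing across phases.
#'
#' @param net a \code{\link{build_supra}} network.
#' @param seed integer seed controlling the sweep order.
#' @return list of class \code{multilayer_partition}: \code{partition}
#'   (N x W integer matrix, consecutive labels), \code{Q}, \code{seed}.
#' @export
genlouvain_optimize <- function(net, seed = 1L) {
  stopifnot(inherits(net, "multilayer_network"))
  b <- modularity_matrix(net)
  n_total <- nrow(b)
  q_of <- function(map) {
    part <- matrix(map, nrow = net$n_nodes, ncol = net$n_layers)
    modularity_Q(net, part)
  }
  node_map <- with_seed(seed, {
    map <- seq_len(n_total)
    level_b <- b
    q_prev <- -Inf
    repeat {
      ph <- louvain_phase1(level_b)
      if (!ph$moved) break
      map <- ph$labels[map]
      q_now <- q_of(map)
      if (q_now < q_prev - 1e-9) {
        stopf("internal error: modularity decreased across Louvain phases")
      }
      q_prev <- q_now
      # phase 2: aggregate communities into super-nodes (both dimensions)
      level_b <- rowsum(t(rowsum(t(level_b), ph$labels)), ph$labels)
    }
    map
  })
  part <- matrix(match(node_map, unique(node_map)),
                 nrow = net$n_nodes, ncol = net$n_layers)
  rownames(part) <- net$node_labels
  q_final <- modularity_Q(net, part)
  structure(list(partition = part, Q = q_final, seed = as.integer(seed)),
            class = "multilayer_partition")
}

#' @export
print.multilayer_partition <- function(x, ...) {
  cat(sprintf("<multilayer_partition> %d communities, Q = %.4f\n",
              length(unique(as.vector(x$partition))), x$Q))
  invisible(x)
}

#' Ensemble of Louvain runs
#'
#' Runs \code{\link{genlouvain_optimize}} \code{n_runs} times with distinct
#' seeds; downstream summaries (allegiance, integration, Q) average over the
#' ensemble to absorb the optimizer's run-to-run variability.
#'
#' @param net a \code{\link{build_supra}} network.
#' @param n_runs number of optimizer runs (default 50).
#' @param base_seed integer; run r uses a seed derived from it.
#' @return object of class \code{partition_ensemble}: \code{partitions}
#'   (list of N x W matrices), \code{Q_values}, \code{seeds}.
#' @export
run_ensemble <- function(net, n_runs = 50L, base_seed = 1L) {
  if (!is_count(n_runs)) stopf("'n_runs' must be a positive integer")
  seeds <- vapply(seq_len(n_runs), function(r) derive_seed(base_seed, r), numeric(1L))
  runs <- lapply(seeds, function(s) genlouvain_optimize(net, seed = s))
  structure(list(partitions = lapply(runs, `[[`, "partition"),
                 Q_values = vapply(runs, `[[`, numeric(1L), "Q"),
                 seeds = as.integer(seeds)),
            class = "partition_ensemble")
}

#' @export
print.partition_ensemble <- function(x, ...) {
  cat(sprintf("<partition_ensemble> %d runs, mean Q = %.4f (sd %.4f)\n",
              length(x$partitions), mean(x$Q_values), stats::sd(x$Q_values)))
  invisible(x)
}

#' Module allegiance matrix
#'
#' \code{P[i,j]} is the relative frequency, over all optimizer runs and all
#' layers, with which nodes i and j are assigned to the same community.
#'
#' @param ens a \code{\link{run_ensemble}} result (or a single
#'   \code{multilayer_partition}).
#' @return N x N symmetric matrix with unit diagonal and entries in [0, 1].
#' @export
module_allegiance <- function(ens) {
  parts <- if (inherits(ens, "multilayer_partition")) {
    list(ens$partition)
  } else if (inherits(ens, "partition_ensemble")) {
    ens$partitions
  } else {
    stopf("'ens' must be a partition_ensemble or multilayer_partition")
  }
  if (!length(parts)) stopf("empty ensemble")
  n <- nrow(parts[[1L]])
  acc <- matrix(0, n, n)
  n_slices <- 0L
  for (g in parts) {
    for (l in seq_len(ncol(g))) {
      acc <- acc + outer(g[, l], g[, l], "==")
      n_slices <- n_slices + 1L
    }
  }
  p <- acc / n_slices
  dimnames(p) <- list(rownames(parts[[1L]]), rownames(parts[[1L]]))
  diag(p) <- 1
  p
}

#' Integration coefficients from a module allegiance matrix
#'
#' Node-level integration is the mean allegiance between a node and all
#' nodes of other networks; network-level integration averages node-level
#' values within each network; network-pair integration is the mean
#' allegiance between the two networks' nodes.
#'
#' @param p allegiance matrix (\code{\link{module_allegiance}}).
#' @param membership named node-to-network map covering all rows of \code{p}.
#' @param Q optional ensemble-mean modularity to carry along.
#' @return object of class \code{integration_summary}: \code{node_integration}
#'   (named, length N), \code{rsn_integration} (one per network),
#'   \code{rsn_pair_integration} (one per unordered network pair, named
#'   "X-Y") and \code{modularity_Q}.
#' @export
integration <- function(p, membership, Q = NA_real_) {
  n <- nrow(p)
  labels <- rownames(p) %||% names(membership)
  if (is.null(labels) || !all(labels %in% names(membership))) {
    stopf("membership map does not cover all nodes of the allegiance matrix")
  }
  nets <- membership[labels]
  net_names <- unique(nets)
  if (length(net_names) < 2L) stopf("need at least 2 networks")
  for (nm in net_names) if (!sum(nets == nm)) stopf("network '%s' has no nodes", nm)
  node_int <- vapply(seq_len(n), function(i) {
    others <- which(nets != nets[i])
    mean(p[i, others])
  }, numeric(1L))
  names(node_int) <- labels
  rsn_int <- vapply(net_names, function(nm) mean(node_int[nets == nm]), numeric(1L))
  pair_names <- as.character(utils::combn(net_names, 2L, paste, collapse = "-"))
  pair_int <- as.numeric(utils::combn(net_names, 2L, function(pr) {
    mean(p[nets == pr[1L], nets == pr[2L], drop = FALSE])
  }))
  names(pair_int) <- pair_names
  structure(list(node_integration = node_int, rsn_integration = rsn_int,
                 rsn_pair_integration = pair_int, modularity_Q = Q),
            class = "integration_summary")
}

#' @export
print.integration_summary <- function(x, ...) {
  cat("<integration_summary>\n")
  cat("  node:    ", paste(sprintf("%s=%.3f", names(x$node_integration),
                                   x$node_integration), collapse = " "), "\n")
  cat("  network: ", paste(sprintf("%s=%.3f", names(x$rsn_integration),
                                   x$rsn_integration), collapse = " "), "\n")
  cat("  pairs:   ", paste(sprintf("%s=%.3f", names(x$rsn_pair_integration),
                                   x$rsn_pair_integration), collapse = " "), "\n")
  if (!is.na(x$modularity_Q)) cat(sprintf("  Q:        %.4f\n", x$modularity_Q))
  invisible(x)
}
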