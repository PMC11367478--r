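#' Build a block-structured target correlation matrix
#'
#' Helper for describing latent connectivity states: starts from a constant
#' baseline off-diagonal correlation and overwrites selected blocks, where a
#' block is the set of edges between two groups of nodes. Groups may be given
#' as network names (resolved through \code{membership}) or as node labels.
#'
#' @param membership named character vector mapping node labels to networks.
#' @param base baseline off-diagonal target correlation.
#' @param blocks list of \code{list(a =, b =, r =)} entries: all edges between
#'   node set \code{a} and node set \code{b} get target \code{r}. \code{a == b}
#'   sets a within-group block.
#' @return N x N symmetric matrix of target correlations with unit diagonal.
#' @export
block_target_matrix <- function(membership, base = 0.05, blocks = list()) {
  nodes <- names(membership)
  n <- length(nodes)
  m <- matrix(base, n, n, dimnames = list(nodes, nodes))
  resolve <- function(g) {
    hits <- nodes[membership %in% g]
    unique(c(hits, intersect(g, nodes)))
  }
  for (b in blocks) {
    a <- resolve(b$a); bb <- resolve(b$b)
    if (!length(a) || !length(bb)) stopf("block refers to unknown nodes/networks")
    m[a, bb] <- b$r
    m[bb, a] <- b$r
  }
  diag(m) <- 1
  m
}

#' Default four-state connectivity templates
#'
#' The four latent states the synthetic generator switches among, chosen to
#' emulate the canonical recurring connectivity profiles of the triple-network
#' model: a sparse state; a state with strong coupling within and between the
#' default-mode and executive-control networks; a globally positive state; and
#' a state coupling the default-mode network with the left executive-control
#' node.
#'
#' @param membership node-to-network map; defaults to
#'   \code{\link{triple_network_membership}}.
#' @return list of per-state target descriptions, each
#'   \code{list(state_id, description, targets)} with \code{targets} an
#'   N x N target correlation matrix.
#' @export
default_state_specs <- function(membership = triple_network_membership()) {
  list(
    list(state_id = 1L, description = "sparse connectivity within and between all networks",
         targets = block_target_matrix(membership, base = 0.02,
           blocks = list(list(a = "DMN", b = "DMN", r = 0.05),
                         list(a = "ECN", b = "ECN", r = 0.05),
                         list(a = "SAN", b = "SAN", r = 0.05)))),
    list(state_id = 2L, description = "strong coupling within and between DMN and ECN",
         targets = block_target_matrix(membership, base = 0.02,
           blocks = list(list(a = "DMN", b = "DMN", r = 0.70),
                         list(a = "ECN", b = "ECN", r = 0.70),
                         list(a = "DMN", b = "ECN", r = 0.70),
                         list(a = "SAN", b = "SAN", r = 0.05)))),
    list(state_id = 3L, description = "tightly positive connectivity everywhere",
         targets = block_target_matrix(membership, base = 0.60)),
    list(state_id = 4L, description = paste(
           "DMN tightly coupled with the left ECN node,",
           "mildly anticorrelated with the remaining nodes"),
         targets = block_target_matrix(membership, base = -0.30,
           blocks = list(list(a = "DMN", b = "DMN", r = 0.70),
                         list(a = "DMN", b = "LECN", r = 0.70),
                         list(a = "SAN", b = "SAN", r = 0.05))))
  )
}

# Eigenvalue clipping + unit-diagonal renormalization; idempotent once SPD.
spd_repair_once <- function(m, floor_eig = 1e-6) {
  e <- eigen(m, symmetric = TRUE)
  vals <- pmax(e$values, floor_eig)
  m2 <- e$vectors %*% (vals * t(e$vectors))
  m2 <- (m2 + t(m2)) / 2
  d <- sqrt(diag(m2))
  m2 <- m2 / tcrossprod(d)
  diag(m2) <- 1
  dimnames(m2) <- dimnames(m)
  m2
}

#' Construct SPD state covariance matrices from block targets
#'
#' Turns per-state target correlation matrices into valid (symmetric
#' positive-definite, unit-diagonal) state covariances by repeated eigenvalue
#' clipping at 1e-6 followed by renormalization to unit diagonal, up to 100
#' repair steps.
#'
#' @param n_nodes number of nodes N.
#' @param membership node-to-network map covering all nodes.
#' @param specs list of state descriptions as returned by
#'   \code{\link{default_state_specs}}; each entry needs \code{state_id},
#'   \code{targets} (N x N) and optionally \code{description}.
#' @return list of \code{state_spec} objects, each with \code{state_id},
#'   \code{covariance} (SPD, unit diagonal) and \code{description}.
#' @examples
#' sp <- make_state_covariances(7, triple_network_membership(),
#'                              default_state_specs())
#' sapply(sp, function(s) min(eigen(s$covariance)$values))
#' @export
make_state_covariances <- function(n_nodes, membership,
                                   specs = default_state_specs(membership)) {
  if (!is_count(n_nodes, min = 2L)) stopf("'n_nodes' must be an integer >= 2")
  if (length(membership) != n_nodes) {
    stopf("membership must map all %d nodes", n_nodes)
  }
  lapply(specs, function(sp) {
    m <- sp$targets
    if (!is.matrix(m) || any(dim(m) != n_nodes)) {
      stopf("state %s: targets must be a %d x %d matrix", sp$state_id, n_nodes, n_nodes)
    }
    m <- (m + t(m)) / 2
    diag(m) <- 1
    ok <- FALSE
    for (i in seq_len(100L)) {
      if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) >= 1e-6) {
        ok <- TRUE
        break
      }
      m <- spd_repair_once(m)
    }
    if (!ok && min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) < 1e-6) {
      stopf("state %s: block targets not repairable to SPD within 100 steps", sp$state_id)
    }
    structure(list(state_id = sp$state_id, covariance = m,
                   description = sp$description %||% ""),
              class = "state_spec")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Markov transition matrix for a target stationary occupancy
#'
#' Builds the k x k transition matrix whose stationary distribution equals
#' \code{occupancy} exactly and whose expected run length (aggregated over
#' states) equals \code{mean_dwell}: off-diagonal entries are proportional to
#' the target occupancies, \code{T[s,t] = a * occupancy[t]} with
#' \code{a = 1 / (mean_dwell * sum(occupancy * (1 - occupancy)))}.
#'
#' @param occupancy probability vector over states (sums to 1).
#' @param mean_dwell target mean run length in windows (>= 1).
#' @return k x k row-stochastic matrix.
#' @keywords internal
markov_transition_matrix <- function(occupancy, mean_dwell) {
  k <- length(occupancy)
  if (k == 1L) return(matrix(1, 1, 1))
  a <- 1 / (mean_dwell * sum(occupancy * (1 - occupancy)))
  tm <- outer(rep(a, k), occupancy)
  diag(tm) <- 1 - a * (1 - occupancy)
  if (any(diag(tm) < -1e-12)) {
    stopf("mean_dwell = %g is too small for these occupancies (self-transition < 0)",
          mean_dwell)
  }
  diag(tm) <- pmax(diag(tm), 0)
  tm / rowSums(tm)
}

validate_sequence_params <- function(params) {
  occ <- params$occupancy
  if (is.null(occ) || length(occ) == 0L) stopf("occupancy must be a nonempty probability vector")
  if (any(occ < 0) || any(occ > 1)) stopf("occupancy entries must lie in [0, 1]")
  if (abs(sum(occ) - 1) > 1e-12) stopf("occupancy must sum to 1 (got %.15f)", sum(occ))
  if (!is_number(params$mean_dwell) || params$mean_dwell < 1) stopf("mean_dwell must be >= 1")
  if (!is_count(params$n_windows)) stopf("n_windows must be a positive integer")
  invisible(params)
}

#' Parameters of the latent state sequence
#'
#' @param occupancy target stationary probability of each state; sums to 1.
#' @param mean_dwell target mean run length in windows (>= 1). A value of 1
#'   means the chain switches state at every window.
#' @param n_windows length of the sequence to generate.
#' @param seed integer seed.
#' @return list of class \code{sequence_params}.
#' @export
sequence_params <- function(occupancy = c(0.42, 0.19, 0.22, 0.17),
                            mean_dwell = 50, n_windows = 148, seed = 1L) {
  p <- structure(list(occupancy = occupancy, mean_dwell = mean_dwell,
                      n_windows = as.integer(n_windows), seed = as.integer(seed)),
                 class = "sequence_params")
  validate_sequence_params(p)
  p
}

#' Simulate a latent state sequence
#'
#' Draws a first-order Markov chain whose stationary distribution equals the
#' target occupancy exactly (the initial state is drawn from it) and whose
#' mean run length matches \code{mean_dwell}; see
#' \code{\link{markov_transition_matrix}}.
#'
#' @param params a \code{\link{sequence_params}} object.
#' @return integer vector of state labels in \code{1..k}.
#' @examples
#' s <- simulate_state_sequence(sequence_params(c(.5, .5), mean_dwell = 5,
#'                                              n_windows = 50, seed = 1))
#' table(s)
#' @export
simulate_state_sequence <- function(params) {
  validate_sequence_params(params)
  occ <- params$occupancy
  k <- length(occ)
  n <- params$n_windows
  if (k == 1L) return(rep(1L, n))
  tm <- markov_transition_matrix(occ, params$mean_dwell)
  with_seed(params$seed, {
    s <- integer(n)
    s[1L] <- sample.int(k, 1L, prob = occ)
    for (w in seq_len(n - 1L)) {
      s[w + 1L] <- sample.int(k, 1L, prob = tm[s[w], ])
    }
    s
  })
}

#' Simulate state-switching node time courses
#'
#' Each subject gets an independent latent state sequence at window
#' granularity; time point t takes the state of window \code{min(t, n_windows)}
#' (so with \code{n_windows = T - L + 1} each window's defining index is its
#' first time point). Observations are zero-mean Gaussian draws with the
#' active state's covariance plus independent observation noise.
#'
#' @param n_subjects number of subjects.
#' @param T_len time points per subject.
#' @param TR repetition time in seconds.
#' @param states list of \code{state_spec} objects
#'   (\code{\link{make_state_covariances}}).
#' @param seq_params \code{\link{sequence_params}}; its \code{n_windows} must
#'   not exceed \code{T_len} and its seed is combined per subject with
#'   \code{seed}.
#' @param obs_noise_sd standard deviation of additive white observation noise.
#' @param seed integer master seed; the run is deterministic given it.
#' @param membership node-to-network map; defaults to the seven-node
#'   triple-network layout.
#' @return list of \code{\link{timecourse_set}} objects; each carries its
#'   ground-truth window state sequence as attribute \code{"state_sequence"}.
#' @examples
#' st <- make_state_covariances(7, triple_network_membership())
#' tcs <- simulate_timecourses(2, T_len = 60, TR = 2, states = st,
#'                             seq_params = sequence_params(n_windows = 39),
#'                             seed = 1)
#' dim(tcs[[1]])
#' @export
simulate_timecourses <- function(n_subjects, T_len = 169L, TR = 2,
                                 states,
                                 seq_params = sequence_params(n_windows = T_len - 21L),
                                 obs_noise_sd = 0.2, seed = 1L,
                                 membership = triple_network_membership()) {
  if (!is_count(n_subjects)) stopf("'n_subjects' must be a positive integer")
  if (!length(states)) stopf("'states' must be a nonempty list of state specs")
  if (!is_number(obs_noise_sd) || obs_noise_sd < 0) stopf("'obs_noise_sd' must be >= 0")
  validate_sequence_params(seq_params)
  if (seq_params$n_windows > T_len) {
    stopf("n_windows (%d) exceeds the number of time points (%d)",
          seq_params$n_windows, T_len)
  }
  n_nodes <- length(membership)
  chols <- lapply(states, function(s) {
    cv <- s$covariance
    if (any(dim(cv) != n_nodes)) stopf("state %s covariance is not %d x %d",
                                       s$state_id, n_nodes, n_nodes)
    ch <- tryCatch(chol(cv), error = function(e)
      stopf("state %s covariance is not positive definite", s$state_id))
    ch
  })
  k <- length(states)
  W <- seq_params$n_windows
  lapply(seq_len(n_subjects), function(i) {
    sp <- seq_params
    sp$seed <- derive_seed(seed, i)
    s_seq <- simulate_state_sequence(sp)
    if (max(s_seq) > k) stopf("state sequence refers to undefined states")
    state_at_t <- s_seq[pmin(seq_len(T_len), W)]
    x <- with_seed(derive_seed(seed, i + n_subjects), {
      z <- matrix(stats::rnorm(T_len * n_nodes), T_len, n_nodes)
      out <- matrix(0, T_len, n_nodes)
      for (s in seq_len(k)) {
        rows <- which(state_at_t == s)
        if (length(rows)) out[rows, ] <- z[rows, , drop = FALSE] %*% chols[[s]]
      }
      if (obs_noise_sd > 0) {
        out <- out + obs_noise_sd * matrix(stats::rnorm(T_len * n_nodes), T_len, n_nodes)
      }
      out
    })
    colnames(x) <- names(membership)
    tc <- timecourse_set(x, TR = TR, membership = membership,
                         subject_id = sprintf("sub%03d", i))
    attr(tc, "state_sequence") <- s_seq
    tc
  })
}

#' Specification of a synthetic cohort
#'
#' Describes group sizes, covariate distributions, derived connectivity
#' measures with additive group effects, and behavior scores linked linearly
#' to measures — the structure needed to exercise the group-comparison and
#' brain-behavior stages with known ground truth.
#'
#' @param group_sizes named integer vector, e.g.
#'   \code{c(CI_L = 62, CI_R = 56, HC = 57)}; all entries >= 2.
#' @param covariates named list; each entry either
#'   \code{list(mean =, sd =)} (Gaussian) or \code{list(prob =)} (binary 0/1).
#' @param measures named list of \code{list(mean =, sd =)} baselines for the
#'   derived measures (e.g. one entry per connectivity edge), \code{sd > 0}.
#' @param effect_sizes data.frame with columns \code{measure}, \code{group},
#'   \code{shift}: additive shift applied to that measure in that group.
#' @param behavior_links data.frame with columns \code{behavior},
#'   \code{measure}, \code{intercept}, \code{slope}, \code{noise_sd}
#'   (\code{noise_sd > 0}): behavior = intercept + slope * measure + noise.
#' @param seed integer seed.
#' @return list of class \code{cohort_spec}.
#' @export
cohort_spec <- function(group_sizes = c(CI_L = 62L, CI_R = 56L, HC = 57L),
                        covariates = list(
                          age = list(mean = 55, sd = 8.4),
                          sex = list(prob = 0.63),
                          education = list(mean = 9.7, sd = 3.3),
                          mean_FD = list(mean = 0.16, sd = 0.05)),
                        measures = list(),
                        effect_sizes = NULL,
                        behavior_links = NULL,
                        seed = 1L) {
  if (is.null(names(group_sizes)) || any(group_sizes < 2)) {
    stopf("'group_sizes' must be a named vector with all entries >= 2")
  }
  if (!is.null(behavior_links) && any(behavior_links$noise_sd <= 0)) {
    stopf("behavior link noise sd must be > 0")
  }
  for (nm in names(measures)) {
    if (!is.null(measures[[nm]]$sd) && measures[[nm]]$sd <= 0) {
      stopf("measure '%s' must have sd > 0", nm)
    }
  }
  structure(list(group_sizes = group_sizes, covariates = covariates,
                 measures = measures, effect_sizes = effect_sizes,
                 behavior_links = behavior_links, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a cohort table with known ground truth
#'
#' Draws per-subject group labels, covariates, derived measures (with the
#' additive group shifts from \code{effect_sizes}) and behavior scores
#' (linear in their linked measure plus Gaussian noise). Optionally attaches
#' simulated node time courses per subject.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @param timecourses if \code{TRUE}, also simulate a
#'   \code{\link{timecourse_set}} per subject (states/geometry from
#'   \code{...} arguments of \code{\link{simulate_timecourses}} defaults).
#' @param ... passed to \code{\link{simulate_timecourses}} when
#'   \code{timecourses = TRUE}.
#' @return list with \code{cohort} (data.frame: subject_id, group, covariates,
#'   measures, behaviors), \code{timecourses} (list or NULL) and
#'   \code{ground_truth} (effect sizes, links, seed).
#' @examples
#' sp <- cohort_spec(group_sizes = c(A = 5, B = 5),
#'                   measures = list(edge1 = list(mean = 0.3, sd = 0.2)),
#'                   effect_sizes = data.frame(measure = "edge1", group = "B",
#'                                             shift = 0.5))
#' head(simulate_cohort(sp)$cohort)
#' @export
simulate_cohort <- function(spec, timecourses = FALSE, ...) {
  if (!inherits(spec, "cohort_spec")) stopf("'spec' must be a cohort_spec")
  gs <- spec$group_sizes
  if (any(gs < 1)) stopf("empty group in cohort spec")
  n <- sum(gs)
  group <- rep(names(gs), gs)
  cohort <- with_seed(spec$seed, {
    df <- data.frame(subject_id = sprintf("sub%03d", seq_len(n)),
                     group = group, stringsAsFactors = FALSE)
    for (nm in names(spec$covariates)) {
      cv <- spec$covariates[[nm]]
      df[[nm]] <- if (!is.null(cv$prob)) {
        stats::rbinom(n, 1L, cv$prob)
      } else {
        stats::rnorm(n, cv$mean, cv$sd)
      }
    }
    for (nm in names(spec$measures)) {
      ms <- spec$measures[[nm]]
      x <- stats::rnorm(n, ms$mean, ms$sd)
      es <- spec$effect_sizes
      if (!is.null(es)) {
        for (r in which(es$measure == nm)) {
          x[df$group == es$group[r]] <- x[df$group == es$group[r]] + es$shift[r]
        }
      }
      df[[nm]] <- x
    }
    bl <- spec$behavior_links
    if (!is.null(bl)) {
      for (r in seq_len(nrow(bl))) {
        mz <- df[[bl$measure[r]]]
        if (is.null(mz)) stopf("behavior link refers to unknown measure '%s'", bl$measure[r])
        df[[bl$behavior[r]]] <- bl$intercept[r] + bl$slope[r] * mz +
          stats::rnorm(n, 0, bl$noise_sd[r])
      }
    }
    df
  })
  tcs <- NULL
  if (isTRUE(timecourses)) {
    tcs <- simulate_timecourses(n_subjects = n, seed = derive_seed(spec$seed, 999L), ...)
    for (i in seq_len(n)) tcs[[i]]$subject_id <- cohort$subject_id[i]
  }
  list(cohort = cohort, timecourses = tcs,
       ground_truth = list(effect_sizes = spec$effect_sizes,
                           behavior_links = spec$behavior_links,
                           seed = spec$seed))
}
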