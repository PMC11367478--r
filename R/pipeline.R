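#' Pipeline configuration
#'
#' Collects every tunable of the analysis with the pipeline's standard
#' defaults: 22-TR windows tapered by a sigma = 3 TR Gaussian in
#' steps of 1 TR; k-means with 500 iterations and 150 replicates (elbow
#' search over k = 2..10 with 20 replicates per candidate); multilayer
#' resolution gamma = 1, ordinal coupling omega = 1, negative weights
#' clipped to zero, 50 Louvain runs; FDR alpha 0.05; low-pass cutoff 0.15 Hz
#' and cubic detrending in post-processing.
#'
#' @param window_length window length in TRs.
#' @param sigma taper Gaussian sd in TRs.
#' @param step window step in TRs.
#' @param lowpass_hz low-pass cutoff in Hz.
#' @param detrend_order polynomial detrending degree.
#' @param despike_z despiking robust-z threshold.
#' @param k fixed number of states; \code{NULL} selects k by the elbow
#'   criterion over \code{k_range}.
#' @param k_range candidate k grid for the elbow search.
#' @param kmeans_iter,kmeans_replicates k-means iteration cap and restarts.
#' @param elbow_replicates k-means restarts per elbow candidate.
#' @param gamma,omega multilayer resolution and interlayer coupling.
#' @param negative_policy "clip_zero" or "absolute".
#' @param n_louvain_runs optimizer runs per subject.
#' @param fdr_alpha FDR-corrected significance level.
#' @param seed master seed for all stochastic stages.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(window_length = 22L, sigma = 3, step = 1L,
                            lowpass_hz = 0.15, detrend_order = 3L,
                            despike_z = 3, k = NULL, k_range = 2:10,
                            kmeans_iter = 500L, kmeans_replicates = 150L,
                            elbow_replicates = 20L, gamma = 1, omega = 1,
                            negative_policy = c("clip_zero", "absolute"),
                            n_louvain_runs = 50L, fdr_alpha = 0.05,
                            seed = 1L) {
  cfg <- list(window_length = as.integer(window_length), sigma = sigma,
              step = as.integer(step), lowpass_hz = lowpass_hz,
              detrend_order = as.integer(detrend_order), despike_z = despike_z,
              k = if (is.null(k)) NULL else as.integer(k),
              k_range = as.integer(k_range),
              kmeans_iter = as.integer(kmeans_iter),
              kmeans_replicates = as.integer(kmeans_replicates),
              elbow_replicates = as.integer(elbow_replicates),
              gamma = gamma, omega = omega,
              negative_policy = match.arg(negative_policy),
              n_louvain_runs = as.integer(n_louvain_runs),
              fdr_alpha = fdr_alpha, seed = as.integer(seed))
  if (cfg$window_length < 2L || cfg$step < 1L || cfg$sigma <= 0) {
    stopf("invalid window parameters")
  }
  if (cfg$fdr_alpha <= 0 || cfg$fdr_alpha >= 1) stopf("fdr_alpha must be in (0, 1)")
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  flat <- x[!vapply(x, is.null, logical(1L))]
  for (nm in names(flat)) {
    cat(sprintf("  %-18s %s\n", nm, paste(flat[[nm]], collapse = " ")))
  }
  invisible(x)
}

run_stage <- function(stage, subject_id = NULL, expr) {
  tryCatch(expr, error = function(e) {
    who <- if (is.null(subject_id)) "" else sprintf(" (subject %s)", subject_id)
    stopf("pipeline stage '%s'%s failed: %s", stage, who, conditionMessage(e))
  })
}

#' Run the full static/dynamic connectivity pipeline
#'
#' Executes every stage in order: time-course post-processing, static FNC,
#' tapered sliding-window dynamic FNC, k-means state analysis (with elbow
#' k selection when no k is fixed) and temporal statistics, multilayer
#' community detection with allegiance/integration/modularity summaries,
#' then GLM group comparisons with covariates, family-wise
#' Benjamini-Hochberg FDR and brain-behavior correlations.
#'
#' @param timecourses list of \code{\link{timecourse_set}} objects, one per
#'   subject, in the order of \code{cohort} rows (matched by subject id).
#' @param cohort data.frame with \code{subject_id}, \code{group}, the
#'   covariates used for adjustment and any behavior columns.
#' @param config a \code{\link{pipeline_config}}.
#' @param nuisance optional named list: subject id -> T x M nuisance
#'   regressor matrix.
#' @param covariate_cols covariate column names present in \code{cohort}
#'   (default: whichever of age, sex, education, mean_FD exist).
#' @param behavior_cols behavior score columns for the correlation stage
#'   (default: none).
#' @param contrasts list of length-2 character vectors \code{c(ref, test)};
#'   default: every non-HC group against HC (t > 0 means higher in the test
#'   group).
#' @param output_dir optional directory; when given, result tables are
#'   written as CSV and provenance as JSON.
#' @return object of class \code{triplenet_result}: list with
#'   \code{measures} (per-subject measure table), \code{comparisons}
#'   (measure x contrast GLM table with t, p, p_fdr, family),
#'   \code{correlations} (brain-behavior table), \code{state_model},
#'   \code{elbow} (or NULL), \code{provenance}.
#' @export
run_pipeline <- function(timecourses, cohort, config = pipeline_config(),
                         nuisance = NULL, covariate_cols = NULL,
                         behavior_cols = character(), contrasts = NULL,
                         output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  ids <- vapply(timecourses, function(tc) tc$subject_id, character(1L))
  if (!all(cohort$subject_id %in% ids) || !all(ids %in% cohort$subject_id)) {
    stopf("subject ids in 'cohort' and 'timecourses' do not match")
  }
  timecourses <- timecourses[match(cohort$subject_id, ids)]
  n_sub <- length(timecourses)
  membership <- timecourses[[1L]]$membership
  node_labels <- timecourses[[1L]]$node_labels
  n_nodes <- length(node_labels)

  # 1. post-processing
  post <- lapply(timecourses, function(tc) {
    run_stage("postprocess", tc$subject_id,
              postprocess_timecourses(tc,
                nuisance = nuisance[[tc$subject_id]],
                detrend_order = config$detrend_order,
                cutoff_hz = config$lowpass_hz,
                z_thresh = config$despike_z))
  })

  # 2. static FNC
  sfnc_edges <- t(vapply(post, function(tc) {
    run_stage("sfnc", tc$subject_id, upper_vec(compute_sfnc(tc)))
  }, numeric(n_nodes * (n_nodes - 1L) / 2L)))
  colnames(sfnc_edges) <- paste0("sfnc_", edge_labels(node_labels))

  # 3. dynamic FNC
  wcs <- lapply(post, function(tc) {
    run_stage("dfnc", tc$subject_id,
              sliding_window_connectivity(tc, config$window_length,
                                          config$step, config$sigma))
  })
  n_windows <- dim(wcs[[1L]]$layers)[3L]

  # 4. state analysis
  elbow <- NULL
  k <- config$k
  if (is.null(k)) {
    elbow <- run_stage("states", NULL,
                       select_k_elbow(wcs, k_range = config$k_range,
                                      n_replicates = config$elbow_replicates,
                                      seed = derive_seed(config$seed, 41L),
                                      max_iter = config$kmeans_iter))
    k <- elbow$k
  }
  state_model <- run_stage("states", NULL,
                           cluster_states(wcs, k,
                                          max_iter = config$kmeans_iter,
                                          n_replicates = config$kmeans_replicates,
                                          seed = derive_seed(config$seed, 42L)))
  temporal <- lapply(cohort$subject_id, function(sid) {
    run_stage("states", sid,
              temporal_properties(state_model$assignments[[sid]], k))
  })
  rf <- t(vapply(temporal, `[[`, numeric(k), "RF"))
  dt <- t(vapply(temporal, `[[`, numeric(k), "DT"))
  colnames(rf) <- paste0("RF_", seq_len(k))
  colnames(dt) <- paste0("DT_", seq_len(k))
  ttn <- vapply(temporal, `[[`, integer(1L), "TTN")

  # 5. multilayer community structure
  ml <- lapply(seq_len(n_sub), function(i) {
    sid <- cohort$subject_id[i]
    run_stage("multilayer", sid, {
      net <- build_supra(wcs[[i]], omega = config$omega, gamma = config$gamma,
                         negative_policy = config$negative_policy)
      ens <- run_ensemble(net, n_runs = config$n_louvain_runs,
                          base_seed = derive_seed(config$seed, 5000L + i))
      p <- module_allegiance(ens)
      integration(p, membership, Q = mean(ens$Q_values))
    })
  })
  node_int <- t(vapply(ml, `[[`, numeric(n_nodes), "node_integration"))
  colnames(node_int) <- paste0("int_", node_labels)
  net_names <- names(ml[[1L]]$rsn_integration)
  rsn_int <- t(vapply(ml, `[[`, numeric(length(net_names)), "rsn_integration"))
  colnames(rsn_int) <- paste0("int_", net_names)
  pair_names <- names(ml[[1L]]$rsn_pair_integration)
  pair_int <- t(vapply(ml, `[[`, numeric(length(pair_names)), "rsn_pair_integration"))
  colnames(pair_int) <- paste0("int_", pair_names)
  q_vals <- vapply(ml, `[[`, numeric(1L), "modularity_Q")

  measures <- data.frame(subject_id = cohort$subject_id, group = cohort$group,
                         sfnc_edges, rf, dt, TTN = ttn, node_int, rsn_int,
                         pair_int, Q = q_vals,
                         check.names = FALSE, stringsAsFactors = FALSE)

  # 6. group statistics with FDR families
  families <- list(
    sfnc = colnames(sfnc_edges),
    RF = colnames(rf),
    DT = colnames(dt),
    integration_ic = colnames(node_int),
    integration_rsn = colnames(rsn_int),
    integration_rsn_pair = colnames(pair_int),
    TTN = "TTN",
    Q = "Q"
  )
  expected_sizes <- c(sfnc = n_nodes * (n_nodes - 1L) / 2L, RF = k, DT = k,
                      integration_ic = n_nodes,
                      integration_rsn = length(net_names),
                      integration_rsn_pair = length(pair_names),
                      TTN = 1L, Q = 1L)
  actual_sizes <- vapply(families, length, integer(1L))
  if (!all(actual_sizes == expected_sizes[names(families)])) {
    stopf("internal error: FDR family sizes do not match the design")
  }
  uncorrected <- c("TTN", "Q")
  if (is.null(contrasts)) {
    gr <- unique(cohort$group)
    contrasts <- if ("HC" %in% gr) {
      lapply(setdiff(gr, "HC"), function(g) c("HC", g))
    } else {
      utils::combn(gr, 2L, simplify = FALSE)
    }
  }
  if (is.null(covariate_cols)) {
    covariate_cols <- intersect(c("age", "sex", "education", "mean_FD"),
                                names(cohort))
  }
  comparisons <- do.call(rbind, lapply(contrasts, function(ct) {
    do.call(rbind, lapply(names(families), function(fam) {
      rows <- do.call(rbind, lapply(families[[fam]], function(ms) {
        res <- run_stage("stats", NULL,
          glm_group_compare(measures[[ms]], cohort$group,
                            covariates = if (length(covariate_cols))
                              cohort[covariate_cols] else NULL,
                            groups = ct))
        data.frame(contrast = paste(ct[2L], "vs", ct[1L]), family = fam,
                   measure = ms, t = res$t, p = res$p,
                   stringsAsFactors = FALSE)
      }))
      rows$p_fdr <- if (fam %in% uncorrected) rows$p else fdr_bh(rows$p, fam)
      rows
    }))
  }))
  rownames(comparisons) <- NULL

  # 7. brain-behavior correlations for measures surviving FDR
  correlations <- NULL
  sig <- unique(comparisons$measure[comparisons$p_fdr < config$fdr_alpha])
  if (length(sig) && length(behavior_cols)) {
    correlations <- do.call(rbind, lapply(sig, function(ms) {
      do.call(rbind, lapply(behavior_cols, function(bh) {
        do.call(rbind, lapply(unique(cohort$group), function(g) {
          idx <- cohort$group == g
          res <- tryCatch(pearson_correlation(measures[[ms]][idx],
                                              cohort[[bh]][idx]),
                          error = function(e) list(r = NA_real_, p = NA_real_,
                                                   n = sum(idx)))
          data.frame(measure = ms, behavior = bh, group = g,
                     r = res$r, p = res$p, n = res$n, stringsAsFactors = FALSE)
        }))
      }))
    }))
    rownames(correlations) <- NULL
  }

  provenance <- list(
    package = "triplenet",
    version = as.character(utils::packageVersion("triplenet")),
    config = unclass(config)[!vapply(unclass(config), is.null, logical(1L))],
    n_subjects = n_sub, n_nodes = n_nodes, n_windows = n_windows,
    k_selected = k, elbow_used = is.null(config$k),
    family_sizes = as.list(actual_sizes),
    negative_policy = config$negative_policy,
    contrasts = lapply(contrasts, paste, collapse = " vs "),
    covariates = covariate_cols,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )

  result <- structure(list(measures = measures, comparisons = comparisons,
                           correlations = correlations,
                           state_model = state_model, elbow = elbow,
                           provenance = provenance),
                      class = "triplenet_result")
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(measures, file.path(output_dir, "measures.csv"),
                     row.names = FALSE)
    utils::write.csv(comparisons, file.path(output_dir, "comparisons.csv"),
                     row.names = FALSE)
    if (!is.null(correlations)) {
      utils::write.csv(correlations, file.path(output_dir, "correlations.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(provenance, file.path(output_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}

#' @export
print.triplenet_result <- function(x, ...) {
  pv <- x$provenance
  cat(sprintf("<triplenet_result> %d subjects, %d windows, k = %d states\n",
              pv$n_subjects, pv$n_windows, pv$k_selected))
  sig <- x$comparisons[x$comparisons$p_fdr < pv$config$fdr_alpha, , drop = FALSE]
  cat(sprintf("  %d of %d comparisons significant after FDR (alpha = %g)\n",
              nrow(sig), nrow(x$comparisons), pv$config$fdr_alpha))
  if (nrow(sig)) {
    for (i in seq_len(nrow(sig))) {
      cat(sprintf("    %s | %s: t = %.3f, p_fdr = %.4f\n", sig$contrast[i],
                  sig$measure[i], sig$t[i], sig$p_fdr[i]))
    }
  }
  invisible(x)
}
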