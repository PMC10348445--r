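`%||%` <- function(a, b) if (is.null(a)) b else a

#' Configuration of a full energy-landscape study
#'
#' Collects every tunable of the end-to-end pipeline: binarization mode,
#' model-fit hyperparameters, random-walk settings, indirect-path templates,
#' the sampling interval, and the statistics options. Defaults follow the
#' standard protocol for seven-network rsfMRI analyses: per-timepoint-mean
#' binarization, gradient ascent at rate 0.2 to a 1e-8 moment gap,
#' `1e5`-step walks with a 100-step burn-in, TR of 2 s, Bonferroni-corrected
#' group tests and 5000 bootstrap replicates for mediation.
#'
#' @param binarize_mode passed to [binarize()].
#' @param learning_rate,tol,max_iter passed to [fit_pairwise_mem()].
#' @param n_steps,burn_in passed to [metropolis_random_walk()].
#' @param seed master seed for walks and bootstraps.
#' @param templates list of [path_template()]s.
#' @param tr_seconds sampling interval for timescale estimation.
#' @param q FDR level.
#' @param n_boot bootstrap replicates for mediation.
#' @param reference_group group whose landscape defines the canonical state
#'   letters; default the first group in the manifest.
#' @param reference_model optional [mem_parameters()] whose landscape
#'   defines the canonical states instead of the reference group's fit
#'   (e.g., the ground-truth model of a synthetic study, or a previously
#'   published group model); every group's fitted minima — including the
#'   reference group's — are then matched to this landscape's minima by
#'   pattern similarity.
#' @param correlations optional list of `list(group, symptom, feature)`
#'   correlation analyses; default derived from the cohort's planted
#'   symptom couplings when available.
#' @param mediations optional list of `list(group, x, m, y)` mediation
#'   analyses over cohort-table columns.
#' @param accuracy_warn_pct warn when a group's fit accuracy (percent)
#'   falls below this.
#' @return a `study_config` list.
#' @export
study_config <- function(binarize_mode = "per-timepoint-mean",
                         learning_rate = 0.2, tol = 1e-8, max_iter = 5e5,
                         n_steps = 1e5, burn_in = 100, seed = 1L,
                         templates = canonical_templates(), tr_seconds = 2,
                         q = 0.05, n_boot = 5000, reference_group = NULL,
                         reference_model = NULL, correlations = NULL,
                         mediations = NULL, accuracy_warn_pct = 80) {
  stopifnot(learning_rate > 0, tol > 0, max_iter >= 1, n_steps > burn_in,
            burn_in >= 0, tr_seconds > 0, q > 0, q < 1, n_boot >= 1)
  structure(list(binarize_mode = binarize_mode, learning_rate = learning_rate,
                 tol = tol, max_iter = max_iter, n_steps = as.integer(n_steps),
                 burn_in = as.integer(burn_in), seed = as.integer(seed),
                 templates = templates, tr_seconds = tr_seconds, q = q,
                 n_boot = as.integer(n_boot),
                 reference_group = reference_group,
                 reference_model = reference_model,
                 correlations = correlations, mediations = mediations,
                 accuracy_warn_pct = accuracy_warn_pct),
            class = "study_config")
}

#' Group-level landscape analysis
#'
#' Runs the group stage of the pipeline on the subjects of one group:
#' binarize each subject's signals, stack them, compute moments, fit the
#' first-order and pairwise maximum-entropy models, quantify fit accuracy,
#' enumerate the energy landscape (minima, basins, disconnectivity tree),
#' and simulate brain-state dynamics with a Metropolis random walk.
#'
#' @param series_list list of T x N continuous signal matrices (one per
#'   subject), or of `binary_time_series`.
#' @param config a [study_config()].
#' @param walk_seed seed of the group's random walk; default `config$seed`.
#' @return a `group_landscape`: list with `params` (pairwise fit),
#'   `first_order`, `fit` (accuracy diagnostics), `landscape`, `minima`,
#'   `basins`, `tree`, `trajectory`, `states`, `summary` (simulated
#'   transition statistics), `path_freq` (simulated template frequencies).
#' @export
run_group_landscape <- function(series_list, config = study_config(),
                                walk_seed = NULL) {
  stopifnot(length(series_list) >= 1)
  bins <- lapply(series_list, function(s) {
    if (inherits(s, "binary_time_series")) s
    else binarize(s, mode = config$binarize_mode)
  })
  moments <- compute_empirical_moments(bins)
  fit <- fit_pairwise_mem(moments, learning_rate = config$learning_rate,
                          tol = config$tol, max_iter = config$max_iter)
  first <- fit_independent_mem(moments)
  emp <- empirical_pattern_distribution(bins)
  acc <- fit_accuracy(emp, first, fit$params)
  if (acc$defined && acc$accuracy_pct < config$accuracy_warn_pct) {
    warning(sprintf("fit accuracy %.1f%% below %.0f%%", acc$accuracy_pct,
                    config$accuracy_warn_pct), call. = FALSE)
  }
  land <- enumerate_energies(fit$params)
  minima <- find_local_minima(land)
  basins <- assign_basins(land, minima)
  tree <- build_disconnectivity_tree(land, minima)
  traj <- metropolis_random_walk(fit$params, n_steps = config$n_steps,
                                 burn_in = config$burn_in,
                                 seed = walk_seed %||% config$seed)
  states <- patterns_to_states(traj, basins)
  summ <- transition_statistics(states)
  pf <- vapply(config$templates, function(tp) {
    ok <- all(c(tp$endpoints, unlist(tp$blocks)) %in% attr(states, "states"))
    if (!ok) return(NA_real_)
    count_path_transitions(states, tp)$frequency
  }, numeric(1))
  structure(list(params = fit$params, first_order = first,
                 fit = c(acc, fit$diagnostics), moments = moments,
                 landscape = land, minima = minima, basins = basins,
                 tree = tree, trajectory = traj, states = states,
                 summary = summ, path_freq = pf),
            class = "group_landscape")
}

# Similarity between two +1/-1 patterns: Pearson correlation over entries,
# falling back to the +-1-scaled agreement rate when a pattern is uniform.
pattern_similarity <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) 2 * mean(a == b) - 1
  else stats::cor(a, b)
}

#' Match brain states across group landscapes
#'
#' Landscapes fitted to different groups label their minima independently;
#' this matches each group's local minima to those of a reference landscape
#' by greedy maximum-magnitude pattern similarity (Pearson correlation of
#' the +1/-1 minimum patterns, ties broken by energy rank), so that state
#' letters are comparable across groups. Signed similarities are reported;
#' unmatched minima (when counts differ) are listed.
#'
#' @param landscapes named list of `group_landscape` objects.
#' @param reference name of the reference group, whose fitted minima define
#'   the canonical states unless `reference_minima` is supplied.
#' @param reference_minima optional [find_local_minima()] table defining the
#'   canonical states directly (e.g., from a ground-truth landscape).
#' @return a `state_correspondence`: per group, a data frame mapping that
#'   group's state labels to reference state labels with similarity scores,
#'   plus `unmatched` labels.
#' @export
match_states <- function(landscapes, reference, reference_minima = NULL) {
  if (is.null(reference_minima)) {
    stopifnot(reference %in% names(landscapes))
    reference_minima <- landscapes[[reference]]$minima
  }
  out <- lapply(names(landscapes), function(g) {
    list_el <- match_minima(landscapes[[g]]$minima, reference_minima)
    list_el
  })
  names(out) <- names(landscapes)
  structure(list(reference = reference, groups = out),
            class = "state_correspondence")
}

match_minima <- function(mm, ref) {
  sim <- matrix(0, nrow(mm), nrow(ref))
  for (i in seq_len(nrow(mm))) {
    for (j in seq_len(nrow(ref))) {
      sim[i, j] <- pattern_similarity(mm$pattern[i, ], ref$pattern[j, ])
    }
  }
  map <- data.frame(group_state = toupper(mm$label),
                    reference_state = NA_character_,
                    similarity = NA_real_, stringsAsFactors = FALSE)
  free_i <- seq_len(nrow(mm)); free_j <- seq_len(nrow(ref))
  while (length(free_i) && length(free_j)) {
    sub <- abs(sim[free_i, free_j, drop = FALSE])
    best <- max(sub)
    # ties by energy rank: minima tables are energy-ordered, so take the
    # first qualifying (i, j) pair in table order
    hit <- which(sub == best, arr.ind = TRUE)[1, ]
    i <- free_i[hit[1]]; j <- free_j[hit[2]]
    map$reference_state[i] <- toupper(ref$label[j])
    map$similarity[i] <- sim[i, j]
    free_i <- setdiff(free_i, i); free_j <- setdiff(free_j, j)
  }
  list(map = map, unmatched = toupper(mm$label[is.na(map$reference_state)]))
}

# Relabel a basin map's states to the canonical (reference) letters.
# Unmatched minima lose their basin: their patterns are flagged and dropped
# from state sequences.
relabel_basins <- function(basins, map) {
  lut <- stats::setNames(tolower(map$reference_state), tolower(map$group_state))
  keep <- !is.na(lut[basins$assignment])
  b <- basins
  b$assignment <- unname(lut[basins$assignment])
  b$ambiguous <- basins$ambiguous | !keep
  b$minima$label <- unname(lut[basins$minima$label])
  b$minima <- b$minima[!is.na(b$minima$label), , drop = FALSE]
  b$minima <- b$minima[order(b$minima$label), , drop = FALSE]
  b$state_labels <- toupper(b$minima$label)
  b
}

#' Run the full study pipeline on a cohort
#'
#' End-to-end analysis: per group, the landscape stage
#' ([run_group_landscape()]); across groups, state matching to the reference
#' landscape; per subject, empirical brain-state dynamics (template path
#' frequencies against the subject's group landscape, relabelled to
#' canonical states) and an intrinsic-timescale map; and at cohort level,
#' group comparisons of the path frequencies (pooled t tests,
#' Bonferroni-corrected per feature), symptom-feature correlations, and
#' bootstrap mediation analyses.
#'
#' Subjects whose series fail a stage are excluded with a logged reason; a
#' group retaining fewer than half of its subjects aborts the run.
#'
#' @param cohort a `synthetic_cohort`, a list with `manifest` and `series`,
#'   or a cohort directory path (see [read_cohort()]).
#' @param config a [study_config()].
#' @param out_dir optional output directory for JSON/CSV result files.
#' @return a `study_results` list: `group_landscapes`, `correspondence`,
#'   `cohort_table` (subject x features/timescales/symptoms),
#'   `group_tests`, `correlations`, `mediations`, `fit_summary`,
#'   `excluded`, `config`.
#' @export
run_full_study <- function(cohort, config = study_config(), out_dir = NULL) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  manifest <- cohort$manifest
  series <- cohort$series
  stopifnot(!anyDuplicated(manifest$subject_id),
            all(manifest$subject_id %in% names(series)))
  groups <- unique(manifest$group)
  reference <- config$reference_group %||% groups[[1]]
  stopifnot(reference %in% groups)
  group_seeds <- split_seeds(config$seed, length(groups) + 1L)

  excluded <- list()
  lands <- list()
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    ids <- manifest$subject_id[manifest$group == g]
    lands[[g]] <- run_group_landscape(series[ids], config,
                                      walk_seed = group_seeds[gi])
  }
  ref_minima <- NULL
  if (!is.null(config$reference_model)) {
    ref_minima <- find_local_minima(enumerate_energies(config$reference_model))
  }
  corr_states <- match_states(lands, reference, reference_minima = ref_minima)
  # simulated path frequencies on the canonical state labels
  for (g in groups) {
    basins_c <- relabel_basins(lands[[g]]$basins, corr_states$groups[[g]]$map)
    st <- patterns_to_states(lands[[g]]$trajectory, basins_c)
    lands[[g]]$states_canonical <- st
    lands[[g]]$path_freq <- vapply(config$templates, function(tp) {
      needed <- c(tp$endpoints, unlist(tp$blocks))
      if (!all(needed %in% attr(st, "states"))) return(NA_real_)
      count_path_transitions(st, tp)$frequency
    }, numeric(1))
  }

  # per-subject empirical dynamics + timescales, on canonical state labels
  rows <- list()
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$subject_id[i]
    g <- manifest$group[i]
    res <- tryCatch({
      basins <- relabel_basins(lands[[g]]$basins,
                               corr_states$groups[[g]]$map)
      bin <- binarize(series[[id]], mode = config$binarize_mode)
      dyn <- subject_dynamics(bin, basins, config$templates)
      ts <- timescale_map(series[[id]], tr_seconds = config$tr_seconds,
                          subject_id = id)
      ints <- ts$int_values
      names(ints) <- paste0("int_", names(ints))
      c(as.list(dyn$path_freq), as.list(ints))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excluded[[id]] <- conditionMessage(res)
    } else {
      rows[[id]] <- as.data.frame(c(list(subject_id = id), res),
                                  stringsAsFactors = FALSE)
    }
  }
  for (g in groups) {
    ids <- manifest$subject_id[manifest$group == g]
    if (sum(ids %in% names(rows)) < length(ids) / 2) {
      stop("more than half of group `", g, "` failed; aborting", call. = FALSE)
    }
  }
  feats <- do.call(rbind, unname(rows))
  cohort_table <- merge(manifest, feats, by = "subject_id", sort = FALSE)

  feature_names <- names(config$templates)
  group_tests <- list()
  for (f in feature_names) {
    ref_vals <- cohort_table[[f]][cohort_table$group == reference]
    res <- lapply(setdiff(groups, reference), function(g) {
      vals <- cohort_table[[f]][cohort_table$group == g]
      tt <- tryCatch(two_sample_t(vals, ref_vals),
                     error = function(e) list(statistic = NA_real_,
                                              df = NA_real_, p = NA_real_,
                                              effect_size = NA_real_))
      data.frame(feature = f, group = g, reference = reference,
                 t = tt$statistic, df = tt$df, p_raw = tt$p,
                 cohens_d = tt$effect_size, stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    ok <- !is.na(res$p_raw)
    res$p_bonferroni <- NA_real_
    res$p_bonferroni[ok] <- bonferroni(res$p_raw[ok])
    group_tests[[f]] <- res
  }
  group_tests <- do.call(rbind, group_tests)
  rownames(group_tests) <- NULL

  cor_specs <- config$correlations %||% default_correlations(cohort)
  correlations <- NULL
  if (length(cor_specs)) {
    correlations <- do.call(rbind, lapply(cor_specs, function(cs) {
      sub <- cohort_table[cohort_table$group == cs$group, ]
      pc <- tryCatch(pearson_correlation(sub[[cs$feature]], sub[[cs$symptom]]),
                     error = function(e) list(r = NA_real_, p = NA_real_,
                                              df = NA_real_))
      data.frame(group = cs$group, symptom = cs$symptom, feature = cs$feature,
                 r = pc$r, p_raw = pc$p, df = pc$df, stringsAsFactors = FALSE)
    }))
    ok <- !is.na(correlations$p_raw)
    correlations$p_bonferroni <- NA_real_
    correlations$p_bonferroni[ok] <- bonferroni(correlations$p_raw[ok])
  }

  mediations <- NULL
  if (length(config$mediations)) {
    mediations <- lapply(config$mediations, function(ms) {
      sub <- if (is.null(ms$group)) cohort_table
             else cohort_table[cohort_table$group %in% ms$group, ]
      res <- tryCatch(
        mediation_bootstrap(sub[[ms$x]], sub[[ms$m]], sub[[ms$y]],
                            n_boot = config$n_boot,
                            seed = group_seeds[length(groups) + 1L]),
        error = function(e) list(error = conditionMessage(e)))
      list(spec = ms, result = res)
    })
  }

  fit_summary <- do.call(rbind, lapply(groups, function(g) {
    f <- lands[[g]]$fit
    data.frame(group = g, accuracy_pct = f$accuracy_pct, d1 = f$d1, d2 = f$d2,
               converged = f$converged, n_minima = nrow(lands[[g]]$minima),
               stringsAsFactors = FALSE)
  }))

  results <- structure(list(group_landscapes = lands,
                            correspondence = corr_states,
                            cohort_table = cohort_table,
                            group_tests = group_tests,
                            correlations = correlations,
                            mediations = mediations,
                            fit_summary = fit_summary,
                            excluded = excluded, config = config),
                       class = "study_results")
  if (!is.null(out_dir)) write_study_results(results, out_dir)
  results
}

# Correlation analyses implied by a synthetic cohort's planted couplings.
default_correlations <- function(cohort) {
  slopes <- NULL
  if (!is.null(cohort$truth)) {
    sp <- cohort$truth$spec %||% cohort$truth
    slopes <- sp$symptom_slopes
  }
  if (!length(slopes)) return(list())
  out <- list()
  for (sy in names(slopes)) {
    gs <- slopes[[sy]]$groups %||% unique(cohort$manifest$group)
    for (g in gs) {
      out[[length(out) + 1L]] <-
        list(group = g, symptom = sy, feature = slopes[[sy]]$feature)
    }
  }
  out
}

#' @export
print.study_results <- function(x, ...) {
  cat("<study_results>\n")
  cat("Fit summary:\n")
  print(x$fit_summary, row.names = FALSE)
  cat("\nGroup tests (path frequencies vs reference):\n")
  print(x$group_tests, row.names = FALSE)
  if (!is.null(x$correlations)) {
    cat("\nSymptom correlations:\n")
    print(x$correlations, row.names = FALSE)
  }
  invisible(x)
}

#' Write study results to disk
#'
#' Writes `cohort_table.csv`, `group_tests.csv`, `correlations.csv`,
#' `fit_summary.csv` and a machine-readable `results.json` (fit summary,
#' minima, state correspondence, simulated path frequencies, tests,
#' correlations, mediations, config echo).
#'
#' @param results a [run_full_study()] result.
#' @param dir output directory.
#' @export
write_study_results <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(results$cohort_table, file.path(dir, "cohort_table.csv"),
                   row.names = FALSE)
  utils::write.csv(results$group_tests, file.path(dir, "group_tests.csv"),
                   row.names = FALSE)
  utils::write.csv(results$fit_summary, file.path(dir, "fit_summary.csv"),
                   row.names = FALSE)
  if (!is.null(results$correlations)) {
    utils::write.csv(results$correlations, file.path(dir, "correlations.csv"),
                     row.names = FALSE)
  }
  json <- list(
    fit_summary = results$fit_summary,
    minima = lapply(results$group_landscapes, function(l) {
      data.frame(label = l$minima$label, code = l$minima$code,
                 energy = l$minima$energy)
    }),
    simulated_path_freq = lapply(results$group_landscapes, function(l) {
      as.list(l$path_freq)
    }),
    correspondence = lapply(results$correspondence$groups, `[[`, "map"),
    group_tests = results$group_tests,
    correlations = results$correlations,
    mediations = lapply(results$mediations %||% list(), function(m) {
      list(spec = m$spec,
           estimates = list(alpha = m$result$alpha, beta = m$result$beta,
                            gamma = m$result$gamma,
                            gamma_prime = m$result$gamma_prime,
                            indirect = m$result$indirect),
           ci = as.data.frame(m$result$ci))
    }),
    excluded = results$excluded,
    config = results$config[setdiff(names(results$config),
                                    c("templates", "reference_model"))]
  )
  jsonlite::write_json(json, file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
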