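#' Random ground-truth Ising models
#'
#' Draws a ground-truth pairwise maximum-entropy model for simulation
#' studies: fields `h` i.i.d. uniform on `[-field_scale, field_scale]` and
#' couplings `J` with upper triangle i.i.d. uniform on
#' `[-coupling_scale, coupling_scale]`, symmetrized, zero diagonal.
#'
#' @param n_nodes number of network nodes (>= 2).
#' @param field_scale,coupling_scale nonnegative half-widths of the uniform
#'   draws.
#' @param seed integer seed; the model is deterministic given the seed.
#' @param label free-text model label.
#' @return a [mem_parameters()] with a `label` attribute.
#' @export
make_ising_model <- function(n_nodes, field_scale = 0.3, coupling_scale = 0.3,
                             seed = 1L, label = "ground-truth") {
  check_n_nodes(n_nodes, enumerate = FALSE)
  stopifnot(field_scale >= 0, coupling_scale >= 0)
  model <- with_seed(seed, {
    h <- stats::runif(n_nodes, -field_scale, field_scale)
    J <- matrix(0, n_nodes, n_nodes)
    ut <- upper.tri(J)
    J[ut] <- stats::runif(sum(ut), -coupling_scale, coupling_scale)
    J <- J + t(J)
    mem_parameters(h, J, order = "pairwise")
  })
  attr(model, "label") <- label
  model
}

#' Scale a model's fields and couplings
#'
#' Multiplying `h` and `J` by a common factor scales every pattern energy by
#' that factor, deepening (`factor > 1`) or flattening (`factor < 1`) the
#' landscape while leaving the set and ordering of local minima unchanged.
#' Used to derive group-specific landscapes of differing depth from a shared
#' base model.
#'
#' @param model a [mem_parameters()].
#' @param factor positive scale factor.
#' @export
scale_model <- function(model, factor) {
  stopifnot(inherits(model, "mem_parameters"), factor > 0)
  out <- mem_parameters(model$h * factor, model$J * factor,
                        order = model$order, node_names = model$node_names)
  attr(out, "label") <- attr(model, "label")
  out
}

#' Exact i.i.d. sampling from a model's Boltzmann distribution
#'
#' Enumerates all `2^N` pattern probabilities and draws patterns by
#' cumulative inverse sampling, giving independent (temporally uncorrelated)
#' samples from the exact distribution.
#'
#' @param model a [mem_parameters()] with at most `max_enumerable_nodes()`
#'   nodes.
#' @param n_samples number of patterns to draw (0 gives an empty series).
#' @param seed integer seed.
#' @return `n_samples x N` matrix of +1/-1.
#' @export
sample_patterns_exact <- function(model, n_samples, seed = 1L) {
  stopifnot(inherits(model, "mem_parameters"), n_samples >= 0)
  n <- model$n_nodes
  check_n_nodes(n)
  if (n_samples == 0L) return(matrix(integer(0), 0, n))
  p <- boltzmann_distribution(model)$probabilities
  cum <- cumsum(p)
  cum[length(cum)] <- 1
  codes <- with_seed(seed, findInterval(stats::runif(n_samples), cum,
                                        left.open = TRUE)) # in 0..2^N-1
  out <- code_to_pattern(codes, n)
  if (!is.matrix(out)) out <- matrix(out, nrow = 1)
  out
}

#' Continuous signals from binary patterns
#'
#' Produces a continuous stand-in for network-averaged neural signals by
#' adding i.i.d. Gaussian noise of standard deviation `1/snr` to the +1/-1
#' pattern values. At high `snr`, re-binarizing with the per-timepoint-mean
#' threshold recovers the input patterns for every row that contains at
#' least one sign change.
#'
#' @param patterns T x N matrix over +1/-1.
#' @param snr positive signal-to-noise ratio.
#' @param seed integer seed.
#' @return T x N numeric matrix of the same dimensions.
#' @export
binary_to_continuous <- function(patterns, snr, seed = 1L) {
  patterns <- as.matrix(patterns)
  check_spins(patterns)
  stopifnot(snr > 0)
  noise <- with_seed(seed, stats::rnorm(length(patterns), sd = 1 / snr))
  patterns + matrix(noise, nrow(patterns), ncol(patterns))
}

#' Stationary AR(1) series
#'
#' Generates `x_t = phi * x_{t-1} + e_t` with standard-normal innovations
#' and a stationary initial value `x_0 ~ N(0, 1/(1 - phi^2))`, for testing
#' autocorrelation-based timescale estimators against known ground truth.
#'
#' @param phi autoregressive coefficient, `|phi| < 1`.
#' @param n_timepoints series length.
#' @param seed integer seed.
#' @return numeric vector of length `n_timepoints`.
#' @export
generate_ar1_series <- function(phi, n_timepoints, seed = 1L) {
  if (abs(phi) >= 1) stop("|phi| must be < 1 for stationarity", call. = FALSE)
  stopifnot(n_timepoints >= 1)
  with_seed(seed, {
    e <- stats::rnorm(n_timepoints)
    x0 <- stats::rnorm(1) / sqrt(1 - phi^2)
    as.numeric(stats::filter(e, phi, method = "recursive", init = x0))
  })
}

#' Specification of a synthetic cohort with planted effects
#'
#' Bundles everything the cohort generator needs: one ground-truth model per
#' group, sample sizes, the continuous-signal noise level, and the planted
#' couplings between dynamics features and symptom scores that give the
#' correlation and mediation stages a known ground truth.
#'
#' Two group-level mechanisms shape the planted dynamics. `steps_per_tr`
#' sets how many Metropolis steps the network evolves between consecutive
#' recorded timepoints: faster groups (larger values) produce signals with
#' shorter intrinsic timescales *and* more completed indirect transitions
#' per recorded step, while leaving the stationary pattern distribution —
#' and hence the fitted landscape — untouched. Group models themselves may
#' additionally differ (e.g., via [scale_model()]) to plant landscape-depth
#' differences.
#'
#' Per-subject heterogeneity has three optional sources: `speed_jitter_sd`
#' rescales each subject's dynamical speed by a log-normal factor (the
#' mechanism that couples a subject's intrinsic timescales to their
#' transition frequencies within a group), `subject_jitter_sd` adds
#' independent Gaussian jitter to each entry of `h` and `J` (default 0, so
#' group-level fits recover the group model exactly), and
#' `temperature_jitter_sd` rescales each subject's whole parameter set by a
#' log-normal factor, making subjects differ in overall landscape depth.
#'
#' @param group_models named list of [mem_parameters()], one per group; all
#'   must share `n_nodes`.
#' @param n_subjects_per_group subjects per group.
#' @param n_timepoints timepoints per subject (>= 2).
#' @param snr continuous-signal signal-to-noise ratio.
#' @param symptom_slopes named list: symptom name -> list(feature, slope,
#'   noise_sd, intercept, groups); `feature` must be a planted dynamics
#'   feature name (see [generate_cohort()]); `groups` optionally restricts
#'   which groups receive non-missing scores.
#' @param mediation_plant optional list(alpha, beta, gamma_prime): adds
#'   `med_x`, `med_m`, `med_y` columns generated from the linear chain
#'   `m = alpha x + e`, `y = gamma_prime x + beta m + e`.
#' @param steps_per_tr Metropolis steps per recorded timepoint: a single
#'   number or a named vector/list with one entry per group.
#' @param speed_jitter_sd sd of the log-normal per-subject speed factor
#'   (subject speeds are rounded to integers >= 1).
#' @param subject_jitter_sd entry-wise Gaussian jitter on h and J.
#' @param temperature_jitter_sd sd of the log-normal per-subject depth
#'   factor.
#' @param tr_seconds sampling interval attached to generated series.
#' @param mcmc_burn_in burn-in of the per-subject Metropolis sampler.
#' @param seed master seed; per-subject seeds are split from it
#'   deterministically.
#' @return an `effect_spec` list.
#' @export
effect_spec <- function(group_models, n_subjects_per_group = 30,
                        n_timepoints = 175, snr = 5,
                        symptom_slopes = list(), mediation_plant = NULL,
                        steps_per_tr = 1, speed_jitter_sd = 0,
                        subject_jitter_sd = 0, temperature_jitter_sd = 0,
                        tr_seconds = 2, mcmc_burn_in = 200, seed = 1L) {
  stopifnot(is.list(group_models), length(group_models) >= 1,
            !is.null(names(group_models)), n_timepoints >= 2, snr > 0,
            n_subjects_per_group >= 1)
  nn <- vapply(group_models, function(m) m$n_nodes, integer(1))
  if (length(unique(nn)) != 1L) {
    stop("all group models must share n_nodes", call. = FALSE)
  }
  if (!is.null(mediation_plant)) {
    stopifnot(all(c("alpha", "beta", "gamma_prime") %in% names(mediation_plant)))
  }
  gl <- names(group_models)
  if (length(steps_per_tr) == 1L && is.null(names(steps_per_tr))) {
    steps_per_tr <- stats::setNames(rep(as.numeric(steps_per_tr), length(gl)), gl)
  } else {
    steps_per_tr <- unlist(steps_per_tr)
    stopifnot(all(gl %in% names(steps_per_tr)))
    steps_per_tr <- steps_per_tr[gl]
  }
  stopifnot(all(steps_per_tr >= 1))
  structure(list(group_models = group_models,
                 n_subjects_per_group = as.integer(n_subjects_per_group),
                 n_timepoints = as.integer(n_timepoints), snr = snr,
                 symptom_slopes = symptom_slopes,
                 mediation_plant = mediation_plant,
                 steps_per_tr = steps_per_tr,
                 speed_jitter_sd = speed_jitter_sd,
                 subject_jitter_sd = subject_jitter_sd,
                 temperature_jitter_sd = temperature_jitter_sd,
                 tr_seconds = tr_seconds,
                 mcmc_burn_in = as.integer(mcmc_burn_in),
                 seed = as.integer(seed), n_nodes = nn[[1]]),
            class = "effect_spec")
}

# Jittered, temperature-scaled copy of a group model for one subject.
subject_model <- function(model, tau, jitter_sd, seed) {
  if (tau == 1 && jitter_sd == 0) return(model)
  with_seed(seed, {
    h <- model$h * tau
    J <- model$J * tau
    if (jitter_sd > 0) {
      n <- length(h)
      h <- h + stats::rnorm(n, sd = jitter_sd)
      ut <- upper.tri(J)
      dJ <- matrix(0, n, n)
      dJ[ut] <- stats::rnorm(sum(ut), sd = jitter_sd)
      J <- J + dJ + t(dJ)
    }
    mem_parameters(h, J, order = "pairwise", node_names = model$node_names)
  })
}

#' Generate a synthetic cohort with planted effects
#'
#' For each subject: (1) draws a subject-specific model from the group model
#' (temperature and entry jitter per the spec), (2) samples a temporally
#' correlated binary pattern series with the Metropolis walker, (3) adds
#' Gaussian noise to obtain continuous signals, (4) computes the subject's
#' planted dynamics features — the per-step frequencies of the three
#' canonical indirect transitions (`freq_ACDB`, `freq_ACDEFB`, `freq_ACFB`)
#' measured against the *group* ground-truth landscape — and (5) generates
#' symptom scores as `intercept + slope * feature + noise`. Everything is
#' seeded from the spec's master seed via deterministic stream splitting.
#'
#' @param spec an [effect_spec()].
#' @return a `synthetic_cohort`: list with `manifest` (data frame:
#'   subject_id, group, symptoms, planted mediation columns), `series`
#'   (named list of T x N continuous matrices), `binary` (the underlying
#'   pattern matrices), and `truth` (spec, per-subject features, temperature
#'   factors, group landscapes).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "effect_spec"))
  groups <- names(spec$group_models)
  n_per <- spec$n_subjects_per_group
  n_total <- n_per * length(groups)
  feature_names <- names(canonical_templates())
  for (sy in spec$symptom_slopes) {
    if (!sy$feature %in% feature_names) {
      stop("unknown planted feature `", sy$feature, "`; available: ",
           paste(feature_names, collapse = ", "), call. = FALSE)
    }
  }
  seeds <- matrix(split_seeds(spec$seed, 4L * n_total), ncol = 4L)
  group_land <- lapply(spec$group_models, function(m) {
    land <- enumerate_energies(m)
    minima <- find_local_minima(land)
    list(landscape = land, minima = minima,
         basins = assign_basins(land, minima))
  })
  templates <- canonical_templates()
  manifest <- list()
  series <- list()
  binary <- list()
  features <- list()
  s <- 0L
  for (g in groups) {
    gm <- spec$group_models[[g]]
    basins <- group_land[[g]]$basins
    for (k in seq_len(n_per)) {
      s <- s + 1L
      id <- sprintf("%s-%02d", gsub("[^A-Za-z0-9]", "", g), k)
      jit2 <- with_seed(seeds[s, 1], stats::rnorm(2))
      tau <- exp(spec$temperature_jitter_sd * jit2[1])
      speed <- max(1L, as.integer(round(
        spec$steps_per_tr[[g]] * exp(spec$speed_jitter_sd * jit2[2]))))
      model_s <- subject_model(gm, tau, spec$subject_jitter_sd, seeds[s, 1])
      pats <- sample_patterns_mcmc(model_s, spec$n_timepoints,
                                   burn_in = spec$mcmc_burn_in,
                                   thin = speed, seed = seeds[s, 2])
      colnames(pats) <- gm$node_names
      cont <- binary_to_continuous(pats, spec$snr, seed = seeds[s, 3])
      colnames(cont) <- gm$node_names
      dyn <- subject_dynamics(binary_time_series(pats, gm$node_names),
                              basins, templates)
      feats <- dyn$path_freq
      row <- list(subject_id = id, group = g)
      sym_noise <- with_seed(seeds[s, 4],
                             stats::rnorm(length(spec$symptom_slopes) + 3L))
      ni <- 0L
      for (sy_name in names(spec$symptom_slopes)) {
        sy <- spec$symptom_slopes[[sy_name]]
        ni <- ni + 1L
        in_group <- is.null(sy$groups) || g %in% sy$groups
        intercept <- if (is.null(sy$intercept)) 0 else sy$intercept
        row[[sy_name]] <- if (in_group) {
          intercept + sy$slope * feats[[sy$feature]] + sy$noise_sd * sym_noise[ni]
        } else NA_real_
      }
      if (!is.null(spec$mediation_plant)) {
        mp <- spec$mediation_plant
        xyz <- with_seed(seeds[s, 4] + 1L, stats::rnorm(3L))
        x <- xyz[1]
        m <- mp$alpha * x + xyz[2]
        y <- mp$gamma_prime * x + mp$beta * m + xyz[3]
        row$med_x <- x; row$med_m <- m; row$med_y <- y
      }
      manifest[[s]] <- row
      series[[id]] <- cont
      binary[[id]] <- pats
      features[[s]] <- c(list(subject_id = id, group = g, tau = tau,
                              speed = speed),
                         as.list(feats))
    }
  }
  manifest <- do.call(rbind, lapply(manifest, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  features <- do.call(rbind, lapply(features, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  structure(list(manifest = manifest, series = series, binary = binary,
                 truth = list(spec = spec, features = features,
                              group_landscapes = group_land)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects, %d groups, T=%d, N=%d\n",
              nrow(x$manifest), length(unique(x$manifest$group)),
              nrow(x$series[[1]]), ncol(x$series[[1]])))
  invisible(x)
}

#' Write / read a cohort directory
#'
#' A cohort directory holds `manifest.csv` (subject_id, group, symptom
#' columns), one `sub-<id>.tsv` per subject (T rows x N named columns of
#' continuous signals), and `truth.json` with the planted ground truth when
#' the cohort is synthetic.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir target directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  for (id in names(cohort$series)) {
    utils::write.table(cohort$series[[id]],
                       file.path(dir, paste0("sub-", id, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(cohort$truth)) {
    spec <- cohort$truth$spec
    truth <- list(
      n_nodes = spec$n_nodes, n_timepoints = spec$n_timepoints,
      snr = spec$snr, seed = spec$seed,
      steps_per_tr = as.list(spec$steps_per_tr),
      speed_jitter_sd = spec$speed_jitter_sd,
      subject_jitter_sd = spec$subject_jitter_sd,
      temperature_jitter_sd = spec$temperature_jitter_sd,
      tr_seconds = spec$tr_seconds,
      symptom_slopes = spec$symptom_slopes,
      mediation_plant = spec$mediation_plant,
      group_models = lapply(spec$group_models, function(m) {
        list(h = m$h, J = m$J, node_names = m$node_names)
      }),
      features = cohort$truth$features
    )
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @param dir cohort directory written by [write_cohort()] (or assembled by
#'   hand in the same layout).
#' @return `read_cohort()` returns a list with `manifest` and `series`; the
#'   planted truth, when present, is attached as `truth`.
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  series <- lapply(manifest$subject_id, function(id) {
    as.matrix(utils::read.table(file.path(dir, paste0("sub-", id, ".tsv")),
                                sep = "\t", header = TRUE, check.names = FALSE))
  })
  names(series) <- manifest$subject_id
  out <- list(manifest = manifest, series = series)
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) out$truth <- jsonlite::read_json(tj, simplifyVector = TRUE)
  out
}
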