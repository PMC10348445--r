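#' Pairwise maximum-entropy (Ising) model parameters
#'
#' Container for a maximum-entropy model over N binary network activities:
#' `h` holds the basal activity (field) of each node and `J` the symmetric
#' pairwise couplings with zero diagonal. `order = "first"` denotes the
#' independent model (`J = 0`); `order = "pairwise"` the full Ising model.
#' The energy of a pattern V is
#' \deqn{E(V) = -\sum_i h_i \sigma_i - \frac{1}{2}\sum_i\sum_j J_{ij}\sigma_i\sigma_j,}
#' the double sum running over all ordered pairs, and the model assigns V the
#' Boltzmann probability \eqn{P(V) = e^{-E(V)} / \sum_l e^{-E(V_l)}}.
#'
#' @param h numeric vector of node fields.
#' @param J symmetric numeric matrix of couplings with zero diagonal; may be
#'   omitted for a first-order model.
#' @param order `"pairwise"` or `"first"`.
#' @param node_names optional node labels.
#' @return an object of class `mem_parameters`.
#' @export
mem_parameters <- function(h, J = NULL, order = c("pairwise", "first"),
                           node_names = NULL) {
  order <- match.arg(order)
  h <- as.numeric(h)
  n <- length(h)
  check_n_nodes(n, enumerate = FALSE)
  if (is.null(J)) J <- matrix(0, n, n)
  J <- unname(as.matrix(J))
  if (!isTRUE(all.equal(dim(J), c(n, n)))) {
    stop("`J` must be ", n, " x ", n, call. = FALSE)
  }
  if (max(abs(J - t(J))) > 1e-10) stop("`J` must be symmetric", call. = FALSE)
  if (max(abs(diag(J))) > 1e-10) stop("`J` must have zero diagonal", call. = FALSE)
  if (order == "first" && max(abs(J)) > 1e-12) {
    stop("a first-order model must have J = 0", call. = FALSE)
  }
  J <- (J + t(J)) / 2
  diag(J) <- 0
  if (is.null(node_names)) node_names <- paste0("node", seq_len(n))
  structure(list(h = unname(h), J = J, order = order,
                 node_names = as.character(node_names), n_nodes = n),
            class = "mem_parameters")
}

#' @export
print.mem_parameters <- function(x, ...) {
  cat(sprintf("<mem_parameters> %s model, %d nodes\n", x$order, x$n_nodes))
  cat("  h:", paste(sprintf("%.3f", x$h), collapse = " "), "\n")
  cat(sprintf("  |J| max: %.3f\n", max(abs(x$J))))
  invisible(x)
}

#' Binarize continuous network signals
#'
#' Converts a timepoints x nodes matrix of continuous signals to +1/-1
#' activities. In the default `per-timepoint-mean` mode the threshold at time
#' t is the mean across nodes at that timepoint (the global-signal threshold
#' used when binarizing network-averaged rsfMRI data); in
#' `per-node-temporal-mean` mode each node is thresholded at its own temporal
#' mean. A signal strictly above threshold maps to +1, otherwise (including
#' exact ties) to -1.
#'
#' @param signals numeric T x N matrix, T >= 1, N >= 2, all entries finite.
#' @param mode thresholding mode.
#' @param node_names optional column labels; defaults to the matrix colnames.
#' @return a `binary_time_series`: list with `values` (T x N +1/-1 matrix)
#'   and `node_names`.
#' @export
binarize <- function(signals, mode = c("per-timepoint-mean",
                                       "per-node-temporal-mean"),
                     node_names = NULL) {
  mode <- match.arg(mode)
  signals <- as.matrix(signals)
  if (nrow(signals) < 1L || ncol(signals) < 2L) {
    stop("`signals` must have at least 1 row and 2 columns", call. = FALSE)
  }
  if (!all(is.finite(signals))) {
    stop("`signals` contains non-finite entries", call. = FALSE)
  }
  thr <- switch(mode,
    "per-timepoint-mean" = rowMeans(signals),
    "per-node-temporal-mean" = rep(colMeans(signals), each = nrow(signals))
  )
  values <- matrix(ifelse(signals > thr, 1L, -1L), nrow(signals), ncol(signals))
  if (is.null(node_names)) node_names <- colnames(signals)
  if (is.null(node_names)) node_names <- paste0("node", seq_len(ncol(signals)))
  binary_time_series(values, node_names)
}

#' @rdname binarize
#' @param values T x N matrix over +1/-1.
#' @export
binary_time_series <- function(values, node_names = NULL) {
  values <- as.matrix(values)
  check_spins(values)
  if (is.null(node_names)) node_names <- paste0("node", seq_len(ncol(values)))
  structure(list(values = unname(values), node_names = as.character(node_names)),
            class = "binary_time_series")
}

#' Empirical first- and second-order moments of binary series
#'
#' Computes the time-averaged node activities and pairwise products
#' \eqn{\langle\sigma_i\rangle, \langle\sigma_i\sigma_j\rangle} from one
#' binary series or a list of several (e.g., all subjects of a group). Series
#' are concatenated by simple row stacking, matching the group-level fitting
#' procedure in which binary data are pooled across participants.
#'
#' @param series a `binary_time_series`, a +1/-1 matrix, or a list of either.
#' @return a `moment_set`: list with `mean_activity` (length N),
#'   `pairwise` (N x N, unit diagonal) and `n_samples`.
#' @export
compute_empirical_moments <- function(series) {
  mats <- series_value_list(series)
  n <- unique(vapply(mats, ncol, integer(1)))
  if (length(n) != 1L) stop("node counts differ across series", call. = FALSE)
  x <- do.call(rbind, mats)
  if (nrow(x) < 1L) stop("need at least one timepoint", call. = FALSE)
  moment_set(colMeans(x), crossprod(x) / nrow(x), nrow(x))
}

series_value_list <- function(series) {
  as_vals <- function(s) {
    if (inherits(s, "binary_time_series")) s$values
    else { m <- as.matrix(s); check_spins(m); m }
  }
  if (is.list(series) && !inherits(series, "binary_time_series")) {
    lapply(series, as_vals)
  } else {
    list(as_vals(series))
  }
}

#' @rdname compute_empirical_moments
#' @param mean_activity length-N vector of first moments in `[-1, 1]`.
#' @param pairwise symmetric N x N matrix of second moments, unit diagonal.
#' @param n_samples number of timepoints the moments were estimated from.
#' @export
moment_set <- function(mean_activity, pairwise, n_samples = NA_integer_) {
  mean_activity <- as.numeric(mean_activity)
  pairwise <- unname(as.matrix(pairwise))
  n <- length(mean_activity)
  stopifnot(all(abs(mean_activity) <= 1 + 1e-12),
            all(dim(pairwise) == c(n, n)),
            max(abs(pairwise - t(pairwise))) < 1e-10,
            max(abs(diag(pairwise) - 1)) < 1e-10)
  structure(list(mean_activity = mean_activity, pairwise = pairwise,
                 n_samples = n_samples, n_nodes = n),
            class = "moment_set")
}

#' Energy of activity patterns under a maximum-entropy model
#'
#' @param pattern a +1/-1 vector, or a matrix of patterns (one per row).
#' @param params a [mem_parameters()] object.
#' @return energy value(s) `E(V)`.
#' @export
pattern_energy <- function(pattern, params) {
  stopifnot(inherits(params, "mem_parameters"))
  p <- if (is.matrix(pattern)) pattern else matrix(pattern, nrow = 1)
  check_spins(p)
  if (ncol(p) != params$n_nodes) {
    stop("pattern length does not match the model", call. = FALSE)
  }
  e <- -(p %*% params$h) - 0.5 * rowSums((p %*% params$J) * p)
  if (is.matrix(pattern)) as.numeric(e) else drop(e)
}

#' Boltzmann distribution over all activity patterns
#'
#' Exhaustively enumerates all `2^N` patterns and returns their appearance
#' probabilities \eqn{P(V_k) = e^{-E(V_k)} / \sum_l e^{-E(V_l)}}, normalized
#' with a log-sum-exp shift for numerical stability. Patterns are indexed by
#' code (see [all_patterns()] for the encoding).
#'
#' @param params a [mem_parameters()] object with at most
#'   `max_enumerable_nodes()` nodes.
#' @return a `pattern_distribution`: list with `probabilities` (length
#'   `2^N`, sums to 1) and `n_nodes`.
#' @export
boltzmann_distribution <- function(params) {
  stopifnot(inherits(params, "mem_parameters"))
  check_n_nodes(params$n_nodes)
  e <- pattern_energy(all_patterns(params$n_nodes), params)
  loge <- -e - max(-e)
  p <- exp(loge)
  pattern_distribution(p / sum(p))
}

#' @rdname boltzmann_distribution
#' @param probabilities nonnegative vector of length `2^N` summing to 1.
#' @export
pattern_distribution <- function(probabilities) {
  probabilities <- as.numeric(probabilities)
  n <- log2(length(probabilities))
  if (n != round(n)) stop("length must be a power of 2", call. = FALSE)
  if (any(probabilities < 0) || abs(sum(probabilities) - 1) > 1e-9) {
    stop("probabilities must be nonnegative and sum to 1", call. = FALSE)
  }
  structure(list(probabilities = probabilities, n_nodes = as.integer(n)),
            class = "pattern_distribution")
}

#' Exact model moments by enumeration
#'
#' Expectations \eqn{\langle\sigma_i\rangle_m} and
#' \eqn{\langle\sigma_i\sigma_j\rangle_m} under the model's Boltzmann
#' distribution, computed exactly over all `2^N` patterns.
#'
#' @inheritParams boltzmann_distribution
#' @return a [moment_set()].
#' @export
compute_model_moments <- function(params) {
  p <- boltzmann_distribution(params)$probabilities
  s <- all_patterns(params$n_nodes)
  m1 <- as.numeric(crossprod(s, p))
  m2 <- crossprod(s, p * s)
  m2 <- (m2 + t(m2)) / 2
  diag(m2) <- 1
  moment_set(m1, m2)
}

#' Fit the independent (first-order) maximum-entropy model
#'
#' The independent model matching given mean activities has closed form
#' `h_i = atanh(<sigma_i>)` and `J = 0`. Means are clamped to
#' `1 - 1e-9` in absolute value so saturated nodes stay finite.
#'
#' @param moments a [moment_set()].
#' @return a first-order [mem_parameters()].
#' @export
fit_independent_mem <- function(moments) {
  stopifnot(inherits(moments, "moment_set"))
  m <- pmin(pmax(moments$mean_activity, -1 + 1e-9), 1 - 1e-9)
  mem_parameters(atanh(m), order = "first")
}

#' Fit the pairwise maximum-entropy model by gradient ascent
#'
#' Starting from `h = 0, J = 0`, iterates
#' \deqn{h_i \leftarrow h_i + \epsilon(\langle\sigma_i\rangle -
#'   \langle\sigma_i\rangle_m), \quad
#'   J_{ij} \leftarrow J_{ij} + \epsilon(\langle\sigma_i\sigma_j\rangle -
#'   \langle\sigma_i\sigma_j\rangle_m)}
#' until the largest absolute moment gap falls below `tol` or `max_iter` is
#' reached. Model moments are recomputed exactly at each step by enumeration,
#' so the fit maximizes likelihood within the pairwise family. `J` stays
#' symmetric with zero diagonal throughout.
#'
#' A warning is emitted when the moments come from fewer than `2^(N-1)`
#' timepoints, below which moment estimates are generally too noisy for an
#' accurate fit; the threshold is configurable via `min_samples`.
#'
#' @param moments a [moment_set()].
#' @param learning_rate gradient step size epsilon.
#' @param tol convergence tolerance on the max absolute moment gap.
#' @param max_iter iteration cap; non-convergence is flagged, not an error.
#' @param min_samples sample-size warning threshold; default `2^(N-1)`.
#' @return list with `params` (a pairwise [mem_parameters()]) and
#'   `diagnostics` (`converged`, `n_iterations`, `max_moment_gap`).
#' @export
fit_pairwise_mem <- function(moments, learning_rate = 0.2, tol = 1e-8,
                             max_iter = 5e5, min_samples = NULL) {
  stopifnot(inherits(moments, "moment_set"), learning_rate > 0, tol > 0)
  n <- moments$n_nodes
  check_n_nodes(n)
  if (is.null(min_samples)) min_samples <- 2^(n - 1)
  if (!is.na(moments$n_samples) && moments$n_samples < min_samples) {
    warning(sprintf(
      "moments estimated from %d timepoints; fewer than %d may be too noisy",
      moments$n_samples, as.integer(min_samples)), call. = FALSE)
  }
  s <- all_patterns(n)
  st <- t(s)
  target1 <- moments$mean_activity
  target2 <- moments$pairwise
  h <- numeric(n)
  J <- matrix(0, n, n)
  gap <- Inf
  iter <- 0L
  off <- diag(n) == 0
  while (iter < max_iter) {
    e <- -(s %*% h) - 0.5 * rowSums((s %*% J) * s)
    w <- exp(-e - max(-e))
    p <- as.numeric(w / sum(w))
    m1 <- as.numeric(st %*% p)
    m2 <- st %*% (p * s)
    g1 <- target1 - m1
    g2 <- target2 - m2
    gap <- max(max(abs(g1)), max(abs(g2[off])))
    iter <- iter + 1L
    if (gap < tol) break
    h <- h + learning_rate * g1
    J <- J + learning_rate * (g2 + t(g2)) / 2
    diag(J) <- 0
  }
  params <- mem_parameters(h, J, order = "pairwise")
  list(params = params,
       diagnostics = list(converged = gap < tol, n_iterations = iter,
                          max_moment_gap = gap))
}

#' Empirical distribution over pattern codes
#'
#' Relative frequency of each of the `2^N` pattern codes in a binary series.
#'
#' @param series a `binary_time_series` or +1/-1 matrix.
#' @return a [pattern_distribution()].
#' @export
empirical_pattern_distribution <- function(series) {
  x <- series_value_list(series)
  x <- do.call(rbind, x)
  n <- ncol(x)
  check_n_nodes(n)
  codes <- pattern_to_code(x)
  counts <- tabulate(codes + 1L, nbins = 2^n)
  pattern_distribution(counts / sum(counts))
}

#' Kullback-Leibler divergence between pattern distributions
#'
#' \eqn{D(p\Vert q) = \sum_k p_k \log(p_k/q_k)} in nats, with
#' `0 log 0 = 0`. `q` must be strictly positive wherever `p` is positive
#' (always true for a Boltzmann distribution).
#'
#' @param p,q [pattern_distribution()] objects of equal length.
#' @return nonnegative divergence.
#' @export
kl_divergence <- function(p, q) {
  stopifnot(inherits(p, "pattern_distribution"),
            inherits(q, "pattern_distribution"))
  pp <- p$probabilities
  qq <- q$probabilities
  if (length(pp) != length(qq)) stop("distribution sizes differ", call. = FALSE)
  pos <- pp > 0
  if (any(qq[pos] <= 0)) {
    stop("q must be positive wherever p is positive", call. = FALSE)
  }
  sum(pp[pos] * log(pp[pos] / qq[pos]))
}

#' Model fit accuracy from KL divergences
#'
#' Quantifies how much of the structure missed by the independent model is
#' captured by the pairwise model: with `D1 = KL(empirical || first-order)`
#' and `D2 = KL(empirical || pairwise)`, the accuracy is `(D1 - D2) / D1`,
#' also reported as a percentage. When `D1` falls below `1e-12` (e.g., a
#' uniform empirical distribution fit perfectly by both models) the accuracy
#' is undefined and flagged.
#'
#' @param empirical a [pattern_distribution()] of observed pattern codes.
#' @param first_order a first-order [mem_parameters()].
#' @param pairwise a pairwise [mem_parameters()].
#' @return list with `d1`, `d2`, `accuracy`, `accuracy_pct`, `defined`.
#' @export
fit_accuracy <- function(empirical, first_order, pairwise) {
  d1 <- kl_divergence(empirical, boltzmann_distribution(first_order))
  d2 <- kl_divergence(empirical, boltzmann_distribution(pairwise))
  defined <- d1 > 1e-12
  acc <- if (defined) (d1 - d2) / d1 else NA_real_
  list(d1 = d1, d2 = d2, accuracy = acc, accuracy_pct = 100 * acc,
       defined = defined)
}

#' Export / import a fitted model as JSON
#'
#' @param params a [mem_parameters()].
#' @param path file path.
#' @param fit optional fit diagnostics list to embed.
#' @export
write_mem_json <- function(params, path, fit = NULL) {
  stopifnot(inherits(params, "mem_parameters"))
  obj <- list(node_names = params$node_names, h = params$h, J = params$J,
              order = params$order)
  if (!is.null(fit)) obj$fit <- fit
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_mem_json
#' @export
read_mem_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mem_parameters(obj$h, obj$J, order = obj$order, node_names = obj$node_names)
}
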