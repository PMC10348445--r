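#' Metropolis-Hastings random walk on the energy landscape
#'
#' Simulates brain-state dynamics as a single-flip Markov chain Monte Carlo
#' walk over activity patterns. At each step one of the N single-flip
#' neighbours of the current pattern is proposed uniformly at random and
#' accepted with probability \eqn{\min[1, e^{E(V_i) - E(V_j)}]}, so downhill
#' moves are always taken while uphill moves remain possible; a rejected
#' proposal repeats the current pattern. The stationary distribution is the
#' model's Boltzmann distribution. The walk starts from a uniformly random
#' pattern (or `start_code`) and the first `burn_in` steps are discarded to
#' reduce the influence of the initial condition.
#'
#' @param params a [mem_parameters()].
#' @param n_steps total number of steps simulated (default `1e5`).
#' @param burn_in number of leading steps dropped (default 100), so the
#'   returned trajectory has `n_steps - burn_in` entries.
#' @param seed integer seed; the walk is reproducible given the seed.
#' @param start_code optional initial pattern code; default random.
#' @return a `pattern_trajectory`: list with `codes` (visited pattern codes
#'   after burn-in), `n_nodes`, `n_steps`, `burn_in`, `seed`.
#' @export
metropolis_random_walk <- function(params, n_steps = 1e5, burn_in = 100,
                                   seed = 1L, start_code = NULL) {
  stopifnot(inherits(params, "mem_parameters"),
            n_steps > burn_in, burn_in >= 0)
  n <- params$n_nodes
  check_n_nodes(n)
  codes <- with_seed(seed, {
    if (is.null(start_code)) start_code <- sample.int(2^n, 1L) - 1L
    mh_walk_cpp(params$h, params$J, as.integer(n_steps),
                as.integer(start_code))
  })
  structure(list(codes = codes[(burn_in + 1L):n_steps], n_nodes = n,
                 n_steps = as.integer(n_steps), burn_in = as.integer(burn_in),
                 seed = as.integer(seed)),
            class = "pattern_trajectory")
}

#' Classify patterns into brain states
#'
#' Maps every visited pattern of a trajectory (or every row of a binary time
#' series) to the brain-state label of its basin. Saddle-ambiguous patterns
#' map to `NA` and are dropped, with the dropped count recorded in the
#' `n_dropped` attribute.
#'
#' @param x a `pattern_trajectory`, `binary_time_series`, +1/-1 matrix, or
#'   integer vector of pattern codes.
#' @param basins an [assign_basins()] result.
#' @param drop_ambiguous map saddle-ambiguous patterns to `NA` and drop them
#'   (default `TRUE`); otherwise they keep their tie-broken basin.
#' @return a `state_sequence`: character vector of uppercase state labels
#'   with attributes `states` (full label set) and `n_dropped`.
#' @export
patterns_to_states <- function(x, basins, drop_ambiguous = TRUE) {
  stopifnot(inherits(basins, "basin_map"))
  codes <- if (inherits(x, "pattern_trajectory")) x$codes
    else if (inherits(x, "binary_time_series")) pattern_to_code(x$values)
    else if (is.matrix(x)) pattern_to_code(x)
    else as.integer(x)
  lab <- toupper(basins$assignment[codes + 1L])
  if (drop_ambiguous) lab[basins$ambiguous[codes + 1L]] <- NA_character_
  n_dropped <- sum(is.na(lab))
  lab <- lab[!is.na(lab)]
  state_sequence(lab, states = toupper(basins$minima$label),
                 n_dropped = n_dropped)
}

#' @rdname patterns_to_states
#' @param labels character vector of state labels.
#' @param states full set of possible states.
#' @param n_dropped count of patterns dropped before constructing the
#'   sequence.
#' @export
state_sequence <- function(labels, states = sort(unique(labels)),
                           n_dropped = 0L) {
  labels <- as.character(labels)
  if (!all(labels %in% states)) {
    stop("sequence contains labels outside the state set", call. = FALSE)
  }
  structure(labels, states = states, n_dropped = as.integer(n_dropped),
            class = "state_sequence")
}

#' Run-length compression of a state sequence
#'
#' Merges consecutive identical states into runs, preserving durations; the
#' duration of a run is the dwelling time of that brain state.
#'
#' @param seq a `state_sequence` or character vector.
#' @return data frame with columns `state` and `duration`; durations sum to
#'   the sequence length.
#' @export
compress_runs <- function(seq) {
  if (length(seq) == 0L) stop("empty state sequence", call. = FALSE)
  r <- rle(as.character(seq))
  data.frame(state = r$values, duration = r$lengths, stringsAsFactors = FALSE)
}

#' Transition and dwell-time statistics of a state sequence
#'
#' Counts transitions between distinct consecutive states, normalizes them
#' per step of the uncompressed sequence (so short empirical scans and long
#' simulated walks are on a common scale), and summarizes dwelling times per
#' state from the run-length compression.
#'
#' @param seq a `state_sequence` (length >= 2).
#' @param states state label set; defaults to the sequence's `states`
#'   attribute.
#' @return a `transition_summary`: list with `transition_counts` and
#'   `transition_freq` (K x K matrices, zero diagonal), `dwell` (per-state
#'   mean/median/count of dwelling times), `n_steps` (sequence length).
#' @export
transition_statistics <- function(seq, states = NULL) {
  if (is.null(states)) states <- attr(seq, "states")
  if (is.null(states)) states <- sort(unique(as.character(seq)))
  x <- as.character(seq)
  if (length(x) < 2L) stop("need at least two entries", call. = FALSE)
  k <- length(states)
  counts <- matrix(0L, k, k, dimnames = list(from = states, to = states))
  from <- x[-length(x)]
  to <- x[-1L]
  move <- from != to
  if (any(move)) {
    tab <- table(factor(from[move], states), factor(to[move], states))
    counts <- counts + unclass(tab)
  }
  runs <- compress_runs(x)
  dwell <- do.call(rbind, lapply(states, function(s) {
    d <- runs$duration[runs$state == s]
    data.frame(state = s, n_visits = length(d),
               mean_dwell = if (length(d)) mean(d) else NA_real_,
               median_dwell = if (length(d)) stats::median(d) else NA_real_,
               total_dwell = sum(d), stringsAsFactors = FALSE)
  }))
  structure(list(transition_counts = counts,
                 transition_freq = counts / (length(x) - 1L),
                 dwell = dwell, n_steps = length(x), states = states),
            class = "transition_summary")
}

#' Indirect-transition path templates
#'
#' A path template describes an indirect transition between the two most
#' stable brain states via prescribed intermediates: an unordered endpoint
#' pair (e.g., `A` and `B`) and an ordered list of interior blocks, each a
#' set of admissible states. A match is a segment of the run-compressed
#' sequence that starts at one endpoint, ends at the other, and whose
#' interior runs decompose into consecutive nonempty groups drawn from the
#' blocks in order (block order is reversed when the segment is traversed
#' from the second endpoint to the first, so both directions count).
#'
#' `canonical_templates()` returns the three templates studied for a
#' six-state landscape: `A-C/D-B` (via state C or D), `A-[C/D-E/F]-B` (a
#' C/D block then an E/F block), and `A-C-F-B` (via C then F).
#'
#' @param endpoints character vector of the two endpoint states.
#' @param blocks list of character vectors, the ordered interior blocks.
#' @param name optional template name.
#' @return a `path_template` object.
#' @export
path_template <- function(endpoints, blocks, name = NULL) {
  endpoints <- as.character(endpoints)
  stopifnot(length(endpoints) == 2L, endpoints[1] != endpoints[2],
            length(blocks) >= 1L)
  blocks <- lapply(blocks, as.character)
  if (any(unlist(blocks) %in% endpoints)) {
    stop("endpoint states may not appear in interior blocks", call. = FALSE)
  }
  if (is.null(name)) {
    name <- paste0(endpoints[1], "-",
                   paste(vapply(blocks, paste, "", collapse = "/"),
                         collapse = "-"), "-", endpoints[2])
  }
  structure(list(endpoints = endpoints, blocks = blocks, name = name),
            class = "path_template")
}

#' @rdname path_template
#' @export
canonical_templates <- function() {
  list(
    freq_ACDB = path_template(c("A", "B"), list(c("C", "D")), "A-C/D-B"),
    freq_ACDEFB = path_template(c("A", "B"), list(c("C", "D"), c("E", "F")),
                                "A-[C/D-E/F]-B"),
    freq_ACFB = path_template(c("A", "B"), list("C", "F"), "A-C-F-B")
  )
}

# Can runs `labs` be split into consecutive nonempty groups matching `blocks`
# in order? Dynamic programme over (run index, block index).
runs_match_blocks <- function(labs, blocks) {
  m <- length(labs)
  k <- length(blocks)
  if (m < k || m == 0L) return(FALSE)
  # ok[i, g]: runs i..m can be decomposed into blocks g..k
  ok <- matrix(FALSE, m + 1L, k + 1L)
  ok[m + 1L, k + 1L] <- TRUE
  for (g in k:1) {
    set <- blocks[[g]]
    for (i in m:1) {
      if (labs[i] %in% set && (ok[i + 1L, g + 1L] || ok[i + 1L, g])) {
        ok[i, g] <- TRUE
      }
    }
  }
  ok[1L, 1L]
}

#' Count indirect transitions matching a path template
#'
#' Scans the run-compressed state sequence for segments bounded by the two
#' template endpoints whose interior decomposes into the template's ordered
#' blocks; both traversal directions are counted (the block order is reversed
#' for the return direction). The frequency is the count divided by the
#' number of steps of the uncompressed sequence (its length minus one).
#'
#' @param seq a `state_sequence`.
#' @param template a [path_template()].
#' @param directions `"both"` (default) or `"forward"` (endpoint 1 to
#'   endpoint 2 only).
#' @return list with `count`, `frequency`, `template`.
#' @export
count_path_transitions <- function(seq, template, directions = c("both", "forward")) {
  directions <- match.arg(directions)
  stopifnot(inherits(template, "path_template"))
  states <- attr(seq, "states")
  if (!is.null(states)) {
    unknown <- setdiff(c(template$endpoints, unlist(template$blocks)), states)
    if (length(unknown)) {
      stop("template uses unknown states: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  x <- as.character(seq)
  runs <- compress_runs(x)
  ep <- template$endpoints
  idx <- which(runs$state %in% ep)
  count <- 0L
  if (length(idx) >= 2L) {
    rev_blocks <- rev(template$blocks)
    for (t in seq_len(length(idx) - 1L)) {
      i <- idx[t]; j <- idx[t + 1L]
      if (j <= i + 1L) next                 # direct transition, no interior
      if (runs$state[i] == runs$state[j]) next  # excursion returning home
      interior <- runs$state[(i + 1L):(j - 1L)]
      blocks <- if (runs$state[i] == ep[1]) template$blocks else rev_blocks
      if (runs$state[i] != ep[1] && directions == "forward") next
      if (runs_match_blocks(interior, blocks)) count <- count + 1L
    }
  }
  list(count = count, frequency = count / (length(x) - 1L),
       template = template$name)
}

#' Per-subject dynamics features from an empirical binary series
#'
#' Chains pattern classification, transition statistics and indirect-path
#' counting for one subject's binary time series, yielding the per-subject
#' dynamics features (path frequencies, dwell times) used in symptom
#' correlation analyses.
#'
#' @param series a `binary_time_series` (or +1/-1 matrix).
#' @param basins an [assign_basins()] result from the subject's group-level
#'   landscape.
#' @param templates list of [path_template()]s; default
#'   [canonical_templates()].
#' @return list with `states`, `summary` (a `transition_summary`) and
#'   `path_freq` (named vector of per-step template frequencies).
#' @export
subject_dynamics <- function(series, basins, templates = canonical_templates()) {
  states <- patterns_to_states(series, basins)
  summ <- transition_statistics(states)
  pf <- vapply(templates, function(tp) {
    needed <- c(tp$endpoints, unlist(tp$blocks))
    if (!all(needed %in% attr(states, "states"))) return(NA_real_)
    count_path_transitions(states, tp)$frequency
  }, numeric(1))
  list(states = states, summary = summ, path_freq = pf)
}

#' Sample temporally correlated patterns with the Metropolis walker
#'
#' Draws binary patterns whose marginal distribution converges to the
#' model's Boltzmann distribution but which retain the Markov-chain temporal
#' correlation of the walk; thinning reduces that correlation.
#'
#' @inheritParams metropolis_random_walk
#' @param n_samples number of patterns returned.
#' @param thin keep every `thin`-th step after burn-in (default 1).
#' @return `n_samples x N` matrix of +1/-1.
#' @export
sample_patterns_mcmc <- function(params, n_samples, burn_in = 100, thin = 1,
                                 seed = 1L) {
  stopifnot(n_samples >= 0, burn_in >= 0, thin >= 1)
  if (n_samples == 0L) {
    return(matrix(integer(0), 0, params$n_nodes))
  }
  total <- burn_in + n_samples * thin
  traj <- metropolis_random_walk(params, n_steps = total, burn_in = burn_in,
                                 seed = seed)
  codes <- traj$codes[seq.int(thin, n_samples * thin, by = thin)]
  out <- code_to_pattern(codes, params$n_nodes)
  if (!is.matrix(out)) out <- matrix(out, nrow = 1)
  out
}
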