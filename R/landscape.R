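#' Enumerate the energy landscape of a fitted model
#'
#' Computes the energy of every one of the `2^N` activity patterns. Patterns
#' are nodes of a hypercube graph in which two patterns are adjacent when
#' they differ in exactly one network activity; this adjacency underlies the
#' local-minimum search, basin assignment and disconnectivity analysis.
#'
#' @param params a [mem_parameters()] with at most `max_enumerable_nodes()`
#'   nodes.
#' @return an `energy_landscape`: list with `n_nodes`, `energies`
#'   (length `2^N`, indexed by pattern code + 1) and `params`.
#' @export
enumerate_energies <- function(params) {
  stopifnot(inherits(params, "mem_parameters"))
  check_n_nodes(params$n_nodes)
  e <- pattern_energy(all_patterns(params$n_nodes), params)
  structure(list(n_nodes = params$n_nodes, energies = e, params = params),
            class = "energy_landscape")
}

#' @export
print.energy_landscape <- function(x, ...) {
  cat(sprintf("<energy_landscape> %d nodes, %d patterns, energies [%.3f, %.3f]\n",
              x$n_nodes, length(x$energies), min(x$energies), max(x$energies)))
  invisible(x)
}

#' Local minima of an energy landscape
#'
#' A local minimum is a pattern whose energy is strictly smaller than those
#' of all N single-flip neighbours. Minima are labelled `a`, `b`, ... in
#' ascending energy order (ties broken by pattern code); these labels also
#' name the corresponding brain states `A`, `B`, ... .
#'
#' @param landscape an [enumerate_energies()] result.
#' @return data frame with columns `label`, `code`, `energy` and a `pattern`
#'   matrix column (+1/-1 rows).
#' @export
find_local_minima <- function(landscape) {
  stopifnot(inherits(landscape, "energy_landscape"))
  e <- landscape$energies
  nb <- neighbor_codes(landscape$n_nodes) + 1L
  nb_min <- apply(matrix(e[nb], nrow = nrow(nb)), 1, min)
  codes <- which(e < nb_min) - 1L
  ord <- order(e[codes + 1L], codes)
  codes <- codes[ord]
  out <- data.frame(label = letters[seq_along(codes)], code = codes,
                    energy = e[codes + 1L], stringsAsFactors = FALSE)
  pat <- code_to_pattern(codes, landscape$n_nodes)
  if (!is.matrix(pat)) {
    pat <- matrix(pat, nrow = length(codes), ncol = landscape$n_nodes,
                  byrow = TRUE)
  }
  out$pattern <- pat
  out
}

#' Assign every pattern to the basin of a local minimum
#'
#' Performs a deterministic steepest-descent walk from each pattern: at each
#' step move to the neighbour with the largest energy drop, breaking exact
#' ties by lowest pattern code, until a local minimum is reached. The basin
#' (attractor) of a minimum is the set of patterns whose walk ends there;
#' basins are the brain states of the analysis. Patterns at which two or more
#' neighbours tie exactly for the steepest descent are flagged
#' saddle-ambiguous; they still receive the tie-broken assignment but can be
#' excluded downstream.
#'
#' @param landscape an [enumerate_energies()] result.
#' @param minima a [find_local_minima()] result for the same landscape.
#' @return a `basin_map`: list with `assignment` (length `2^N` factor of
#'   minimum labels), `ambiguous` (logical flags), `minima`, and
#'   `state_labels` (uppercase state names, one per minimum).
#' @export
assign_basins <- function(landscape, minima) {
  stopifnot(inherits(landscape, "energy_landscape"))
  if (nrow(minima) == 0L) stop("landscape has no local minima", call. = FALSE)
  e <- landscape$energies
  n_pat <- length(e)
  nb <- neighbor_codes(landscape$n_nodes) + 1L
  assignment <- rep(NA_character_, n_pat)
  ambiguous <- logical(n_pat)
  assignment[minima$code + 1L] <- minima$label
  # ascending-energy processing: the steepest neighbour of any non-minimum
  # has strictly lower energy, hence is already assigned
  ord <- order(e, seq_len(n_pat))
  for (idx in ord) {
    if (!is.na(assignment[idx])) next
    nbr <- nb[idx, ]
    ne <- e[nbr]
    best <- min(ne)
    cand <- nbr[ne == best]
    ambiguous[idx] <- length(cand) > 1L
    assignment[idx] <- assignment[min(cand)]
  }
  structure(list(assignment = assignment, ambiguous = ambiguous,
                 minima = minima, state_labels = toupper(minima$label),
                 descent_rule = "steepest-descent, lowest-code tie-break"),
            class = "basin_map")
}

#' Disconnectivity graph of the local minima
#'
#' Summarizes the hierarchy between local minima as a tree whose leaves are
#' the minima and whose internal nodes record the threshold energy at which
#' two groups of minima first become mutually reachable. Equivalent to the
#' descending-threshold procedure (remove all patterns above a threshold,
#' lower it stepwise, record when minima disconnect): here patterns are
#' inserted in ascending energy order into a union-find structure, unioned
#' with already-inserted neighbours, and a merge event is recorded at the
#' energy of the pattern whose insertion first connects two minima-bearing
#' components.
#'
#' @inheritParams assign_basins
#' @return a `disconnectivity_tree`: list with `leaves` (the minima table),
#'   `merges` (matrix in [stats::hclust()] convention: negative entries are
#'   leaf indices, positive entries earlier merge rows) and `merge_energies`.
#' @export
build_disconnectivity_tree <- function(landscape, minima) {
  stopifnot(inherits(landscape, "energy_landscape"))
  if (nrow(minima) == 0L) stop("landscape has no local minima", call. = FALSE)
  e <- landscape$energies
  n_pat <- length(e)
  nb <- neighbor_codes(landscape$n_nodes) + 1L
  parent <- seq_len(n_pat)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  # cluster id carried by each union-find root: 0 = no minimum inside,
  # -k = leaf k alone, +m = tree node created by merge row m
  cluster <- integer(n_pat)
  is_min_leaf <- integer(n_pat)
  is_min_leaf[minima$code + 1L] <- seq_len(nrow(minima))
  inserted <- logical(n_pat)
  ord <- order(e, seq_len(n_pat))
  n_merge <- nrow(minima) - 1L
  merges <- matrix(0L, n_merge, 2)
  heights <- numeric(n_merge)
  m_row <- 0L
  for (idx in ord) {
    inserted[idx] <- TRUE
    if (is_min_leaf[idx] > 0L) cluster[idx] <- -is_min_leaf[idx]
    for (j in nb[idx, ]) {
      if (!inserted[j]) next
      ra <- find(idx); rb <- find(j)
      if (ra == rb) next
      ca <- cluster[ra]; cb <- cluster[rb]
      parent[ra] <- rb
      r <- rb
      if (ca != 0L && cb != 0L) {
        m_row <- m_row + 1L
        merges[m_row, ] <- c(ca, cb)
        heights[m_row] <- e[idx]
        cluster[r] <- m_row
      } else {
        cluster[r] <- if (ca != 0L) ca else cb
      }
    }
    if (m_row == n_merge) break
  }
  structure(list(leaves = minima, merges = merges, merge_energies = heights),
            class = "disconnectivity_tree")
}

#' @export
print.disconnectivity_tree <- function(x, ...) {
  cat(sprintf("<disconnectivity_tree> %d local minima, %d merges\n",
              nrow(x$leaves), nrow(x$merges)))
  if (nrow(x$merges) > 0) {
    cat("  merge energies:",
        paste(sprintf("%.3f", x$merge_energies), collapse = " "), "\n")
  }
  invisible(x)
}

#' Basin sizes of a basin map
#'
#' @param basins an [assign_basins()] result.
#' @param drop_ambiguous exclude saddle-ambiguous patterns from the counts.
#' @return named integer vector of basin sizes per minimum label.
#' @export
basin_sizes <- function(basins, drop_ambiguous = FALSE) {
  stopifnot(inherits(basins, "basin_map"))
  keep <- if (drop_ambiguous) !basins$ambiguous else rep(TRUE, length(basins$assignment))
  table(factor(basins$assignment[keep], levels = basins$minima$label))
}

#' Newick representation of a disconnectivity tree
#'
#' Branch lengths place each node at a depth equal to its (merge) energy, so
#' standard tree viewers reproduce the disconnectivity-graph layout.
#'
#' @param tree a [build_disconnectivity_tree()] result.
#' @return a Newick string.
#' @export
disconnectivity_newick <- function(tree) {
  stopifnot(inherits(tree, "disconnectivity_tree"))
  lv <- tree$leaves
  if (nrow(tree$merges) == 0L) return(paste0(lv$label[1], ";"))
  node_str <- function(id, parent_h) {
    if (id < 0) {
      k <- -id
      sprintf("%s:%g", lv$label[k], parent_h - lv$energy[k])
    } else {
      h <- tree$merge_energies[id]
      kids <- vapply(tree$merges[id, ], node_str, "", parent_h = h)
      sprintf("(%s):%g", paste(kids, collapse = ","), parent_h - h)
    }
  }
  root <- nrow(tree$merges)
  h <- tree$merge_energies[root]
  kids <- vapply(tree$merges[root, ], node_str, "", parent_h = h)
  sprintf("(%s);", paste(kids, collapse = ","))
}

#' Export a landscape summary as JSON
#'
#' @param landscape an [enumerate_energies()] result.
#' @param basins an [assign_basins()] result.
#' @param tree a [build_disconnectivity_tree()] result.
#' @param path file path.
#' @param include_energies write the full energy vector (large for big N).
#' @export
write_landscape_json <- function(landscape, basins, tree, path,
                                 include_energies = TRUE) {
  mm <- basins$minima
  obj <- list(
    n_nodes = landscape$n_nodes,
    minima = lapply(seq_len(nrow(mm)), function(k) {
      list(label = mm$label[k], code = mm$code[k], energy = mm$energy[k],
           pattern = as.integer(mm$pattern[k, ]))
    }),
    basin_assignment = basins$assignment,
    ambiguous_count = sum(basins$ambiguous),
    tree = list(merges = tree$merges, merge_energies = tree$merge_energies,
                newick = disconnectivity_newick(tree))
  )
  if (include_energies) obj$energies <- landscape$energies
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
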