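# Independent brute-force oracles used across tests. These deliberately
# avoid the package's vectorized code paths: everything is plain loops on
# +1/-1 pattern vectors.

# Energy computed directly from the double-sum definition.
oracle_energy <- function(pattern, h, J) {
  n <- length(pattern)
  e <- -sum(h * pattern)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      e <- e - 0.5 * J[i, j] * pattern[i] * pattern[j]
    }
  }
  e
}

oracle_pattern <- function(code, n) {
  p <- integer(n)
  for (i in seq_len(n)) {
    p[i] <- if (bitwAnd(bitwShiftR(code, i - 1L), 1L) == 1L) 1L else -1L
  }
  p
}

oracle_neighbors <- function(code, n) {
  vapply(seq_len(n), function(i) bitwXor(code, bitwShiftL(1L, i - 1L)), 0L)
}

# Local minima by a direct neighbour scan.
oracle_minima <- function(energies, n) {
  codes <- 0:(2^n - 1)
  mins <- c()
  for (k in codes) {
    ne <- energies[oracle_neighbors(k, n) + 1L]
    if (all(energies[k + 1L] < ne)) mins <- c(mins, k)
  }
  mins
}

# Basin of each pattern by literally following the steepest-descent rule
# (largest drop, lowest code on ties) one step at a time.
oracle_basins <- function(energies, n) {
  codes <- 0:(2^n - 1)
  mins <- oracle_minima(energies, n)
  sapply(codes, function(k) {
    cur <- k
    repeat {
      nb <- oracle_neighbors(cur, n)
      ne <- energies[nb + 1L]
      if (min(ne) >= energies[cur + 1L]) return(cur)
      cand <- nb[ne == min(ne)]
      cur <- min(cand)
    }
  })
}

# Literal implementation of the descending-threshold disconnectivity
# procedure: prepare the hypercube graph, lower a threshold through the
# sorted energy values, delete patterns above it, and record for each pair
# of minima the smallest threshold at which they remain connected.
oracle_merge_energies <- function(energies, n) {
  mins <- oracle_minima(energies, n)
  k <- length(mins)
  if (k < 2) return(matrix(numeric(0), 0, 0))
  merge <- matrix(NA_real_, k, k)
  thresholds <- sort(unique(energies), decreasing = TRUE)
  for (thr in thresholds) {
    keep <- which(energies <= thr) - 1L
    present <- mins[mins %in% keep]
    if (length(present) < 2) break
    comp <- oracle_components(keep, n)
    for (a in 1:(k - 1)) {
      for (b in (a + 1):k) {
        if (!(mins[a] %in% present) || !(mins[b] %in% present)) next
        if (comp[as.character(mins[a])] == comp[as.character(mins[b])]) {
          merge[a, b] <- merge[b, a] <- thr
        }
      }
    }
    # stop once every remaining pair of minima is mutually isolated
    if (all(table(comp[as.character(present)]) == 1)) break
  }
  rownames(merge) <- colnames(merge) <- as.character(mins)
  merge
}

# Connected components of the hypercube restricted to `keep` codes (BFS).
# Returns an integer vector indexed by code + 1 (0 = removed), plus a named
# view restricted to `keep` for the merge oracle.
oracle_components <- function(keep, n) {
  total <- 2^n
  inside <- logical(total)
  inside[keep + 1L] <- TRUE
  comp_all <- integer(total)
  cid <- 0L
  for (start in keep) {
    if (comp_all[start + 1L] != 0L) next
    cid <- cid + 1L
    queue <- start
    comp_all[start + 1L] <- cid
    while (length(queue)) {
      cur <- queue[[1]]
      queue <- queue[-1]
      for (nb in oracle_neighbors(cur, n)) {
        if (inside[nb + 1L] && comp_all[nb + 1L] == 0L) {
          comp_all[nb + 1L] <- cid
          queue <- c(queue, nb)
        }
      }
    }
  }
  stats::setNames(comp_all[keep + 1L], as.character(keep))
}

# Pairwise merge energy of two leaves from the package's tree (height of
# their lowest common ancestor in the merge table).
tree_pair_merge <- function(tree) {
  k <- nrow(tree$leaves)
  below <- list()
  out <- matrix(NA_real_, k, k)
  for (m in seq_len(nrow(tree$merges))) {
    kids <- tree$merges[m, ]
    leaves_of <- function(id) if (id < 0) -id else below[[id]]
    l1 <- leaves_of(kids[1]); l2 <- leaves_of(kids[2])
    for (a in l1) for (b in l2) {
      out[a, b] <- out[b, a] <- tree$merge_energies[m]
    }
    below[[m]] <- c(l1, l2)
  }
  rownames(out) <- colnames(out) <- as.character(tree$leaves$code)
  out
}

# A small random state sequence over given labels.
random_state_seq <- function(n, states, seed) {
  withr::with_seed(seed, sample(states, n, replace = TRUE))
}

# All permutations of 1..n (tiny n only), for exhaustive assignment oracles.
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- NULL
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}
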