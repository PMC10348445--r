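#' Pattern codes and binary activity patterns
#'
#' Binary activity patterns over `n_nodes` networks are vectors of +1/-1
#' spins. Each pattern is identified by an integer code in `0:(2^n_nodes - 1)`
#' using a fixed encoding: node 1 is the least-significant bit, with spin -1
#' stored as bit 0 and spin +1 as bit 1. All landscape, sampler and counting
#' functions in the package share this encoding.
#'
#' @param n_nodes number of network nodes (spins); must be at least 2 and at
#'   most `max_enumerable_nodes()` for functions that enumerate all patterns.
#' @return `all_patterns()` returns a `2^n_nodes x n_nodes` matrix of +1/-1
#'   whose row `k + 1` is the pattern with code `k`.
#' @examples
#' all_patterns(3)
#' pattern_to_code(c(1, -1, 1))  # bits 101 -> 5
#' code_to_pattern(5, 3)
#' @export
all_patterns <- function(n_nodes) {
  check_n_nodes(n_nodes)
  codes <- 0:(2^n_nodes - 1)
  bits <- outer(codes, 0:(n_nodes - 1), function(k, b) bitwAnd(bitwShiftR(k, b), 1L))
  matrix(2L * bits - 1L, nrow = length(codes), ncol = n_nodes)
}

#' @rdname all_patterns
#' @param code integer pattern code(s) in `0:(2^n_nodes - 1)`.
#' @export
code_to_pattern <- function(code, n_nodes) {
  check_n_nodes(n_nodes)
  stopifnot(all(code >= 0), all(code < 2^n_nodes))
  bits <- outer(as.integer(code), 0:(n_nodes - 1),
                function(k, b) bitwAnd(bitwShiftR(k, b), 1L))
  out <- matrix(2L * bits - 1L, nrow = length(code), ncol = n_nodes)
  if (length(code) == 1L) drop(out) else out
}

#' @rdname all_patterns
#' @param pattern a +1/-1 vector, or a matrix with one pattern per row.
#' @export
pattern_to_code <- function(pattern) {
  if (is.matrix(pattern)) {
    check_spins(pattern)
    n <- ncol(pattern)
    as.integer((pattern == 1) %*% 2^(0:(n - 1)))
  } else {
    check_spins(pattern)
    sum((pattern == 1) * 2^(seq_along(pattern) - 1))
  }
}

#' @rdname all_patterns
#' @export
max_enumerable_nodes <- function() 20L

# Neighbour codes under single-spin flips: row k+1 lists the n_nodes codes at
# Hamming distance 1 from code k.
neighbor_codes <- function(n_nodes) {
  codes <- 0:(2^n_nodes - 1)
  outer(codes, 2^(0:(n_nodes - 1)), bitwXor)
}

check_n_nodes <- function(n_nodes, enumerate = TRUE) {
  if (length(n_nodes) != 1L || !is.finite(n_nodes) || n_nodes < 2 ||
      n_nodes != round(n_nodes)) {
    stop("`n_nodes` must be a single integer >= 2", call. = FALSE)
  }
  if (enumerate && n_nodes > max_enumerable_nodes()) {
    stop("exhaustive enumeration supported only up to ",
         max_enumerable_nodes(), " nodes", call. = FALSE)
  }
  invisible(as.integer(n_nodes))
}

check_spins <- function(x) {
  if (!all(x == 1 | x == -1)) {
    stop("binary patterns must contain only +1 and -1", call. = FALSE)
  }
  invisible(x)
}

# Run `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# Deterministic stream splitting: draw `n` independent sub-seeds from a master
# seed, all below 2^31 so they remain valid R integer seeds.
split_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}
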