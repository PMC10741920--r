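#' Enumerate single-sequence conformations of a chain
#'
#' Under the single sequence approximation a chain conformation is either
#' fully unfolded or has exactly one contiguous stretch of folded units.
#' Conformations are returned in a fixed canonical order: the empty (fully
#' unfolded) conformation first, then stretches ordered by (first, last).
#' The empty conformation is encoded as the interval `[1, 0]` so that its
#' folding degree `last - first + 1` is 0 and it covers no unit.
#'
#' @param n_units number of folding units in the chain (>= 1).
#' @return integer matrix with columns `first`, `last`; one row per
#'   conformation, `n_units * (n_units + 1) / 2 + 1` rows in total.
#' @export
#' @examples
#' enumerate_conformations(3)
enumerate_conformations <- function(n_units) {
  if (length(n_units) != 1L || is.na(n_units) || n_units < 1)
    stop("n_units must be a single integer >= 1")
  n <- as.integer(n_units)
  first <- rep(seq_len(n), times = n - seq_len(n) + 1L)
  last <- unlist(lapply(seq_len(n), function(f) f:n), use.names = FALSE)
  out <- rbind(c(1L, 0L), cbind(first, as.integer(last)))
  dimnames(out) <- list(NULL, c("first", "last"))
  attr(out, "n_units") <- n
  out
}

#' Folding degree of conformations
#'
#' The folding degree Q is the number of folded units, including any padding
#' (dummy) units inside the folded stretch.
#'
#' @param conf conformation matrix from [enumerate_conformations()], or a
#'   single `c(first, last)` pair.
#' @return integer vector of folding degrees.
#' @export
folding_degree <- function(conf) {
  if (is.null(dim(conf))) conf <- matrix(conf, ncol = 2L)
  pmax(0L, conf[, 2L] - conf[, 1L] + 1L)
}

# Does each conformation fold unit k? Returns nc x n_units logical matrix.
.conf_covers <- function(conf, n_units) {
  outer(conf[, 1L], seq_len(n_units), "<=") &
    outer(conf[, 2L], seq_len(n_units), ">=")
}

# Conformational move set: elongation/shortening of the folded stretch by one
# unit at either end; EMPTY <-> single-unit stretches (nucleation). Returns a
# list (one element per conformation index) of neighbour conformation indices.
.conf_neighbors <- function(conf) {
  n <- attr(conf, "n_units")
  lookup <- matrix(NA_integer_, n, n)
  body <- conf[-1L, , drop = FALSE]
  lookup[body] <- seq_len(nrow(body)) + 1L
  idx <- function(f, l) if (l < f) 1L else lookup[f, l]
  out <- vector("list", nrow(conf))
  out[[1L]] <- vapply(seq_len(n), function(k) idx(k, k), integer(1))
  for (r in seq_len(nrow(body))) {
    f <- body[r, 1L]; l <- body[r, 2L]
    nb <- integer(0)
    if (f > 1L) nb <- c(nb, idx(f - 1L, l))
    if (l < n) nb <- c(nb, idx(f, l + 1L))
    if (f == l) nb <- c(nb, 1L) else nb <- c(nb, idx(f + 1L, l), idx(f, l - 1L))
    out[[r + 1L]] <- unique(nb)
  }
  out
}

#' Count two-layer network microstates
#'
#' Total number of microstates of the two-layer homodimer network: the
#' per-chain conformation count squared (ordered conformation pairs) times two
#' (associated and dissociated layers). Under the single sequence
#' approximation a chain with n units has `n(n+1)/2 + 1` conformations; the
#' double sequence approximation adds conformations with exactly two folded
#' stretches separated by at least one unfolded unit, `choose(n+1, 4)` of
#' them.
#'
#' @param n_units folding units per chain.
#' @param approximation `"single"` or `"double"` sequence approximation.
#' @return total microstate count (numeric).
#' @export
#' @examples
#' count_states(11, "single")  # 8978
#' count_states(11, "double")  # 631688
count_states <- function(n_units, approximation = c("single", "double")) {
  approximation <- match.arg(approximation)
  if (length(n_units) != 1L || is.na(n_units) || n_units < 1)
    stop("n_units must be a single integer >= 1")
  n <- as.numeric(n_units)
  per_chain <- n * (n + 1) / 2 + 1
  if (approximation == "double") per_chain <- per_chain + choose(n + 1, 4)
  2 * per_chain^2
}
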