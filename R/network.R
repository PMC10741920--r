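# The two-layer kinetic transition network: nodes are (conf_A, conf_B, delta)
# microstates, edges are single moves (grow/shrink one chain's stretch by one
# unit, or flip the association layer), and edge weights are
# Metropolis-Hastings transition probabilities.

#' Metropolis-Hastings transition probability
#'
#' `p_ij = min(1, (n_i / n_j) * exp((F_i - F_j) / RT)) / n_i` where `n_i`,
#' `n_j` are the out-degrees (distinct neighbour counts) of the two states.
#' The a-priori move probability is `1 / n_i`; the degree ratio keeps the
#' chain reversible with respect to the Boltzmann distribution.
#'
#' @param F_i,F_j free energies in J/mol (vectorised).
#' @param n_i,n_j out-degrees (>= 1).
#' @param temperature temperature in K.
#' @return transition probabilities in (0, 1].
#' @export
transition_probability <- function(F_i, F_j, n_i, n_j, temperature) {
  x <- (F_i - F_j) / (.GAS_CONSTANT * temperature)
  x <- pmin(x, 700)  # overflow clamp; min(1, .) makes larger values equivalent
  pmin(1, (n_i / n_j) * exp(x)) / n_i
}

#' Neighbours of a microstate under the move set
#'
#' One move either grows or shrinks one chain's folded stretch by one unit
#' (the fully unfolded conformation nucleates to any single-unit stretch and
#' vice versa) or flips the association layer while both conformations stay
#' fixed. Duplicate targets are collapsed: the out-degree is the number of
#' distinct neighbour states.
#'
#' @param conf_A,conf_B `c(first, last)` pairs.
#' @param delta 0 or 1.
#' @param n_units folding units per chain.
#' @return data frame of neighbour microstates with columns `first_A`,
#'   `last_A`, `first_B`, `last_B`, `delta`.
#' @export
neighbors <- function(conf_A, conf_B, delta, n_units) {
  conf <- enumerate_conformations(n_units)
  nbrs <- .conf_neighbors(conf)
  find <- function(cc) {
    hit <- which(conf[, 1L] == cc[1L] & conf[, 2L] == cc[2L])
    if (!length(hit)) stop("invalid conformation for this unit count")
    hit
  }
  a <- find(conf_A); b <- find(conf_B)
  rows <- rbind(
    cbind(conf[nbrs[[a]], , drop = FALSE], conf[rep(b, length(nbrs[[a]])), , drop = FALSE], delta),
    cbind(conf[rep(a, length(nbrs[[b]])), , drop = FALSE], conf[nbrs[[b]], , drop = FALSE], delta),
    cbind(conf[a, , drop = FALSE], conf[b, , drop = FALSE], 1L - delta))
  out <- as.data.frame(rows)
  names(out) <- c("first_A", "last_A", "first_B", "last_B", "delta")
  rownames(out) <- NULL
  out
}

#' Build the two-layer transition network
#'
#' Enumerates all `2 * nc^2` microstates (nc single-sequence conformations per
#' chain) in canonical order (dissociated layer first, then associated;
#' conf_A major, conf_B minor), precomputes their free energies, and assigns
#' every move-set edge its Metropolis-Hastings probability. Self-loops carry
#' the residual probability `1 - sum_j p_ij` and are stored on the diagonal of
#' the sparse transition matrix.
#'
#' @param model a [dimer_model].
#' @param s_diss dissociation entropy override in J/(K mol) (defaults to the
#'   model's value).
#' @param check_connected verify that the network is a single connected
#'   component (default TRUE).
#' @return object of class `dimer_network`: node table, free energies `F`,
#'   out-degrees, sparse row-stochastic transition matrix `P`, and the
#'   conformation enumeration.
#' @export
build_network <- function(model, s_diss = model$s_diss, check_connected = TRUE) {
  parts <- .node_energy_parts(model, s_diss = s_diss)
  nc <- parts$nc
  n_nodes <- 2L * nc * nc
  F <- parts$e0 - model$epsilon * parts$count
  nbrs <- .conf_neighbors(parts$conf)
  deg_conf <- lengths(nbrs)

  a_of <- rep(rep(seq_len(nc), each = nc), 2L)
  b_of <- rep(rep(seq_len(nc), times = nc), 2L)
  delta_of <- rep(c(0L, 1L), each = nc * nc)
  out_degree <- deg_conf[a_of] + deg_conf[b_of] + 1L

  # conformation-level directed pairs (a -> a')
  pair_from <- rep(seq_len(nc), times = deg_conf)
  pair_to <- unlist(nbrs, use.names = FALSE)
  npair <- length(pair_from)

  node <- function(d, a, b) .node_index(d, a, b, nc)
  all_b <- seq_len(nc)
  # A-moves: for every (a -> a'), every b, both layers
  fromA <- c(outer(node(0L, pair_from, 1L) - 1L, all_b, "+"),
             outer(node(1L, pair_from, 1L) - 1L, all_b, "+"))
  toA <- c(outer(node(0L, pair_to, 1L) - 1L, all_b, "+"),
           outer(node(1L, pair_to, 1L) - 1L, all_b, "+"))
  # B-moves: for every (b -> b'), every a, both layers
  fromB <- c(outer(rep(0L, npair), (all_b - 1L) * nc, "+") + pair_from,
             outer(rep(nc * nc, npair), (all_b - 1L) * nc, "+") + pair_from)
  toB <- c(outer(rep(0L, npair), (all_b - 1L) * nc, "+") + pair_to,
           outer(rep(nc * nc, npair), (all_b - 1L) * nc, "+") + pair_to)
  # layer flips
  half <- seq_len(nc * nc)
  fromX <- c(half, half + nc * nc)
  toX <- c(half + nc * nc, half)

  from <- c(fromA, fromB, fromX)
  to <- c(toA, toB, toX)
  p <- transition_probability(F[from], F[to], out_degree[from],
                              out_degree[to], model$temperature)
  P <- sparseMatrix(i = from, j = to, x = p, dims = c(n_nodes, n_nodes))
  P <- P + Diagonal(n_nodes, x = 1 - rowSums(P))

  net <- structure(list(
    model = model, s_diss = s_diss, n_units = parts$n_units, nc = nc,
    n_nodes = n_nodes, conf = parts$conf,
    a = a_of, b = b_of, delta = delta_of,
    F = F, out_degree = out_degree, P = P,
    temperature = model$temperature, gas_constant = model$gas_constant),
    class = "dimer_network")
  if (check_connected && !.is_connected(P))
    stop("transition network is not connected")
  net
}

# BFS reachability on the sparsity pattern
.is_connected <- function(P) {
  n <- nrow(P)
  pat <- P
  pat@x <- rep(1, length(pat@x))
  reach <- logical(n)
  frontier <- numeric(n)
  frontier[1L] <- 1
  while (any(frontier > 0)) {
    reach <- reach | frontier > 0
    frontier <- as.numeric(Matrix::crossprod(pat, frontier))
    frontier[reach] <- 0
  }
  all(reach)
}

#' @export
print.dimer_network <- function(x, ...) {
  cat(sprintf("<dimer_network> %d nodes (%d units/chain, %d conformations/chain), %d directed edges\n",
              x$n_nodes, x$n_units, x$nc,
              length(x$P@x) - x$n_nodes))
  cat(sprintf("  T = %g K, S_diss = %g J/(K mol), epsilon = %.1f J/mol\n",
              x$temperature, x$s_diss, x$model$epsilon))
  invisible(x)
}

#' Boltzmann stationary distribution of a network
#'
#' The Metropolis chain is reversible with respect to the Boltzmann
#' distribution by construction, so `pi_i` is proportional to
#' `exp(-F_i / RT)` (computed with a max shift for stability).
#'
#' @param net a [build_network()] result.
#' @return numeric vector `pi` summing to 1.
#' @export
stationary_distribution <- function(net) {
  RT <- net$gas_constant * net$temperature
  w <- exp(-(net$F - min(net$F)) / RT)
  w / sum(w)
}

#' Export the network as plain-text tables
#'
#' Writes a tab-separated edge list (i, j, p_ij, F_i, F_j; self-loops
#' excluded) and a node table (index, stretch endpoints of both chains,
#' layer, free energy).
#'
#' @param net a `dimer_network`.
#' @param edge_file,node_file output paths.
#' @param header_lines optional character vector of `#`-prefixed provenance
#'   lines to prepend.
#' @return invisibly, the two paths.
#' @export
export_network <- function(net, edge_file, node_file, header_lines = NULL) {
  tr <- .P_triplets(net$P, drop_diag = TRUE)
  edges <- data.frame(i = tr$i, j = tr$j, p_ij = tr$x,
                      F_i = net$F[tr$i], F_j = net$F[tr$j])
  nodes <- data.frame(index = seq_len(net$n_nodes),
                      first_A = net$conf[net$a, 1L], last_A = net$conf[net$a, 2L],
                      first_B = net$conf[net$b, 1L], last_B = net$conf[net$b, 2L],
                      delta = net$delta, F = net$F)
  for (spec in list(list(f = edge_file, d = edges), list(f = node_file, d = nodes))) {
    con <- file(spec$f, "w")
    if (!is.null(header_lines)) writeLines(header_lines, con)
    write.table(spec$d, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  invisible(c(edge_file, node_file))
}

# sparse matrix triplets ordered by row
.P_triplets <- function(P, drop_diag = FALSE) {
  tr <- Matrix::summary(P)
  if (drop_diag) tr <- tr[tr$i != tr$j, , drop = FALSE]
  tr <- tr[order(tr$i, tr$j), , drop = FALSE]
  tr
}
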