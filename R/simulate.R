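# Monte Carlo trajectory oracles: direct path sampling on the transition
# network, used to cross-check committors, mechanism fractions and the
# (Q_A, Q_B) association flux map against the linear-solve TPT values.
# Randomness comes from R's RNG (Mersenne-Twister), so set.seed() makes every
# estimate reproducible.

# CSR representation of P with the diagonal (self-loop) dropped; 0-based for C++
.as_csr <- function(P) {
  tr <- .P_triplets(P, drop_diag = TRUE)
  n <- nrow(P)
  counts <- tabulate(tr$i, nbins = n)
  list(row_ptr = as.integer(c(0L, cumsum(counts))),
       col_idx = as.integer(tr$j - 1L),
       prob = as.numeric(tr$x))
}

#' Sample absorption outcomes of network trajectories
#'
#' Runs `n_paths` trajectories from `start` (recycled if shorter), each until
#' it is absorbed in the reactant or product set, and reports the fraction
#' reaching the products first -- a Monte Carlo committor estimate with a
#' binomial standard error. Trajectories exceeding `max_steps` are counted
#' separately; more than 1% truncation triggers a warning.
#'
#' @param net a `dimer_network` (or any list with a row-stochastic sparse `P`).
#' @param start node index or vector of node indices.
#' @param reactants,products absorbing node sets.
#' @param n_paths number of trajectories.
#' @param max_steps truncation bound per path (default 1e6).
#' @param seed optional RNG seed (applied with [set.seed()]).
#' @return list: `outcome` (+1 product / 0 reactant / -1 truncated per path),
#'   `hit_fraction`, `se` (binomial), `n_truncated`.
#' @export
simulate_trajectories <- function(net, start, reactants, products,
                                  n_paths = 1000, max_steps = 1e6,
                                  seed = NULL) {
  if (n_paths < 1) stop("n_paths must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  csr <- .as_csr(net$P)
  n <- nrow(net$P)
  in_R <- logical(n); in_R[reactants] <- TRUE
  in_P <- logical(n); in_P[products] <- TRUE
  starts <- rep_len(as.integer(start), n_paths) - 1L
  out <- run_paths_cpp(csr$row_ptr, csr$col_idx, csr$prob, starts,
                       in_R, in_P, max_steps)
  n_trunc <- sum(out < 0L)
  if (n_trunc > 0.01 * n_paths)
    warning(sprintf("%d of %d paths truncated at max_steps", n_trunc, n_paths))
  done <- out >= 0L
  phat <- mean(out[done] == 1L)
  list(outcome = out, hit_fraction = phat,
       se = sqrt(phat * (1 - phat) / sum(done)), n_truncated = n_trunc)
}

#' Monte Carlo estimate of the association-flux observables
#'
#' Samples reactive association events directly: an excursion of the
#' equilibrium chain leaves the dissociated layer through the layer-crossing
#' edge of conformation pair (a, b) with probability proportional to
#' `pi * p_cross`, and it is reactive iff the trajectory then reaches the
#' product set before touching any dissociated state. The start edges are
#' drawn from `pi * p_cross` and the continuation is simulated; because the
#' reactant set is the whole dissociated layer, each reactive excursion
#' crosses the association boundary exactly once (its last crossing is its
#' first), so the empirical distribution of successful crossing edges
#' estimates `f_ij / f_total`.
#'
#' @param net a `dimer_network`.
#' @param n_events number of attempted association events.
#' @param folded_chain mechanism classification switch, see
#'   [classify_association_edge()].
#' @param max_steps truncation bound per continuation.
#' @param seed optional RNG seed.
#' @return list: `n_reactive`, `mechanism` (estimated fractions),
#'   `q_map` (estimated folding-degree histogram), `edge_counts` (successful
#'   crossings per conformation pair), `n_truncated`.
#' @export
mc_association_events <- function(net, n_events = 1e5,
                                  folded_chain = c("contacts", "all-units"),
                                  max_steps = 1e6, seed = NULL) {
  folded_chain <- match.arg(folded_chain)
  if (!is.null(seed)) set.seed(seed)
  model <- net$model
  n <- net$n_units; nc <- net$nc
  pi <- stationary_distribution(net)
  diss <- which(net$delta == 0L)
  ass <- diss + nc * nc
  p_cross <- transition_probability(net$F[diss], net$F[ass],
                                    net$out_degree[diss], net$out_degree[ass],
                                    net$temperature)
  w <- pi[diss] * p_cross
  picks <- sample.int(length(diss), n_events, replace = TRUE, prob = w)

  csr <- .as_csr(net$P)
  in_R <- net$delta == 0L
  prod_set <- native_product_set(model)
  in_P <- logical(net$n_nodes)
  in_P[.node_index(1L, prod_set$a, prod_set$b, nc)] <- TRUE
  out <- run_paths_cpp(csr$row_ptr, csr$col_idx, csr$prob,
                       as.integer(ass[picks] - 1L), in_R, in_P, max_steps)
  ok <- out == 1L
  n_reactive <- sum(ok)
  if (n_reactive == 0L) stop("no reactive events sampled")

  counts <- tabulate(picks[ok], nbins = length(diss))
  foldA <- .folded_confs(net$conf, model$intra_A, n, folded_chain)
  foldB <- .folded_confs(net$conf, model$intra_B, n, folded_chain)
  a_idx <- net$a[diss]; b_idx <- net$b[diss]
  mech_code <- 1L + foldA[a_idx] + foldB[b_idx]
  mech <- vapply(1:3, function(k) sum(counts[mech_code == k]),
                 numeric(1)) / n_reactive
  names(mech) <- c("induced", "confsel", "rigid")
  Q <- folding_degree(net$conf)
  q_map <- matrix(0, n + 1L, n + 1L, dimnames = list(Q_A = 0:n, Q_B = 0:n))
  for (kk in which(counts > 0L))
    q_map[Q[a_idx[kk]] + 1L, Q[b_idx[kk]] + 1L] <-
      q_map[Q[a_idx[kk]] + 1L, Q[b_idx[kk]] + 1L] + counts[kk]
  q_map <- q_map / n_reactive
  list(n_reactive = n_reactive, mechanism = mech, q_map = q_map,
       edge_counts = counts, n_truncated = sum(out < 0L))
}

#' Occupation frequencies of a long equilibrium trajectory
#'
#' Runs a single trajectory of `n_steps` moves (including self-loops) and
#' returns per-node visit frequencies, a sampling check of the Boltzmann
#' stationary distribution.
#'
#' @param net a `dimer_network`.
#' @param n_steps trajectory length.
#' @param start starting node (default 1).
#' @param seed optional RNG seed.
#' @return numeric vector of visit frequencies (sums to 1).
#' @export
occupation_frequencies <- function(net, n_steps = 1e5, start = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  csr <- .as_csr(net$P)
  counts <- run_occupation_cpp(csr$row_ptr, csr$col_idx, csr$prob,
                               as.integer(start - 1L), n_steps)
  counts / sum(counts)
}

#' Simulate trajectories from a fitted TPT analysis
#'
#' [simulate()] method for `dimer_tpt`: draws `nsim` trajectories from a
#' chosen start node (default: the fully unfolded dissociated state is not
#' useful since it is absorbing as a reactant, so the default start is the
#' associated fully-unfolded state) and reports the committor estimate.
#'
#' @param object a [dimer_kinetics()] result.
#' @param nsim number of trajectories.
#' @param seed optional RNG seed.
#' @param start node index (default: associated, both chains unfolded).
#' @param ... ignored.
#' @return see [simulate_trajectories()].
#' @export
simulate.dimer_tpt <- function(object, nsim = 1000, seed = NULL,
                               start = NULL, ...) {
  net <- object$network
  if (is.null(start)) start <- .node_index(1L, 1L, 1L, net$nc)
  simulate_trajectories(net, start, object$reactants, object$products,
                        n_paths = nsim, seed = seed)
}
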