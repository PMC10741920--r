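# Two-chain WSME free energies.
#
# Chain free energy (per conformation v): sum over intra native contacts (i,j)
# that are fully inside the folded stretch of -epsilon * m_ij, minus
# T * sum of unit entropies outside the stretch. Inter-chain contacts only
# require their two endpoint units to be folded. Dissociated microstates gain
# -T * S_diss.

# per-conformation intra contact counts (sum of multiplicities of formed
# entries) for a whole conformation matrix; an entry (i,j) is formed iff
# first <= i and j <= last
.conf_contact_counts <- function(conf, intra) {
  if (nrow(intra) == 0L) return(numeric(nrow(conf)))
  formed <- outer(conf[, 1L], intra$i, "<=") & outer(conf[, 2L], intra$j, ">=")
  as.numeric(formed %*% intra$m)
}

# per-conformation folded entropy inside the stretch
.conf_entropy_outside <- function(conf, unit_entropies) {
  cs <- c(0, cumsum(unit_entropies))
  inside <- cs[pmax(conf[, 2L], 0L) + 1L] - cs[pmax(conf[, 1L] - 1L, 0L) + 1L]
  inside[conf[, 2L] < conf[, 1L]] <- 0
  sum(unit_entropies) - inside
}

#' Chain free energy of one conformation
#'
#' Evaluates the single-chain WSME free energy: formed intra contacts
#' contribute `-epsilon * m`, and every unit outside the folded stretch
#' contributes `-T * s_i`.
#'
#' @param conf a `c(first, last)` pair (use `c(1, 0)` for the fully unfolded
#'   conformation).
#' @param chain a segmented chain (or numeric vector of unit entropies).
#' @param intra the chain's intra [contact_set()].
#' @param epsilon elementary contact energy, J/mol.
#' @param temperature temperature, K.
#' @return free energy in J/mol.
#' @export
chain_free_energy <- function(conf, chain, intra, epsilon, temperature) {
  s <- if (inherits(chain, "segmented_chain")) chain$unit_entropies else
    as.numeric(chain)
  cm <- matrix(as.integer(conf), ncol = 2L)
  -epsilon * .conf_contact_counts(cm, intra) -
    temperature * .conf_entropy_outside(cm, s)
}

#' Inter-chain interaction energy of a conformation pair
#'
#' An inter contact (i, j) contributes `-epsilon * m` iff unit i is folded in
#' chain A's conformation and unit j in chain B's; no path condition applies
#' between the chains.
#'
#' @param conf_A,conf_B `c(first, last)` pairs.
#' @param inter the inter [contact_set()].
#' @param epsilon elementary contact energy, J/mol.
#' @return interaction energy in J/mol.
#' @export
interaction_energy <- function(conf_A, conf_B, inter, epsilon) {
  if (nrow(inter) == 0L) return(0)
  fa <- conf_A[1L] <= inter$i & inter$i <= conf_A[2L]
  fb <- conf_B[1L] <= inter$j & inter$j <= conf_B[2L]
  -epsilon * sum(inter$m[fa & fb])
}

#' Free energy of a two-layer microstate
#'
#' `F = F_A(conf_A) + F_B(conf_B) + delta * E_inter - (1 - delta) * T * S_diss`.
#' Dissociated states (`delta = 0`) are stabilised by the dissociation
#' entropy, so larger `s_diss` means lower effective concentration.
#'
#' @param conf_A,conf_B `c(first, last)` pairs.
#' @param delta 1 (associated) or 0 (dissociated).
#' @param model a [dimer_model()].
#' @return free energy in J/mol.
#' @export
microstate_free_energy <- function(conf_A, conf_B, delta, model) {
  fa <- chain_free_energy(conf_A, model$chain_A, model$intra_A,
                          model$epsilon, model$temperature)
  fb <- chain_free_energy(conf_B, model$chain_B, model$intra_B,
                          model$epsilon, model$temperature)
  if (delta == 1)
    fa + fb + interaction_energy(conf_A, conf_B, model$inter, model$epsilon)
  else
    fa + fb - model$temperature * model$s_diss
}

# Epsilon-independent decomposition of all node free energies:
#   F(node) = e0(node) - epsilon * contact_count(node)
# Node order is canonical: dissociated layer first, then associated; within a
# layer, conf_A index major, conf_B index minor.
.node_energy_parts <- function(model, s_diss = model$s_diss) {
  n <- model$chain_A$n_units
  conf <- enumerate_conformations(n)
  nc <- nrow(conf)
  T <- model$temperature
  cA <- .conf_contact_counts(conf, model$intra_A)
  cB <- .conf_contact_counts(conf, model$intra_B)
  eA <- -T * .conf_entropy_outside(conf, model$chain_A$unit_entropies)
  eB <- -T * .conf_entropy_outside(conf, model$chain_B$unit_entropies)
  # inter contact counts per conformation pair
  covA <- .conf_covers(conf, n); covB <- covA
  ci <- matrix(0, nc, nc)
  for (r in seq_len(nrow(model$inter))) {
    ci <- ci + model$inter$m[r] *
      tcrossprod(covA[, model$inter$i[r]], covB[, model$inter$j[r]])
  }
  pair_c <- outer(cA, cB, "+")        # conf_A in rows, conf_B in cols
  pair_e <- outer(eA, eB, "+")
  # canonical flattening: (a - 1) * nc + b  <=>  row-major over (a, b)
  flat <- function(m) as.vector(t(m))
  list(conf = conf, nc = nc, n_units = n,
       count = c(flat(pair_c), flat(pair_c + ci)),
       e0 = c(flat(pair_e) - T * s_diss, flat(pair_e)))
}

# node index in canonical order (delta = 0 layer first)
.node_index <- function(delta, a, b, nc) delta * nc * nc + (a - 1L) * nc + b

#' Native product set of a dimer model
#'
#' The product set contains every associated microstate in which all native
#' contacts (intra-chain of both chains and inter-chain) are formed. Because a
#' chain folds one contiguous stretch, this is every conformation pair where
#' each chain's stretch covers its full contact-bearing span; it is not
#' necessarily a single state when terminal units carry no contacts.
#'
#' @param model a [dimer_model()].
#' @return data frame with columns `a`, `b` (conformation indices in the
#'   canonical enumeration) and `delta` (always 1).
#' @export
native_product_set <- function(model) {
  n <- model$chain_A$n_units
  conf <- enumerate_conformations(n)
  spanA <- range(c(model$intra_A$i, model$intra_A$j, model$inter$i))
  spanB <- range(c(model$intra_B$i, model$intra_B$j, model$inter$j))
  okA <- which(conf[, 1L] <= spanA[1L] & conf[, 2L] >= spanA[2L])
  okB <- which(conf[, 1L] <= spanB[1L] & conf[, 2L] >= spanB[2L])
  if (!length(okA) || !length(okB)) stop("degenerate model: empty product set")
  out <- expand.grid(b = okB, a = okA)[, c("a", "b")]
  out$delta <- 1L
  out[order(out$a, out$b), , drop = FALSE]
}

#' Equilibrium probability of the native dimer
#'
#' Boltzmann weight of the product set over the partition sum of all
#' two-layer microstates at the model temperature. Free energies are shifted
#' by their minimum before exponentiation.
#'
#' @param model a [dimer_model()].
#' @param epsilon elementary contact energy to evaluate at (defaults to the
#'   model's).
#' @return probability in (0, 1).
#' @export
native_dimer_probability <- function(model, epsilon = model$epsilon) {
  parts <- .node_energy_parts(model)
  prod_set <- native_product_set(model)
  idx <- .node_index(1L, prod_set$a, prod_set$b, parts$nc)
  .native_prob_from_parts(parts, idx, epsilon, model)
}

.native_prob_from_parts <- function(parts, prod_idx, epsilon, model) {
  RT <- model$gas_constant * model$temperature
  F <- parts$e0 - epsilon * parts$count
  w <- exp(-(F - min(F)) / RT)
  sum(w[prod_idx]) / sum(w)
}

#' Calibrate the elementary contact energy
#'
#' Bisects epsilon on `[0, 1e5]` J/mol until the native-dimer probability
#' matches `target` within 1e-6. The probability is strictly increasing in
#' epsilon, so the root is unique.
#'
#' @param model a [dimer_model()].
#' @param target native-dimer probability in (0, 1), default 0.5.
#' @param lower,upper bisection bracket in J/mol.
#' @param tol tolerance on the probability (default 1e-6).
#' @return calibrated epsilon in J/mol.
#' @export
calibrate_epsilon <- function(model, target = 0.5, lower = 0, upper = 1e5,
                              tol = 1e-6) {
  if (target <= 0 || target >= 1) stop("target must be in (0, 1)")
  parts <- .node_energy_parts(model)
  prod_set <- native_product_set(model)
  idx <- .node_index(1L, prod_set$a, prod_set$b, parts$nc)
  p <- function(eps) .native_prob_from_parts(parts, idx, eps, model)
  plo <- p(lower); phi <- p(upper)
  if ((plo - target) * (phi - target) > 0)
    stop(sprintf(
      "no sign change in bracket: P(native) = %.3g at epsilon = %g and %.3g at %g",
      plo, lower, phi, upper))
  for (it in seq_len(200L)) {
    mid <- (lower + upper) / 2
    pm <- p(mid)
    if (abs(pm - target) < tol) return(mid)
    if (pm < target) lower <- mid else upper <- mid
  }
  stop("calibration did not converge within 200 bisection steps")
}
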