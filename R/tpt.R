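# Discrete Transition Path Theory on the two-layer network: committors by
# sparse linear solve, gross reactive fluxes f_ij = pi_i q-_i p_ij q+_j, the
# mechanism partition of the association flux, the (Q_A, Q_B) flux map,
# per-segment foldedness at association, and dissociation-entropy scans.

#' Forward and backward committors
#'
#' Solves the harmonic committor system `q+_i = sum_j p_ij q+_j` on interior
#' nodes with boundary values 0 on the reactant set and 1 on the product set,
#' by sparse direct factorisation. The backward committor of the reversible
#' chain is `q- = 1 - q+`.
#'
#' @param P row-stochastic sparse transition matrix (self-loops on the
#'   diagonal).
#' @param reactants,products disjoint, non-empty node index vectors.
#' @return list with `q_plus`, `q_minus`, the maximum harmonicity residual
#'   `residual`, and the largest out-of-range value clipped (`clipped`).
#' @export
committors <- function(P, reactants, products) {
  n <- nrow(P)
  if (!length(reactants) || !length(products))
    stop("reactant and product sets must be non-empty")
  if (length(intersect(reactants, products)))
    stop("reactant and product sets must be disjoint")
  q <- numeric(n)
  q[products] <- 1
  interior <- setdiff(seq_len(n), c(reactants, products))
  if (length(interior)) {
    A <- Diagonal(length(interior)) - P[interior, interior, drop = FALSE]
    rhs <- rowSums(P[interior, products, drop = FALSE])
    sol <- tryCatch(as.numeric(solve(A, rhs)),
                    error = function(e) stop(
                      "singular committor system (interior node with no path to either boundary): ",
                      conditionMessage(e)))
    clip <- max(0, max(sol - 1, -sol, 0))
    q[interior] <- pmin(1, pmax(0, sol))
  } else clip <- 0
  res <- if (length(interior))
    max(abs(as.numeric(P[interior, , drop = FALSE] %*% q) - q[interior])) else 0
  list(q_plus = q, q_minus = 1 - q, residual = res, clipped = clip)
}

#' Gross reactive fluxes
#'
#' `f_ij = pi_i * q-_i * p_ij * q+_j` on every edge (self-loops excluded).
#'
#' @param P sparse transition matrix.
#' @param pi stationary distribution.
#' @param q_plus,q_minus committors.
#' @return sparse matrix of edge fluxes.
#' @export
reactive_fluxes <- function(P, pi, q_plus, q_minus) {
  tr <- .P_triplets(P, drop_diag = TRUE)
  f <- pi[tr$i] * q_minus[tr$i] * tr$x * q_plus[tr$j]
  sparseMatrix(i = tr$i, j = tr$j, x = f, dims = dim(P))
}

# "folded" chain classification: a chain is folded iff all of its intra-chain
# native contact entries are formed (its stretch covers the intra contact
# span); chains with no intra contacts are vacuously folded. The stricter
# alternative requires every unit folded.
.folded_confs <- function(conf, intra, n_units,
                          folded_chain = c("contacts", "all-units")) {
  folded_chain <- match.arg(folded_chain)
  if (folded_chain == "all-units")
    return(conf[, 1L] == 1L & conf[, 2L] == n_units)
  if (nrow(intra) == 0L) return(rep(TRUE, nrow(conf)))
  span <- range(c(intra$i, intra$j))
  conf[, 1L] <= span[1L] & conf[, 2L] >= span[2L]
}

#' Classify an association edge by mechanism
#'
#' At the moment of association each chain is either folded (F: all of its
#' intra-chain native contacts formed) or unfolded (U). Both folded: rigid
#' docking; exactly one: conformational selection; neither: induced folding.
#'
#' @param conf_A,conf_B `c(first, last)` pairs of the dissociated state.
#' @param model a [dimer_model()].
#' @param folded_chain `"contacts"` (default) or `"all-units"`.
#' @return one of `"induced"`, `"confsel"`, `"rigid"`.
#' @export
classify_association_edge <- function(conf_A, conf_B, model,
                                      folded_chain = c("contacts", "all-units")) {
  folded_chain <- match.arg(folded_chain)
  n <- model$chain_A$n_units
  cm <- rbind(conf_A, conf_B)
  fa <- .folded_confs(cm[1L, , drop = FALSE], model$intra_A, n, folded_chain)
  fb <- .folded_confs(cm[2L, , drop = FALSE], model$intra_B, n, folded_chain)
  c("induced", "confsel", "rigid")[1L + fa + fb]
}

#' Two-layer TPT analysis of dimer formation
#'
#' The main analysis function. Builds the transition network for the model
#' (optionally overriding the dissociation entropy), takes the reactant set as
#' all dissociated microstates and the product set as the native associated
#' states (all contacts formed), solves for committors, computes reactive
#' fluxes, and partitions the total association flux into induced folding,
#' conformational selection and rigid docking. Also returns the association
#' flux map over per-chain folding degrees and the per-segment foldedness at
#' the moment of association.
#'
#' @param model a [dimer_model()].
#' @param s_diss dissociation entropy in J/(K mol); defaults to the model's.
#' @param folded_chain chain foldedness definition used for the mechanism
#'   classification: `"contacts"` (all intra contacts formed; default) or
#'   `"all-units"`.
#' @param network optionally, a prebuilt [build_network()] result for this
#'   model and `s_diss`.
#' @return object of class `dimer_tpt` with components `mechanism`
#'   (named fractions summing to 1), `f_total`, `q_map` (the
#'   `(n+1) x (n+1)` association flux matrix over folding degrees, summing to
#'   1), `foldedness` (per-unit and per-residue, both chains), committors,
#'   stationary distribution, and numerical diagnostics in `checks`.
#' @export
dimer_kinetics <- function(model, s_diss = model$s_diss,
                           folded_chain = c("contacts", "all-units"),
                           network = NULL) {
  folded_chain <- match.arg(folded_chain)
  net <- if (is.null(network)) build_network(model, s_diss = s_diss) else network
  nc <- net$nc
  n <- net$n_units
  pi <- stationary_distribution(net)

  reactants <- which(net$delta == 0L)
  prod_set <- native_product_set(model)
  products <- .node_index(1L, prod_set$a, prod_set$b, nc)
  cm <- committors(net$P, reactants, products)
  q_plus <- cm$q_plus; q_minus <- cm$q_minus

  # association edges: dissociated node (0, a, b) -> associated partner
  diss <- reactants                       # canonical order: all (a, b), delta 0
  ass <- diss + nc * nc
  p_cross <- transition_probability(net$F[diss], net$F[ass],
                                    net$out_degree[diss], net$out_degree[ass],
                                    net$temperature)
  f_assoc <- pi[diss] * q_minus[diss] * p_cross * q_plus[ass]
  f_total <- sum(f_assoc)
  if (f_total <= 0) stop("no reactive flux (product set unreachable)")

  # flux identities: reactant-exit and product-entry sums from the full edge set
  flux <- reactive_fluxes(net$P, pi, q_plus, q_minus)
  in_R <- logical(net$n_nodes); in_R[reactants] <- TRUE
  in_P <- logical(net$n_nodes); in_P[products] <- TRUE
  tr <- .P_triplets(flux)
  f_exit <- sum(tr$x[in_R[tr$i] & !in_R[tr$j]])
  f_entry <- sum(tr$x[!in_P[tr$i] & in_P[tr$j]])

  # flux conservation at interior nodes (net out = net in)
  netflux <- flux - Matrix::t(flux)
  pos <- netflux
  pos@x <- pmax(pos@x, 0)
  interior <- !(in_R | in_P)
  imbalance <- if (any(interior))
    max(abs(rowSums(pos)[interior] - colSums(pos)[interior])) else 0

  # mechanism partition over association edges
  foldA <- .folded_confs(net$conf, model$intra_A, n, folded_chain)
  foldB <- .folded_confs(net$conf, model$intra_B, n, folded_chain)
  a_idx <- net$a[diss]; b_idx <- net$b[diss]
  mech_code <- 1L + foldA[a_idx] + foldB[b_idx]
  mech <- vapply(1:3, function(k) sum(f_assoc[mech_code == k]), numeric(1)) / f_total
  names(mech) <- c("induced", "confsel", "rigid")

  # association flux over folding degrees
  Q <- folding_degree(net$conf)
  q_map <- matrix(0, n + 1L, n + 1L,
                  dimnames = list(Q_A = 0:n, Q_B = 0:n))
  inc <- tapply(f_assoc, list(Q[a_idx], Q[b_idx]), sum)
  q_map[cbind(as.integer(rownames(inc))[row(inc)],
              as.integer(colnames(inc))[col(inc)]) + 1L] <-
    ifelse(is.na(inc), 0, inc)
  q_map <- q_map / f_total

  # per-segment foldedness at the moment of association
  cov <- .conf_covers(net$conf, n)
  fa_sum <- rowsum(f_assoc, a_idx)      # flux by A conformation
  fb_sum <- rowsum(f_assoc, b_idx)
  FkA <- as.numeric(crossprod(cov[as.integer(rownames(fa_sum)), , drop = FALSE],
                              fa_sum)) / f_total
  FkB <- as.numeric(crossprod(cov[as.integer(rownames(fb_sum)), , drop = FALSE],
                              fb_sum)) / f_total
  foldedness <- list(
    unit_A = FkA, unit_B = FkB,
    residue_A = .per_residue(FkA, model$chain_A),
    residue_B = .per_residue(FkB, model$chain_B))

  structure(list(
    model = model, network = net, s_diss = s_diss,
    folded_chain = folded_chain,
    pi = pi, q_plus = q_plus, q_minus = q_minus,
    reactants = reactants, products = products,
    f_assoc = f_assoc, f_total = f_total,
    mechanism = mech, q_map = q_map, foldedness = foldedness,
    checks = list(
      committor_residual = cm$residual,
      committor_clip = cm$clipped,
      row_sum_error = max(abs(rowSums(net$P) - 1)),
      f_total_exit = f_exit, f_total_entry = f_entry,
      flux_imbalance = imbalance,
      mechanism_sum = sum(mech), q_map_sum = sum(q_map))),
    class = "dimer_tpt")
}

# expand per-unit values over residues; trailing padding dummies trimmed
.per_residue <- function(unit_values, chain) {
  v <- rep(unit_values, each = chain$unit_size)
  v[seq_len(chain$n_res)]
}

#' @export
print.dimer_tpt <- function(x, ...) {
  cat("Two-layer WSME/TPT analysis of dimer formation\n")
  cat(sprintf("  nodes: %d  (units/chain: %d)   S_diss = %g J/(K mol)\n",
              x$network$n_nodes, x$network$n_units, x$s_diss))
  cat(sprintf("  total reactive flux f_total = %.4g\n", x$f_total))
  cat("  mechanism flux fractions:\n")
  cat(sprintf("    induced folding          %.4g\n", x$mechanism[["induced"]]))
  cat(sprintf("    conformational selection %.4g\n", x$mechanism[["confsel"]]))
  cat(sprintf("    rigid docking            %.4g\n", x$mechanism[["rigid"]]))
  cat(sprintf("  dominant mechanism: %s\n",
              c(induced = "induced folding",
                confsel = "conformational selection",
                rigid = "rigid docking")[names(which.max(x$mechanism))]))
  invisible(x)
}

#' @export
summary.dimer_tpt <- function(object, ...) {
  print(object)
  ck <- object$checks
  cat(sprintf("  diagnostics: committor residual %.2e, clip %.2e, row-sum error %.2e\n",
              ck$committor_residual, ck$committor_clip, ck$row_sum_error))
  cat(sprintf("  f_total via exits %.6g / entries %.6g (association sum %.6g)\n",
              ck$f_total_exit, ck$f_total_entry, object$f_total))
  cat(sprintf("  flux imbalance at interior nodes: %.2e\n", ck$flux_imbalance))
  invisible(object)
}

#' @export
coef.dimer_tpt <- function(object, ...) object$mechanism

#' Heatmap of the association flux over folding degrees
#'
#' Plots `log10 F(Q_A, Q_B)` (floored at -12) as an image: rigid docking mass
#' sits in the fully folded corner, conformational selection along the edges,
#' induced folding elsewhere.
#'
#' @param x a [dimer_kinetics()] result.
#' @param floor log10 floor for empty cells (default -12).
#' @param ... passed to [graphics::image()].
#' @export
plot.dimer_tpt <- function(x, floor = -12, ...) {
  n <- x$network$n_units
  z <- log10(pmax(x$q_map, 10^floor))
  image(0:n, 0:n, z, col = hcl.colors(64, "YlOrRd", rev = TRUE),
        xlab = expression(Q[A]), ylab = expression(Q[B]),
        main = "Association flux over folding degrees (log10)", ...)
  box()
  invisible(x)
}

#' Scan the dissociation entropy (concentration proxy)
#'
#' Reruns the TPT analysis over a grid of dissociation entropies. Only the
#' dissociated-layer free-energy offset changes between grid points; a larger
#' `S_diss` corresponds to a lower protein concentration.
#'
#' @param model a [dimer_model()].
#' @param sdiss_grid values in J/(K mol); default `seq(0, 150, by = 5)`.
#' @param folded_chain passed to [dimer_kinetics()].
#' @return object of class `dimer_scan`: a data frame `table` (s_diss, the
#'   three mechanism fractions, f_total, dissociated-layer probability) plus
#'   the list of full `dimer_tpt` results.
#' @export
sdiss_scan <- function(model, sdiss_grid = seq(0, 150, by = 5),
                       folded_chain = c("contacts", "all-units")) {
  folded_chain <- match.arg(folded_chain)
  if (!length(sdiss_grid) || any(sdiss_grid < 0))
    stop("sdiss_grid must be non-empty and >= 0")
  runs <- lapply(sdiss_grid, function(sd)
    dimer_kinetics(model, s_diss = sd, folded_chain = folded_chain))
  tab <- data.frame(
    s_diss = sdiss_grid,
    induced = vapply(runs, function(r) r$mechanism[["induced"]], numeric(1)),
    confsel = vapply(runs, function(r) r$mechanism[["confsel"]], numeric(1)),
    rigid = vapply(runs, function(r) r$mechanism[["rigid"]], numeric(1)),
    f_total = vapply(runs, function(r) r$f_total, numeric(1)),
    p_dissociated = vapply(runs, function(r)
      sum(r$pi[r$reactants]), numeric(1)))
  structure(list(table = tab, runs = runs), class = "dimer_scan")
}

#' @export
print.dimer_scan <- function(x, ...) {
  cat(sprintf("<dimer_scan> %d dissociation-entropy values\n", nrow(x$table)))
  print(x$table[, c("s_diss", "induced", "confsel", "rigid")], digits = 4)
  invisible(x)
}

#' @export
plot.dimer_scan <- function(x, ...) {
  tab <- x$table
  matplot(tab$s_diss, tab[, c("induced", "confsel", "rigid")],
          type = "l", lty = 1, lwd = 2, col = c("#D55E00", "#0072B2", "#009E73"),
          xlab = expression(S[diss] ~ "(J K"^-1 * " mol"^-1 * ")"),
          ylab = "flux fraction", ...)
  legend("right", c("induced folding", "conformational selection",
                    "rigid docking"),
         lty = 1, lwd = 2, col = c("#D55E00", "#0072B2", "#009E73"), bty = "n")
  invisible(x)
}
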