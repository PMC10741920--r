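# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities from first principles (explicit bit strings, all-pairs
# scans, term-by-term energy sums) so they share no code with the package
# internals they check.

# count length-n binary strings with at most max_runs maximal runs of ones
bf_count_conformations <- function(n, max_runs = 1) {
  count <- 0L
  for (x in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(x))[seq_len(n)]
    runs <- sum(diff(c(0L, bits)) == 1L)
    if (runs <= max_runs) count <- count + 1L
  }
  count
}

# explicit folded/unfolded vector for a stretch
conf_to_v <- function(first, last, n) {
  v <- integer(n)
  if (last >= first) v[first:last] <- 1L
  v
}

# term-by-term single-chain free energy over an explicit 0/1 vector
bf_chain_free_energy <- function(v, entropies, intra, epsilon, temperature) {
  e <- 0
  for (r in seq_len(nrow(intra)))
    if (all(v[intra$i[r]:intra$j[r]] == 1L)) e <- e - epsilon * intra$m[r]
  e - temperature * sum(entropies[v == 0L])
}

bf_interaction_energy <- function(vA, vB, inter, epsilon) {
  e <- 0
  for (r in seq_len(nrow(inter)))
    if (vA[inter$i[r]] == 1L && vB[inter$j[r]] == 1L) e <- e - epsilon * inter$m[r]
  e
}

# all-pairs minimum-distance contact scan over residue coordinate lists
bf_contacts <- function(coords1, coords2, cutoff, min_sep = NULL) {
  hits <- list()
  for (i in seq_along(coords1)) for (j in seq_along(coords2)) {
    if (!is.null(min_sep) && (j - i) < min_sep) next
    a <- coords1[[i]]; b <- coords2[[j]]
    if (nrow(a) == 0L || nrow(b) == 0L) next
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
    if (sqrt(max(0, min(d2))) < cutoff) hits[[length(hits) + 1L]] <- c(i, j)
  }
  if (!length(hits)) return(data.frame(i = integer(0), j = integer(0)))
  out <- as.data.frame(do.call(rbind, hits))
  names(out) <- c("i", "j")
  out[order(out$i, out$j), , drop = FALSE]
}

# fixed-width PDB ATOM/HETATM line
pdb_line <- function(record = "ATOM", serial = 1, name = " CA ", alt = " ",
                     resn = "ALA", chain = "A", resno = 1,
                     x = 0, y = 0, z = 0, occ = 1, elem = " C") {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, alt, resn, chain, resno, x, y, z, occ, 0, elem)
}

# row-stochastic transition matrix of an unbiased nearest-neighbour walk on a
# path graph with absorbing ends
path_graph_P <- function(n) {
  P <- matrix(0, n, n)
  P[1, 1] <- 1
  P[n, n] <- 1
  for (i in 2:(n - 1)) {
    P[i, i - 1] <- 0.5
    P[i, i + 1] <- 0.5
  }
  methods::as(P, "CsparseMatrix")
}

# small calibrated hairpin model shared by the TPT and oracle tests
calibrated_hairpin <- function(n = 3) {
  m <- toy_dimer(n, "hairpin")
  m$epsilon <- calibrate_epsilon(m)
  m
}
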