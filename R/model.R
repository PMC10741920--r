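# The dimer model object: two segmented chains, unit-level contact sets, and
# the thermodynamic parameters of the two-chain WSME free energy.

#' Build a two-chain WSME dimer model
#'
#' Assembles the validated model object holding everything the free-energy
#' function needs: per-chain folding-unit entropies, intra- and inter-chain
#' native contact multiplicities, the elementary contact energy epsilon
#' (each residue-level contact contributes -epsilon when formed), the
#' temperature and the dissociation entropy. Dissociated microstates are
#' stabilised by `-T * s_diss`, so a larger `s_diss` corresponds to a lower
#' protein concentration.
#'
#' @param chain_A,chain_B segmented chains from [segment_chain()], or plain
#'   numeric vectors of per-unit folding entropies (J/(K mol)) for abstract
#'   (toy) models.
#' @param intra_A,intra_B,inter unit-level [contact_set()]s.
#' @param epsilon elementary contact energy in J/mol (> 0).
#' @param temperature temperature in K (default 310).
#' @param s_diss dissociation entropy in J/(K mol) (default 87).
#' @return object of class `dimer_model`.
#' @export
dimer_model <- function(chain_A, chain_B, intra_A, intra_B, inter,
                        epsilon, temperature = 310, s_diss = 87) {
  as_chain <- function(x) {
    if (inherits(x, "segmented_chain")) return(x)
    structure(list(residues = NULL, unit_size = 1L, n_units = length(x),
                   n_res = length(x), unit_entropies = as.numeric(x)),
              class = "segmented_chain")
  }
  chain_A <- as_chain(chain_A); chain_B <- as_chain(chain_B)
  if (chain_A$n_units != chain_B$n_units)
    stop("homodimer chains must have equal unit counts")
  if (!is.numeric(epsilon) || epsilon <= 0) stop("epsilon must be > 0")
  if (temperature <= 0) stop("temperature must be > 0")
  if (s_diss < 0) stop("s_diss must be >= 0")
  if (any(chain_A$unit_entropies < 0) || any(chain_B$unit_entropies < 0))
    stop("unit entropies must be >= 0")
  check_cs <- function(cs, scope, n) {
    if (!inherits(cs, "contact_set") || !identical(attr(cs, "scope"), scope))
      stop(sprintf("expected a contact_set with scope '%s'", scope))
    if (nrow(cs) && (max(cs$i, cs$j) > n || min(cs$i, cs$j) < 1))
      stop(sprintf("%s contact references a unit outside 1..%d", scope, n))
    cs
  }
  n <- chain_A$n_units
  intra_A <- check_cs(intra_A, "intra_A", n)
  intra_B <- check_cs(intra_B, "intra_B", n)
  inter <- check_cs(inter, "inter", n)
  if (nrow(inter) == 0L) stop("no binding interface: inter contact set is empty")
  structure(list(chain_A = chain_A, chain_B = chain_B,
                 intra_A = intra_A, intra_B = intra_B, inter = inter,
                 epsilon = as.numeric(epsilon),
                 temperature = as.numeric(temperature),
                 s_diss = as.numeric(s_diss),
                 gas_constant = .GAS_CONSTANT),
            class = "dimer_model")
}

#' @export
print.dimer_model <- function(x, ...) {
  cat("Two-chain WSME dimer model\n")
  cat(sprintf("  units per chain : %d (k = %d residues/unit)\n",
              x$chain_A$n_units, x$chain_A$unit_size))
  cat(sprintf("  contacts (multiplicity): intra A %d (%g), intra B %d (%g), inter %d (%g)\n",
              nrow(x$intra_A), sum(x$intra_A$m), nrow(x$intra_B),
              sum(x$intra_B$m), nrow(x$inter), sum(x$inter$m)))
  cat(sprintf("  epsilon = %.1f J/mol, T = %g K, S_diss = %g J/(K mol)\n",
              x$epsilon, x$temperature, x$s_diss))
  cat(sprintf("  two-layer microstates (single sequence): %d\n",
              as.integer(count_states(x$chain_A$n_units, "single"))))
  invisible(x)
}

#' Build a dimer model from a PDB structure
#'
#' Runs the full structure-preparation pipeline: parse the two chains, remove
#' hydrogens/heteroatoms, fill missing residues with dummies, assign coil
#' flags from a secondary-structure source, segment into k-residue folding
#' units (C-terminal dummy padding), extract native contacts (< `cutoff`
#' Angstrom minimum heavy-atom distance; intra contacts require
#' `|i - j| >= min_separation`), coarse-grain them onto unit pairs, and
#' calibrate epsilon if requested.
#'
#' @param pdb_source PDB file path or PDB text.
#' @param chain_ids two chain identifiers (default `c("A", "B")`).
#' @param target_units desired folding units per chain (default 12); the unit
#'   size is `ceiling(n_res / target_units)` of the longer chain.
#' @param unit_size explicit unit size k, overriding `target_units`.
#' @param per_residue_entropy folding entropy per structured residue in
#'   J/(K mol). Default 16.5; this is a documented model assumption, not a
#'   structurally derived quantity.
#' @param secondary_structure `NULL` (all residues structured), a DSSP file,
#'   or a one-letter-per-residue string covering both chains in input order
#'   (blank/`-`/`C` = coil, zero folding entropy).
#' @param epsilon elementary contact energy in J/mol, or `"calibrate"` to
#'   bisect for the value making the native-dimer probability
#'   `calibrate_target`.
#' @param calibrate_target native-dimer probability used when
#'   `epsilon = "calibrate"` (default 0.5).
#' @param temperature,s_diss model parameters (defaults 310 K, 87 J/(K mol)).
#' @param cutoff,min_separation contact definition, see [compute_contacts()].
#' @return a [dimer_model()]; the calibrated epsilon (if any) is recorded in
#'   attribute `"calibrated"`.
#' @export
dimer_model_from_pdb <- function(pdb_source, chain_ids = c("A", "B"),
                                 target_units = 12, unit_size = NULL,
                                 per_residue_entropy = 16.5,
                                 secondary_structure = NULL,
                                 epsilon = "calibrate", calibrate_target = 0.5,
                                 temperature = 310, s_diss = 87,
                                 cutoff = 4, min_separation = 3) {
  chains <- parse_structure(pdb_source, chain_ids)
  rA <- chains[[1L]]; rB <- chains[[2L]]
  coilA <- coilB <- NULL
  if (!is.null(secondary_structure)) {
    coil <- secondary_structure_coil(secondary_structure)
    if (length(coil) != rA$n + rB$n)
      stop(sprintf("secondary structure covers %d residues but the chains have %d",
                   length(coil), rA$n + rB$n))
    coilA <- coil[seq_len(rA$n)]
    coilB <- coil[rA$n + seq_len(rB$n)]
  }
  k <- if (!is.null(unit_size)) as.integer(unit_size) else
    choose_unit_size(max(rA$n, rB$n), target_units)
  sA <- segment_chain(rA, k, per_residue_entropy, coilA)
  sB <- segment_chain(rB, k, per_residue_entropy, coilB)
  rc <- compute_contacts(rA, rB, cutoff, min_separation)
  model <- dimer_model(sA, sB,
                       coarse_grain_contacts(rc$intra_A, k, "intra_A"),
                       coarse_grain_contacts(rc$intra_B, k, "intra_B"),
                       coarse_grain_contacts(rc$inter, k, "inter"),
                       epsilon = if (identical(epsilon, "calibrate")) 1 else epsilon,
                       temperature = temperature, s_diss = s_diss)
  if (identical(epsilon, "calibrate")) {
    eps <- calibrate_epsilon(model, target = calibrate_target)
    model$epsilon <- eps
    attr(model, "calibrated") <- eps
  }
  model
}

#' Summarise a dimer model as a provenance list
#'
#' @param model a [dimer_model()].
#' @return list suitable for JSON serialisation: unit counts, unit size,
#'   entropies, contact multiplicities, parameters and microstate counts.
#' @export
model_summary <- function(model) {
  n <- model$chain_A$n_units
  list(
    n_units = n,
    unit_size = model$chain_A$unit_size,
    n_residues = c(A = model$chain_A$n_res, B = model$chain_B$n_res),
    unit_entropies_A = model$chain_A$unit_entropies,
    unit_entropies_B = model$chain_B$unit_entropies,
    contacts = list(
      intra_A = as.data.frame(model$intra_A),
      intra_B = as.data.frame(model$intra_B),
      inter = as.data.frame(model$inter)),
    epsilon = model$epsilon,
    temperature = model$temperature,
    s_diss = model$s_diss,
    n_conformations_per_chain = n * (n + 1) / 2 + 1,
    n_network_nodes = count_states(n, "single"))
}
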