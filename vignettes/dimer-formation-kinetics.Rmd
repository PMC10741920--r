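---
title: "Two-layer WSME/TPT analysis of homodimer formation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-layer WSME/TPT analysis of homodimer formation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimerTPT)
```

## The model

`dimerTPT` treats a homodimer as two coupled Ising-like folding chains. Each
chain is segmented into folding units of *k* consecutive residues; a unit is
either folded or unfolded, and under the **single sequence approximation** at
most one contiguous stretch of units is folded at a time. A chain of *n*
units therefore has `n(n+1)/2 + 1` conformations, and the dimer's state space
is the set of ordered conformation pairs, each present twice: once
dissociated and once associated (the two *layers*). For the 11-unit chains
used as the reference working size this gives `count_states(11, "single")`
= 8978 microstates.

The single-chain free energy is the WSME (Wako–Saito–Muñoz–Eaton) form: a
native contact between units *i* and *j* contributes its (negative) contact
energy only when every unit from *i* to *j* is folded, and every unfolded
unit contributes `-T * s_i` where `s_i` is the folding entropy released on
unfolding. Inter-chain contacts are active in the associated layer whenever
their two endpoint units are folded — no path condition couples the two
chains. Dissociated microstates gain `-T * S_diss`.

Two modelling assumptions are inherited from the two-layer construction and
worth keeping in mind:

* all dissociated arrangements of a conformation pair are energetically
  equivalent and merged into one node;
* of all associated arrangements only the minimum-energy (native-like docked)
  one is kept, i.e. the binding landscape between any two conformations is
  assumed funneled.

## Parameters

| parameter | units | default | role |
|---|---|---|---|
| `temperature` | K | 310 | sets RT in Boltzmann weights and Metropolis rates |
| `s_diss` | J/(K mol) | 87 | dissociation entropy; concentration proxy (larger = more dilute) |
| `epsilon` | J/mol | calibrated | elementary energy of one residue-level native contact |
| `per_residue_entropy` | J/(K mol) | 16.5 | folding entropy per structured residue |
| `target_units` | — | 12 | folding units per chain after segmentation |
| `cutoff` | Å | 4 | native-contact distance threshold (strict `<`, heavy atoms) |
| `min_separation` | residues | 3 | intra-chain contacts need `|i - j| >= 3` |

`epsilon` is by default **calibrated** by bisection so that the equilibrium
probability of the native dimer is 0.5 at the model temperature — the native
ensemble and the rest of the state space are balanced, which makes mechanism
fractions comparable across dimers. The calibration target set is the
*product set*: every associated microstate in which all native contacts
(intra- and inter-chain) are formed. This is deliberately the same set that
defines the TPT products, and it can contain more than one state when
terminal units carry no contacts.

The per-residue folding entropy is the one parameter that cannot be derived
from the input structure. The default of 16.5 J/(K mol) per structured
residue is a typical literature-scale value for the conformational entropy
lost per residue on folding; it is an explicit model assumption, exposed as
`per_residue_entropy`, and results that depend on its absolute scale (the
calibrated `epsilon`, absolute fluxes) should be interpreted accordingly.
Residues without regular secondary structure (blank/`-`/`C` in the
DSSP-style input) and dummy residues (gap fill, C-terminal padding)
contribute zero folding entropy: they are coil in the native state, so no
entropy is released when they "unfold".

## Contact extraction and segmentation

Hydrogens and hetero-residues are removed; alternate locations resolve to the
highest occupancy (ties by altloc order); missing residues become dummy
records. Residue-level contacts use the minimum heavy-atom distance with a
strict 4 Å cutoff. Contacts are then coarse-grained: each residue-level
contact increments the multiplicity `m_ij` of its unit pair, and the unit
pair's energy is `-epsilon * m_ij`. Counting residue-level contacts (rather
than atom pairs) keeps `epsilon` interpretable as "energy per residue
contact"; contacts that fall inside a single unit (`i = j`) are retained and
become active when that unit folds. The unit size is
`ceiling(n_res / target_units)`, and the C-terminus is padded with dummy
residues to a multiple of *k*.

## Dynamics and Transition Path Theory

The move set changes one chain's stretch by one unit at either end
(nucleation from, and denucleation to, the fully unfolded conformation
included) or flips the association layer at fixed conformations. Transition
probabilities follow the Metropolis–Hastings rule with a priori probability
`1/n_i`:

```
p_ij = min(1, (n_i / n_j) * exp((F_i - F_j) / RT)) / n_i
```

Duplicate move targets are collapsed, so `n_i` counts *distinct* neighbour
states and the adjacency is a simple symmetric graph. This choice is what
makes the chain exactly reversible with respect to the Boltzmann
distribution — the property the whole TPT layer rests on (`q⁻ = 1 − q⁺`,
detailed balance, Boltzmann stationarity) — and it is asserted at run time
and in the test suite. Self-loops absorb the residual row probability and
carry no reactive flux.

TPT takes the reactant set R as *all* dissociated microstates and the
product set P as the native product set above. Forward committors solve the
harmonic boundary-value problem by sparse LU factorisation; gross reactive
fluxes `f_ij = π_i q⁻_i p_ij q⁺_j` are used in all aggregates (the
summations are over directed edges, not net currents). Because R is the
whole dissociated layer, every reactive excursion crosses the layer boundary
exactly once, through the layer-flip edge of one conformation pair; that
crossing is classified as

* **rigid docking** — both chains folded,
* **conformational selection** — exactly one folded,
* **induced folding** — neither folded,

where "folded" means the chain's stretch forms *all of its intra-chain
native contacts* (covers their span). This contact-based definition is
robust to contact-free terminal units; the stricter alternative requiring
every unit folded is available via `folded_chain = "all-units"`. A chain
with no intra-chain contacts at all is vacuously folded — defensible because
such a chain has no folding transition to speak of — so an interface-only
model reports pure rigid docking.

The same crossing fluxes, accumulated differently, give the association-flux
map over folding degrees `F(Q_A, Q_B)` (folding degree counts all folded
units, including entropy-free padding units inside the stretch — an axis
labelling choice only) and the per-segment foldedness `F_k` at the moment of
association, reported for both chains at unit and residue granularity.

`sdiss_scan()` repeats the analysis over a grid of `S_diss` values
(default `seq(0, 150, by = 5)`, bracketing the 87 J/(K mol) reference
value); only the dissociated-layer offset changes, and the characteristic
trend — rigid docking growing, induced folding shrinking with dilution — is
part of the acceptance suite.

### A note on the dissociated-layer term

The two-chain free energy adds the dissociation entropy to dissociated
states. Dimensional consistency (J/(K mol) vs J/mol) requires the term to
enter as `-T * S_diss`; with this sign larger `S_diss` stabilises the
dissociated layer, i.e. corresponds to lower concentration, which is the
behaviour the concentration scan relies on. This convention is asserted by
the `microstate_free_energy()` tests.

## Numerical choices

* All Boltzmann sums shift free energies by their minimum before
  exponentiation; Metropolis exponents are clamped at 700 (the `min(1, ·)`
  makes larger values equivalent).
* Nodes are ordered canonically (dissociated layer first; conformation of
  chain A major, chain B minor; conformations ordered EMPTY, then by
  (first, last)), so every output is bit-for-bit reproducible.
* Committor solutions are clipped to [0, 1]; the clip magnitude is recorded
  in `checks$committor_clip` and must stay below 1e-8. The harmonicity
  residual (`< 1e-10`), row-sum error (`< 1e-12`), the three independent
  `f_total` computations (association-edge, reactant-exit, product-entry
  sums; `< 1e-10` relative) and the interior-node flux imbalance are all
  recorded in the fitted object's `checks`.
* `calibrate_epsilon()` bisects on [0, 1e5] J/mol to `|P_native − 0.5| <
  1e-6`; the probability is strictly increasing in `epsilon`, so the root is
  unique, and a non-bracketing interval is reported with the probabilities
  at both ends.
* Degenerate inputs fail loudly: a missing chain lists the available ones,
  an empty inter-chain contact set is "no binding interface", an empty
  product set or zero reactive flux is an explicit error rather than NaNs.

## The synthetic generator and what passing tests mean

`toy_dimer()` builds fully specified unit-level models (templates:
`interface-only`, `hairpin`, `helix-ladder`, seeded `random`), and
`write_toy_pdb()` emits a minimal two-chain ladder structure so the full
PDB-to-mechanism pipeline runs end to end without any download. The Monte
Carlo oracle (`simulate_trajectories()`, `mc_association_events()`,
`occupation_frequencies()`; Mersenne-Twister via `set.seed()`) samples the
very same transition matrix, so agreement with the linear-solve results
validates the TPT algebra and its implementation — it does not validate the
physical model. The toys emulate the *structure* of real inputs (contact
topology, entropies, the two layers), not their energetics: real proteins
have hundreds of contacts with strong topological correlation, while toys
have a handful. Conclusions about real dimers therefore require real
structures; the synthetic suite establishes that, given a model, the
kinetics and flux accounting are computed correctly.

Test problem sizes: invariants run on 2–4-unit toys (32–242 nodes), the
Monte Carlo cross-check uses the 98-node three-unit hairpin with at least
1e5 reactive paths, and the full pipeline is exercised at up to 11 units
(8978 nodes), the working size for real chains of ~100 residues with
`target_units = 12`.

## Limitations

* Kinetics are computed under the single sequence approximation only; the
  double sequence approximation is implemented for state counting (to size
  the problem), not for dynamics — its 11-unit network would have 631,688
  nodes and a correspondingly denser transition matrix.
* The chain is discrete-time; transition probabilities are per move, so
  fluxes are relative. Mechanism fractions and flux maps are
  dimensionless and unaffected, but no physical rate constants or
  first-passage times are produced.
* One structure parameterises the whole landscape (a structure-based,
  Gō-like philosophy): non-native interactions, and any difference between
  the monomeric and dimeric native structures (e.g. domain swaps), are
  outside the model.
* mmCIF input, assembly expansion and symmetry mates are not handled; the
  input must already contain the two chains of the biological dimer.
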