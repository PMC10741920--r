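# dimerTPT

Kinetics of protein homodimer formation from a two-layer kinetic transition
network: a two-chain Wako–Saito–Muñoz–Eaton (WSME) folding model analysed
with discrete Transition Path Theory (TPT).

## The problem

When two identical protein chains form a homodimer, folding and binding are
coupled: the chains may fold first and dock as rigid bodies (*rigid
docking*), one pre-folded chain may select its partner (*conformational
selection*), or binding may precede folding entirely (*induced folding*).
`dimerTPT` quantifies the relative contribution of each mechanism as a
fraction of the reactive probability flux from the fully dissociated
ensemble to the native dimer, for users studying coupled folding-and-binding
thermodynamics and kinetics from structure-based models.

## The model

Each chain is divided into folding units of *k* consecutive residues; under
the single sequence approximation a chain conformation is a single
contiguous folded stretch (or none), giving `n(n+1)/2 + 1` conformations for
*n* units. The single-chain free energy is the WSME form

F(v) = Σ_{(i,j)∈N} ε_ij Π_{k=i..j} v_k − T Σ_i s_i (1 − v_i),

with native contacts N (minimum heavy-atom distance < 4 Å; intra-chain
contacts require at least two intervening residues), ε_ij = −ε·m_ij for
m_ij residue-level contacts between units i and j, and folding entropy s_i
per structured residue. The two-chain state adds a layer flag δ:

F(u, v, δ) = F(u) + F(v) + δ Σ_{(i,j)∈M} ε_ij u_i v_j − (1 − δ) T S_diss,

so each ordered conformation pair contributes one associated (δ = 1) and one
dissociated (δ = 0) microstate — the two layers of the network. Inter-chain
contacts M need only their endpoint units folded. The dissociation entropy
S_diss stabilises the dissociated layer and acts as a concentration proxy
(larger S_diss ⇔ lower concentration). ε is calibrated per dimer so that the
native dimer (all contacts formed) has equilibrium probability 0.5 at
T = 310 K.

Moves grow or shrink one chain's stretch by one unit, or flip δ at fixed
conformations; edge weights are Metropolis–Hastings probabilities
`p_ij = min(1, (n_i/n_j) exp((F_i − F_j)/RT)) / n_i` with out-degrees n_i,
reversible with respect to the Boltzmann distribution. TPT committors are
solved sparsely, and the gross reactive fluxes
`f_ij = π_i q⁻_i p_ij q⁺_j` on dissociation→association edges are
partitioned by the folding state of the two chains at the moment of binding,
accumulated over folding degrees (Q_A, Q_B), and resolved per segment.

## Worked example

```r
library(dimerTPT)

model <- toy_dimer(3, "hairpin")             # 3 folding units per chain
model$epsilon <- calibrate_epsilon(model)    # native-dimer probability 0.5
round(model$epsilon, 1)
#> [1] 29452.4

fit <- dimer_kinetics(model)
fit
#> Two-layer WSME/TPT analysis of dimer formation
#>   nodes: 98  (units/chain: 3)   S_diss = 87 J/(K mol)
#>   total reactive flux f_total = 0.03824
#>   mechanism flux fractions:
#>     induced folding          1.659e-06
#>     conformational selection 0.001951
#>     rigid docking            0.998
#>   dominant mechanism: rigid docking

scan <- sdiss_scan(model, c(20, 87, 150))
scan
#> <dimer_scan> 3 dissociation-entropy values
#>   s_diss   induced   confsel  rigid
#> 1     20 8.722e-04 0.0645619 0.9346
#> 2     87 1.659e-06 0.0019513 0.9980
#> 3    150 3.379e-07 0.0008849 0.9991
```

The mechanism fractions are shares of the total reactive association flux:
here 99.8 % of dimer-forming events at S_diss = 87 J/(K mol) bind after both
chains have formed all their intra-chain contacts (rigid docking), and the
rigid share grows as the concentration drops (S_diss = 150) while induced
folding shrinks — the expected concentration dependence. `plot(fit)` draws
the association-flux heatmap over folding degrees; `fit$foldedness` gives
per-segment foldedness at the moment of association; `simulate(fit)` draws
Monte Carlo trajectories on the same network as an independent check.

For a real structure:

```r
model <- dimer_model_from_pdb("1xyz.pdb", chains = c("A", "B"),
                              target_units = 12,
                              secondary_structure = "1xyz.dssp",
                              epsilon = "calibrate")
fit <- dimer_kinetics(model)
```

or from the shell: `exec/dimertpt run --pdb 1xyz.pdb --out-dir out/`.

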