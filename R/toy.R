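# Synthetic toy dimers: small, fully specified models so every downstream
# stage (energies, network, TPT, Monte Carlo) is testable without any
# structure download.

#' Generate a toy dimer model
#'
#' Named templates:
#' * `"interface-only"`: no intra-chain contacts, a single inter contact
#'   between the middle units. With `n_units = 1` this is the 8-state model
#'   with a closed-form partition function.
#' * `"hairpin"`: one intra contact spanning the whole chain (1, n) on both
#'   chains plus a single inter contact between the middle units.
#' * `"helix-ladder"`: intra contacts between consecutive unit pairs
#'   (i, i + 1) on both chains and inter contacts (i, i) along the whole
#'   interface.
#' * `"random"`: seeded random intra/inter contact pattern and entropies;
#'   the same seed always yields the identical model.
#'
#' Explicit `intra_A`, `intra_B`, `inter` contact sets override the template.
#'
#' @param n_units folding units per chain.
#' @param template one of `"interface-only"`, `"hairpin"`, `"helix-ladder"`,
#'   `"random"`.
#' @param intra_A,intra_B,inter optional explicit [contact_set()]s.
#' @param unit_entropy per-unit folding entropy (scalar or length-n vector),
#'   J/(K mol).
#' @param epsilon,temperature,s_diss model parameters.
#' @param seed RNG seed used by the `"random"` template.
#' @return a [dimer_model()].
#' @export
toy_dimer <- function(n_units = 3,
                      template = c("interface-only", "hairpin", "helix-ladder",
                                   "random"),
                      intra_A = NULL, intra_B = NULL, inter = NULL,
                      unit_entropy = 30, epsilon = 2000,
                      temperature = 310, s_diss = 87, seed = 1) {
  template <- match.arg(template)
  n <- as.integer(n_units)
  mid <- (n + 1L) %/% 2L
  ent <- rep_len(unit_entropy, n)
  if (template == "random") {
    made <- .with_seed(seed, {
      n_intra <- sample.int(max(1L, n), 1L)
      pick <- function() {
        i <- sample.int(n, n_intra, replace = TRUE)
        j <- sample.int(n, n_intra, replace = TRUE)
        unique(data.frame(i = pmin(i, j), j = pmax(i, j)))
      }
      pa <- pick(); pb <- pick()
      n_inter <- sample.int(n, 1L)
      pi_ <- data.frame(i = sample.int(n, n_inter, replace = TRUE),
                        j = sample.int(n, n_inter, replace = TRUE))
      pi_ <- unique(pi_)
      list(
        intra_A = contact_set(pa$i, pa$j, sample.int(3L, nrow(pa), TRUE), "intra_A"),
        intra_B = contact_set(pb$i, pb$j, sample.int(3L, nrow(pb), TRUE), "intra_B"),
        inter = contact_set(pi_$i, pi_$j, sample.int(3L, nrow(pi_), TRUE), "inter"),
        ent = round(runif(n, 15, 60), 1))
    })
    ent <- made$ent
    tpl <- made[c("intra_A", "intra_B", "inter")]
  } else {
    tpl <- switch(template,
      "interface-only" = list(
        intra_A = contact_set(integer(0), integer(0), integer(0), "intra_A"),
        intra_B = contact_set(integer(0), integer(0), integer(0), "intra_B"),
        inter = contact_set(mid, mid, 1L, "inter")),
      "hairpin" = list(
        intra_A = contact_set(1L, n, 1L, "intra_A"),
        intra_B = contact_set(1L, n, 1L, "intra_B"),
        inter = contact_set(mid, mid, 1L, "inter")),
      "helix-ladder" = list(
        intra_A = if (n > 1L)
          contact_set(seq_len(n - 1L), seq_len(n - 1L) + 1L,
                      rep(1L, n - 1L), "intra_A")
          else contact_set(integer(0), integer(0), integer(0), "intra_A"),
        intra_B = if (n > 1L)
          contact_set(seq_len(n - 1L), seq_len(n - 1L) + 1L,
                      rep(1L, n - 1L), "intra_B")
          else contact_set(integer(0), integer(0), integer(0), "intra_B"),
        inter = contact_set(seq_len(n), seq_len(n), rep(1L, n), "inter")))
  }
  if (!is.null(intra_A)) tpl$intra_A <- intra_A
  if (!is.null(intra_B)) tpl$intra_B <- intra_B
  if (!is.null(inter)) tpl$inter <- inter
  dimer_model(ent, ent, tpl$intra_A, tpl$intra_B, tpl$inter,
              epsilon = epsilon, temperature = temperature, s_diss = s_diss)
}

# evaluate expr under a local RNG seed without disturbing the caller's RNG
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Write a minimal toy-dimer PDB file
#'
#' Emits valid PDB text for two chains of single-atom (CA) residues laid out
#' as a parallel ladder: residues `spacing` Angstrom apart along x, the chains
#' `gap` Angstrom apart in y. With the defaults, each residue is in contact
#' (< 4 Angstrom) only with its opposite number on the other chain, so the
#' parsed model has a pure interface-ladder contact map -- a predictable
#' end-to-end fixture for the structure pipeline.
#'
#' @param n_res residues per chain.
#' @param path output file (default: a tempfile).
#' @param spacing along-chain CA spacing in Angstrom (default 5).
#' @param gap inter-chain separation in Angstrom (default 3.5).
#' @param chain_ids two chain identifiers.
#' @return the path, invisibly.
#' @export
write_toy_pdb <- function(n_res = 6, path = tempfile(fileext = ".pdb"),
                          spacing = 5, gap = 3.5, chain_ids = c("A", "B")) {
  lines <- character(0)
  serial <- 0L
  for (ci in 1:2) {
    y <- (ci - 1L) * gap
    for (r in seq_len(n_res)) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial, chain_ids[ci], r, (r - 1) * spacing, y, 0))
    }
    lines <- c(lines, "TER")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
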