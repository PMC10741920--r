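# Structure preparation: PDB parsing, secondary structure, segmentation into
# folding units, native contact extraction.

# A residue set is the per-chain list of residue records: 1-based index, 3-letter
# name, heavy-atom coordinates (0-row matrix for dummy residues), dummy flag
# (missing residues filled in, or C-terminal padding) and coil flag (no regular
# secondary structure; dummy residues are always coil and carry zero folding
# entropy).
.new_residue_set <- function(name, coords, is_dummy, is_coil) {
  stopifnot(length(name) == length(coords),
            length(name) == length(is_dummy),
            length(name) == length(is_coil))
  structure(list(n = length(name), name = name, coords = coords,
                 is_dummy = is_dummy, is_coil = is_coil | is_dummy),
            class = "residue_set")
}

#' @export
print.residue_set <- function(x, ...) {
  cat(sprintf("<residue_set> %d residues (%d dummy, %d coil)\n",
              x$n, sum(x$is_dummy), sum(x$is_coil)))
  invisible(x)
}

#' Parse a homodimer structure from PDB
#'
#' Reads standard ATOM records of the first model, removes hydrogens and
#' hetero-residues, resolves alternate locations to the highest-occupancy
#' conformer (ties broken by altloc identifier order), and fills gaps in the
#' residue numbering with dummy residues (no coordinates, coil conformation).
#'
#' @param pdb_source path to a PDB file, or PDB text (string containing
#'   newlines).
#' @param chain_ids character vector of two chain identifiers.
#' @return named list of two residue sets (one per chain).
#' @export
parse_structure <- function(pdb_source, chain_ids = c("A", "B")) {
  stopifnot(length(chain_ids) == 2L)
  path <- pdb_source
  if (length(pdb_source) > 1L || grepl("\n", pdb_source[1L], fixed = TRUE)) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(unlist(strsplit(pdb_source, "\n", fixed = TRUE)), path)
  }
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  elem <- toupper(trimws(at$elesy))
  no_elem <- is.na(elem) | elem == ""
  # fall back on the atom-name convention when the element column is blank
  elem[no_elem] <- substr(gsub("^[0-9]", "", trimws(at$elety[no_elem])), 1, 1)
  at <- at[!(elem %in% c("H", "D")), , drop = FALSE]
  if (nrow(at) == 0L) stop("no standard heavy atoms found in PDB input")
  have <- unique(at$chain)
  missing <- setdiff(chain_ids, have)
  if (length(missing))
    stop(sprintf("chain(s) %s not found; available chains: %s",
                 paste(missing, collapse = ", "), paste(have, collapse = ", ")))

  out <- lapply(chain_ids, function(ch) {
    a <- at[at$chain == ch, , drop = FALSE]
    if (nrow(a) == 0L) stop(sprintf("chain %s has no standard residues", ch))
    a$insert[is.na(a$insert)] <- ""
    a$alt[is.na(a$alt)] <- ""
    rkey <- paste(a$resno, a$insert, sep = "_")
    # altloc: within each residue/atom-name group keep highest occupancy,
    # ties by altloc identifier order ("" sorts first, i.e. wins ties)
    akey <- paste(rkey, a$elety, sep = "|")
    occ <- a$o; occ[is.na(occ)] <- 1
    ord <- order(akey, -occ, a$alt)
    a <- a[ord, , drop = FALSE]
    a <- a[!duplicated(akey[ord]), , drop = FALSE]
    a <- a[order(a$resno, a$insert, a$eleno), , drop = FALSE]
    rkey <- paste(a$resno, a$insert, sep = "_")
    ukeys <- unique(rkey)
    resno <- a$resno[match(ukeys, rkey)]
    rname <- a$resid[match(ukeys, rkey)]
    coords <- lapply(ukeys, function(k) {
      m <- as.matrix(a[rkey == k, c("x", "y", "z")])
      dimnames(m) <- NULL
      m
    })
    # fill numbering gaps with dummy residues
    name <- character(0); crd <- list(); dummy <- logical(0)
    for (i in seq_along(ukeys)) {
      if (i > 1L) {
        gap <- resno[i] - resno[i - 1L] - 1L
        if (gap > 0L) {
          name <- c(name, rep("UNK", gap))
          crd <- c(crd, rep(list(matrix(numeric(0), 0L, 3L)), gap))
          dummy <- c(dummy, rep(TRUE, gap))
        }
      }
      name <- c(name, rname[i])
      crd <- c(crd, coords[i])
      dummy <- c(dummy, FALSE)
    }
    .new_residue_set(name, crd, dummy, is_coil = dummy)
  })
  names(out) <- chain_ids
  out
}

#' Read a secondary-structure assignment
#'
#' Accepts either a DSSP output file or a plain one-letter-per-residue string
#' (chain-concatenated in input order). Blank, space, `-` and `C` codes map to
#' coil; every other code (H, G, I, E, B, T, S) is treated as structured.
#'
#' @param x path to a DSSP file, a plain secondary-structure string, or a path
#'   to a text file holding such a string.
#' @return logical vector: `TRUE` where the residue is coil.
#' @export
secondary_structure_coil <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    lines <- readLines(x, warn = FALSE)
    hdr <- grep("^  #  RESIDUE", lines)
    if (length(hdr)) {                      # DSSP format
      data <- lines[(hdr[1L] + 1L):length(lines)]
      data <- data[nchar(data) >= 17]
      data <- data[substr(data, 14, 14) != "!"]  # chain breaks
      codes <- substr(data, 17, 17)
    } else {
      codes <- strsplit(paste(gsub("\\s", "", lines), collapse = ""), "")[[1L]]
    }
  } else {
    codes <- strsplit(paste(x, collapse = ""), "")[[1L]]
  }
  toupper(codes) %in% c(" ", "", "-", "C")
}

#' Pick the folding-unit size for a target unit count
#'
#' Chooses the smallest k such that the chain, after C-terminal padding,
#' has at most `target_units` folding units: `k = ceiling(n / target)`.
#'
#' @param n_residues residue count of the chain.
#' @param target_units desired number of folding units (>= 1).
#' @return unit size k (integer).
#' @export
choose_unit_size <- function(n_residues, target_units) {
  if (target_units < 1) stop("target_units must be >= 1")
  as.integer(ceiling(n_residues / target_units))
}

#' Segment a chain into folding units
#'
#' Combines k consecutive residues into one folding unit, padding the
#' C-terminus with dummy residues so the length is a multiple of k. The
#' folding entropy of a unit is `per_residue_entropy` times the number of its
#' non-coil, non-dummy residues (coil and dummy residues carry zero folding
#' entropy).
#'
#' @param residues a residue set from [parse_structure()].
#' @param unit_size residues per folding unit (k >= 1).
#' @param per_residue_entropy folding entropy per structured residue,
#'   J/(K mol).
#' @param coil_flags optional logical vector overriding the residue set's coil
#'   flags (dummy residues are forced coil regardless).
#' @return a `segmented_chain`: the padded residue set, `unit_size`,
#'   `n_units`, `n_res` (unpadded residue count) and `unit_entropies`.
#' @export
segment_chain <- function(residues, unit_size, per_residue_entropy = 16.5,
                          coil_flags = NULL) {
  if (unit_size < 1) stop("unit_size must be >= 1")
  k <- as.integer(unit_size)
  r <- residues
  if (!is.null(coil_flags)) {
    if (length(coil_flags) != r$n)
      stop("coil_flags length must equal the residue count")
    r$is_coil <- coil_flags | r$is_dummy
  }
  n0 <- r$n
  pad <- (k - n0 %% k) %% k
  if (pad > 0L) {
    r <- .new_residue_set(c(r$name, rep("UNK", pad)),
                          c(r$coords, rep(list(matrix(numeric(0), 0L, 3L)), pad)),
                          c(r$is_dummy, rep(TRUE, pad)),
                          c(r$is_coil, rep(TRUE, pad)))
  }
  n_units <- r$n %/% k
  unit_of <- rep(seq_len(n_units), each = k)
  structured <- !r$is_coil & !r$is_dummy
  ent <- as.numeric(rowsum(as.numeric(structured), unit_of)) * per_residue_entropy
  structure(list(residues = r, unit_size = k, n_units = n_units, n_res = n0,
                 unit_entropies = ent),
            class = "segmented_chain")
}

#' @export
print.segmented_chain <- function(x, ...) {
  cat(sprintf("<segmented_chain> %d residues, k = %d -> %d units; total entropy %.1f J/(K mol)\n",
              x$n_res, x$unit_size, x$n_units, sum(x$unit_entropies)))
  invisible(x)
}

# minimum heavy-atom distance between every residue of r1 and every residue of
# r2; dummy residues get +Inf rows/columns
.min_dist_matrix <- function(r1, r2) {
  n1 <- r1$n; n2 <- r2$n
  a1 <- do.call(rbind, r1$coords); a2 <- do.call(rbind, r2$coords)
  if (is.null(a1) || nrow(a1) == 0L || is.null(a2) || nrow(a2) == 0L)
    stop("chain has no heavy-atom coordinates")
  id1 <- rep(seq_len(n1), vapply(r1$coords, nrow, integer(1)))
  id2 <- rep(seq_len(n2), vapply(r2$coords, nrow, integer(1)))
  d2 <- matrix(rowSums(a1^2), nrow(a1), nrow(a2)) +
    matrix(rowSums(a2^2), nrow(a1), nrow(a2), byrow = TRUE) -
    2 * a1 %*% t(a2)
  d2[d2 < 0] <- 0
  out <- matrix(Inf, n1, n2)
  for (j in seq_len(n2)) {
    cols <- which(id2 == j)
    if (!length(cols)) next
    cmin <- if (length(cols) == 1L) d2[, cols] else
      do.call(pmin, lapply(cols, function(cc) d2[, cc]))
    m <- vapply(seq_len(n1), function(i) {
      rows <- which(id1 == i)
      if (!length(rows)) Inf else min(cmin[rows])
    }, numeric(1))
    out[, j] <- m
  }
  sqrt(out)
}

#' Native residue-level contacts of a dimer
#'
#' Two residues are in native contact if the minimum distance between their
#' heavy atoms is strictly below `cutoff`. Intra-chain contacts additionally
#' require at least `min_separation - 1` intervening residues
#' (`|i - j| >= min_separation`); inter-chain contacts are unrestricted.
#' Dummy residues are never in contact.
#'
#' @param residues_A,residues_B residue sets of the two chains.
#' @param cutoff contact distance cutoff in Angstrom (default 4).
#' @param min_separation minimum intra-chain sequence separation (default 3,
#'   i.e. at least two residues between the partners).
#' @return list of three data frames (`intra_A`, `intra_B`, `inter`) with
#'   columns `i`, `j` (residue indices; `i <= j` for intra).
#' @export
compute_contacts <- function(residues_A, residues_B, cutoff = 4,
                             min_separation = 3) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  intra <- function(r) {
    d <- .min_dist_matrix(r, r)
    sel <- which(d < cutoff, arr.ind = TRUE)
    sel <- sel[sel[, 2L] - sel[, 1L] >= min_separation, , drop = FALSE]
    out <- data.frame(i = as.integer(sel[, 1L]), j = as.integer(sel[, 2L]))
    out[order(out$i, out$j), , drop = FALSE]
  }
  d <- .min_dist_matrix(residues_A, residues_B)
  sel <- which(d < cutoff, arr.ind = TRUE)
  inter <- data.frame(i = as.integer(sel[, 1L]), j = as.integer(sel[, 2L]))
  list(intra_A = intra(residues_A), intra_B = intra(residues_B),
       inter = inter[order(inter$i, inter$j), , drop = FALSE])
}

#' Map residue-level contacts onto folding units
#'
#' Each residue-level contact (i, j) increments the multiplicity of the unit
#' pair (ceiling(i/k), ceiling(j/k)). Intra pairs are stored with i <= j;
#' contacts falling inside one unit (i = j) are kept and become active when
#' that unit folds.
#'
#' @param residue_contacts data frame with residue index columns `i`, `j`.
#' @param unit_size residues per folding unit.
#' @param scope one of `"intra_A"`, `"intra_B"`, `"inter"`.
#' @return a `contact_set`: data frame `i`, `j`, `m` (unit indices and
#'   multiplicity) with a `scope` attribute.
#' @export
coarse_grain_contacts <- function(residue_contacts, unit_size,
                                  scope = c("intra_A", "intra_B", "inter")) {
  scope <- match.arg(scope)
  k <- as.integer(unit_size)
  ui <- ceiling(residue_contacts$i / k)
  uj <- ceiling(residue_contacts$j / k)
  if (scope != "inter") {
    lo <- pmin(ui, uj); hi <- pmax(ui, uj)
    ui <- lo; uj <- hi
  }
  if (length(ui) == 0L)
    return(contact_set(integer(0), integer(0), integer(0), scope))
  key <- paste(ui, uj)
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
  cs <- contact_set(as.integer(parts[, 1L]), as.integer(parts[, 2L]),
                    as.integer(tab), scope)
  cs[order(cs$i, cs$j), , drop = FALSE]
}

#' Construct a unit-level contact set
#'
#' @param i,j 1-based folding-unit indices (`i <= j` required for intra
#'   scopes).
#' @param m contact multiplicities (>= 1); each unit-pair energy enters the
#'   model as `-epsilon * m`.
#' @param scope one of `"intra_A"`, `"intra_B"`, `"inter"`.
#' @return data frame of class `contact_set`.
#' @export
contact_set <- function(i, j, m = rep(1L, length(i)),
                        scope = c("intra_A", "intra_B", "inter")) {
  scope <- match.arg(scope)
  if (any(m < 1)) stop("contact multiplicities must be >= 1")
  if (scope != "inter" && any(i > j)) stop("intra contacts require i <= j")
  out <- data.frame(i = as.integer(i), j = as.integer(j), m = as.numeric(m))
  class(out) <- c("contact_set", "data.frame")
  attr(out, "scope") <- scope
  out
}
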