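test_that("PDB parsing keeps standard heavy atoms of the requested chains", {
  pdb <- write_toy_pdb(6, tempfile(fileext = ".pdb"))
  chains <- parse_structure(pdb)
  expect_named(chains, c("A", "B"))
  expect_identical(chains$A$n, 6L)
  expect_identical(chains$B$n, 6L)
  expect_false(any(chains$A$is_dummy))
  expect_true(all(vapply(chains$A$coords, nrow, integer(1)) == 1L))
})

test_that("numbering gaps are filled with dummy coil residues", {
  lines <- c(
    pdb_line(serial = 1, resno = 1, x = 0),
    pdb_line(serial = 2, resno = 2, x = 4),
    pdb_line(serial = 3, resno = 4, x = 12),
    pdb_line(serial = 4, resno = 5, x = 16),
    pdb_line(serial = 5, chain = "B", resno = 1, y = 30),
    "END")
  chains <- parse_structure(paste(lines, collapse = "\n"), c("A", "B"))
  expect_identical(chains$A$n, 5L)
  expect_true(chains$A$is_dummy[3L])
  expect_true(chains$A$is_coil[3L])
  expect_identical(nrow(chains$A$coords[[3L]]), 0L)
  expect_false(any(chains$A$is_dummy[-3L]))
})

test_that("hydrogens and hetero-residues are excluded", {
  lines <- c(
    pdb_line(serial = 1, resno = 1),
    pdb_line(serial = 2, name = " HB2", resno = 1, x = 1, elem = " H"),
    pdb_line(record = "HETATM", serial = 3, name = " O  ", resn = "HOH",
             resno = 2, x = 2, elem = " O"),
    pdb_line(serial = 4, chain = "B", resno = 1, y = 30),
    "END")
  chains <- parse_structure(paste(lines, collapse = "\n"), c("A", "B"))
  expect_identical(chains$A$n, 1L)
  expect_identical(nrow(chains$A$coords[[1L]]), 1L)  # only the CA survives
})

test_that("altloc conflicts resolve to the highest occupancy", {
  lines <- c(
    pdb_line(serial = 1, alt = "A", resno = 1, x = 0, occ = 0.4),
    pdb_line(serial = 2, alt = "B", resno = 1, x = 9, occ = 0.6),
    pdb_line(serial = 3, chain = "B", resno = 1, y = 30),
    "END")
  chains <- parse_structure(paste(lines, collapse = "\n"), c("A", "B"))
  expect_identical(chains$A$n, 1L)
  expect_equal(chains$A$coords[[1L]][1L, 1L], 9)
})

test_that("a missing chain is reported with the available ones", {
  pdb <- write_toy_pdb(3)
  expect_error(parse_structure(pdb, c("A", "C")), "available chains: A, B")
})

test_that("segmentation pads with dummies and sums structured-residue entropy", {
  pdb <- write_toy_pdb(25)
  r <- parse_structure(pdb)$A
  sc <- segment_chain(r, 2, per_residue_entropy = 16.5)
  expect_identical(sc$residues$n, 26L)
  expect_identical(sc$n_units, 13L)
  expect_true(sc$residues$is_dummy[26L])
  # padding unit: one real + one dummy residue
  expect_equal(sc$unit_entropies[13L], 16.5)

  # a 4-residue unit with 2 coil residues carries entropy for the other 2
  r4 <- parse_structure(write_toy_pdb(4))$A
  sc4 <- segment_chain(r4, 4, 16.5, coil_flags = c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(sc4$unit_entropies, 33)

  # an all-dummy padding unit has zero entropy
  r5 <- parse_structure(write_toy_pdb(5))$A
  sc5 <- segment_chain(r5, 5, 16.5, coil_flags = rep(FALSE, 5))
  expect_identical(sc5$n_units, 1L)
  sc10 <- segment_chain(r5, 10, 16.5)
  expect_identical(sc10$n_units, 1L)
  expect_error(segment_chain(r5, 0), "unit_size")
  expect_error(segment_chain(r5, 2, coil_flags = c(TRUE, FALSE)), "length")
})

test_that("unit size choice respects the target unit count", {
  expect_identical(choose_unit_size(100, 12), 9L)
  expect_identical(choose_unit_size(12, 12), 1L)
  expect_identical(choose_unit_size(11, 12), 1L)
  # enumeration: padded unit count never exceeds the target
  for (n in c(7, 23, 100, 101, 107, 131)) for (target in c(1, 5, 11, 12)) {
    k <- choose_unit_size(n, target)
    expect_lte(ceiling(n / k), target)
    if (k > 1L) expect_gt(ceiling(n / (k - 1L)), target)  # smallest such k
  }
  expect_error(choose_unit_size(10, 0), "target_units")
})

test_that("contact detection applies the cutoff strictly and the separation rule", {
  # residues on a line, 3.8 apart; |i-j| = 1..3
  mk <- function(xs, y = 0) lapply(xs, function(x) matrix(c(x, y, 0), 1L))
  rs <- structure(list(n = 4L, name = rep("ALA", 4),
                       coords = mk(c(0, 3.8, 7.6, 11.4)),
                       is_dummy = rep(FALSE, 4), is_coil = rep(FALSE, 4)),
                  class = "residue_set")
  other <- structure(list(n = 1L, name = "ALA", coords = mk(30),
                          is_dummy = FALSE, is_coil = FALSE),
                     class = "residue_set")
  cc <- compute_contacts(rs, other, cutoff = 4, min_separation = 3)
  expect_identical(nrow(cc$intra_A), 0L)  # neighbours are < 4 A but |i-j| < 3

  rs2 <- rs
  rs2$coords <- mk(c(0, 10, 20, 3.8))     # |1-4| = 3, 3.8 A apart
  cc2 <- compute_contacts(rs2, other, cutoff = 4, min_separation = 3)
  expect_identical(cc2$intra_A, data.frame(i = 1L, j = 4L))
  # exactly at the cutoff: no contact (strict inequality)
  rs3 <- rs2
  rs3$coords <- mk(c(0, 10, 20, 4.0))
  expect_identical(nrow(compute_contacts(rs3, other, 4, 3)$intra_A), 0L)
})

test_that("contacts match a brute-force all-pairs scan on random fixtures", {
  for (seed in 1:4) {
    set.seed(seed)
    nA <- sample(8:20, 1); nB <- sample(8:20, 1)
    coords <- function(n) lapply(seq_len(n), function(i)
      matrix(rnorm(3 * sample(1:4, 1), sd = 6), ncol = 3L))
    cA <- coords(nA); cB <- coords(nB)
    rsA <- structure(list(n = nA, name = rep("ALA", nA), coords = cA,
                          is_dummy = rep(FALSE, nA), is_coil = rep(FALSE, nA)),
                     class = "residue_set")
    rsB <- structure(list(n = nB, name = rep("ALA", nB), coords = cB,
                          is_dummy = rep(FALSE, nB), is_coil = rep(FALSE, nB)),
                     class = "residue_set")
    got <- compute_contacts(rsA, rsB, cutoff = 6, min_separation = 3)
    expect_equal(got$inter, bf_contacts(cA, cB, 6), ignore_attr = TRUE)
    intra_oracle <- bf_contacts(cA, cA, 6, min_sep = 3)
    expect_equal(got$intra_A, intra_oracle, ignore_attr = TRUE)
    # symmetry of the intra rule: scanning (j, i) finds the mirrored pairs
    mirrored <- bf_contacts(rev(cA), rev(cA), 6, min_sep = 3)
    expect_identical(nrow(mirrored), nrow(intra_oracle))
  }
})

test_that("coarse graining counts residue contacts per unit pair", {
  cs <- coarse_grain_contacts(data.frame(i = c(1L, 2L), j = c(7L, 8L)), 2,
                              "intra_A")
  expect_identical(cs$i, 1L)
  expect_identical(cs$j, 4L)
  expect_identical(cs$m, 2)
  same_unit <- coarse_grain_contacts(data.frame(i = 1L, j = 4L), 4, "intra_B")
  expect_identical(same_unit$i, 1L)
  expect_identical(same_unit$j, 1L)
  empty <- coarse_grain_contacts(data.frame(i = integer(0), j = integer(0)),
                                 3, "inter")
  expect_identical(nrow(empty), 0L)
})

test_that("model construction validates its invariants", {
  ia <- contact_set(1L, 3L, 1L, "intra_A")
  ib <- contact_set(1L, 3L, 1L, "intra_B")
  ix <- contact_set(2L, 2L, 1L, "inter")
  none <- contact_set(integer(0), integer(0), integer(0), "inter")
  expect_s3_class(dimer_model(rep(30, 3), rep(30, 3), ia, ib, ix, 1000),
                  "dimer_model")
  expect_error(dimer_model(rep(30, 3), rep(30, 3), ia, ib, ix, -1), "epsilon")
  expect_error(dimer_model(rep(30, 3), rep(30, 4), ia, ib, ix, 1000), "equal")
  expect_error(dimer_model(rep(30, 3), rep(30, 3), ia, ib, none, 1000),
               "binding interface")
  expect_error(contact_set(3L, 1L, 1L, "intra_A"), "i <= j")
  expect_error(contact_set(1L, 2L, 0L, "inter"), "multiplicities")
})

test_that("identical inputs give byte-identical contact sets and models", {
  pdb <- write_toy_pdb(10, tempfile(fileext = ".pdb"))
  m1 <- dimer_model_from_pdb(pdb, target_units = 5, epsilon = 1500)
  m2 <- dimer_model_from_pdb(pdb, target_units = 5, epsilon = 1500)
  expect_identical(serialize(m1, NULL), serialize(m2, NULL))
})

test_that("secondary-structure sources map blanks to coil", {
  expect_identical(secondary_structure_coil("HHC-E"),
                   c(FALSE, FALSE, TRUE, TRUE, FALSE))
  # DSSP-format fragment: SS code in column 17
  dssp <- c("==== Secondary Structure Definition ====",
            "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
            "    1    1 A M  H  >         0   0  200",
            "    2    2 A K                0   0  180",
            "    3    3 A V  E             0   0   50")
  f <- tempfile(fileext = ".dssp")
  writeLines(dssp, f)
  expect_identical(secondary_structure_coil(f), c(FALSE, TRUE, FALSE))
})
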