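test_that("read_structure echoes hand-written PDB fields and selects models", {
  pdb <- c(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1       2.500   2.000   3.000  1.00 10.00           C",
    "ATOM      3  C   ALA A   1       3.000   3.400   3.000  1.00 10.00           C",
    "END")
  tf <- tempfile(fileext = ".pdb")
  writeLines(pdb, tf)
  m <- read_structure(tf)
  expect_s3_class(m, "StructureModel")
  expect_equal(nrow(m), 3)
  expect_identical(m$x, c(1.0, 2.5, 3.0))
  expect_identical(m$name, c("N", "CA", "C"))

  # two-model file: model_index picks the right coordinates
  pdb2 <- c("MODEL        1", pdb[1:3], "ENDMDL",
            "MODEL        2",
            sub("1\\.000", "9.000", pdb[1]), pdb[2:3], "ENDMDL", "END")
  tf2 <- tempfile(fileext = ".pdb")
  writeLines(pdb2, tf2)
  expect_equal(read_structure(tf2, 2)$x[1], 9.0)
  expect_error(read_structure(tf2, 3), "out of range")
  expect_error(read_structure(tempfile_with("JUNK")), "no ATOM")
})

test_that("altloc resolution keeps highest occupancy, ties keep A", {
  tf <- tempfile_with(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.40 10.00           C",
    "ATOM      2  CA BALA A   1       2.000   0.000   0.000  0.60 10.00           C",
    "ATOM      3  CB AALA A   1       3.000   0.000   0.000  0.50 10.00           C",
    "ATOM      4  CB BALA A   1       4.000   0.000   0.000  0.50 10.00           C",
    "END"))
  m <- read_structure(tf)
  expect_equal(nrow(m), 2)
  expect_equal(m$x[m$name == "CA"], 2.0)  # higher occupancy wins
  expect_equal(m$x[m$name == "CB"], 3.0)  # tie -> altloc A
})

test_that("mmCIF atom_site parsing agrees with the PDB reader", {
  cif <- c("data_toy", "loop_",
           "_atom_site.group_PDB", "_atom_site.id",
           "_atom_site.type_symbol", "_atom_site.label_atom_id",
           "_atom_site.label_comp_id", "_atom_site.auth_asym_id",
           "_atom_site.auth_seq_id", "_atom_site.Cartn_x",
           "_atom_site.Cartn_y", "_atom_site.Cartn_z",
           "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
           "ATOM 1 N N ALA A 1 1.000 2.000 3.000 1.00 10.0",
           "ATOM 2 C CA ALA A 1 2.500 2.000 3.000 1.00 10.0",
           "HETATM 3 O O1 LIG A 9 8.000 2.000 3.000 1.00 10.0", "#")
  tf <- tempfile(fileext = ".cif")
  writeLines(cif, tf)
  m <- read_structure(tf)
  expect_equal(nrow(m), 3)
  expect_equal(m$x[m$name == "CA"], 2.5)
  expect_true(residue_key("A", 9) %in% ligand_keys(m))
})

test_that("ensembles round-trip and reject topology mismatches", {
  gen <- gen_dihedral_ensemble(10, matrix(seq(-100, 100, length.out = 10),
                                          6, 10, byrow = TRUE))
  tf <- tempfile(fileext = ".pdb")
  write_pdb(gen$ensemble, tf)
  e2 <- read_ensemble(tf)
  expect_length(e2, 10)
  expect_equal(rigidnet:::model_xyz(e2$frames[[4]]),
               round(rigidnet:::model_xyz(gen$ensemble$frames[[4]]), 3),
               tolerance = 1e-9)

  # single-model file is an ensemble of length 1
  tf1 <- tempfile(fileext = ".pdb")
  write_pdb(gen$ensemble$frames[[1]], tf1)
  expect_length(read_ensemble(tf1), 1)

  # drop one atom from frame 2 -> topology error naming the frame
  lines <- readLines(tf)
  drop <- which(grepl("^ATOM", lines))[30]
  writeLines(lines[-drop], tf)
  expect_error(read_ensemble(tf), "frame 2")
})

test_that("polar hydrogen placement follows the geometric rules", {
  m <- backbone_chain(3)
  mh <- add_polar_hydrogens(m)
  # N-terminus excluded: exactly 2 amide H on a tripeptide
  expect_equal(sum(mh$element == "H"), 2)
  # bisector construction: angle C(-1)-N-H equals angle CA-N-H
  keys <- rigidnet:::atom_residue_keys(mh)
  xyz <- rigidnet:::model_xyz(mh)
  at <- function(res, nm) xyz[which(keys == residue_key("A", res) &
                                      mh$name == nm)[1], ]
  a1 <- rigidnet:::vec_angle(at(1, "C"), at(2, "N"), at(2, "H"))
  a2 <- rigidnet:::vec_angle(at(2, "CA"), at(2, "N"), at(2, "H"))
  expect_equal(a1, a2, tolerance = 1e-6)
  expect_equal(rigidnet:::vnorm(at(2, "H") - at(2, "N")), 1.01,
               tolerance = 1e-9)
  # idempotent
  expect_equal(nrow(add_polar_hydrogens(mh)), nrow(mh))
  # proline N gains no H
  df <- as.data.frame(m)
  df$res_name[df$res_seq == 2] <- "PRO"
  mp <- add_polar_hydrogens(rigidnet:::new_structure_model(df))
  expect_equal(sum(mp$element == "H" &
                     rigidnet:::atom_residue_keys(mp) == residue_key("A", 2)), 0)
})

test_that("select_neighborhood uses a closed interval and is monotone", {
  m <- toy_model(list(
    list("C1", "C", "LIG", "A", 9, c(0, 0, 0), het = TRUE),
    list("CA", "C", "ALA", "A", 1, c(2.9, 0, 0)),
    list("CA", "C", "ALA", "A", 2, c(3.1, 0, 0))))
  lig <- residue_key("A", 9)
  expect_length(select_neighborhood(m, lig, 0)$atoms, 0)
  sel <- select_neighborhood(m, lig, 3.0)
  expect_equal(sel$residues, residue_key("A", 1))
  expect_error(select_neighborhood(m, residue_key("Z", 1)), "not found")

  # brute-force equality + radius monotonicity on a random toy
  set.seed(42)
  atoms <- c(list(list("C1", "C", "LIG", "B", 1, runif(3, 0, 5), het = TRUE)),
             lapply(1:200, function(k)
               list("CA", "C", "ALA", "A", k, runif(3, 0, 20))))
  big <- toy_model(atoms)
  ligk <- residue_key("B", 1)
  xyz <- rigidnet:::model_xyz(big)
  ligrow <- which(rigidnet:::atom_residue_keys(big) == ligk)
  prev <- integer()
  for (r in c(2, 5, 8, 12)) {
    sel <- sort(select_neighborhood(big, ligk, r)$atoms)
    brute <- sort(setdiff(which(sqrt(colSums((t(xyz) - xyz[ligrow, ])^2)) <= r),
                          ligrow))
    expect_identical(sel, brute)
    expect_true(all(prev %in% sel))
    prev <- sel
  }
})
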