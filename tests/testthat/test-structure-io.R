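test_that("fixed-column records map to atom fields", {
  txt <- mini_pdb(list(
    atom_spec(1, "CA", "ALA", "A", 1, 1.0, 2.0, 3.0, "C")
  ))
  st <- parse_pdb(txt, "mini")
  expect_equal(nrow(st$atoms), 1L)
  expect_equal(st$atoms$x, 1.0)
  expect_equal(st$atoms$y, 2.0)
  expect_equal(st$atoms$z, 3.0)
  expect_equal(st$atoms$chain_id, "A")
  expect_equal(st$atoms$res_name, "ALA")
  expect_false(st$atoms$is_het)

  het <- mini_pdb(list(
    atom_spec(1, "C1", "LIG", "A", 90, 1, 2, 3, "C", het = TRUE)
  ))
  expect_true(parse_pdb(het, "het")$atoms$is_het)
})

test_that("MODEL blocks, REMARK 2 and altLoc handling", {
  atoms <- c(lapply(1:10, function(i)
    atom_spec(i, "CA", "GLY", "A", i, i, 0, 0, "C")),
    lapply(1:9, function(i)
      atom_spec(i, "CA", "GLY", "A", i, i, 0, 0, "C")))
  txt <- mini_pdb(atoms, remarks = "REMARK   2 RESOLUTION.    1.80 ANGSTROMS.",
                  models = c(10L, 9L))
  st <- parse_pdb(txt, "models")
  expect_equal(st$model_atom_counts, c(10L, 9L))
  expect_equal(st$resolution, 1.8)
  expect_equal(nrow(st$atoms), 10L)  # first model only

  # altLoc: keep blank or A only
  lines <- strsplit(mini_pdb(list(
    atom_spec(1, "CA", "ALA", "A", 1, 0, 0, 0, "C"),
    atom_spec(2, "CB", "ALA", "A", 1, 1, 0, 0, "C"),
    atom_spec(3, "CB", "ALA", "A", 1, 2, 0, 0, "C")
  )), "\n")[[1]]
  substr(lines[2], 17, 17) <- "A"
  substr(lines[3], 17, 17) <- "B"
  st2 <- parse_pdb(paste(lines, collapse = "\n"), "alt")
  expect_equal(nrow(st2$atoms), 2L)
})

test_that("parse errors carry line information", {
  bad <- "ATOM      1  CA  ALA A   1      bad.000   2.000   3.000  1.00  0.00           C"
  expect_error(parse_pdb(bad, "bad"), "line 1")
  expect_error(parse_pdb("", "empty"), "empty")
  expect_error(parse_pdb("REMARK only", "norec"), "no ATOM")
})

test_that("curation filters follow the strict 2 Angstrom boundary", {
  mk <- function(res_line, res = "ALA") {
    parse_pdb(mini_pdb(list(atom_spec(1, "CA", res, "A", 1, 0, 0, 0, "C")),
                       remarks = res_line), "x")
  }
  dec <- apply_curation_filters(
    mk("REMARK   2 RESOLUTION.    2.10 ANGSTROMS."))
  expect_false(dec$accept)
  expect_equal(dec$reason, "resolution")

  dec2 <- apply_curation_filters(
    mk("REMARK   2 RESOLUTION.    2.00 ANGSTROMS."))
  expect_true(dec2$accept)

  # missing resolution: accepted on that criterion, with a warning
  nores <- parse_pdb(mini_pdb(list(atom_spec(1, "CA", "ALA", "A", 1,
                                             0, 0, 0, "C"))), "nores")
  expect_warning(dec3 <- apply_curation_filters(nores), "REMARK 2")
  expect_true(dec3$accept)
})

test_that("model mismatch and nucleic acids are rejected", {
  atoms <- c(lapply(1:3, function(i)
    atom_spec(i, "CA", "GLY", "A", i, i, 0, 0, "C")),
    lapply(1:2, function(i)
      atom_spec(i, "CA", "GLY", "A", i, i, 0, 0, "C")))
  st <- parse_pdb(mini_pdb(atoms,
                           remarks = "REMARK   2 RESOLUTION.    1.50 ANGSTROMS.",
                           models = c(3L, 2L)), "mm")
  dec <- apply_curation_filters(st)
  expect_false(dec$accept)
  expect_equal(dec$reason, "model mismatch")

  dna <- parse_pdb(mini_pdb(list(
    atom_spec(1, "CA", "ALA", "A", 1, 0, 0, 0, "C"),
    atom_spec(2, "P", "DA", "B", 1, 5, 0, 0, "P")
  ), remarks = "REMARK   2 RESOLUTION.    1.50 ANGSTROMS."), "dna")
  dec2 <- apply_curation_filters(dna)
  expect_false(dec2$accept)
  expect_equal(dec2$reason, "nucleic acid")
})

test_that("chain grouping partitions atoms across modes", {
  st <- parse_pdb(mini_pdb(list(
    atom_spec(1, "CA", "ALA", "A", 1, 0, 0, 0, "C"),
    atom_spec(2, "CA", "GLY", "A", 2, 3, 0, 0, "C"),
    atom_spec(3, "CA", "SER", "B", 1, 6, 0, 0, "C")
  )), "two")
  per <- group_chains(st, "per_chain")
  expect_length(per, 2L)
  expect_equal(sum(vapply(per, function(u) nrow(u$atoms), integer(1))),
               nrow(group_chains(st, "single_complex")[[1]]$atoms))
  sub <- group_chains(st, "chain_subset", chains = c("A", "B"))
  expect_length(sub, 1L)
  expect_setequal(sub[[1]]$chain_ids, c("A", "B"))
  expect_error(group_chains(st, "chain_subset", chains = "Z"), "Z")
  expect_error(group_chains(st, "chain_subset"), "non-empty")
})

test_that("pocket PDB output round-trips coordinates at 0.001 A", {
  set.seed(42)
  cx <- generate_complex(synthetic_spec(n_atoms = 120, box_size = 25,
                                        seed = 3))
  st <- cx$structure
  atoms <- retained_atoms(st)
  pocket <- structure(list(pocket_id = 1L, member_atoms = 1:5,
                           member_residues = unique(atoms[1:5, c("chain_id",
                                                                 "res_seq", "i_code", "res_name")]),
                           center = colMeans(as.matrix(atoms[1:5, c("x", "y", "z")])),
                           mean_probability = 0.9),
                      class = "pocket")
  txt <- write_pocket_pdb(st, list(pocket))
  expect_equal(sum(grepl("^ATOM", strsplit(txt, "\n")[[1]])), 5L)
  expect_equal(sum(grepl("^TER", strsplit(txt, "\n")[[1]])), 1L)
  back <- parse_pdb(txt, "back")
  expect_equal(as.matrix(back$atoms[, c("x", "y", "z")]),
               as.matrix(atoms[1:5, c("x", "y", "z")]),
               tolerance = 1e-9, ignore_attr = TRUE)

  expect_equal(sum(grepl("^ATOM",
                         strsplit(write_pocket_pdb(st, list()), "\n")[[1]])), 0L)
  bad <- pocket; bad$member_atoms <- c(1L, 10000L)
  expect_error(write_pocket_pdb(st, list(bad)), "indices")
})

test_that("parse-write-parse is a fixed point on retained fields", {
  cx <- generate_complex(synthetic_spec(n_atoms = 150, box_size = 26,
                                        seed = 9))
  t1 <- write_pdb(cx$structure)
  st1 <- parse_pdb(t1, cx$structure$structure_id)
  t2 <- write_pdb(st1)
  expect_identical(t1, t2)
})

test_that("ligand extraction from HETATM records and CSV", {
  cx <- generate_complex(synthetic_spec(seed = 2))
  lig <- extract_ligand(cx$structure, "LIG", res_seq = 901L)
  expect_equal(nrow(lig$atom_coords), 8L)
  expect_error(extract_ligand(cx$structure, "HEM"), "HEM")

  tmp <- tempfile(fileext = ".csv")
  write.csv(data.frame(x = c(1, 2), y = c(0, 0), z = c(0, 1)), tmp,
            row.names = FALSE)
  l2 <- read_ligand_csv(tmp)
  expect_equal(dim(l2$atom_coords), c(2L, 3L))
  expect_error(ligand_coordinates(matrix(numeric(0), 0, 3)), "at least one")
})
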