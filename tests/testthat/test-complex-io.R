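test_that("read_protein parses atoms and strips waters and HETATM records", {
  p1 <- write_pdb(c(
    pdb_atom_line(1, "N", "ALA", "A", 1, 11.1, 6.1, -6.5, "N"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 11.6, 6.0, -5.1, "C"),
    pdb_atom_line(3, "C", "ALA", "A", 1, 10.5, 5.7, -4.1, "C")
  ))
  prot <- read_protein(p1)
  expect_equal(nrow(prot), 3)
  expect_equal(unique(prot$resname), "ALA")
  expect_equal(prot$x[1], 11.1)

  p2 <- write_pdb(c(
    pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0, "C"),
    pdb_atom_line(2, "CA", "GLY", "A", 2, 3, 0, 0, "C"),
    pdb_atom_line(3, "O", "HOH", "A", 101, 9, 9, 9, "O", record = "HETATM")
  ))
  prot2 <- read_protein(p2)
  expect_equal(nrow(prot2), 2)
  expect_false("HOH" %in% prot2$resname)
  # stripping everything leaves an error, not an empty structure
  p3 <- write_pdb(pdb_atom_line(1, "O", "HOH", "A", 1, 0, 0, 0, "O",
                                record = "HETATM"))
  expect_error(read_protein(p3), "no chain atoms")
})

test_that("read_protein recovers a generated pocket's residue multiset", {
  lib <- generate_ligand_library(1, seed = 21)
  comp <- c(GLY = 4, ILE = 3, ARG = 2, TRP = 1)
  prot <- generate_pocket(comp, lib$mol[[1]], seed = 7)
  path <- tempfile(fileext = ".pdb")
  sfbias:::write_protein_pdb(prot, path)
  back <- read_protein(path)
  got <- table(back$resname[!duplicated(paste(back$chain, back$resno))])
  expect_equal(got[names(comp)], table(rep(names(comp), comp))[names(comp)],
               ignore_attr = TRUE)
})

test_that("read_ligand computes the InChI-Key and is format-independent", {
  sdf <- write_ethanol_sdf()
  mol <- read_ligand(sdf)
  expect_equal(mol$inchikey, "LFQSCWFLJHTTHZ-UHFFFAOYSA-N")
  expect_equal(nrow(mol$atoms), 3)
  expect_equal(nrow(mol$bonds), 2)

  mol2_txt <- ChemmineOB::convertFormat(
    "SDF", "MOL2", paste0(paste(ethanol_sdf_lines(), collapse = "\n"), "\n"))
  mol2_path <- tempfile(fileext = ".mol2")
  writeLines(mol2_txt, mol2_path)
  expect_equal(read_ligand(mol2_path)$inchikey, mol$inchikey)

  bad <- tempfile(fileext = ".sdf")
  writeLines(c("garbage", "more garbage"), bad)
  expect_error(read_ligand(bad), "parse failure")
})

test_that("InChI-Key is invariant under conformation change", {
  lib <- generate_ligand_library(5, seed = 3)
  for (i in seq_len(nrow(lib))) {
    mol <- lib$mol[[i]]
    moved <- set_ligand_coords(mol, ligand_coords(mol) + 5)
    path <- tempfile(fileext = ".sdf")
    write_ligand_pose(moved, NULL, path)
    expect_equal(read_ligand(path)$inchikey, mol$inchikey)
  }
})

test_that("pk_from_affinity applies -log10 on the molar scale", {
  expect_equal(pk_from_affinity(1, "uM"), 6)
  expect_equal(pk_from_affinity(1, "nM"), 9)
  expect_equal(pk_from_affinity(49, "uM"), -log10(49e-6))
  expect_equal(round(pk_from_affinity(49, "uM"), 4), 4.3098)
  # exact for powers of ten across the unit range
  expect_identical(vapply(0:15, function(p) pk_from_affinity(10^-p, "M"),
                          numeric(1)),
                   as.numeric(0:15))
  expect_error(pk_from_affinity(-1, "uM"), "positive")
  expect_error(pk_from_affinity(1, "furlongs"), "unknown")
})

test_that("parse_affinity_index handles the PDBBind dialect", {
  path <- tempfile()
  writeLines(c(
    "# header comment",
    "1abc 2.50 2019 6.30 Kd=0.5uM // some text (3MER)",
    "2xyz 1.90 2015 6.10 badfield",
    "3pqr 2.10 2008 7.00 IC50~10nM // (L07)"
  ), path)
  expect_warning(idx <- parse_affinity_index(path), "skipped 1")
  expect_equal(nrow(idx), 2)
  expect_equal(idx$complex_id, c("1abc", "3pqr"))
  expect_equal(idx$year[1], 2019L)
  expect_equal(idx$measurement_type, c("Kd", "IC50"))
  expect_equal(idx$qualifier, c("=", "~"))
  expect_equal(idx$pk[1], -log10(5e-7))
  expect_equal(idx$ligand_code, c("3MER", "L07"))
  skipped <- attr(idx, "skipped")
  expect_equal(nrow(skipped), 1)
  expect_equal(skipped$reason, "bad_measurement")
})

test_that("load_dataset excludes unreadable complexes with reasons", {
  dir <- tempfile()
  rec <- generate_dataset(generator_config(n_complexes = 8, seed = 13),
                          out_dir = dir, n_corrupt = 2)
  loaded <- suppressWarnings(
    load_dataset(file.path(dir, "index.txt"), dir))
  excl <- exclusion_report(loaded)
  expect_equal(nrow(loaded), 6)
  expect_equal(nrow(excl), 2)
  expect_setequal(excl$reason, "ligand_parse")
  expect_setequal(excl$complex_id, attr(rec, "corrupted_ids"))
  # accounting: records + exclusions = index entries
  expect_equal(nrow(loaded) + nrow(excl), 8)
  # missing structure directory
  unlink(file.path(dir, loaded$complex_id[1]), recursive = TRUE)
  loaded2 <- suppressWarnings(load_dataset(file.path(dir, "index.txt"), dir))
  expect_true("missing_file" %in% exclusion_report(loaded2)$reason)
})

test_that("write_ligand_pose round-trips connectivity and coordinates", {
  lib <- generate_ligand_library(2, seed = 8)
  mol <- lib$mol[[2]]
  ref <- ligand_coords(mol)
  path <- tempfile(fileext = ".sdf")

  write_ligand_pose(mol, ref, path)
  back <- read_ligand(path)
  expect_equal(back$atoms$element, mol$atoms$element)
  expect_equal(as.data.frame(back$bonds), as.data.frame(mol$bonds))
  expect_lt(max(abs(ligand_coords(back) - ref)), 1e-4)

  shifted <- sweep(ref, 2, c(1, 0, 0), "+")
  write_ligand_pose(mol, shifted, path)
  back2 <- read_ligand(path)
  expect_equal(colMeans(ligand_coords(back2)) - colMeans(ref),
               c(x = 1, y = 0, z = 0), tolerance = 1e-3)

  rot <- sfbias:::rotation_matrix(c(1, 2, 3), 0.7)
  rotated <- ref %*% t(rot)
  write_ligand_pose(mol, rotated, path)
  back3 <- read_ligand(path)
  expect_lt(max(abs(dist(ligand_coords(back3)) - dist(ref))), 1e-3)

  expect_error(write_ligand_pose(mol, ref[-1, , drop = FALSE], path), "matrix")
})
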