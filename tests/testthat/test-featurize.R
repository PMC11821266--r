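test_that("descriptor schema excludes NaN and overflow producers", {
  lib <- generate_ligand_library(6, seed = 2)
  battery <- c(ligand_descriptor_battery(), list(
    always_nan = function(mol) NaN,
    huge = function(mol) 1e12
  ))
  schema <- build_descriptor_schema(lib$mol, overflow_threshold = 1e8,
                                    battery = battery)
  expect_true("always_nan" %in% schema$exclusion_log$name)
  expect_equal(
    schema$exclusion_log$reason[schema$exclusion_log$name == "always_nan"], "nan")
  expect_equal(
    schema$exclusion_log$reason[schema$exclusion_log$name == "huge"], "overflow")
  expect_false(any(c("always_nan", "huge") %in% schema$names))

  # infinite threshold: no overflow exclusions
  schema2 <- build_descriptor_schema(lib$mol, overflow_threshold = Inf)
  expect_false("overflow" %in% schema2$exclusion_log$reason)
  expect_error(
    build_descriptor_schema(lib$mol, battery = list(bad = function(m) NaN)),
    "all descriptors excluded")
})

test_that("schema building is deterministic and serialization round-trips", {
  lib <- generate_ligand_library(20, seed = 5)
  s1 <- build_descriptor_schema(lib$mol)
  s2 <- build_descriptor_schema(lib$mol)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_descriptor_schema(s1, f1)
  write_descriptor_schema(s2, f2)
  expect_identical(readLines(f1), readLines(f2))
  s3 <- read_descriptor_schema(f1)
  expect_identical(s3$names, s1$names)
  expect_equal(s3$medians, s1$medians)
  expect_identical(s3$schema_id, s1$schema_id)
})

test_that("ligand descriptors are 2D-only: conformer invariant", {
  lib <- generate_ligand_library(8, seed = 4)
  schema <- build_descriptor_schema(lib$mol)
  for (i in c(1, 4, 8)) {
    mol <- lib$mol[[i]]
    rot <- sfbias:::rotation_matrix(c(0.3, -1, 2), 1.1)
    conf <- set_ligand_coords(mol, ligand_coords(mol) %*% t(rot) + 3)
    expect_identical(ligand_descriptors(mol, schema),
                     ligand_descriptors(conf, schema))
  }
})

test_that("molecular weight uses implicit hydrogens; distinct molecules differ", {
  sdf <- write_ethanol_sdf()
  ethanol <- read_ligand(sdf)
  schema <- build_descriptor_schema(list(ethanol))
  v <- ligand_descriptors(ethanol, schema)
  expect_equal(unname(v["mol_weight"]), 46.07, tolerance = 1e-3)

  lib <- generate_ligand_library(10, seed = 6)
  schema2 <- build_descriptor_schema(lib$mol)
  v1 <- ligand_descriptors(lib$mol[[1]], schema2)
  v2 <- ligand_descriptors(lib$mol[[2]], schema2)
  expect_false(isTRUE(all.equal(v1, v2)))
})

test_that("predict-time descriptor failure imputes the training median", {
  lib <- generate_ligand_library(5, seed = 9)
  flaky <- new.env(); flaky$fail <- FALSE
  battery <- c(ligand_descriptor_battery(), list(
    flaky_desc = function(mol) if (flaky$fail) NaN else 7
  ))
  schema <- build_descriptor_schema(lib$mol, battery = battery)
  expect_true("flaky_desc" %in% schema$names)
  flaky$fail <- TRUE
  expect_warning(
    v <- ligand_descriptors(lib$mol[[1]], schema, battery = battery),
    "imputed")
  expect_equal(unname(v["flaky_desc"]), 7)
})

test_that("pocket counts respect the distance threshold definition", {
  lig <- matrix(c(0, 0, 0), ncol = 3)
  prot <- sfbias:::new_protein_structure(tibble::tibble(
    element = c("C", "C"), resname = c("GLY", "ALA"),
    resno = c(1L, 2L), chain = "A", ins = "",
    x = c(10, 20), y = 0, z = 0
  ))
  counts <- pocket_residue_counts(prot, lig, threshold_A = 15)
  expect_equal(unname(counts["GLY"]), 1L)
  expect_equal(unname(counts["ALA"]), 0L)
  expect_equal(sum(counts), 1L)
  # degenerate threshold
  expect_equal(sum(pocket_residue_counts(prot, lig, threshold_A = 0)), 0L)
  # a residue counts once however many atoms are in range
  prot2 <- sfbias:::new_protein_structure(tibble::tibble(
    element = c("C", "N", "C"), resname = "HIS", resno = 1L,
    chain = "A", ins = "", x = c(1, 2, 3), y = 0, z = 0
  ))
  expect_equal(sum(pocket_residue_counts(prot2, lig, threshold_A = 15)), 1L)
  # non-standard residues land in UNK
  prot3 <- sfbias:::new_protein_structure(tibble::tibble(
    element = "C", resname = "MSE", resno = 1L, chain = "A", ins = "",
    x = 5, y = 0, z = 0
  ))
  expect_equal(unname(pocket_residue_counts(prot3, lig, 15)["UNK"]), 1L)
})

test_that("pocket counts match a brute-force oracle and grow with threshold", {
  lib <- generate_ligand_library(3, seed = 17)
  withr::with_seed(99, {
    for (trial in 1:5) {
      mol <- lib$mol[[sample(3, 1)]]
      comp <- stats::setNames(
        tabulate(sample(20, 40, replace = TRUE), nbins = 20),
        pocket_residue_order()[1:20])
      prot <- generate_pocket(comp[comp > 0], mol, n_distractors = 3)
      prev <- -1L
      for (thr in c(5, 10, 15, 20, 30)) {
        got <- pocket_residue_counts(prot, mol, threshold_A = thr)
        expect_identical(got, brute_force_pocket_counts(prot, mol, thr),
                         ignore_attr = TRUE)
        expect_gte(sum(got), prev)
        prev <- sum(got)
      }
    }
  })
})

test_that("concat_features stacks ligand block then pocket block", {
  lib <- generate_ligand_library(4, seed = 11)
  schema <- build_descriptor_schema(lib$mol)
  mol <- lib$mol[[1]]
  lv <- ligand_descriptors(mol, schema)
  pocket <- stats::setNames(integer(21), pocket_residue_order())
  pocket["GLY"] <- 3L
  v <- concat_features(lv, pocket)
  expect_length(v, length(lv) + 21)
  expect_equal(unname(v[seq_along(lv)]), as.numeric(lv))
  expect_equal(unname(v["pocket_GLY"]), 3)
  # zero pocket -> all-zero tail
  zero <- concat_features(lv, stats::setNames(integer(21), pocket_residue_order()))
  expect_true(all(zero[-seq_along(lv)] == 0))
  # same ligand, different pockets: identical head, differing tail
  pocket2 <- pocket; pocket2["ILE"] <- 5L
  v2 <- concat_features(lv, pocket2)
  expect_equal(v2[seq_along(lv)], v[seq_along(lv)])
  expect_false(all(v2[-seq_along(lv)] == v[-seq_along(lv)]))
  expect_error(concat_features(lv, pocket[1:5]), "21")
})
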