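test_that("in-place rmsd has its closed-form values and matches a loop oracle", {
  withr::with_seed(7, {
    a <- matrix(rnorm(30), ncol = 3)
    expect_equal(rmsd(a, a), 0)
    shifted <- sweep(a, 2, c(2, 0, 0), "+")
    expect_equal(rmsd(a, shifted), 2)
    b <- matrix(rnorm(30), ncol = 3)
    loop <- sqrt(mean(vapply(seq_len(nrow(a)),
                             function(i) sum((a[i, ] - b[i, ])^2), numeric(1))))
    expect_equal(rmsd(a, b), loop, tolerance = 1e-12)
    expect_error(rmsd(a, b[-1, ]), "matched")
  })
})

test_that("clash_direction points from ligand into protein", {
  prot <- sfbias:::new_protein_structure(tibble::tibble(
    element = "C", resname = "GLY", resno = 1L, chain = "A", ins = "",
    x = 3, y = 0, z = 0))
  u <- clash_direction(prot, matrix(c(0, 0, 0), ncol = 3))
  expect_equal(as.numeric(u), c(1, 0, 0))
  prot2 <- sfbias:::new_protein_structure(tibble::tibble(
    element = "C", resname = "GLY", resno = 1L, chain = "A", ins = "",
    x = 1, y = 1, z = 1))
  u2 <- clash_direction(prot2, matrix(c(0, 0, 0), ncol = 3))
  expect_equal(as.numeric(u2), rep(1 / sqrt(3), 3), tolerance = 1e-4)
  # coincident atoms are a degenerate geometry
  prot3 <- sfbias:::new_protein_structure(tibble::tibble(
    element = "C", resname = "GLY", resno = 1L, chain = "A", ins = "",
    x = 0, y = 0, z = 0))
  expect_error(clash_direction(prot3, matrix(c(0, 0, 0), ncol = 3)),
               "coincident")
})

test_that("clash_direction ties break on the lowest index pair", {
  # two protein atoms both at distance 2 from ligand atom 1
  prot <- sfbias:::new_protein_structure(tibble::tibble(
    element = c("C", "C"), resname = "GLY", resno = c(1L, 2L),
    chain = "A", ins = "",
    x = c(0, 2), y = c(2, 0), z = 0))
  u <- clash_direction(prot, matrix(c(0, 0, 0), ncol = 3))
  expect_equal(as.numeric(u), c(0, 1, 0))  # protein atom 1 wins the tie
  expect_equal(attr(u, "protein_atom"), 1)
})

test_that("clash_direction equals brute-force nearest-pair search", {
  withr::with_seed(41, {
    for (trial in 1:50) {
      nl <- sample(3:12, 1); np <- sample(5:40, 1)
      lig <- matrix(rnorm(nl * 3, sd = 2), ncol = 3)
      pxyz <- matrix(rnorm(np * 3, sd = 6) + 5, ncol = 3)
      prot <- sfbias:::new_protein_structure(tibble::tibble(
        element = "C", resname = "GLY", resno = seq_len(np),
        chain = "A", ins = "",
        x = pxyz[, 1], y = pxyz[, 2], z = pxyz[, 3]))
      best <- c(Inf, NA, NA)
      for (i in seq_len(nl)) for (j in seq_len(np)) {
        d <- sqrt(sum((lig[i, ] - pxyz[j, ])^2))
        if (d < best[1]) best <- c(d, i, j)
      }
      u <- clash_direction(prot, lig)
      expected <- (pxyz[best[3], ] - lig[best[2], ]) / best[1]
      expect_equal(as.numeric(u), expected, tolerance = 1e-12)
      expect_equal(attr(u, "min_dist"), best[1], tolerance = 1e-12)
    }
  })
})

test_that("translate_series is rigid with exact RMSD per step", {
  withr::with_seed(13, {
    lig <- matrix(rnorm(24), ncol = 3)
    u <- c(1, -2, 2) / 3
    series <- translate_series(lig, u, step_A = 1, n_steps = 10)
    expect_length(series, 10)
    d0 <- dist(lig)
    for (k in seq_along(series)) {
      expect_lt(abs(rmsd(lig, series[[k]]) - k), 1e-9)
      expect_lt(max(abs(dist(series[[k]]) - d0)), 1e-9)
      expect_equal(colMeans(series[[k]]) - colMeans(lig), k * u,
                   tolerance = 1e-9)
    }
    expect_error(translate_series(lig, c(1, 1, 0)), "unit")
  })
})

test_that("clash pose sets have monotonically increasing RMSD", {
  lib <- generate_ligand_library(2, seed = 19)
  mol <- lib$mol[[1]]
  prot <- generate_pocket(c(LEU = 4, SER = 3), mol, seed = 3)
  ps <- clash_pose_set(prot, mol, step_A = 1, n_steps = 10)
  expect_equal(nrow(ps$poses), 10)
  expect_equal(ps$poses$rmsd, 1:10, tolerance = 1e-9)
  expect_true(all(diff(ps$poses$rmsd) > 0))
  expect_equal(unique(ps$poses$provenance), "translated")
})

test_that("select_binned_poses picks the pose nearest the bin midpoint", {
  tab <- tibble::tibble(pose_id = c("a", "b", "c"), rmsd = c(2.1, 3.1, 3.9))
  sel <- select_binned_poses(tab)
  row <- sel[sel$lo == 2 & sel$hi == 4, ]
  expect_equal(row$pose_id, "b")
  # empty bin stays empty
  expect_true(is.na(sel$pose_id[sel$lo == 25]))
  # tie on distance to midpoint: first pose in table order wins
  tab2 <- tibble::tibble(pose_id = c("p1", "p2"), rmsd = c(2.9, 3.1))
  sel2 <- select_binned_poses(tab2)
  expect_equal(sel2$pose_id[sel2$lo == 2], "p1")
})

test_that("bin selection equals the brute-force oracle on random multisets", {
  bins <- default_rmsd_bins()
  withr::with_seed(77, {
    for (trial in 1:100) {
      n <- sample(1:60, 1)
      r <- round(runif(n, 0, 32), 3)
      tab <- tibble::tibble(pose_id = paste0("p", seq_len(n)), rmsd = r)
      sel <- select_binned_poses(tab, bins)
      for (b in seq_len(nrow(bins))) {
        lo <- bins$lo[b]; hi <- bins$hi[b]; mid <- (lo + hi) / 2
        inb <- which(r >= lo & (if (b == nrow(bins)) r <= hi else r < hi))
        if (length(inb) == 0) {
          expect_true(is.na(sel$pose_id[b]))
        } else {
          pick <- inb[order(abs(r[inb] - mid), inb)][1]
          expect_equal(sel$pose_id[b], paste0("p", pick))
          expect_gte(sel$rmsd[b], lo)
          expect_true(sel$rmsd[b] < hi || (b == nrow(bins) && sel$rmsd[b] <= hi))
        }
      }
    }
  })
})

test_that("pose sets round-trip through SDF plus manifest", {
  lib <- generate_ligand_library(2, seed = 23)
  mol <- lib$mol[[2]]
  dec <- generate_pose_decoys(mol, c(1, 4, 9), seed = 5, complex_id = "cplx")
  dir <- tempfile()
  write_pose_set(dec, mol, dir)
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"),
                              show_col_types = FALSE)
  expect_equal(nrow(manifest), 3)
  # multi-record SDF read back as a pose set
  multi <- tempfile(fileext = ".sdf")
  writeLines(unlist(lapply(manifest$file, function(f) {
    readLines(file.path(dir, f))
  })), multi)
  ref_path <- tempfile(fileext = ".sdf")
  write_ligand_pose(mol, NULL, ref_path)
  ps <- read_pose_set(multi, ref_path)
  expect_equal(ps$poses$rmsd, dec$poses$rmsd, tolerance = 1e-3)
})
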