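#' In-place RMSD between two matched coordinate sets
#'
#' Root-mean-square deviation over matched atom pairs with no
#' superposition: pose accuracy is positional, so a rigid displacement of
#' d Angstrom has RMSD exactly d. Atom order must match (same molecule,
#' same file ordering); heavy-atom selection is the caller's
#' responsibility.
#'
#' @param coords_a,coords_b Numeric n x 3 matrices.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a)
  coords_b <- as.matrix(coords_b)
  if (!all(dim(coords_a) == dim(coords_b)) || ncol(coords_a) != 3) {
    abort("rmsd: coordinate sets must be matched n x 3 matrices")
  }
  sqrt(mean(rowSums((coords_a - coords_b)^2)))
}

#' Direction of steric-clash translation
#'
#' The unit vector pointing from the ligand into the protein: find the
#' globally closest (ligand atom, protein atom) pair over heavy atoms and
#' normalize protein_atom - ligand_atom. Exact distance ties are broken by
#' the lowest (ligand index, protein index) pair, so the result is
#' deterministic.
#'
#' @param protein A `protein_structure`.
#' @param lig_coords Ligand coordinates (n x 3 matrix) or a `ligand_molecule`.
#' @param heavy_only Restrict to heavy atoms (default `TRUE`).
#' @return Unit 3-vector with attributes `ligand_atom`, `protein_atom`
#'   (indices of the closest pair) and `min_dist`.
#' @export
clash_direction <- function(protein, lig_coords, heavy_only = TRUE) {
  if (inherits(lig_coords, "ligand_molecule")) {
    mol <- lig_coords
    keep <- if (heavy_only) toupper(mol$atoms$element) != "H" else
      rep(TRUE, nrow(mol$atoms))
    lig_coords <- ligand_coords(mol)[keep, , drop = FALSE]
  }
  lig_coords <- as.matrix(lig_coords)
  prot <- protein
  if (heavy_only) prot <- prot[toupper(prot$element) != "H", , drop = FALSE]
  if (nrow(prot) == 0 || nrow(lig_coords) == 0) {
    abort("clash_direction: empty structure")
  }
  pxyz <- as.matrix(prot[, c("x", "y", "z")])
  d2 <- outer(rowSums(lig_coords^2), rowSums(pxyz^2), "+") -
    2 * (lig_coords %*% t(pxyz))
  d2[d2 < 0] <- 0
  m <- min(d2)
  if (sqrt(m) < 1e-9) abort("clash_direction: coincident closest atoms (zero distance)")
  hits <- which(d2 == m, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  li <- hits[1, 1]; pj <- hits[1, 2]
  v <- pxyz[pj, ] - lig_coords[li, ]
  u <- v / sqrt(sum(v^2))
  attr(u, "ligand_atom") <- unname(li)
  attr(u, "protein_atom") <- unname(pj)
  attr(u, "min_dist") <- sqrt(m)
  u
}

#' Progressive rigid translation series
#'
#' Translates the ligand rigidly along a fixed unit direction in
#' `step_A`-Angstrom increments: pose k is the input displaced by
#' k * step_A, so its in-place RMSD to the input is exactly k * step_A and
#' all interatomic distances are preserved. The direction is computed once
#' from the unperturbed complex and reused for every step.
#'
#' @param lig_coords Ligand coordinates (n x 3 matrix).
#' @param direction Unit 3-vector (validated to 1e-9).
#' @param step_A Step size in Angstrom (default 1).
#' @param n_steps Number of steps (default 10).
#' @return List of `n_steps` coordinate matrices.
#' @export
translate_series <- function(lig_coords, direction, step_A = 1, n_steps = 10) {
  lig_coords <- as.matrix(lig_coords)
  direction <- as.numeric(direction)
  if (length(direction) != 3 || abs(sqrt(sum(direction^2)) - 1) > 1e-9) {
    abort("translate_series: direction must be a unit 3-vector")
  }
  if (n_steps < 1) abort("translate_series: n_steps must be >= 1")
  lapply(seq_len(n_steps), function(k) {
    sweep(lig_coords, 2, k * step_A * direction, "+")
  })
}

#' Build the clash pose set for one complex
#'
#' Convenience wrapper: computes the clash direction from the unperturbed
#' complex and generates the translated pose series as a `pose_set` with
#' provenance `"translated"`.
#'
#' @param protein A `protein_structure`.
#' @param ligand A `ligand_molecule`.
#' @param complex_id Identifier carried on the pose set.
#' @param step_A,n_steps Passed to [translate_series()].
#' @return A `pose_set`.
#' @export
clash_pose_set <- function(protein, ligand, complex_id = ligand$name,
                           step_A = 1, n_steps = 10) {
  ref <- ligand_coords(ligand)
  u <- clash_direction(protein, ligand)
  # direction computed on heavy atoms; translation applied to all atoms
  poses <- translate_series(ref, u, step_A = step_A, n_steps = n_steps)
  pose_set(complex_id, ref, poses,
           pose_ids = paste0("clash_", seq_len(n_steps)),
           provenance = "translated")
}

#' Construct a pose set
#'
#' A pose set is the reference (crystal) ligand coordinates plus a
#' collection of alternative poses of the same atoms, each annotated with
#' its in-place RMSD to the reference.
#'
#' @param complex_id Identifier.
#' @param reference Reference coordinates (n x 3).
#' @param poses List of coordinate matrices (each n x 3).
#' @param pose_ids Character ids, default `pose_1..k`.
#' @param provenance One of `"docked"`, `"minimized"`, `"translated"`
#'   (recycled).
#' @return An object of class `pose_set`; `as_tibble()` gives the pose
#'   table (`pose_id`, `rmsd`, `provenance`, `coords` list-column).
#' @export
pose_set <- function(complex_id, reference, poses,
                     pose_ids = paste0("pose_", seq_along(poses)),
                     provenance = "docked") {
  reference <- as.matrix(reference)
  if (length(poses) == 0) abort("pose_set: need at least one pose")
  provenance <- rep_len(provenance, length(poses))
  bad <- !provenance %in% c("docked", "minimized", "translated")
  if (any(bad)) abort("pose_set: provenance must be docked/minimized/translated")
  r <- vapply(poses, function(p) {
    p <- as.matrix(p)
    if (!all(dim(p) == dim(reference))) {
      abort("pose_set: pose atom count differs from reference")
    }
    rmsd(reference, p)
  }, numeric(1))
  structure(
    list(complex_id = complex_id, reference = reference,
         poses = tibble(pose_id = pose_ids, coords = poses, rmsd = r,
                        provenance = provenance)),
    class = "pose_set"
  )
}

#' @export
print.pose_set <- function(x, ...) {
  cat("<pose_set> ", x$complex_id, ": ", nrow(x$poses), " poses, RMSD ",
      sprintf("%.2f", min(x$poses$rmsd)), "-",
      sprintf("%.2f", max(x$poses$rmsd)), " A\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.pose_set <- function(x, ...) x$poses

#' The standard RMSD bin edges
#'
#' @return Tibble with columns `lo`, `hi` (Angstrom): 0-1, 1-2, 2-4, 4-6,
#'   6-8, 8-10, 10-15, 15-20, 20-25, 25-30. Bins are half-open `[lo, hi)`
#'   except the last, closed at 30.
#' @export
default_rmsd_bins <- function() {
  lo <- c(0, 1, 2, 4, 6, 8, 10, 15, 20, 25)
  hi <- c(1, 2, 4, 6, 8, 10, 15, 20, 25, 30)
  tibble(lo = lo, hi = hi)
}

#' Select one pose per RMSD bin
#'
#' For each bin, among the poses whose RMSD falls inside it, selects the
#' pose closest to the bin midpoint (ties broken by lowest pose id in the
#' pose table order); bins with no candidate stay empty.
#'
#' @param poses A `pose_set`, or a tibble with columns `pose_id`, `rmsd`.
#' @param bins Bin edge tibble as from [default_rmsd_bins()].
#' @return Tibble with one row per bin: `lo`, `hi`, `mid`, `pose_id`
#'   (`NA` when empty), `rmsd`, `n_candidates`.
#' @export
select_binned_poses <- function(poses, bins = default_rmsd_bins()) {
  tab <- if (inherits(poses, "pose_set")) poses$poses else as_tibble(poses)
  if (any(diff(bins$lo) <= 0) || any(bins$hi <= bins$lo)) {
    abort("select_binned_poses: bins must be ascending and non-degenerate")
  }
  n_bins <- nrow(bins)
  out <- bins
  out$mid <- (bins$lo + bins$hi) / 2
  out$pose_id <- rep(NA_character_, n_bins)
  out$rmsd <- rep(NA_real_, n_bins)
  out$n_candidates <- integer(n_bins)
  last <- n_bins
  for (b in seq_len(n_bins)) {
    in_bin <- tab$rmsd >= bins$lo[b] &
      (if (b == last) tab$rmsd <= bins$hi[b] else tab$rmsd < bins$hi[b])
    out$n_candidates[b] <- sum(in_bin)
    if (!any(in_bin)) next
    cand <- which(in_bin)
    d <- abs(tab$rmsd[cand] - out$mid[b])
    pick <- cand[order(d, cand)][1]
    out$pose_id[b] <- as.character(tab$pose_id[pick])
    out$rmsd[b] <- tab$rmsd[pick]
  }
  out
}

#' Write a pose set to disk
#'
#' One SDF per pose plus a CSV manifest (`complex_id`, `pose_id`, `rmsd`,
#' `provenance`, `file`).
#'
#' @param ps A `pose_set`.
#' @param mol The `ligand_molecule` supplying connectivity for serialization.
#' @param dir Output directory.
#' @export
write_pose_set <- function(ps, mol, dir) {
  stopifnot(inherits(ps, "pose_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(nrow(ps$poses))
  for (i in seq_len(nrow(ps$poses))) {
    files[i] <- paste0(ps$complex_id, "_", ps$poses$pose_id[i], ".sdf")
    write_ligand_pose(mol, ps$poses$coords[[i]], file.path(dir, files[i]),
                      title = paste0(ps$complex_id, " ", ps$poses$pose_id[i]))
  }
  manifest <- dplyr::bind_cols(
    tibble(complex_id = ps$complex_id),
    ps$poses[, c("pose_id", "rmsd", "provenance")],
    tibble(file = files)
  )
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(dir)
}

#' Read a pose set from a multi-record SDF
#'
#' Each record in the SDF is one pose of the same molecule; the reference
#' crystal pose comes from a separate file.
#'
#' @param poses_path Multi-record SDF of poses.
#' @param reference_path Single-record SDF of the reference pose.
#' @param complex_id Identifier; defaults to the reference file stem.
#' @param provenance Provenance tag for all read poses.
#' @return A `pose_set`.
#' @export
read_pose_set <- function(poses_path, reference_path,
                          complex_id = sub("\\.[^.]*$", "", basename(reference_path)),
                          provenance = "docked") {
  ref <- read_ligand(reference_path)
  lines <- readLines(poses_path, warn = FALSE)
  breaks <- which(trimws(lines) == "$$$$")
  starts <- c(1, head(breaks, -1) + 1)
  coords <- list()
  for (k in seq_along(starts)) {
    rec <- lines[starts[k]:breaks[k]]
    if (all(!nzchar(trimws(rec)))) next
    m <- mol_from_molblock(rec, origin = poses_path)
    if (nrow(m$atoms) != nrow(ref$atoms)) {
      abort("read_pose_set: pose atom count differs from reference")
    }
    coords[[length(coords) + 1]] <- ligand_coords(m)
  }
  pose_set(complex_id, ligand_coords(ref), coords, provenance = provenance)
}
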