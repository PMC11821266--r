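# Curated library of drug-like molecules (SMILES), spanning ~3-40 heavy
# atoms so that ligand identity can carry a size-like signal.
BASE_SMILES <- c(
  ethanol = "CCO",
  glycerol = "OCC(O)CO",
  benzene = "c1ccccc1",
  pyridine = "c1ccncc1",
  phenol = "Oc1ccccc1",
  aniline = "Nc1ccccc1",
  benzoic_acid = "OC(=O)c1ccccc1",
  metformin = "CN(C)C(=N)NC(=N)N",
  nicotinamide = "NC(=O)c1cccnc1",
  salicylic_acid = "OC(=O)c1ccccc1O",
  valproic_acid = "CCCC(CCC)C(=O)O",
  paracetamol = "CC(=O)Nc1ccc(O)cc1",
  gabapentin = "NCC1(CC(=O)O)CCCCC1",
  aspirin = "CC(=O)Oc1ccccc1C(=O)O",
  theophylline = "Cn1c(=O)c2[nH]cnc2n(C)c1=O",
  caffeine = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
  ibuprofen = "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
  lidocaine = "CCN(CC)CC(=O)Nc1c(C)cccc1C",
  naproxen = "COc1ccc2cc(ccc2c1)C(C)C(=O)O",
  sulfamethoxazole = "Cc1onc(c1)NS(=O)(=O)c1ccc(N)cc1",
  tramadol = "CN(C)CC1CCCCC1(O)c1cccc(OC)c1",
  atenolol = "CC(C)NCC(O)COc1ccc(CC(N)=O)cc1",
  propranolol = "CC(C)NCC(O)COc1cccc2ccccc12",
  metoprolol = "COCCc1ccc(OCC(O)CNC(C)C)cc1",
  diclofenac = "OC(=O)Cc1ccccc1Nc1c(Cl)cccc1Cl",
  diazepam = "CN1C(=O)CN=C(c2ccccc2)c2cc(Cl)ccc21",
  sertraline = "CNC1CCC(c2ccc(Cl)c(Cl)c2)c2ccccc21",
  chlorpromazine = "CN(C)CCCN1c2ccccc2Sc2ccc(Cl)cc21",
  fluoxetine = "CNCCC(Oc1ccc(cc1)C(F)(F)F)c1ccccc1",
  quercetin = "Oc1cc(O)c2c(c1)oc(-c1ccc(O)c(O)c1)c(O)c2=O",
  penicillin_g = "CC1(C)SC2C(NC(=O)Cc3ccccc3)C(=O)N2C1C(=O)O",
  omeprazole = "COc1ccc2[nH]c(S(=O)Cc3ncc(C)c(OC)c3C)nc2c1",
  ciprofloxacin = "OC(=O)c1cn(C2CC2)c2cc(N3CCNCC3)c(F)cc2c1=O",
  amoxicillin = "CC1(C)SC2C(NC(=O)C(N)c3ccc(O)cc3)C(=O)N2C1C(=O)O",
  warfarin = "CC(=O)CC(c1ccccc1)c1c(O)c2ccccc2oc1=O",
  celecoxib = "Cc1ccc(cc1)-c1cc(nn1-c1ccc(cc1)S(N)(=O)=O)C(F)(F)F",
  losartan = "CCCCc1nc(Cl)c(CO)n1Cc1ccc(-c2ccccc2-c2nn[nH]n2)cc1",
  sildenafil = "CCCc1nn(C)c2c1nc([nH]c2=O)-c1cc(ccc1OCC)S(=O)(=O)N1CCN(C)CC1",
  imatinib = "Cc1ccc(NC(=O)c2ccc(CN3CCN(C)CC3)cc2)cc1Nc1nccc(-c2cccnc2)n1",
  atorvastatin = "CC(C)c1c(C(=O)Nc2ccccc2)c(-c2ccccc2)c(-c2ccc(F)cc2)n1CCC(O)CC(O)CC(=O)O"
)

# SMILES -> ligand_molecule conversions are pure, so memoise per session.
.mol_cache <- new.env(parent = emptyenv())

smiles_to_mol <- function(smiles, name) {
  key <- paste0(name, "|", smiles)
  if (!is.null(.mol_cache[[key]])) return(.mol_cache[[key]])
  sdf <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, " ", name, "\n")),
    error = function(e) abort(paste0("SMILES conversion failed for ", name))
  )
  lines <- strsplit(sdf, "\n", fixed = TRUE)[[1]]
  lines[2] <- "  sfbias2D"   # drop the converter's embedded timestamp
  mol <- mol_from_molblock(lines, name = name, origin = paste0("smiles:", name))
  mol <- set_ligand_coords(mol, spiral_coords(nrow(mol$atoms)))
  .mol_cache[[key]] <- mol
  mol
}

# Deterministic compact 3D placement: golden-angle spherical spiral with
# slowly growing radius. Not chemically meaningful; every in-scope
# computation depends only on element identities, topology and distances.
spiral_coords <- function(n) {
  i <- seq_len(n)
  golden <- pi * (3 - sqrt(5))
  z <- if (n == 1) 0 else 1 - 2 * (i - 1) / (n - 1)
  r <- sqrt(pmax(0, 1 - z^2))
  rad <- 1.3 * i^(1 / 3) + 0.4
  cbind(x = rad * r * cos(golden * i), y = rad * r * sin(golden * i),
        z = rad * z)
}

#' Replace the coordinates of a ligand molecule
#'
#' Returns a copy with new coordinates in both the atom table and the
#' stored molblock, leaving connectivity and identity untouched.
#'
#' @param mol A `ligand_molecule`.
#' @param coords n x 3 numeric matrix.
#' @return A `ligand_molecule`.
#' @export
set_ligand_coords <- function(mol, coords) {
  coords <- as.matrix(coords)
  n <- nrow(mol$atoms)
  if (nrow(coords) != n || ncol(coords) != 3) {
    abort("coords must be n_atoms x 3")
  }
  mol$atoms$x <- coords[, 1]
  mol$atoms$y <- coords[, 2]
  mol$atoms$z <- coords[, 3]
  if (!is.null(mol$molblock)) {
    idx <- 4 + seq_len(n)
    tails <- substring(mol$molblock[idx], 31)
    mol$molblock[idx] <- paste0(
      sprintf("%10.4f%10.4f%10.4f", coords[, 1], coords[, 2], coords[, 3]),
      tails
    )
  }
  mol
}

#' Ligand identity effect
#'
#' The fixed functional assigning each molecule its contribution to pK in
#' the synthetic model: a centered, scaled heavy-atom count, so ligand
#' identity carries a size-like signal that 2D descriptors can recover.
#'
#' @param mol A `ligand_molecule` (or a heavy-atom count).
#' @return Numeric effect in pK units.
#' @export
ligand_effect <- function(mol) {
  heavy <- if (inherits(mol, "ligand_molecule")) {
    sum(toupper(mol$atoms$element) != "H")
  } else {
    as.numeric(mol)
  }
  (heavy - 15) / 6
}

#' Generate a deterministic ligand library
#'
#' Draws `size` molecules from the built-in curated list (seeded
#' permutation; sampling with replacement, flagged, if `size` exceeds the
#' list), converts each to a molecule with deterministic 3D coordinates,
#' and assigns its fixed [ligand_effect()].
#'
#' @param size Number of molecules (>= 1).
#' @param seed Integer seed.
#' @return Tibble of class `ligand_library`: `name`, `smiles`, `code`,
#'   `inchikey`, `heavy_atoms`, `ligand_effect`, `mol` (list-column). The
#'   attribute `oversampled` flags with-replacement reuse.
#' @export
generate_ligand_library <- function(size, seed = 1) {
  if (size < 1) abort("size must be >= 1")
  base <- names(BASE_SMILES)
  picks <- withr::with_seed(as.integer(seed), {
    if (size <= length(base)) {
      sample(base, size)
    } else {
      c(sample(base), sample(base, size - length(base), replace = TRUE))
    }
  })
  oversampled <- size > length(base)
  if (oversampled) {
    warn("generate_ligand_library: size exceeds the curated list; sampling with replacement")
  }
  mols <- lapply(picks, function(nm) smiles_to_mol(BASE_SMILES[[nm]], nm))
  heavy <- vapply(mols, function(m) sum(toupper(m$atoms$element) != "H"), numeric(1))
  out <- tibble(
    name = picks,
    smiles = unname(BASE_SMILES[picks]),
    code = sprintf("L%02d", match(picks, base)),
    inchikey = vapply(mols, function(m) m$inchikey, character(1)),
    heavy_atoms = as.integer(heavy),
    ligand_effect = ligand_effect(heavy),
    mol = mols
  )
  class(out) <- c("ligand_library", class(out))
  attr(out, "oversampled") <- oversampled
  out
}

#' Pocket composition effect weights
#'
#' The fixed linear functional mapping a pocket's residue-type counts to
#' its contribution to pK: Kyte-Doolittle hydropathy divided by 10 per
#' residue (UNK weighs 0). Purely a synthetic signal choice: hydrophobic
#' pockets are assigned higher pK.
#'
#' @return Named numeric vector over [pocket_residue_order()].
#' @export
pocket_effect_weights <- function() {
  kd <- c(ALA = 1.8, ARG = -4.5, ASN = -3.5, ASP = -3.5, CYS = 2.5,
          GLN = -3.5, GLU = -3.5, GLY = -0.4, HIS = -3.2, ILE = 4.5,
          LEU = 3.8, LYS = -3.9, MET = 1.9, PHE = 2.8, PRO = -1.6,
          SER = -0.8, THR = -0.7, TRP = -0.9, TYR = -1.3, VAL = 4.2)
  c(kd / 10, UNK = 0)
}

#' Pocket effect of a composition vector
#'
#' @param counts Named counts over (a subset of) [pocket_residue_order()].
#' @return Numeric effect in pK units.
#' @export
pocket_effect <- function(counts) {
  w <- pocket_effect_weights()
  idx <- names(counts)
  if (is.null(idx) || !all(idx %in% names(w))) {
    abort("counts must be named with standard residue codes (or UNK)")
  }
  sum(as.numeric(counts) * w[idx])
}

as_full_composition <- function(counts) {
  full <- setNames(integer(length(AA3_UNK)), AA3_UNK)
  full[names(counts)] <- full[names(counts)] + as.integer(counts)
  full
}

#' Generate a synthetic binding pocket
#'
#' Places residues of the requested types as rigid three-atom templates
#' (N, CA, C) scattered at 5-11 Angstrom from the ligand centroid — inside
#' the 15 Angstrom pocket shell — plus optional distractor residues
#' beyond 15 Angstrom (but within 30) of every ligand atom. The output is
#' constructed so that [pocket_residue_counts()] at threshold 15 recovers
#' the requested composition exactly (verified internally, with placement
#' retries on failure). Pockets are geometric residue scatters, not folded
#' proteins: every in-scope computation sees only residue identities and
#' atom distances.
#'
#' @param composition Named residue counts (e.g. `c(GLY = 3, ILE = 2)`).
#' @param lig_xyz Ligand coordinates (n x 3 matrix) or a `ligand_molecule`.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @param n_distractors Number of out-of-shell residues (default 0).
#' @param distractor_types Residue types for distractors (recycled;
#'   default `"GLY"`).
#' @return A `protein_structure` with attributes `composition` (the full
#'   21-vector) and `pocket_effect`.
#' @export
generate_pocket <- function(composition, lig_xyz, seed = NULL,
                            n_distractors = 0, distractor_types = "GLY") {
  if (inherits(lig_xyz, "ligand_molecule")) lig_xyz <- ligand_coords(lig_xyz)
  lig_xyz <- as.matrix(lig_xyz)
  counts <- composition[composition > 0]
  if (sum(counts) < 1) abort("total residues must be >= 1")
  types <- rep(names(counts), times = counts)
  want <- as_full_composition(counts)
  run <- function() {
    for (attempt in 1:5) {
      prot <- place_pocket(types, lig_xyz, n_distractors,
                           rep_len(distractor_types, max(1, n_distractors)))
      got <- pocket_residue_counts(prot, lig_xyz, threshold_A = 15)
      if (identical(unname(got[AA3_UNK]), unname(want[AA3_UNK]))) return(prot)
    }
    abort("generate_pocket: placement failed to reproduce the requested composition")
  }
  prot <- if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
  attr(prot, "composition") <- want
  attr(prot, "pocket_effect") <- pocket_effect(want)
  prot
}

place_pocket <- function(types, lig_xyz, n_distractors, distractor_types) {
  centroid <- colMeans(lig_xyz)
  max_rad <- sqrt(max(rowSums(sweep(lig_xyz, 2, centroid)^2)))
  centers <- matrix(NA_real_, nrow = 0, ncol = 3)
  min_lig_dist <- function(p) sqrt(min(colSums((t(lig_xyz) - p)^2)))
  draw_center <- function(lo_ok, hi_ok, rad_fn) {
    for (try in 1:200) {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      p <- centroid + rad_fn() * u
      d <- min_lig_dist(p)
      sep_ok <- nrow(centers) == 0 ||
        min(rowSums(sweep(centers, 2, p)^2)) > 2.8^2
      if (d >= lo_ok && d <= hi_ok && sep_ok) return(p)
    }
    abort("generate_pocket: could not place residue (overcrowded)")
  }
  n_res <- length(types) + n_distractors
  xyz <- matrix(NA_real_, nrow = 3 * n_res, ncol = 3)
  resnames <- character(3 * n_res)
  resnos <- integer(3 * n_res)
  add_residue <- function(type, center, resno) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    v <- rnorm(3); v <- v - sum(v * u) * u; v <- v / sqrt(sum(v^2))
    at <- 3 * (resno - 1) + 1:3
    xyz[at, ] <<- rbind(center + 1.46 * u, center, center + 1.52 * v)
    resnames[at] <<- type
    resnos[at] <<- resno
  }
  resno <- 0L
  for (type in types) {
    resno <- resno + 1L
    center <- draw_center(2.8, 12.5, function() runif(1, 5, 11))
    centers <- rbind(centers, center)
    add_residue(type, center, resno)
  }
  for (k in seq_len(n_distractors)) {
    resno <- resno + 1L
    center <- draw_center(17.5, 26,
                          function() max_rad + runif(1, 17, 24))
    centers <- rbind(centers, center)
    add_residue(distractor_types[k], center, resno)
  }
  new_protein_structure(
    tibble(element = rep(c("N", "C", "C"), n_res), resname = resnames,
           resno = resnos, chain = "A", ins = "",
           x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
    source_path = "<generated>")
}

#' Generator configuration
#'
#' Study conditions for [generate_dataset()]: the label model is
#' `pK = base_pk + alpha_ligand * ligand_effect + beta_pocket * pocket_effect
#'  + N(0, noise_sd^2)`.
#'
#' @param n_complexes Number of complexes (default 500).
#' @param ligand_library_size Library size (default 40).
#' @param duplicate_ligand_fraction Fraction of complexes that reuse an
#'   already-used ligand, bound to a different pocket (default 0.5; capped
#'   by the library size).
#' @param alpha_ligand,beta_pocket Effect weights (defaults 1, 1).
#' @param noise_sd Gaussian label noise in pK units (default 0.3).
#' @param base_pk Intercept (default 6, near the center of typical
#'   affinity databases).
#' @param year_range Deposition years sampled uniformly (default 2010-2022).
#' @param peptide_fraction Fraction of distinct ligands given a
#'   peptide-style code containing "MER" (default 0.1).
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_complexes = 500, ligand_library_size = 40,
                             duplicate_ligand_fraction = 0.5,
                             alpha_ligand = 1, beta_pocket = 1,
                             noise_sd = 0.3, base_pk = 6,
                             year_range = c(2010, 2022),
                             peptide_fraction = 0.1, seed = 1) {
  if (n_complexes < 1) abort("n_complexes must be >= 1")
  if (duplicate_ligand_fraction < 0 || duplicate_ligand_fraction > 1) {
    abort("duplicate_ligand_fraction must be in [0, 1]")
  }
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (peptide_fraction < 0 || peptide_fraction > 1) {
    abort("peptide_fraction must be in [0, 1]")
  }
  structure(list(
    n_complexes = as.integer(n_complexes),
    ligand_library_size = as.integer(ligand_library_size),
    duplicate_ligand_fraction = duplicate_ligand_fraction,
    alpha_ligand = alpha_ligand, beta_pocket = beta_pocket,
    noise_sd = noise_sd, base_pk = base_pk,
    year_range = as.integer(year_range),
    peptide_fraction = peptide_fraction,
    seed = as.integer(seed)
  ), class = "generator_config")
}

random_composition <- function() {
  n_res <- sample(18:30, 1)
  counts <- tabulate(sample(length(AA3), n_res, replace = TRUE), nbins = length(AA3))
  setNames(counts, AA3)
}

pk_to_measurement <- function(pk) {
  molar <- 10^(-pk)
  scale <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12, fM = 1e-15)
  fits <- which(scale <= molar)
  unit <- if (length(fits) == 0) "fM" else names(scale)[min(fits)]
  list(value = molar / scale[[unit]], unit = unit)
}

#' Generate a synthetic complex dataset with known ground truth
#'
#' Builds `n_complexes` protein-ligand complexes: each complex pairs a
#' library ligand (with deterministic coordinates and InChI-Key) with a
#' freshly scattered synthetic pocket, and labels it with
#' `pK = base_pk + alpha * ligand_effect + beta * pocket_effect + noise`.
#' A controllable fraction of complexes reuse ligands across different
#' pockets, giving identical-ligand clusters for the bias benchmarks.
#' When `out_dir` is given the dataset is additionally written in the
#' exact on-disk layout [load_dataset()] consumes (per-complex PDB + SDF,
#' affinity index, ground-truth CSV); generation is byte-reproducible
#' from the config seed.
#'
#' @param config A [generator_config()].
#' @param out_dir Optional output directory.
#' @param n_corrupt Number of ligand files deliberately corrupted on disk
#'   (exercises exclusion reporting; in-memory records are unaffected).
#' @return Records tibble (the same shape [load_dataset()] returns) with
#'   ground-truth columns `ligand_name`, `inchikey`, `ligand_effect`,
#'   `pocket_effect`, `noise`; attributes `config` and (if written)
#'   `out_dir`, `corrupted_ids`.
#' @export
generate_dataset <- function(config = generator_config(), out_dir = NULL,
                             n_corrupt = 0) {
  stopifnot(inherits(config, "generator_config"))
  lib <- generate_ligand_library(config$ligand_library_size, seed = config$seed)
  n <- config$n_complexes
  records <- withr::with_seed(config$seed, {
    n_distinct <- min(nrow(lib),
                      max(1L, ceiling(n * (1 - config$duplicate_ligand_fraction))))
    idx <- c(seq_len(min(n, n_distinct)),
             if (n > n_distinct) sample(n_distinct, n - n_distinct, replace = TRUE))
    idx <- sample(idx)
    codes <- lib$code
    n_pep <- ceiling(config$peptide_fraction * n_distinct)
    if (n_pep > 0) {
      pep_rows <- sample(n_distinct, n_pep)
      codes[pep_rows] <- sprintf("%dMER", seq_len(n_pep))
    }
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      li <- idx[i]
      mol <- lib$mol[[li]]
      comp <- random_composition()
      prot <- generate_pocket(comp, ligand_coords(mol))
      pe <- attr(prot, "pocket_effect")
      noise <- rnorm(1, 0, config$noise_sd)
      pk <- config$base_pk + config$alpha_ligand * lib$ligand_effect[li] +
        config$beta_pocket * pe + noise
      meas <- pk_to_measurement(pk)
      rows[[i]] <- tibble(
        complex_id = sprintf("s%04d", i),
        year = sample(seq(config$year_range[1], config$year_range[2]), 1),
        measurement_type = sample(c("Ki", "Kd", "IC50"), 1),
        qualifier = "=",
        value = meas$value, unit = meas$unit, pk = pk,
        ligand_code = codes[li],
        protein = list(prot), ligand = list(mol),
        ligand_name = lib$name[li], inchikey = lib$inchikey[li],
        ligand_effect = lib$ligand_effect[li], pocket_effect = pe,
        noise = noise
      )
    }
    bind_rows(rows)
  })
  attr(records, "config") <- config
  if (!is.null(out_dir)) {
    corrupted <- write_synthetic_dataset(records, out_dir, n_corrupt = n_corrupt)
    attr(records, "out_dir") <- out_dir
    attr(records, "corrupted_ids") <- corrupted
  }
  records
}

write_protein_pdb <- function(prot, path) {
  bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = as.numeric(t(as.matrix(prot[, c("x", "y", "z")]))),
    type = rep("ATOM", nrow(prot)),
    resno = prot$resno, resid = prot$resname, chain = prot$chain,
    eleno = seq_len(nrow(prot)),
    elety = ifelse(prot$element == "N", "N",
                   rep(c("N", "CA", "C"), length.out = nrow(prot))),
    elesy = prot$element
  )
  invisible(path)
}

write_synthetic_dataset <- function(records, out_dir, n_corrupt = 0) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  index_lines <- c(
    "# synthetic affinity index (sfbias)",
    "# id  resolution  year  -logK  measurement // (ligand code)"
  )
  for (i in seq_len(nrow(records))) {
    id <- records$complex_id[i]
    d <- file.path(out_dir, id)
    dir.create(d, showWarnings = FALSE)
    write_protein_pdb(records$protein[[i]],
                      file.path(d, paste0(id, "_protein.pdb")))
    write_ligand_pose(records$ligand[[i]], NULL,
                      file.path(d, paste0(id, "_ligand.sdf")),
                      title = records$ligand_name[i])
    index_lines <- c(index_lines, sprintf(
      "%s  2.00  %d  %.2f  %s=%.6g%s // (%s)",
      id, records$year[i], records$pk[i], records$measurement_type[i],
      records$value[i], records$unit[i], records$ligand_code[i]
    ))
  }
  writeLines(index_lines, file.path(out_dir, "index.txt"))
  truth <- records %>%
    select("complex_id", "ligand_name", "inchikey", "ligand_effect",
           "pocket_effect", "noise", "pk", "year", "ligand_code")
  readr::write_csv(truth, file.path(out_dir, "ground_truth.csv"))
  corrupted <- character()
  if (n_corrupt > 0) {
    corrupted <- head(records$complex_id, n_corrupt)
    for (id in corrupted) {
      writeLines("this is not a molecule",
                 file.path(out_dir, id, paste0(id, "_ligand.sdf")))
    }
  }
  corrupted
}

# Compose a pocket whose effect approximates `target` (pK units): coarse
# ILE/ARG balance plus fine ALA/SER adjustment; exact effect is whatever
# the returned counts imply.
composition_for_effect <- function(target) {
  w <- pocket_effect_weights()
  total <- 24
  n1 <- round((target / w[["ILE"]] + total) / 2)
  n1 <- max(0, min(total, n1))
  n2 <- total - n1
  counts <- c(ILE = n1, ARG = n2)
  resid <- target - (n1 * w[["ILE"]] + n2 * w[["ARG"]])
  if (resid > 0.05) {
    counts <- c(counts, ALA = min(6, round(resid / w[["ALA"]])))
  } else if (resid < -0.05) {
    counts <- c(counts, SER = min(8, round(resid / w[["SER"]])))
  }
  counts[counts > 0]
}

#' Generate the zero-ligand-bias testbed
#'
#' Builds a dataset where pK is driven purely by the pocket
#' (`alpha_ligand` must be 0): a set of planted identical-ligand clusters
#' whose realized mean pK lies in [6, 7] and whose sample variance exceeds
#' 1 (the within-cluster spread comes from different pockets), plus
#' background complexes whose ligand groups deliberately fail the filter
#' (tight within-group spread, group means covering 3.5-9.5 so
#' pocket-view models can be trained on the background). Applying
#' [zero_ligand_bias_filter()] to the output retains exactly the planted
#' clusters.
#'
#' @param n_clusters Number of planted clusters (default 8).
#' @param cluster_sizes Candidate cluster sizes (default 2:4).
#' @param n_background Number of background complexes (default 80).
#' @param base_pk Intercept (default 6).
#' @param noise_sd Label noise, kept small so planted spreads are
#'   controlled (default 0.05).
#' @param alpha_ligand Must be 0: ligand identity cannot be allowed to
#'   explain within-cluster spread.
#' @param seed Integer seed.
#' @return Records tibble with attributes `planted` (tibble: `inchikey`,
#'   `member_ids` list) and `planted_ids`.
#' @export
generate_zero_bias_testbed <- function(n_clusters = 8, cluster_sizes = 2:4,
                                       n_background = 80, base_pk = 6,
                                       noise_sd = 0.05, alpha_ligand = 0,
                                       seed = 1) {
  if (alpha_ligand != 0) {
    abort("alpha_ligand must be 0: planted within-cluster spread cannot coexist with ligand signal")
  }
  lib <- generate_ligand_library(40, seed = seed)
  if (n_clusters + 2 > nrow(lib)) abort("too many planted clusters for the library")
  withr::with_seed(as.integer(seed) + 1L, {
    planted_lib <- lib[seq_len(n_clusters), ]
    background_lib <- lib[(n_clusters + 1):nrow(lib), ]
    rows <- list()
    planted <- list()
    cid <- 0L
    next_id <- function() { cid <<- cid + 1L; sprintf("z%04d", cid) }
    offsets <- function(m) {
      switch(as.character(m), `2` = c(-1, 1), `3` = c(-1, 0, 1),
             `4` = c(-1, -1 / 3, 1 / 3, 1), abort("unsupported cluster size"))
    }
    make_record <- function(id, mol, lig_row, target_pk) {
      comp <- composition_for_effect(target_pk - base_pk)
      prot <- generate_pocket(comp, ligand_coords(mol))
      pe <- attr(prot, "pocket_effect")
      noise <- rnorm(1, 0, noise_sd)
      pk <- base_pk + pe + noise
      meas <- pk_to_measurement(pk)
      tibble(
        complex_id = id, year = sample(2010:2022, 1),
        measurement_type = sample(c("Ki", "Kd", "IC50"), 1),
        qualifier = "=", value = meas$value, unit = meas$unit, pk = pk,
        ligand_code = lig_row$code,
        protein = list(prot), ligand = list(mol),
        ligand_name = lig_row$name, inchikey = lig_row$inchikey,
        ligand_effect = 0, pocket_effect = pe, noise = noise
      )
    }
    for (j in seq_len(n_clusters)) {
      lig_row <- planted_lib[j, ]
      mol <- lig_row$mol[[1]]
      for (attempt in 1:50) {
        m <- sample(cluster_sizes, 1)
        mu <- runif(1, 6.25, 6.75)
        d <- runif(1, 1.3, 1.6)
        targets <- mu + d * offsets(m)
        members <- lapply(targets, function(t) make_record(next_id(), mol, lig_row, t))
        pks <- vapply(members, function(r) r$pk, numeric(1))
        if (mean(pks) >= 6.05 && mean(pks) <= 6.95 && var(pks) > 1.05) {
          rows <- c(rows, members)
          planted[[length(planted) + 1]] <- tibble(
            inchikey = lig_row$inchikey,
            member_ids = list(vapply(members, function(r) r$complex_id, character(1)))
          )
          break
        }
        cid <- cid - length(members)  # roll back ids of the rejected draw
        if (attempt == 50) abort("could not plant cluster within tolerance")
      }
    }
    group_mean <- list()
    for (i in seq_len(n_background)) {
      bi <- sample(nrow(background_lib), 1)
      lig_row <- background_lib[bi, ]
      key <- lig_row$inchikey
      if (is.null(group_mean[[key]])) {
        group_mean[[key]] <- sample(list(
          function() runif(1, 3.5, 5.5),
          function() runif(1, 6.05, 6.95),
          function() runif(1, 7.5, 9.5)
        ), 1)[[1]]()
      }
      target <- group_mean[[key]] + runif(1, -0.2, 0.2)
      rows[[length(rows) + 1]] <-
        make_record(next_id(), lig_row$mol[[1]], lig_row, target)
    }
    records <- bind_rows(rows)
    planted <- bind_rows(planted)
    attr(records, "planted") <- planted
    attr(records, "planted_ids") <-
      unlist(planted$member_ids, use.names = FALSE)
    attr(records, "base_pk") <- base_pk
    records
  })
}

# Rodrigues rotation matrix about unit axis u by angle theta.
rotation_matrix <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              nrow = 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Generate rigid-body decoy poses at prescribed RMSDs
#'
#' Each decoy is a rigid rotation about the centroid plus a translation.
#' Because the rotation is centroid-centered, the in-place RMSD
#' decomposes exactly as `rmsd^2 = rmsd_rot^2 + |t|^2`, so the rotation
#' angle is shrunk until its RMSD contribution is below the target and
#' the translation magnitude supplies the exact remainder: realized RMSDs
#' match their targets to floating-point precision (tolerance 0.05 A in
#' the contract).
#'
#' @param mol A `ligand_molecule` or an n x 3 coordinate matrix (the
#'   reference pose).
#' @param target_rmsds Positive target RMSDs in Angstrom (0 allowed:
#'   identity pose).
#' @param seed Integer seed.
#' @param complex_id Identifier carried on the pose set.
#' @return A `pose_set` with provenance `"docked"`.
#' @export
generate_pose_decoys <- function(mol, target_rmsds, seed = 1,
                                 complex_id = "decoys") {
  ref <- if (inherits(mol, "ligand_molecule")) ligand_coords(mol) else as.matrix(mol)
  if (any(target_rmsds < 0)) abort("target RMSDs must be >= 0")
  centroid <- colMeans(ref)
  centered <- sweep(ref, 2, centroid)
  poses <- withr::with_seed(as.integer(seed), {
    lapply(target_rmsds, function(target) {
      if (target == 0) return(ref)
      axis <- rnorm(3)
      theta <- runif(1, 0.15, 0.9)
      repeat {
        R <- rotation_matrix(axis, theta)
        rot <- sweep(centered %*% t(R), 2, -centroid)
        r_rot <- rmsd(ref, rot)
        if (r_rot <= 0.8 * target) break
        theta <- theta / 2
      }
      shift <- sqrt(target^2 - r_rot^2)
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      sweep(rot, 2, shift * dir, "+")
    })
  })
  pose_set(complex_id, ref, poses,
           pose_ids = sprintf("decoy_%02d", seq_along(poses)),
           provenance = "docked")
}
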