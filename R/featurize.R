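# Atomic masses (most common elements in drug-like molecules).
ATOMIC_MASS <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  SI = 28.086, P = 30.974, S = 32.06, CL = 35.453, BR = 79.904, I = 126.904
)

# Default valences used to infer implicit hydrogen counts from the 2D graph.
DEFAULT_VALENCE <- c(
  B = 3, C = 4, N = 3, O = 2, F = 1, SI = 4, P = 3, S = 2,
  CL = 1, BR = 1, I = 1
)

atom_masses <- function(elements) {
  m <- ATOMIC_MASS[toupper(elements)]
  m[is.na(m)] <- 0
  unname(m)
}

# Per-atom bond order sums and degrees over the heavy-atom graph; aromatic
# bonds (order 4 in the molblock) contribute 1.5 to the valence sum.
ligand_graph_stats <- function(mol) {
  el <- toupper(mol$atoms$element)
  heavy <- el != "H"
  n <- length(el)
  deg <- numeric(n)
  bosum <- numeric(n)
  b <- mol$bonds
  ord <- ifelse(b$order == 4, 1.5, b$order)
  for (k in seq_len(nrow(b))) {
    i <- b$from[k]; j <- b$to[k]
    deg[i] <- deg[i] + 1; deg[j] <- deg[j] + 1
    bosum[i] <- bosum[i] + ord[k]; bosum[j] <- bosum[j] + ord[k]
  }
  val <- DEFAULT_VALENCE[el]
  implicit_h <- pmax(0, ifelse(is.na(val), 0, val) - bosum)
  implicit_h[!heavy] <- 0
  # explicit hydrogens attached per atom
  hn <- numeric(n)
  for (k in seq_len(nrow(b))) {
    if (el[b$from[k]] == "H") hn[b$to[k]] <- hn[b$to[k]] + 1
    if (el[b$to[k]] == "H") hn[b$from[k]] <- hn[b$from[k]] + 1
  }
  list(element = el, heavy = heavy, degree = deg, bond_order_sum = bosum,
       implicit_h = implicit_h, explicit_h = hn)
}

count_components <- function(n, from, to) {
  if (n == 0) return(0L)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_along(from)) {
    a <- find(from[k]); b <- find(to[k])
    if (a != b) parent[a] <- b
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# A bond is a ring bond iff its endpoints stay connected after its removal.
ring_bond_flags <- function(n, from, to) {
  nb <- length(from)
  flags <- logical(nb)
  if (nb == 0) return(flags)
  adj <- vector("list", n)
  for (k in seq_len(nb)) {
    adj[[from[k]]] <- c(adj[[from[k]]], k)
    adj[[to[k]]] <- c(adj[[to[k]]], k)
  }
  for (k in seq_len(nb)) {
    # BFS from from[k] to to[k] avoiding bond k
    target <- to[k]
    seen <- logical(n)
    queue <- from[k]; seen[from[k]] <- TRUE
    found <- FALSE
    while (length(queue) > 0 && !found) {
      v <- queue[1]; queue <- queue[-1]
      for (e in adj[[v]]) {
        if (e == k) next
        w <- if (from[e] == v) to[e] else from[e]
        if (w == target) { found <- TRUE; break }
        if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    flags[k] <- found
  }
  flags
}

#' The built-in 2D ligand descriptor battery
#'
#' A named list of descriptor functions, each mapping a `ligand_molecule`
#' to one number computed from the 2D molecular graph and element identities
#' only — never from 3D coordinates, so all conformers and poses of one
#' molecule featurize identically. Implicit hydrogens are inferred from
#' default valences, so e.g. molecular weight for ethanol read from an
#' H-free SDF is still 46.07.
#'
#' @return Named list of functions `ligand_molecule -> numeric(1)`.
#' @export
ligand_descriptor_battery <- function() {
  count_el <- function(sym) {
    force(sym)
    function(mol) sum(toupper(mol$atoms$element) == sym)
  }
  battery <- list(
    mol_weight = function(mol) {
      g <- ligand_graph_stats(mol)
      sum(atom_masses(mol$atoms$element)) + sum(g$implicit_h) * ATOMIC_MASS[["H"]]
    },
    heavy_atom_count = function(mol) sum(toupper(mol$atoms$element) != "H"),
    total_atom_count = function(mol) {
      g <- ligand_graph_stats(mol)
      nrow(mol$atoms) + sum(g$implicit_h)
    },
    n_carbon = count_el("C"), n_nitrogen = count_el("N"),
    n_oxygen = count_el("O"), n_sulfur = count_el("S"),
    n_phosphorus = count_el("P"), n_fluorine = count_el("F"),
    n_chlorine = count_el("CL"), n_bromine = count_el("BR"),
    n_iodine = count_el("I"),
    n_halogen = function(mol) sum(toupper(mol$atoms$element) %in% c("F", "CL", "BR", "I")),
    n_heteroatom = function(mol) sum(!toupper(mol$atoms$element) %in% c("C", "H")),
    frac_carbon = function(mol) {
      el <- toupper(mol$atoms$element)
      h <- sum(el != "H")
      if (h == 0) NaN else sum(el == "C") / h
    },
    n_bonds_heavy = function(mol) {
      el <- toupper(mol$atoms$element)
      sum(el[mol$bonds$from] != "H" & el[mol$bonds$to] != "H")
    },
    n_single_bonds = function(mol) sum(mol$bonds$order == 1),
    n_double_bonds = function(mol) sum(mol$bonds$order == 2),
    n_triple_bonds = function(mol) sum(mol$bonds$order == 3),
    n_aromatic_bonds = function(mol) sum(mol$bonds$order == 4),
    total_bond_order = function(mol) sum(ifelse(mol$bonds$order == 4, 1.5, mol$bonds$order)),
    ring_count = function(mol) {
      el <- toupper(mol$atoms$element)
      heavy_idx <- which(el != "H")
      remap <- match(seq_along(el), heavy_idx)
      keep <- el[mol$bonds$from] != "H" & el[mol$bonds$to] != "H"
      nb <- sum(keep)
      comp <- count_components(length(heavy_idx),
                               remap[mol$bonds$from[keep]],
                               remap[mol$bonds$to[keep]])
      nb - length(heavy_idx) + comp
    },
    n_rotatable_bonds = function(mol) {
      el <- toupper(mol$atoms$element)
      g <- ligand_graph_stats(mol)
      keep <- el[mol$bonds$from] != "H" & el[mol$bonds$to] != "H"
      if (!any(keep)) return(0)
      ring <- ring_bond_flags(nrow(mol$atoms), mol$bonds$from[keep], mol$bonds$to[keep])
      single <- mol$bonds$order[keep] == 1
      internal <- g$degree[mol$bonds$from[keep]] >= 2 & g$degree[mol$bonds$to[keep]] >= 2
      sum(single & !ring & internal)
    },
    hbond_donors = function(mol) {
      g <- ligand_graph_stats(mol)
      sum(g$element %in% c("N", "O") & (g$implicit_h + g$explicit_h) >= 1)
    },
    hbond_acceptors = function(mol) sum(toupper(mol$atoms$element) %in% c("N", "O")),
    mean_heavy_degree = function(mol) {
      g <- ligand_graph_stats(mol)
      d <- g$degree[g$heavy]
      if (length(d) == 0) NaN else mean(d)
    },
    max_heavy_degree = function(mol) {
      g <- ligand_graph_stats(mol)
      d <- g$degree[g$heavy]
      if (length(d) == 0) NaN else max(d)
    },
    n_terminal_atoms = function(mol) {
      g <- ligand_graph_stats(mol)
      sum(g$heavy & g$degree == 1)
    },
    n_branch_points = function(mol) {
      g <- ligand_graph_stats(mol)
      sum(g$heavy & g$degree >= 3)
    },
    mw_per_heavy_atom = function(mol) {
      g <- ligand_graph_stats(mol)
      h <- sum(g$heavy)
      if (h == 0) NaN else
        (sum(atom_masses(mol$atoms$element)) + sum(g$implicit_h) * ATOMIC_MASS[["H"]]) / h
    },
    implicit_h_count = function(mol) sum(ligand_graph_stats(mol)$implicit_h)
  )
  battery
}

#' Build a frozen descriptor schema from training ligands
#'
#' Evaluates the descriptor battery on every training ligand and freezes the
#' list of retained descriptors: a descriptor is excluded if it produces a
#' non-finite value ("nan") or an absolute value above `overflow_threshold`
#' ("overflow") on any training ligand. Retained names are sorted so two
#' builds on the same ligands serialize byte-identically. Training medians
#' of retained descriptors are stored for predict-time imputation.
#'
#' @param training_ligands List of `ligand_molecule` objects.
#' @param overflow_threshold Exclusion threshold for "extremely large"
#'   descriptor values (default 1e8).
#' @param battery Named list of descriptor functions; defaults to
#'   [ligand_descriptor_battery()].
#' @return An object of class `descriptor_schema`: fields `names`
#'   (retained, sorted), `exclusion_log` (tibble name/reason), `medians`,
#'   `overflow_threshold`, `schema_id`.
#' @export
build_descriptor_schema <- function(training_ligands,
                                    overflow_threshold = 1e8,
                                    battery = ligand_descriptor_battery()) {
  if (length(training_ligands) == 0) abort("need at least one training ligand")
  vals <- matrix(NA_real_, nrow = length(training_ligands), ncol = length(battery),
                 dimnames = list(NULL, names(battery)))
  for (i in seq_along(training_ligands)) {
    for (j in seq_along(battery)) {
      v <- tryCatch(battery[[j]](training_ligands[[i]]), error = function(e) NaN)
      vals[i, j] <- if (length(v) == 1 && is.numeric(v)) v else NaN
    }
  }
  has_nan <- apply(vals, 2, function(col) any(!is.finite(col)))
  has_ovf <- apply(vals, 2, function(col) any(is.finite(col) & abs(col) > overflow_threshold))
  excl <- tibble(
    name = c(names(battery)[has_nan], names(battery)[!has_nan & has_ovf]),
    reason = c(rep("nan", sum(has_nan)), rep("overflow", sum(!has_nan & has_ovf)))
  )
  retained <- sort(setdiff(names(battery), excl$name))
  if (length(retained) == 0) {
    abort("all descriptors excluded; check inputs or overflow_threshold")
  }
  medians <- apply(vals[, retained, drop = FALSE], 2, median)
  schema <- structure(
    list(names = retained,
         exclusion_log = excl[order(excl$name), , drop = FALSE],
         medians = medians,
         overflow_threshold = overflow_threshold,
         schema_id = rlang::hash(list(retained, overflow_threshold))),
    class = "descriptor_schema"
  )
  schema
}

#' @export
print.descriptor_schema <- function(x, ...) {
  cat("<descriptor_schema> ", length(x$names), " retained descriptors, ",
      nrow(x$exclusion_log), " excluded (id ", x$schema_id, ")\n", sep = "")
  invisible(x)
}

#' Serialize / restore a descriptor schema
#'
#' Schemas serialize to JSON; reloading gives an identical schema (same
#' retained names in the same order, same medians, same id).
#'
#' @param schema A `descriptor_schema`.
#' @param path JSON file path.
#' @return `read_descriptor_schema` returns the restored `descriptor_schema`.
#' @export
write_descriptor_schema <- function(schema, path) {
  stopifnot(inherits(schema, "descriptor_schema"))
  obj <- list(
    names = schema$names,
    exclusion_log = schema$exclusion_log,
    medians = as.list(schema$medians),
    overflow_threshold = schema$overflow_threshold,
    schema_id = schema$schema_id
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_descriptor_schema
#' @export
read_descriptor_schema <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(names = obj$names,
         exclusion_log = as_tibble(obj$exclusion_log),
         medians = unlist(obj$medians),
         overflow_threshold = obj$overflow_threshold,
         schema_id = obj$schema_id),
    class = "descriptor_schema"
  )
}

#' Ligand descriptor vector under a frozen schema
#'
#' Computes the retained descriptors for one molecule. Descriptors are
#' functions of the 2D graph only, so different conformers or poses of the
#' same molecule give identical vectors. A descriptor that fails or is
#' non-finite at predict time is imputed with its training median (with a
#' warning).
#'
#' @param mol A `ligand_molecule`.
#' @param schema A `descriptor_schema` from [build_descriptor_schema()].
#' @param battery The descriptor battery the schema was built with.
#' @return Named numeric vector (length `length(schema$names)`) with
#'   attribute `schema_id`.
#' @export
ligand_descriptors <- function(mol, schema, battery = ligand_descriptor_battery()) {
  stopifnot(inherits(schema, "descriptor_schema"))
  out <- vapply(schema$names, function(nm) {
    f <- battery[[nm]]
    if (is.null(f)) return(NA_real_)
    v <- tryCatch(f(mol), error = function(e) NA_real_)
    if (length(v) != 1 || !is.numeric(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  bad <- !is.finite(out)
  if (any(bad)) {
    warn(paste0("ligand_descriptors: imputed ", sum(bad),
                " descriptor(s) with training median for '", mol$name, "': ",
                paste(names(out)[bad], collapse = ", ")))
    out[bad] <- schema$medians[names(out)[bad]]
  }
  attr(out, "schema_id") <- schema$schema_id
  out
}

#' Pocket residue-type composition
#'
#' Counts, for each of the 20 standard amino acids (plus a UNK bucket for
#' anything else), the number of distinct residues with at least one atom
#' within `threshold_A` of any ligand atom. A residue counts once no matter
#' how many of its atoms are in range; distances are Euclidean between
#' heavy atoms (hydrogens excluded by default, as their placement varies
#' across PDB files).
#'
#' @param protein A `protein_structure`.
#' @param ligand A `ligand_molecule` (or an n x 3 coordinate matrix).
#' @param threshold_A Pocket distance cutoff in Angstrom (default 15).
#' @param heavy_only Exclude hydrogens from the distance search (default `TRUE`).
#' @return Named integer vector of length 21 in [pocket_residue_order()]
#'   order, with attribute `threshold_A`.
#' @export
pocket_residue_counts <- function(protein, ligand, threshold_A = 15,
                                  heavy_only = TRUE) {
  if (threshold_A < 0) abort("threshold_A must be non-negative")
  lig_xyz <- if (inherits(ligand, "ligand_molecule")) {
    keep <- if (heavy_only) toupper(ligand$atoms$element) != "H" else
      rep(TRUE, nrow(ligand$atoms))
    ligand_coords(ligand)[keep, , drop = FALSE]
  } else {
    as.matrix(ligand)
  }
  prot <- protein
  if (heavy_only) prot <- prot[toupper(prot$element) != "H", , drop = FALSE]
  counts <- setNames(integer(length(AA3_UNK)), AA3_UNK)
  if (nrow(prot) == 0 || nrow(lig_xyz) == 0) {
    attr(counts, "threshold_A") <- threshold_A
    return(counts)
  }
  pxyz <- as.matrix(prot[, c("x", "y", "z")])
  # min squared distance from each protein atom to any ligand atom
  cross <- pxyz %*% t(lig_xyz)
  d2 <- outer(rowSums(pxyz^2), rowSums(lig_xyz^2), "+") - 2 * cross
  mind2 <- apply(d2, 1, min)
  in_pocket <- mind2 <= threshold_A^2 + 1e-9
  if (any(in_pocket)) {
    res_key <- paste(prot$chain, prot$resno, prot$ins, sep = "|")
    hit <- !duplicated(res_key) & res_key %in% unique(res_key[in_pocket])
    types <- prot$resname[hit]
    types[!types %in% AA3] <- "UNK"
    tab <- table(factor(types, levels = AA3_UNK))
    counts[] <- as.integer(tab)
  }
  attr(counts, "threshold_A") <- threshold_A
  counts
}

#' Concatenate ligand and pocket feature blocks
#'
#' The combined feature view: the ligand descriptor block first, then the
#' 21 pocket composition counts (names prefixed `pocket_`).
#'
#' @param ligand_vec Vector from [ligand_descriptors()].
#' @param pocket Vector from [pocket_residue_counts()].
#' @return Named numeric vector of length `length(ligand_vec) + 21` with
#'   attribute `schema_id` carried over from the ligand block.
#' @export
concat_features <- function(ligand_vec, pocket) {
  if (length(pocket) != length(AA3_UNK) ||
      !identical(names(pocket), AA3_UNK)) {
    abort("pocket must be a 21-long composition vector in pocket_residue_order()")
  }
  sid <- attr(ligand_vec, "schema_id")
  out <- c(as.numeric(ligand_vec), as.numeric(pocket))
  names(out) <- c(names(ligand_vec), paste0("pocket_", AA3_UNK))
  attr(out, "schema_id") <- sid
  out
}

#' Feature matrix for a records tibble
#'
#' Builds the design matrix a bias model sees: ligand descriptors
#' (`view = "ligand"`), pocket composition (`view = "pocket"`), or their
#' concatenation (`view = "both"`), one row per complex.
#'
#' @param records Records tibble (list-columns `protein`, `ligand`).
#' @param view One of `"ligand"`, `"pocket"`, `"both"`.
#' @param schema `descriptor_schema`; required for ligand/both views.
#' @param threshold_A Pocket cutoff in Angstrom.
#' @return Numeric matrix with rownames = `complex_id`.
#' @export
feature_matrix <- function(records, view = c("ligand", "pocket", "both"),
                           schema = NULL, threshold_A = 15) {
  view <- match.arg(view)
  if (view %in% c("ligand", "both") && !inherits(schema, "descriptor_schema")) {
    abort("a descriptor_schema is required for ligand/both views")
  }
  rows <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    lv <- if (view %in% c("ligand", "both")) {
      ligand_descriptors(records$ligand[[i]], schema)
    }
    pv <- if (view %in% c("pocket", "both")) {
      pocket_residue_counts(records$protein[[i]], records$ligand[[i]],
                            threshold_A = threshold_A)
    }
    rows[[i]] <- switch(view,
      ligand = lv,
      pocket = setNames(as.numeric(pv), paste0("pocket_", names(pv))),
      both = concat_features(lv, pv)
    )
  }
  m <- do.call(rbind, rows)
  rownames(m) <- records$complex_id
  m
}

#' Write a feature matrix as CSV
#'
#' @param m Matrix from [feature_matrix()].
#' @param path Output CSV path; header = feature names, first column
#'   `complex_id`.
#' @export
write_feature_matrix <- function(m, path) {
  df <- as_tibble(m)
  df <- dplyr::bind_cols(tibble(complex_id = rownames(m)), df)
  readr::write_csv(df, path)
  invisible(path)
}
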