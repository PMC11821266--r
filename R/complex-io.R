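#' Construct a ligand molecule
#'
#' Internal container for one small molecule: an atom table (element + 3D
#' coordinates in Angstrom), a bond table, the molecule's InChI-Key, a
#' name/code, and the V2000 molblock text it was read from (kept so poses can
#' be re-serialized without touching connectivity).
#'
#' @param atoms Tibble with columns `element`, `x`, `y`, `z`.
#' @param bonds Tibble with columns `from`, `to`, `order` (atom indices 1-based).
#' @param inchikey 27-character InChI-Key.
#' @param name Molecule name or ligand code.
#' @param molblock Character vector: the V2000 molblock lines (through `M  END`).
#' @return An object of class `ligand_molecule`.
#' @keywords internal
ligand_molecule <- function(atoms, bonds, inchikey, name = "", molblock = NULL) {
  atoms <- as_tibble(atoms)
  bonds <- as_tibble(bonds)
  if (nrow(atoms) < 1) abort("ligand must have at least one atom")
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    abort("ligand coordinates must be finite")
  }
  if (nrow(bonds) > 0) {
    idx <- c(bonds$from, bonds$to)
    if (any(idx < 1 | idx > nrow(atoms))) abort("bond atom indices out of range")
  }
  if (!is_inchikey(inchikey)) {
    abort(paste0("invalid InChI-Key: '", inchikey, "'"))
  }
  structure(
    list(atoms = atoms, bonds = bonds, inchikey = inchikey,
         name = name, molblock = molblock),
    class = "ligand_molecule"
  )
}

is_inchikey <- function(x) {
  is.character(x) && length(x) == 1 && !is.na(x) &&
    grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", x)
}

#' @export
print.ligand_molecule <- function(x, ...) {
  cat("<ligand_molecule> ", x$name, "\n", sep = "")
  cat("  atoms: ", nrow(x$atoms), "  bonds: ", nrow(x$bonds),
      "  InChI-Key: ", x$inchikey, "\n", sep = "")
  invisible(x)
}

#' Coordinates of a ligand as a matrix
#'
#' @param mol A `ligand_molecule`.
#' @return Numeric matrix with one row per atom and columns x, y, z.
#' @export
ligand_coords <- function(mol) {
  stopifnot(inherits(mol, "ligand_molecule"))
  as.matrix(mol$atoms[, c("x", "y", "z")])
}

#' Read a protein structure from a PDB file
#'
#' Parses a PDB file into an atom tibble. By default waters (HOH/WAT/DOD)
#' and all HETATM records are dropped, keeping only polymer-chain ATOM
#' records; alternate location A is kept and insertion codes are retained
#' as part of residue identity.
#'
#' @param path Path to a PDB file.
#' @param strip_nonchain Drop waters and HETATM records (default `TRUE`).
#' @return A tibble of class `protein_structure` with columns `element`,
#'   `resname`, `resno`, `chain`, `ins`, `x`, `y`, `z`.
#' @export
read_protein <- function(path, strip_nonchain = TRUE) {
  if (!file.exists(path)) abort(paste0("cannot read PDB file: ", path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) abort(paste0("PDB parse failure for ", path, ": ",
                                     conditionMessage(e)))
  )
  at <- pdb$atom
  if (strip_nonchain) {
    at <- at[at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT", "DOD")), ,
             drop = FALSE]
  }
  # keep blank altloc or altloc A
  if ("alt" %in% names(at)) {
    at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  }
  if (nrow(at) == 0) abort(paste0("no chain atoms left after filtering: ", path))
  elem <- at$elesy
  bad <- is.na(elem) | elem == ""
  elem[bad] <- substr(gsub("[^A-Za-z].*", "", at$elety[bad]), 1, 1)
  out <- tibble(
    element = toupper(trimws(elem)),
    resname = trimws(at$resid),
    resno = as.integer(at$resno),
    chain = ifelse(is.na(at$chain), "A", at$chain),
    ins = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z
  )
  if (!all(is.finite(c(out$x, out$y, out$z)))) {
    abort(paste0("non-finite coordinates in ", path))
  }
  new_protein_structure(out, source_path = path)
}

new_protein_structure <- function(df, source_path = NA_character_) {
  out <- as_tibble(df)
  class(out) <- c("protein_structure", class(out))
  attr(out, "source_path") <- source_path
  out
}

#' Protein atom coordinates as a matrix
#'
#' @param protein A `protein_structure` tibble.
#' @return Numeric matrix with columns x, y, z.
#' @export
protein_coords <- function(protein) {
  as.matrix(protein[, c("x", "y", "z")])
}

#' Read a ligand from an SDF or MOL2 file
#'
#' MOL2 input is converted to SDF via OpenBabel on read; the InChI-Key is
#' computed and stored so identical molecules can be matched regardless of
#' file format, atom order or conformation. Hydrogens are kept if present.
#'
#' @param path Path to an SDF (or MOL) or MOL2 file.
#' @param name Optional molecule name; defaults to the molblock title or
#'   the file stem.
#' @return A `ligand_molecule`.
#' @export
read_ligand <- function(path, name = NULL) {
  if (!file.exists(path)) abort(paste0("cannot read ligand file: ", path))
  ext <- tolower(tools::file_ext(path))
  txt <- readLines(path, warn = FALSE)
  if (ext == "mol2") {
    sdf_txt <- tryCatch(
      ChemmineOB::convertFormat("MOL2", "SDF", paste0(paste(txt, collapse = "\n"), "\n")),
      error = function(e) abort(paste0("MOL2 parse failure for ", path))
    )
    txt <- strsplit(sdf_txt, "\n", fixed = TRUE)[[1]]
  }
  mol_from_molblock(txt, name = name, origin = path)
}

# Parse the first V2000 record out of SDF text lines.
mol_from_molblock <- function(lines, name = NULL, origin = "<text>") {
  mend <- which(trimws(lines) == "M  END")
  if (length(mend) == 0 || length(lines) < 5) {
    abort(paste0("ligand parse failure (no valid molblock) in ", origin))
  }
  block <- lines[seq_len(mend[1])]
  counts <- block[4]
  natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(natoms) || natoms < 1 || is.na(nbonds) || nbonds < 0 ||
      length(block) < 4 + natoms + nbonds) {
    abort(paste0("ligand parse failure (malformed counts line) in ", origin))
  }
  atom_lines <- block[4 + seq_len(natoms)]
  x <- suppressWarnings(as.numeric(substr(atom_lines, 1, 10)))
  y <- suppressWarnings(as.numeric(substr(atom_lines, 11, 20)))
  z <- suppressWarnings(as.numeric(substr(atom_lines, 21, 30)))
  element <- trimws(substr(atom_lines, 32, 34))
  if (any(!is.finite(c(x, y, z))) || any(element == "")) {
    abort(paste0("ligand parse failure (atom block) in ", origin))
  }
  if (nbonds > 0) {
    bond_lines <- block[4 + natoms + seq_len(nbonds)]
    bonds <- tibble(
      from = suppressWarnings(as.integer(substr(bond_lines, 1, 3))),
      to = suppressWarnings(as.integer(substr(bond_lines, 4, 6))),
      order = suppressWarnings(as.integer(substr(bond_lines, 7, 9)))
    )
    if (any(is.na(bonds$from)) || any(is.na(bonds$to))) {
      abort(paste0("ligand parse failure (bond block) in ", origin))
    }
  } else {
    bonds <- tibble(from = integer(), to = integer(), order = integer())
  }
  key <- inchikey_from_molblock(block, origin)
  title <- trimws(block[1])
  if (is.null(name)) {
    name <- if (nzchar(title)) title else sub("\\.[^.]*$", "", basename(origin))
  }
  ligand_molecule(
    atoms = tibble(element = element, x = x, y = y, z = z),
    bonds = bonds, inchikey = key, name = name, molblock = block
  )
}

inchikey_from_molblock <- function(block, origin = "<molblock>") {
  sdf_txt <- paste0(paste(c(block, "$$$$"), collapse = "\n"), "\n")
  key <- tryCatch(
    trimws(ChemmineOB::convertFormat("SDF", "INCHIKEY", sdf_txt)),
    error = function(e) ""
  )
  key <- sub("\n.*$", "", key)
  if (!is_inchikey(key)) {
    abort(paste0("InChI-Key computation failed for ", origin))
  }
  key
}

#' Convert a binding affinity to pK
#'
#' pK = -log10(affinity in molar). Ki, Kd and IC50 are deliberately put on
#' one common scale: the measurement type does not enter the conversion.
#'
#' @param value Positive affinity value(s).
#' @param unit Unit symbol(s): one of `"M"`, `"mM"`, `"uM"`, `"nM"`, `"pM"`, `"fM"`.
#' @return Numeric pK value(s).
#' @examples
#' pk_from_affinity(1, "uM")   # 6
#' pk_from_affinity(49, "uM")  # 4.3098
#' @export
pk_from_affinity <- function(value, unit) {
  scale <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12, fM = 1e-15)
  if (any(!unit %in% names(scale))) {
    abort(paste0("unknown affinity unit: ",
                 paste(setdiff(unique(unit), names(scale)), collapse = ", ")))
  }
  if (any(!is.finite(value) | value <= 0)) {
    abort("affinity values must be positive and finite")
  }
  -log10(value * unname(scale[unit]))
}

# "Kd=49uM" / "Ki~3nM" / "IC50>=1mM" -> list(type, qualifier, value, unit)
parse_measurement <- function(s) {
  m <- regexec("^(Ki|Kd|IC50)(>=|<=|=|~|>|<)([0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?)(fM|pM|nM|uM|mM|M)$",
               s, ignore.case = TRUE)
  g <- regmatches(s, m)[[1]]
  if (length(g) != 5) return(NULL)
  type <- c(ki = "Ki", kd = "Kd", ic50 = "IC50")[tolower(g[2])]
  unit <- g[5]
  # unit prefix is case-sensitive except the trailing M
  unit <- paste0(substr(unit, 1, nchar(unit) - 1), "M")
  if (nchar(unit) == 1) unit <- "M"
  val <- as.numeric(g[4])
  if (!is.finite(val) || val <= 0) return(NULL)
  list(measurement_type = unname(type), qualifier = g[3], value = val, unit = unit)
}

#' Parse an affinity index file
#'
#' Reads a PDBBind-dialect whitespace-delimited index: one complex per line
#' with columns `id  resolution  year  -logK  measurement`, an optional
#' `// comment` trailer (a ligand code in parentheses is picked up when
#' present), and `#` comment lines. Malformed lines are skipped with a
#' warning and reported in the `skipped` attribute.
#'
#' @param path Path to the index file.
#' @return A tibble with columns `complex_id`, `year`, `measurement_type`,
#'   `qualifier`, `value`, `unit`, `pk`, `ligand_code`; skipped lines (if
#'   any) in `attr(, "skipped")`.
#' @export
parse_affinity_index <- function(path) {
  if (!file.exists(path)) abort(paste0("cannot read index file: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  rows <- list()
  skipped <- list()
  for (i in which(keep)) {
    line <- lines[i]
    parts <- strsplit(line, "//", fixed = TRUE)[[1]]
    data_part <- trimws(parts[1])
    comment <- if (length(parts) > 1) paste(parts[-1], collapse = "//") else ""
    fields <- strsplit(data_part, "\\s+")[[1]]
    if (length(fields) < 5) {
      skipped[[length(skipped) + 1]] <-
        tibble(line_no = i, line = line, reason = "too_few_fields")
      next
    }
    year <- suppressWarnings(as.integer(fields[3]))
    meas <- parse_measurement(fields[5])
    if (is.null(meas)) {
      skipped[[length(skipped) + 1]] <-
        tibble(line_no = i, line = line, reason = "bad_measurement")
      next
    }
    code <- NA_character_
    cm <- regmatches(comment, regexec("\\(([^)]+)\\)", comment))[[1]]
    if (length(cm) == 2) code <- trimws(cm[2])
    rows[[length(rows) + 1]] <- tibble(
      complex_id = fields[1],
      year = year,
      measurement_type = meas$measurement_type,
      qualifier = meas$qualifier,
      value = meas$value,
      unit = meas$unit,
      pk = pk_from_affinity(meas$value, meas$unit),
      ligand_code = code
    )
  }
  out <- if (length(rows)) bind_rows(rows) else
    tibble(complex_id = character(), year = integer(),
           measurement_type = character(), qualifier = character(),
           value = numeric(), unit = character(), pk = numeric(),
           ligand_code = character())
  skipped <- if (length(skipped)) bind_rows(skipped) else
    tibble(line_no = integer(), line = character(), reason = character())
  if (nrow(skipped) > 0) {
    warn(paste0("parse_affinity_index: skipped ", nrow(skipped),
                " malformed line(s)"))
  }
  attr(out, "skipped") <- skipped
  out
}

#' Load a complex dataset from an index file and a structure directory
#'
#' Assembles one record per complex: affinity label from the index joined
#' to the protein PDB and ligand SDF found under
#' `structure_dir/<id>/<id>_protein.pdb` and `<id>/<id>_ligand.sdf`
#' (patterns configurable; `{id}` is substituted). Complexes that cannot
#' be processed are excluded and reported, never silently dropped.
#'
#' @param index_path Path to the affinity index file.
#' @param structure_dir Directory holding per-complex subdirectories.
#' @param protein_pattern,ligand_pattern Relative path patterns with `{id}`.
#' @param exclude_qualified Drop records whose affinity qualifier is not
#'   `=` or `~` (default `FALSE`: qualified values treated as exact).
#' @return A tibble of complex records (one row per complex, list-columns
#'   `protein` and `ligand`) with the exclusion report in
#'   `attr(, "exclusions")`; see [exclusion_report()].
#' @export
load_dataset <- function(index_path, structure_dir,
                         protein_pattern = "{id}/{id}_protein.pdb",
                         ligand_pattern = "{id}/{id}_ligand.sdf",
                         exclude_qualified = FALSE) {
  index <- parse_affinity_index(index_path)
  skipped <- attr(index, "skipped")
  excl <- list()
  for (k in seq_len(nrow(skipped))) {
    id_guess <- strsplit(trimws(skipped$line[k]), "\\s+")[[1]][1]
    excl[[length(excl) + 1]] <- tibble(complex_id = id_guess,
                                       reason = "label_parse")
  }
  if (exclude_qualified) {
    qual <- !(index$qualifier %in% c("=", "~"))
    for (id in index$complex_id[qual]) {
      excl[[length(excl) + 1]] <- tibble(complex_id = id,
                                         reason = "qualified_label")
    }
    index <- index[!qual, , drop = FALSE]
  }
  rows <- list()
  for (k in seq_len(nrow(index))) {
    id <- index$complex_id[k]
    ppath <- file.path(structure_dir, gsub("{id}", id, protein_pattern, fixed = TRUE))
    lpath <- file.path(structure_dir, gsub("{id}", id, ligand_pattern, fixed = TRUE))
    if (!file.exists(ppath) || !file.exists(lpath)) {
      excl[[length(excl) + 1]] <- tibble(complex_id = id, reason = "missing_file")
      next
    }
    prot <- tryCatch(read_protein(ppath), error = function(e) NULL)
    if (is.null(prot)) {
      excl[[length(excl) + 1]] <- tibble(complex_id = id, reason = "protein_parse")
      next
    }
    lig <- tryCatch(read_ligand(lpath), error = function(e) NULL)
    if (is.null(lig)) {
      excl[[length(excl) + 1]] <- tibble(complex_id = id, reason = "ligand_parse")
      next
    }
    row <- index[k, , drop = FALSE]
    row$protein <- list(prot)
    row$ligand <- list(lig)
    rows[[length(rows) + 1]] <- row
  }
  exclusions <- if (length(excl)) bind_rows(excl) else
    tibble(complex_id = character(), reason = character())
  if (length(rows) == 0) {
    abort("load_dataset: no complex could be loaded (empty dataset)")
  }
  records <- bind_rows(rows)
  if (anyDuplicated(records$complex_id)) {
    abort("load_dataset: duplicate complex IDs in index")
  }
  attr(records, "exclusions") <- exclusions
  records
}

#' Exclusion report of a loaded dataset
#'
#' @param records A records tibble from [load_dataset()].
#' @return Tibble with columns `complex_id` and `reason`.
#' @export
exclusion_report <- function(records) {
  ex <- attr(records, "exclusions")
  if (is.null(ex)) tibble(complex_id = character(), reason = character()) else ex
}

#' Write an exclusion report as CSV
#'
#' @param records Records tibble from [load_dataset()].
#' @param path Output CSV path.
#' @export
write_exclusion_report <- function(records, path) {
  readr::write_csv(exclusion_report(records), path)
  invisible(path)
}

#' Write a ligand pose to SDF
#'
#' Serializes the molecule with replacement coordinates, leaving the
#' connectivity block untouched, so the written file re-reads to the same
#' molecule with the new pose (coordinates round-trip at SDF precision,
#' 1e-4 Angstrom).
#'
#' @param mol A `ligand_molecule`.
#' @param coords Numeric matrix (n_atoms x 3) of replacement coordinates;
#'   defaults to the molecule's own coordinates.
#' @param path Output SDF path.
#' @param title Optional molblock title line.
#' @export
write_ligand_pose <- function(mol, coords = NULL, path, title = NULL) {
  stopifnot(inherits(mol, "ligand_molecule"))
  if (is.null(coords)) coords <- ligand_coords(mol)
  coords <- as.matrix(coords)
  n <- nrow(mol$atoms)
  if (!is.numeric(coords) || nrow(coords) != n || ncol(coords) != 3) {
    abort(paste0("coords must be a ", n, " x 3 numeric matrix"))
  }
  if (any(!is.finite(coords))) abort("coords must be finite")
  block <- mol$molblock
  if (is.null(block)) block <- molblock_from_tables(mol)
  if (!is.null(title)) block[1] <- title
  atom_idx <- 4 + seq_len(n)
  tails <- substring(block[atom_idx], 31)
  block[atom_idx] <- paste0(
    sprintf("%10.4f%10.4f%10.4f", coords[, 1], coords[, 2], coords[, 3]),
    tails
  )
  writeLines(c(block, "$$$$"), path)
  invisible(path)
}

# Rebuild a minimal V2000 molblock from the atom/bond tables (used only for
# molecules constructed in code without a source molblock).
molblock_from_tables <- function(mol) {
  n <- nrow(mol$atoms)
  b <- nrow(mol$bonds)
  header <- c(mol$name, " sfbias", "",
              sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, b))
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   mol$atoms$x, mol$atoms$y, mol$atoms$z, mol$atoms$element)
  bonds <- if (b > 0) {
    sprintf("%3d%3d%3d  0  0  0  0", mol$bonds$from, mol$bonds$to, mol$bonds$order)
  } else character()
  c(header, atoms, bonds, "M  END")
}
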