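# Shared fixtures, all generated in code.

# A hand-written ethanol SDF (explicit 3D heavy atoms, no hydrogens).
ethanol_sdf_lines <- function() {
  c("ethanol",
    "  fixture",
    "",
    "  3  2  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.5000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.0000    1.3000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0  0  0  0",
    "  2  3  1  0  0  0  0",
    "M  END",
    "$$$$")
}

write_ethanol_sdf <- function(path = tempfile(fileext = ".sdf")) {
  writeLines(ethanol_sdf_lines(), path)
  path
}

# Minimal PDB text: one line per atom.
pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          element = substr(name, 1, 1), record = "ATOM") {
  sprintf("%-6s%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          record, serial, name, resname, chain, resno, x, y, z, element)
}

write_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# Stub records for split logic that only needs ids / keys / labels.
stub_records <- function(ids, keys, pks, years = NULL, codes = NULL) {
  tibble::tibble(
    complex_id = ids,
    pk = pks,
    year = if (is.null(years)) rep(2015L, length(ids)) else years,
    ligand_code = if (is.null(codes)) rep("LIG", length(ids)) else codes,
    ligand = lapply(keys, function(k) {
      structure(list(inchikey = k), class = "ligand_molecule")
    })
  )
}

# One small labeled dataset reused across test files (built on first use).
shared_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_dataset(
        generator_config(n_complexes = 120, noise_sd = 0.3, seed = 42))
    }
    cache
  }
})

brute_force_pocket_counts <- function(protein, mol, threshold) {
  counts <- stats::setNames(integer(21), pocket_residue_order())
  lig <- ligand_coords(mol)[toupper(mol$atoms$element) != "H", , drop = FALSE]
  prot <- protein[toupper(protein$element) != "H", , drop = FALSE]
  for (key in unique(paste(prot$chain, prot$resno, prot$ins, sep = "|"))) {
    res <- prot[paste(prot$chain, prot$resno, prot$ins, sep = "|") == key, ]
    hit <- FALSE
    for (i in seq_len(nrow(res))) {
      for (j in seq_len(nrow(lig))) {
        d <- sqrt(sum((c(res$x[i], res$y[i], res$z[i]) - lig[j, ])^2))
        if (d <= threshold) { hit <- TRUE; break }
      }
      if (hit) break
    }
    if (hit) {
      type <- res$resname[1]
      if (!type %in% pocket_residue_order()) type <- "UNK"
      counts[type] <- counts[type] + 1L
    }
  }
  counts
}
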