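#' Read a macromolecular structure (PDB or mmCIF)
#'
#' Parses a structure file down to the protein heavy atoms the analysis
#' needs: first model only, waters/ligands excluded, highest-occupancy
#' alternate location kept, chains in file order. Nonstandard residues with
#' a known parent amino acid (MSE, SEC, ...) are retained under their own
#' name and mapped to the parent's hydrophobicity at lookup time.
#'
#' @param path Path to a PDB or mmCIF file.
#' @param format `"auto"` (by extension), `"pdb"`, or `"mmcif"`.
#' @return A `fod_structure`: list with `id`, `source_format`, and `atoms`
#'   (data.frame: chain, resno, insert, resid, elety, x, y, z, o).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "pdb")
      bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
    else bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("failed to parse ", path, " as ", format, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  atoms <- parsed$atom
  keep <- atoms$resid %in% .standard_aa |
    atoms$resid %in% names(.nonstandard_parent)
  atoms <- atoms[keep, , drop = FALSE]
  # drop hydrogens / deuteriums
  if ("elesy" %in% names(atoms) && !all(is.na(atoms$elesy))) {
    atoms <- atoms[!(toupper(trimws(atoms$elesy)) %in% c("H", "D")), , drop = FALSE]
  } else {
    atoms <- atoms[!grepl("^[0-9]*[HD]", trimws(atoms$elety)), , drop = FALSE]
  }
  if (nrow(atoms) == 0) stop("no protein residues in ", path)
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$o[is.na(atoms$o)] <- 1
  # alternate locations: keep the highest-occupancy conformer per atom site
  site <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety)
  if (anyDuplicated(site)) {
    ord <- order(match(site, unique(site)), -atoms$o)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$insert,
                                     atoms$elety)), , drop = FALSE]
  }
  out <- atoms[, c("chain", "resno", "insert", "resid", "elety",
                   "x", "y", "z", "o")]
  rownames(out) <- NULL
  if (!all(is.finite(as.matrix(out[, c("x", "y", "z")]))))
    stop("non-finite coordinates in ", path)
  structure(
    list(id = tools::file_path_sans_ext(basename(path)),
         source_format = format, atoms = out),
    class = "fod_structure"
  )
}

#' @export
print.fod_structure <- function(x, ...) {
  ea <- unique(x$atoms[, c("chain", "resno", "insert")])
  cat("fod_structure", x$id, "(", x$source_format, "):",
      length(unique(x$atoms$chain)), "chain(s),",
      nrow(ea), "residues,", nrow(x$atoms), "heavy atoms\n")
  invisible(x)
}

#' Reduce a structure to effective atoms
#'
#' One point per residue at the centroid of its heavy atoms (optionally side
#' chain only), carrying the residue's normalized intrinsic hydrophobicity.
#'
#' @param structure A `fod_structure`.
#' @param scale A `fod_scale` (default Kyte-Doolittle normalized to \[0,1\]).
#' @param atoms `"all"` (backbone + side chain, default) or `"sidechain"`
#'   (side-chain heavy atoms; glycine falls back to all atoms).
#' @return data.frame with one row per residue, in file order: chain, resno,
#'   insert, resid, label, x, y, z, h.
#' @export
effective_atoms <- function(structure, scale = fod_scale(),
                            atoms = c("all", "sidechain")) {
  stopifnot(inherits(structure, "fod_structure"))
  atoms <- match.arg(atoms)
  at <- structure$atoms
  if (atoms == "sidechain") {
    bb <- at$elety %in% c("N", "CA", "C", "O", "OXT")
    key_all <- paste(at$chain, at$resno, at$insert)
    has_sc <- key_all %in% key_all[!bb]
    at <- at[!bb | !has_sc, , drop = FALSE]  # GLY keeps backbone
  }
  key <- paste(at$chain, at$resno, at$insert)
  idx <- match(key, unique(key))
  res <- at[!duplicated(key), c("chain", "resno", "insert", "resid")]
  out <- data.frame(
    res,
    label = paste0(res$chain, ":", res$resno,
                   ifelse(res$insert == "", "", res$insert)),
    x = tapply(at$x, idx, mean),
    y = tapply(at$y, idx, mean),
    z = tapply(at$z, idx, mean),
    stringsAsFactors = FALSE
  )
  out$h <- scale_lookup(out$resid, scale)
  rownames(out) <- NULL
  out
}
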