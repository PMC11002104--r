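#' Built-in intrinsic hydrophobicity scales
#'
#' A hydrophobicity scale assigns every standard amino acid a raw intrinsic
#' hydrophobicity; before use all values are affinely rescaled to \[0, 1\]
#' (minimum to 0, maximum to 1) so that different scales are comparable and
#' the observed profile stays nonnegative.
#'
#' @format A `fod_scale` object is a list with elements `name` (character),
#'   `raw` (named numeric, 3-letter codes), and `values` (named numeric,
#'   normalized to \[0, 1\]).
#' @name hydrophobicity-scales
NULL

# Raw Kyte-Doolittle hydropathy values, 3-letter codes.
.kd_raw <- c(
  ALA =  1.8, ARG = -4.5, ASN = -3.5, ASP = -3.5, CYS =  2.5,
  GLN = -3.5, GLU = -3.5, GLY = -0.4, HIS = -3.2, ILE =  4.5,
  LEU =  3.8, LYS = -3.9, MET =  1.9, PHE =  2.8, PRO = -1.6,
  SER = -0.8, THR = -0.7, TRP = -0.9, TYR = -1.3, VAL =  4.2
)

# Fauchere-Pliska pi scale, used by the sensitivity sweep as an alternative.
.fp_raw <- c(
  ALA = 0.31, ARG = -1.01, ASN = -0.60, ASP = -0.77, CYS = 1.54,
  GLN = -0.22, GLU = -0.64, GLY = 0.00, HIS = 0.13, ILE = 1.80,
  LEU = 1.70, LYS = -0.99, MET = 1.23, PHE = 1.79, PRO = 0.72,
  SER = -0.04, THR = 0.26, TRP = 2.25, TYR = 0.96, VAL = 1.22
)

# Common nonstandard residues mapped to their parent standard residue.
.nonstandard_parent <- c(
  MSE = "MET", SEC = "CYS", PYL = "LYS", HYP = "PRO", SEP = "SER",
  TPO = "THR", PTR = "TYR", CSO = "CYS", MLY = "LYS", KCX = "LYS"
)

.standard_aa <- names(.kd_raw)

#' Construct a hydrophobicity scale
#'
#' @param name Scale name. `"kyte_doolittle"` (default) and
#'   `"fauchere_pliska"` are built in; alternatively supply `raw`.
#' @param raw Optional named numeric vector (3-letter residue codes, all 20
#'   standard residues) of raw scale values; overrides `name`'s built-in.
#' @return A `fod_scale` object: raw values plus values rescaled to \[0, 1\].
#' @examples
#' sc <- fod_scale()
#' range(sc$values)   # 0 1
#' sc$values[["GLY"]]
#' @export
fod_scale <- function(name = "kyte_doolittle", raw = NULL) {
  if (is.null(raw)) {
    raw <- switch(name,
      kyte_doolittle = .kd_raw,
      fauchere_pliska = .fp_raw,
      stop("unknown built-in scale: ", name)
    )
  }
  raw <- raw[order(names(raw))]
  missing <- setdiff(.standard_aa, names(raw))
  if (length(missing) > 0)
    stop("scale does not cover standard residues: ", paste(missing, collapse = ", "))
  if (!all(is.finite(raw))) stop("scale values must be finite")
  rng <- range(raw)
  if (rng[1] == rng[2]) stop("scale is constant; cannot normalize to [0,1]")
  values <- (raw - rng[1]) / (rng[2] - rng[1])
  structure(list(name = name, raw = raw, values = values), class = "fod_scale")
}

#' Read a hydrophobicity scale from a two-column text file
#'
#' Format: one residue per line, `<3-letter code> <raw value>`, `#` comments.
#'
#' @param path File path.
#' @param name Scale name to record; defaults to the file name.
#' @return A `fod_scale` object.
#' @export
read_scale <- function(path, name = tools::file_path_sans_ext(basename(path))) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "[[:space:]]+")
  bad <- vapply(fields, length, 1L) != 2L
  if (any(bad)) stop("malformed scale line: ", lines[bad][1])
  raw <- vapply(fields, function(f) as.numeric(f[2]), numeric(1))
  names(raw) <- toupper(vapply(fields, `[[`, character(1), 1L))
  if (anyNA(raw)) stop("non-numeric scale value in ", path)
  if (anyDuplicated(names(raw))) stop("duplicate residue in scale file")
  fod_scale(name = name, raw = raw)
}

#' Look up normalized hydrophobicities for residue names
#'
#' Nonstandard residues with a known parent (e.g. MSE -> MET) are mapped to
#' the parent's value; unknown names are an error.
#'
#' @param resid Character vector of 3-letter residue codes.
#' @param scale A `fod_scale`.
#' @return Numeric vector in \[0, 1\], same length as `resid`.
#' @export
scale_lookup <- function(resid, scale = fod_scale()) {
  stopifnot(inherits(scale, "fod_scale"))
  resid <- toupper(resid)
  mapped <- ifelse(resid %in% names(.nonstandard_parent),
                   .nonstandard_parent[resid], resid)
  unknown <- setdiff(unique(mapped), names(scale$values))
  if (length(unknown) > 0)
    stop("residue(s) absent from scale '", scale$name, "': ",
         paste(unknown, collapse = ", "))
  unname(scale$values[mapped])
}

#' @export
print.fod_scale <- function(x, ...) {
  cat("Hydrophobicity scale:", x$name, "\n")
  cat("  raw range: [", min(x$raw), ",", max(x$raw), "] -> normalized [0, 1]\n")
  invisible(x)
}
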