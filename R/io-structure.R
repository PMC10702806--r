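# Bondi-style van der Waals radii (A). United-atom style defaults; H kept
# for models that include it.
.vdw_table <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
                SE = 1.90, FE = 1.40, ZN = 1.39, MG = 1.73, CA = 2.31,
                "NA" = 2.27, K = 2.75)

#' Van der Waals radii from a Bondi-style element table
#'
#' @param element character vector of element symbols.
#' @param default_radius radius (Angstrom) assigned to elements not in the
#'   table, with one warning listing them.
#' @return numeric vector of radii (Angstrom).
#' @export
vdw_radius <- function(element, default_radius = 1.5) {
  key <- toupper(trimws(element))
  r <- .vdw_table[key]
  unknown <- is.na(r)
  if (any(unknown)) {
    warning("unknown element(s) ", paste(unique(key[unknown]), collapse = ", "),
            "; assigned default radius ", default_radius, " A")
    r[unknown] <- default_radius
  }
  unname(r)
}

bio3d_to_model <- function(pdb, default_radius = 1.5) {
  a <- pdb$atom
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem) | trimws(elem) == "")) {
    # fall back on the first letter of the atom name
    elem <- substr(trimws(a$elety), 1, 1)
  }
  elem[is.na(elem) | trimws(elem) == ""] <-
    substr(trimws(a$elety[is.na(elem) | trimws(elem) == ""]), 1, 1)
  atom_model(data.frame(element = trimws(elem), name = trimws(a$elety),
                        resid = a$resno, resname = trimws(a$resid),
                        chain = ifelse(is.na(a$chain), "A", a$chain),
                        x = a$x, y = a$y, z = a$z,
                        stringsAsFactors = FALSE),
             default_radius = default_radius)
}

#' Read a structural model (PDB or mmCIF)
#'
#' Parsing is delegated to \pkg{bio3d}; atoms receive van der Waals radii
#' from the Bondi-style table in \code{\link{vdw_radius}} (unknown elements
#' get \code{default_radius} with a warning).
#'
#' @param path path to a .pdb or .cif file.
#' @param default_radius fallback radius (Angstrom).
#' @return an \code{\link{atom_model}}.
#' @export
read_structure <- function(path, default_radius = 1.5) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- tryCatch(
    if (ext == "cif") bio3d::read.cif(path) else bio3d::read.pdb(path),
    error = function(e) stop("format error reading ", path, ": ",
                             conditionMessage(e)))
  bio3d_to_model(pdb, default_radius = default_radius)
}

#' Write an atom model as PDB
#'
#' @param model an \code{\link{atom_model}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "atom_model"))
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(model[, c("x", "y", "z")]))),
                   resno = model$resid, resid = model$resname,
                   chain = model$chain, elety = model$name,
                   elesy = model$element)
  invisible(path)
}

#' Select atoms in a model or trajectory annotation table
#'
#' @param atoms an \code{\link{atom_model}} or trajectory \code{atoms} table.
#' @param chain chain id(s), or NULL for any.
#' @param resid residue numbers (e.g. \code{75:95}), or NULL for any.
#' @param name atom name(s), or NULL for any.
#' @return integer vector of atom indices.
#' @export
select_atoms <- function(atoms, chain = NULL, resid = NULL, name = NULL) {
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(chain)) keep <- keep & atoms$chain %in% chain
  if (!is.null(resid)) keep <- keep & atoms$resid %in% resid
  if (!is.null(name)) keep <- keep & atoms$name %in% name
  which(keep)
}
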