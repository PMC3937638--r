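# Receptor handling.  The receptor is immutable: every operation in this
# package reads its coordinates and none modifies them.

.receptor_from_frame <- function(atoms, source = "memory") {
  atoms$elem <- ifelse(is.na(atoms$elem) | atoms$elem == "",
                       element_of(atoms$elety), atoms$elem)
  atoms$radius <- unname(VDW_RADII[atoms$elem])
  if (anyNA(atoms$radius))
    stop("no van der Waals radius for element(s): ",
         paste(unique(atoms$elem[is.na(atoms$radius)]), collapse = ", "))
  structure(list(atoms = atoms, source = source), class = "receptor")
}

#' Load a receptor from a PDB file
#'
#' Multi-model files (e.g. NMR ensembles) expose each MODEL; one member is
#' selected by \code{model_index}.
#'
#' @param path PDB file path.
#' @param model_index 1-based MODEL number to extract.
#' @param required optional list of atom requirements, each
#'   \code{list(resno =, elety =)}; loading fails with a message listing any
#'   missing atoms (used to verify that all restraint anchors are present).
#' @return an object of class \code{receptor} with an atom table
#'   (elety, resid, resno, coordinates, element, van der Waals radius).
#' @export
load_receptor <- function(path, model_index = 1, required = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  nmod <- nrow(pdb$xyz)
  if (model_index < 1 || model_index > nmod)
    stop("model_index ", model_index, " out of range; file has ",
         nmod, " model(s)")
  sel <- pdb$atom$type == "ATOM" | pdb$atom$type == "HETATM"
  xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
  atoms <- data.frame(elety = pdb$atom$elety[sel],
                      resid = pdb$atom$resid[sel],
                      resno = pdb$atom$resno[sel],
                      x = xyz[sel, 1], y = xyz[sel, 2], z = xyz[sel, 3],
                      elem = element_of(pdb$atom$elety[sel]),
                      stringsAsFactors = FALSE)
  # heavy atoms only
  atoms <- atoms[atoms$elem != "H", ]
  rec <- .receptor_from_frame(atoms, source = path)
  rec$n_models <- nmod
  if (!is.null(required)) {
    missing <- character(0)
    for (req in required) {
      for (a in req$elety) {
        hit <- rec$atoms$resno == req$resno & rec$atoms$elety == a
        if (!any(hit))
          missing <- c(missing, paste0(req$resno, ":", a))
      }
    }
    if (length(missing) > 0)
      stop("receptor lacks required restraint atoms: ",
           paste(missing, collapse = ", "))
  }
  rec
}

#' @export
print.receptor <- function(x, ...) {
  cat("<receptor> ", nrow(x$atoms), " heavy atoms, ",
      length(unique(x$atoms$resno)), " residues",
      if (!is.null(x$n_models)) paste0(" (file holds ", x$n_models, " models)"),
      "\n  source: ", x$source, "\n", sep = "")
  invisible(x)
}

receptor_xyz <- function(rec, resno = NULL, elety = NULL) {
  df <- rec$atoms
  if (!is.null(resno)) df <- df[df$resno %in% resno, ]
  if (!is.null(elety)) df <- df[df$elety %in% elety, ]
  as.matrix(df[, c("x", "y", "z")])
}

#' Checksum of receptor coordinates
#'
#' Used to verify the immutability invariant: the receptor checksum must be
#' identical before and after any modeling operation.
#' @param rec a \code{receptor}.
#' @return a single numeric digest of the coordinates.
#' @export
receptor_checksum <- function(rec) {
  xyz <- receptor_xyz(rec)
  sum(xyz * rep(c(1, exp(1), pi), each = nrow(xyz)))
}

#' Write a receptor to a PDB file
#' @param rec a \code{receptor}.
#' @param file output path.
#' @param chain chain identifier (default \code{"A"}).
#' @return the path, invisibly.
#' @export
write_receptor_pdb <- function(rec, file, chain = "A") {
  a <- rec$atoms
  bio3d::write.pdb(pdb = NULL, file = file,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, elety = a$elety,
                   chain = rep(chain, nrow(a)), o = rep(1, nrow(a)),
                   b = rep(0, nrow(a)))
  invisible(file)
}
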