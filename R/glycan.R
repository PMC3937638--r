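# Oligosaccharide sequence parsing and torsion-parameterized 3-D building.
#
# Dihedral convention (heavy-atom): for the linkage joining residue i to
# residue i+1 through the glycosidic oxygen Og,
#   phi = O5(i) - C1(i) - Og - Cx(i+1)
#   psi = C1(i) - Og - Cx(i+1) - C(x+1)(i+1)
# with x = 3 for beta-1,3 linkages (out of a GlcUA) and x = 4 for beta-1,4
# linkages (out of a HexNAc).  The convention string is carried on every
# conformer and torsion map so mixed conventions fail loudly.

TORSION_CONVENTION <- "phi=O5-C1-Og-Cx psi=C1-Og-Cx-Cx+1 heavy-atom"

# glycosidic attachment atoms on the child residue, per linkage type
.link_atoms <- function(linkage) {
  switch(linkage,
         b13 = list(Ox = "O3", Cx = "C3", Cnext = "C4"),
         b14 = list(Ox = "O4", Cx = "C4", Cnext = "C5"),
         stop("unknown linkage type: ", linkage))
}

# bond angle at the glycosidic oxygen (C1-Og-Cx), degrees
GLYCOSIDIC_ANGLE <- 116.5

#' Parse an oligosaccharide specifier
#'
#' Supported forms: \code{HA{n}^{AN|NA|AA|NN}} for HA oligomers (A = GlcUA,
#' N = GlcNAc, first letter = non-reducing terminus, second = reducing
#' terminus), \code{C{n}^AN} for chondroitin oligomers (GalNAc at every
#' HexNAc position), and the hybrids \code{HA4C4} (chondroitin disaccharides
#' in the non-reducing half) and \code{C4HA4} (chondroitin in the reducing
#' half).  The caret is optional.
#'
#' Note on hybrid naming: \code{HA4C4} carries its chondroitin (GalNAc)
#' sugars at the NON-reducing end and its HA tetrasaccharide at the reducing
#' end; \code{C4HA4} is the reverse.  This follows the source material's
#' definition of the reagents and deliberately overrides any left-to-right
#' reading of the name.
#'
#' @param spec specifier string, e.g. \code{"HA8^AN"}.
#' @return an object of class \code{glycan_sequence} with fields
#'   \code{residues} (character vector, index 1 = non-reducing terminus) and
#'   \code{linkages} (\code{"b13"}/\code{"b14"}, linkage i joins residue i to
#'   residue i+1).
#' @export
parse_glycan <- function(spec) {
  spec0 <- gsub("\\s", "", spec)
  up <- toupper(spec0)
  residues <- NULL
  if (up == "HA4C4") {
    residues <- c("GlcUA", "GalNAc", "GlcUA", "GalNAc",
                  "GlcUA", "GlcNAc", "GlcUA", "GlcNAc")
  } else if (up == "C4HA4") {
    residues <- c("GlcUA", "GlcNAc", "GlcUA", "GlcNAc",
                  "GlcUA", "GalNAc", "GlcUA", "GalNAc")
  } else if (grepl("^(HA|C)([0-9]+)\\^?(AN|NA|AA|NN)?$", up)) {
    m <- regmatches(up, regexec("^(HA|C)([0-9]+)\\^?(AN|NA|AA|NN)?$", up))[[1]]
    family <- m[2]
    n <- as.integer(m[3])
    term <- m[4]
    if (term == "") term <- "AN"
    if (n < 2) stop("oligosaccharide must have at least 2 residues: ", spec)
    same <- substr(term, 1, 1) == substr(term, 2, 2)
    if ((n %% 2 == 0) == same)
      stop("parity-impossible terminal combination '", term,
           "' for length ", n, " in spec '", spec, "'")
    hexnac <- if (family == "C") "GalNAc" else "GlcNAc"
    first_uronic <- substr(term, 1, 1) == "A"
    residues <- vapply(seq_len(n), function(i) {
      uronic <- if (first_uronic) i %% 2 == 1 else i %% 2 == 0
      if (uronic) "GlcUA" else hexnac
    }, character(1))
  } else {
    stop("unparseable oligosaccharide specifier: '", spec, "'")
  }
  linkages <- vapply(residues[-length(residues)],
                     function(r) if (is_uronic(r)) "b13" else "b14",
                     character(1), USE.NAMES = FALSE)
  out <- structure(list(spec = spec0, residues = residues, linkages = linkages),
                   class = "glycan_sequence")
  validate_glycan_sequence(out)
  out
}

validate_glycan_sequence <- function(seq) {
  res <- seq$residues
  n <- length(res)
  cls <- ifelse(vapply(res, is_uronic, logical(1)), "U", "N")
  if (n > 1 && any(cls[-1] == cls[-n]))
    stop("residues must strictly alternate uronic acid / HexNAc")
  if (length(seq$linkages) != n - 1)
    stop("linkage count must equal residue count - 1")
  ok <- vapply(seq_len(n - 1), function(i) {
    if (is_uronic(res[i])) seq$linkages[i] == "b13" else seq$linkages[i] == "b14"
  }, logical(1))
  if (!all(ok)) stop("linkage types inconsistent with residue types")
  invisible(seq)
}

#' @export
print.glycan_sequence <- function(x, ...) {
  cat("<glycan_sequence> ", x$spec, ": ", length(x$residues), " residues\n",
      sep = "")
  cat("  ", paste(x$residues, collapse = "-"), "\n", sep = "")
  invisible(x)
}

#' Number of residues in a glycan sequence
#' @param seq a \code{glycan_sequence}.
#' @return integer residue count.
#' @export
n_residues <- function(seq) length(seq$residues)

.as_torsion_matrix <- function(torsions, nlink) {
  if (is.list(torsions)) torsions <- do.call(rbind, torsions)
  torsions <- matrix(as.numeric(torsions), ncol = 2,
                     dimnames = list(NULL, c("phi", "psi")))
  if (nrow(torsions) != nlink)
    stop("torsion list length (", nrow(torsions),
         ") does not match linkage count (", nlink, ")")
  torsions
}

#' Build a 3-D conformer from a sequence and glycosidic torsions
#'
#' Residues are rigid 4C1 templates; the only degrees of freedom are the
#' phi/psi torsions of each glycosidic linkage, realized exactly under the
#' package's dihedral convention.  Residue 1 (the non-reducing terminus) is
#' placed in the template frame; each subsequent residue is positioned by
#' natural-extension placement of its attachment atoms followed by an exact
#' rigid superposition of the template.
#'
#' @param seq a \code{glycan_sequence} (or specifier string).
#' @param torsions (n-1) x 2 matrix (or list of pairs) of phi/psi in degrees.
#' @return an object of class \code{glycan_conformer}: the sequence, an atom
#'   table (resno, residue, PDB residue name, atom, element, x/y/z, radius,
#'   glycosidic-oxygen flag) and the requested torsions.
#' @export
build_conformer <- function(seq, torsions) {
  if (is.character(seq)) seq <- parse_glycan(seq)
  n <- n_residues(seq)
  torsions <- .as_torsion_matrix(torsions, n - 1)

  placed <- vector("list", n)
  tpl1 <- mono_template(seq$residues[1])
  atoms1 <- tpl1$atoms
  placed[[1]] <- atoms1

  for (i in seq_len(n - 1)) {
    parent <- placed[[i]]
    link <- .link_atoms(seq$linkages[i])
    tpl <- mono_template(seq$residues[i + 1])
    pco <- function(df, a) as.numeric(df[df$atom == a, c("x", "y", "z")])

    o5p <- pco(parent, "O5")
    c1p <- pco(parent, "C1")
    og <- pco(parent, "O1")      # glycosidic O sits on the parent O1 bond

    txyz <- template_xyz(tpl, c(link$Ox, link$Cx, link$Cnext))
    r_ox_cx <- vnorm(txyz[2, ] - txyz[1, ])
    r_cx_cn <- vnorm(txyz[3, ] - txyz[2, ])
    ang_cx <- angle3(txyz[1, ], txyz[2, ], txyz[3, ])

    cxp <- place_atom(o5p, c1p, og, r_ox_cx, GLYCOSIDIC_ANGLE,
                      torsions[i, "phi"])
    cnp <- place_atom(c1p, og, cxp, r_cx_cn, ang_cx, torsions[i, "psi"])

    tr <- rigid_from_three(txyz, rbind(og, cxp, cnp))
    child <- tpl$atoms
    cxyz <- apply_rigid(as.matrix(child[, c("x", "y", "z")]), tr)
    child$x <- cxyz[, 1]; child$y <- cxyz[, 2]; child$z <- cxyz[, 3]

    # the parent anomeric oxygen becomes the child's glycosidic Ox
    placed[[i]] <- parent[parent$atom != "O1", ]
    child$glyco <- child$atom == link$Ox
    placed[[i + 1]] <- child
  }
  for (i in seq_len(n)) {
    if (is.null(placed[[i]]$glyco)) placed[[i]]$glyco <- FALSE
    placed[[i]]$resno <- i
    placed[[i]]$residue <- seq$residues[i]
    placed[[i]]$resname <- unname(PDB_RESNAME[seq$residues[i]])
  }
  atoms <- do.call(rbind, placed)
  rownames(atoms) <- NULL
  atoms <- atoms[, c("resno", "residue", "resname", "atom", "elem",
                     "x", "y", "z", "radius", "glyco")]
  structure(list(sequence = seq, atoms = atoms,
                 torsions = wrap_angle(torsions),
                 convention = TORSION_CONVENTION),
            class = "glycan_conformer")
}

#' @export
print.glycan_conformer <- function(x, ...) {
  cat("<glycan_conformer> ", x$sequence$spec, ": ",
      n_residues(x$sequence), " residues, ", nrow(x$atoms), " heavy atoms\n",
      sep = "")
  if (nrow(x$torsions) > 0) {
    cat("  torsions (phi/psi, deg):\n")
    for (i in seq_len(nrow(x$torsions)))
      cat(sprintf("    %d-%d (%s): %8.2f %8.2f\n", i, i + 1,
                  x$sequence$linkages[i], x$torsions[i, 1], x$torsions[i, 2]))
  }
  cat("  convention: ", x$convention, "\n", sep = "")
  invisible(x)
}

conformer_xyz <- function(conf, resno = NULL, atoms = NULL) {
  df <- conf$atoms
  if (!is.null(resno)) df <- df[df$resno %in% resno, ]
  if (!is.null(atoms)) df <- df[df$atom %in% atoms, ]
  as.matrix(df[, c("x", "y", "z")])
}

.conf_atom <- function(conf, resno, atom) {
  row <- conf$atoms[conf$atoms$resno == resno & conf$atoms$atom == atom, ]
  if (nrow(row) != 1)
    stop("missing atom ", atom, " in residue ", resno)
  as.numeric(row[1, c("x", "y", "z")])
}

#' Measure glycosidic torsions of a conformer
#'
#' Inverse of \code{\link{build_conformer}} under the same dihedral
#' convention; values are wrapped into \[-180, 180).
#'
#' @param conf a \code{glycan_conformer} (atom table may have been
#'   rigid-body transformed; torsions are re-derived from coordinates).
#' @return (n-1) x 2 matrix of phi/psi in degrees.
#' @export
measure_torsions <- function(conf) {
  seq <- conf$sequence
  n <- n_residues(seq)
  out <- matrix(NA_real_, n - 1, 2, dimnames = list(NULL, c("phi", "psi")))
  for (i in seq_len(n - 1)) {
    link <- .link_atoms(seq$linkages[i])
    coords <- tryCatch(list(
      o5 = .conf_atom(conf, i, "O5"),
      c1 = .conf_atom(conf, i, "C1"),
      og = .conf_atom(conf, i + 1, link$Ox),
      cx = .conf_atom(conf, i + 1, link$Cx),
      cn = .conf_atom(conf, i + 1, link$Cnext)),
      error = function(e) stop("linkage ", i, "-", i + 1, ": ",
                               conditionMessage(e), call. = FALSE))
    out[i, "phi"] <- dihedral(coords$o5, coords$c1, coords$og, coords$cx)
    out[i, "psi"] <- dihedral(coords$c1, coords$og, coords$cx, coords$cn)
  }
  out
}

#' Write a conformer to a PDB file
#'
#' Residues are written as BDP (GlcUA), NAG (GlcNAc) and A2G (GalNAc) on a
#' dedicated chain so ligand and receptor records never collide.
#'
#' @param conf a \code{glycan_conformer}.
#' @param file output path.
#' @param chain chain identifier (default \code{"S"}; receptors written by
#'   this package use chain \code{"A"}).
#' @return the file path, invisibly.
#' @export
write_conformer_pdb <- function(conf, file, chain = "S") {
  a <- conf$atoms
  bio3d::write.pdb(pdb = NULL, file = file,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resname, elety = a$atom,
                   chain = rep(chain, nrow(a)), o = rep(1, nrow(a)),
                   b = rep(0, nrow(a)))
  invisible(file)
}

#' Read a conformer written by \code{write_conformer_pdb}
#'
#' @param file PDB path.
#' @param seq the \code{glycan_sequence} the file encodes (or specifier).
#' @return a \code{glycan_conformer} with torsions re-measured from the
#'   coordinates.
#' @export
read_conformer_pdb <- function(file, seq) {
  if (is.character(seq)) seq <- parse_glycan(seq)
  pdb <- bio3d::read.pdb(file)
  at <- pdb$atom
  atoms <- data.frame(resno = at$resno, residue = seq$residues[at$resno],
                      resname = at$resid, atom = at$elety,
                      elem = element_of(at$elety),
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  atoms$radius <- unname(VDW_RADII[atoms$elem])
  atoms$glyco <- FALSE
  conf <- structure(list(sequence = seq, atoms = atoms,
                         torsions = NULL, convention = TORSION_CONVENTION),
                    class = "glycan_conformer")
  conf$torsions <- measure_torsions(conf)
  conf
}

# Apply a rigid-body transform (3x3 rotation + translation) to a conformer.
transform_conformer <- function(conf, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  xyz <- as.matrix(conf$atoms[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% t(rotation), 2, translation, "+")
  conf$atoms$x <- xyz[, 1]; conf$atoms$y <- xyz[, 2]; conf$atoms$z <- xyz[, 3]
  conf
}

# centroid of the six ring atoms of residue `resno`
ring_centroid <- function(conf, resno) {
  colMeans(conformer_xyz(conf, resno = resno, atoms = RING_ATOMS))
}

ring_normal <- function(conf, resno) {
  plane_normal(conformer_xyz(conf, resno = resno, atoms = RING_ATOMS))
}
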