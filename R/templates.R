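# Rigid 4C1 pyranose templates for the three residue types found in HA,
# chondroitin and their hybrids.  Templates are idealized chairs built from
# literature-standard bond lengths; only heavy atoms plus the N-acetyl methyl
# carbon are represented, since restraints, clashes and contacts all operate
# on heavy atoms.

.template_cache <- new.env(parent = emptyenv())

# van der Waals radii (Angstrom) by element
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20)

element_of <- function(atom) substr(gsub("[0-9']", "", atom), 1, 1)

RING_ATOMS <- c("C1", "C2", "C3", "C4", "C5", "O5")

# PDB residue names used when conformers are written out
PDB_RESNAME <- c(GlcUA = "BDP", GlcNAc = "NAG", GalNAc = "A2G")

is_uronic <- function(residue) residue == "GlcUA"
is_hexnac <- function(residue) residue %in% c("GlcNAc", "GalNAc")

# Ideal chair ring: atoms on a hexagon of radius 1.43 A with alternating
# out-of-plane displacement +-0.25 A, giving ring bonds of ~1.52 A.  The sign
# pattern puts C1 below and C4 above the mean plane (the 4C1 chair).
.ideal_ring <- function() {
  k <- 0:5
  r <- 1.43
  z <- 0.25 * ifelse(k %% 2 == 0, -1, 1)
  xyz <- cbind(r * cos(k * pi / 3), r * sin(k * pi / 3), z)
  rownames(xyz) <- RING_ATOMS
  xyz
}

# The two exocyclic bond directions (axial, equatorial) at ring atom `at`,
# each making a tetrahedral angle with both ring bonds.
.subst_dirs <- function(ring, at) {
  idx <- match(at, RING_ATOMS)
  nb <- RING_ATOMS[c((idx - 2) %% 6 + 1, idx %% 6 + 1)]
  p <- ring[at, ]
  b1 <- unit(ring[nb[1], ] - p)
  b2 <- unit(ring[nb[2], ] - p)
  bis <- -unit(b1 + b2)
  perp <- unit(cross3(b1, b2))
  if (perp[3] < 0) perp <- -perp
  # delta about the bisector giving a 109.47 deg angle to the ring bonds
  cd <- cos(deg2rad(109.47)) / sum(bis * b1)
  delta <- acos(max(-1, min(1, cd)))
  d1 <- unit(cos(delta) * bis + sin(delta) * perp)
  d2 <- unit(cos(delta) * bis - sin(delta) * perp)
  # axial = larger |z| component (ring mean plane is z = 0)
  if (abs(d1[3]) >= abs(d2[3])) list(axial = d1, equatorial = d2)
  else list(axial = d2, equatorial = d1)
}

.add_atom <- function(atoms, name, xyz) {
  rbind(atoms, data.frame(atom = name, elem = element_of(name),
                          x = xyz[1], y = xyz[2], z = xyz[3],
                          stringsAsFactors = FALSE))
}

.build_template <- function(name) {
  stopifnot(name %in% c("GlcUA", "GlcNAc", "GalNAc"))
  ring <- .ideal_ring()
  atoms <- data.frame(atom = rownames(ring), elem = element_of(rownames(ring)),
                      x = ring[, 1], y = ring[, 2], z = ring[, 3],
                      stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  dir1 <- .subst_dirs(ring, "C1")
  dir2 <- .subst_dirs(ring, "C2")
  dir3 <- .subst_dirs(ring, "C3")
  dir4 <- .subst_dirs(ring, "C4")
  dir5 <- .subst_dirs(ring, "C5")

  # anomeric oxygen, beta (equatorial)
  atoms <- .add_atom(atoms, "O1", ring["C1", ] + 1.41 * dir1$equatorial)
  atoms <- .add_atom(atoms, "O3", ring["C3", ] + 1.42 * dir3$equatorial)
  o4dir <- if (name == "GalNAc") dir4$axial else dir4$equatorial
  atoms <- .add_atom(atoms, "O4", ring["C4", ] + 1.42 * o4dir)
  c6 <- ring["C5", ] + 1.52 * dir5$equatorial
  atoms <- .add_atom(atoms, "C6", c6)

  if (name == "GlcUA") {
    atoms <- .add_atom(atoms, "O2", ring["C2", ] + 1.42 * dir2$equatorial)
    # carboxylate oxygens, symmetric about the C5-C6 axis
    atoms <- .add_atom(atoms, "O6A",
                       place_atom(ring["C4", ], ring["C5", ], c6, 1.25, 117, 90))
    atoms <- .add_atom(atoms, "O6B",
                       place_atom(ring["C4", ], ring["C5", ], c6, 1.25, 117, -90))
  } else {
    n2 <- ring["C2", ] + 1.45 * dir2$equatorial
    atoms <- .add_atom(atoms, "N2", n2)
    c7 <- place_atom(ring["C3", ], ring["C2", ], n2, 1.33, 122, 150)
    atoms <- .add_atom(atoms, "C7", c7)
    atoms <- .add_atom(atoms, "O7",
                       place_atom(ring["C2", ], n2, c7, 1.23, 121, 0))
    atoms <- .add_atom(atoms, "C8",
                       place_atom(ring["C2", ], n2, c7, 1.50, 116, 180))
    # exocyclic hydroxymethyl oxygen, fixed anti orientation
    atoms <- .add_atom(atoms, "O6",
                       place_atom(ring["C4", ], ring["C5", ], c6, 1.43, 111, 180))
  }
  atoms$radius <- unname(VDW_RADII[atoms$elem])
  structure(list(name = name, atoms = atoms, ring = RING_ATOMS,
                 carboxylate = if (name == "GlcUA") c("C6", "O6A", "O6B") else NULL,
                 methyl = if (name != "GlcUA") "C8" else NULL),
            class = "mono_template")
}

#' Monosaccharide template
#'
#' Returns the rigid, idealized 4C1-chair template for one of the three
#' residue types used in HA/chondroitin oligosaccharides. GlcNAc and GalNAc
#' differ only in the orientation of the C4 hydroxyl (equatorial vs axial).
#'
#' @param name one of \code{"GlcUA"}, \code{"GlcNAc"}, \code{"GalNAc"}.
#' @return an object of class \code{mono_template} with an \code{atoms} data
#'   frame (atom name, element, ideal coordinates in Angstrom, van der Waals
#'   radius) and marker fields for the ring cycle, carboxylate and N-acetyl
#'   methyl atoms.
#' @export
mono_template <- function(name) {
  if (!name %in% c("GlcUA", "GlcNAc", "GalNAc"))
    stop("unknown residue type: ", name)
  if (is.null(.template_cache[[name]]))
    .template_cache[[name]] <- .build_template(name)
  .template_cache[[name]]
}

template_xyz <- function(tpl, atom_names) {
  idx <- match(atom_names, tpl$atoms$atom)
  if (anyNA(idx)) stop("template ", tpl$name, " lacks atoms: ",
                       paste(atom_names[is.na(idx)], collapse = ", "))
  as.matrix(tpl$atoms[idx, c("x", "y", "z")])
}

#' Signed chair pucker of a six-membered ring
#'
#' Measures the mean signed alternation of the ring atoms about their
#' best-fit plane.  An ideal chair built here has amplitude 0.25 A; a planar
#' ring has amplitude 0.
#'
#' @param xyz 6 x 3 matrix of ring-atom coordinates in cycle order.
#' @return signed pucker amplitude in Angstrom.
#' @export
ring_pucker <- function(xyz) {
  stopifnot(nrow(xyz) == 6)
  n <- plane_normal(xyz)
  z <- as.numeric(sweep(xyz, 2, colMeans(xyz)) %*% n)
  mean(z * rep(c(1, -1), 3))
}
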