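# Structural restraints driving the complex models.  Each restraint is a
# flat-bottomed quadratic: the violation energy is zero while the geometry is
# inside its bound and grows as k * excess^2 outside it.

#' Ring-stacking restraint
#'
#' Pulls the centroid of a ligand sugar ring to within \code{target}
#' Angstrom of the centroid of a receptor aromatic ring while keeping the
#' two ring planes near-parallel.  Energy:
#' \code{k * max(0, d - target)^2 + k_angle * max(0, theta - max_angle)^2}
#' with \code{d} the centroid-centroid distance and \code{theta} the acute
#' angle between the ring normals in degrees.
#'
#' @param receptor_resno receptor residue number carrying the aromatic ring.
#' @param receptor_atoms atom names forming the receptor ring (e.g. the five
#'   imidazole atoms of a histidine).
#' @param ligand_ring ligand residue (ring) index.
#' @param target centroid-centroid target distance in Angstrom.
#' @param max_angle largest penalty-free normal-normal angle in degrees.
#' @param k force constant, kcal/(mol A^2).
#' @param k_angle angular force constant, kcal/(mol deg^2).
#' @return an object of class \code{stacking_restraint}.
#' @export
stacking_restraint <- function(receptor_resno, receptor_atoms, ligand_ring,
                               target = 3.5, max_angle = 30,
                               k = 1, k_angle = 0.01) {
  structure(list(type = "stacking", receptor_resno = receptor_resno,
                 receptor_atoms = receptor_atoms, ligand_ring = ligand_ring,
                 target = target, max_angle = max_angle,
                 k = k, k_angle = k_angle),
            class = c("stacking_restraint", "restraint"))
}

#' Upper-bound distance restraint
#'
#' Energy \code{k * max(0, d - bound)^2} between one receptor atom and one
#' ligand atom.
#'
#' @param receptor_resno,receptor_atom receptor atom specifier.
#' @param ligand_resno,ligand_atom ligand atom specifier (e.g. the N-acetyl
#'   methyl carbon \code{"C8"} of ring 4).
#' @param bound upper bound in Angstrom.
#' @param k force constant, kcal/(mol A^2).
#' @return an object of class \code{distance_restraint}.
#' @export
distance_restraint <- function(receptor_resno, receptor_atom,
                               ligand_resno, ligand_atom,
                               bound = 4.5, k = 1) {
  structure(list(type = "distance", receptor_resno = receptor_resno,
                 receptor_atom = receptor_atom, ligand_resno = ligand_resno,
                 ligand_atom = ligand_atom, bound = bound, k = k),
            class = c("distance_restraint", "restraint"))
}

.resolve_receptor_xyz <- function(rec, resno, elety) {
  xyz <- receptor_xyz(rec, resno = resno, elety = elety)
  if (nrow(xyz) != length(elety))
    stop("cannot resolve receptor atoms ", paste(elety, collapse = ","),
         " in residue ", resno)
  xyz
}

restraint_energy_one <- function(restraint, rec, conf) {
  if (inherits(restraint, "stacking_restraint")) {
    rxyz <- .resolve_receptor_xyz(rec, restraint$receptor_resno,
                                  restraint$receptor_atoms)
    rc <- colMeans(rxyz)
    rn <- plane_normal(rxyz)
    lc <- ring_centroid(conf, restraint$ligand_ring)
    ln <- ring_normal(conf, restraint$ligand_ring)
    d <- vnorm(lc - rc)
    theta <- rad2deg(acos(min(1, abs(sum(rn * ln)))))
    restraint$k * max(0, d - restraint$target)^2 +
      restraint$k_angle * max(0, theta - restraint$max_angle)^2
  } else if (inherits(restraint, "distance_restraint")) {
    rxyz <- .resolve_receptor_xyz(rec, restraint$receptor_resno,
                                  restraint$receptor_atom)
    lxyz <- .conf_atom(conf, restraint$ligand_resno, restraint$ligand_atom)
    d <- vnorm(as.numeric(rxyz) - lxyz)
    restraint$k * max(0, d - restraint$bound)^2
  } else stop("unknown restraint class")
}

#' Total restraint energy of a ligand pose
#'
#' @param rec a \code{receptor}.
#' @param conf a placed \code{glycan_conformer}.
#' @param restraints list of restraints built with
#'   \code{\link{stacking_restraint}} / \code{\link{distance_restraint}}.
#' @return total violation energy in kcal/mol-equivalent units.
#' @export
restraint_energy <- function(rec, conf, restraints) {
  if (length(restraints) == 0) return(0)
  sum(vapply(restraints, restraint_energy_one, numeric(1),
             rec = rec, conf = conf))
}

# Receptor/ligand atom index pairs referenced by the restraints; these pairs
# are excluded from clash counting (restrained contacts are intentional).
restrained_pairs <- function(restraints, rec, conf) {
  rpairs <- matrix(integer(0), ncol = 2)
  for (r in restraints) {
    if (inherits(r, "stacking_restraint")) {
      ri <- which(rec$atoms$resno == r$receptor_resno &
                    rec$atoms$elety %in% r$receptor_atoms)
      li <- which(conf$atoms$resno == r$ligand_ring)
    } else {
      ri <- which(rec$atoms$resno == r$receptor_resno &
                    rec$atoms$elety %in% r$receptor_atom)
      li <- which(conf$atoms$resno == r$ligand_resno &
                    conf$atoms$atom == r$ligand_atom)
    }
    if (length(ri) && length(li))
      rpairs <- rbind(rpairs, as.matrix(expand.grid(ri, li)))
  }
  rpairs
}
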