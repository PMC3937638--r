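# Periodic phi/psi energy surfaces per glycosidic linkage type.
#
# A map is a regular lattice over [-180, 180)^2 in kcal/mol, normalized so
# its minimum is 0.  The surfaces shipped as defaults are explicit smooth
# two-basin surrogates (see default_torsion_maps); user-supplied grids in the
# plain-text format read by read_torsion_map can replace them.

#' Construct a torsion map
#'
#' @param grid numeric matrix of energies (kcal/mol); rows index phi, columns
#'   index psi, both starting at -180 with uniform spacing.
#' @param linkage linkage type, \code{"b13"} or \code{"b14"}.
#' @param spacing grid spacing in degrees; must divide 360 and match the grid
#'   dimensions.
#' @param convention dihedral-convention tag; maps and conformers with
#'   different tags cannot be combined.
#' @return an object of class \code{torsion_map}, normalized to min = 0.
#' @export
torsion_map <- function(grid, linkage = c("b13", "b14"),
                        spacing = 360 / nrow(grid),
                        convention = TORSION_CONVENTION) {
  linkage <- match.arg(linkage)
  grid <- as.matrix(grid)
  if (nrow(grid) != 360 / spacing || ncol(grid) != 360 / spacing)
    stop("grid must be (360/spacing) x (360/spacing); got ",
         nrow(grid), " x ", ncol(grid), " for spacing ", spacing)
  if (any(!is.finite(grid))) stop("grid energies must be finite")
  grid <- grid - min(grid)
  structure(list(linkage = linkage, grid = grid, spacing = spacing,
                 convention = convention),
            class = "torsion_map")
}

#' @export
print.torsion_map <- function(x, ...) {
  cat("<torsion_map> ", x$linkage, ": ", nrow(x$grid), "x", ncol(x$grid),
      " grid, ", x$spacing, " deg spacing, max ",
      sprintf("%.2f", max(x$grid)), " kcal/mol\n", sep = "")
  cat("  convention: ", x$convention, "\n", sep = "")
  invisible(x)
}

#' Write a torsion map to a plain-text grid file
#'
#' Format: three header lines (\code{# linkage:}, \code{# spacing:},
#' \code{# convention:}) followed by the whitespace-delimited energy matrix.
#'
#' @param map a \code{torsion_map}.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_torsion_map <- function(map, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(paste("# linkage:", map$linkage),
               paste("# spacing:", map$spacing),
               paste("# convention:", map$convention)), con)
  utils::write.table(format(map$grid, digits = 10), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a torsion map grid file
#'
#' @param file path to a file written in the format of
#'   \code{\link{write_torsion_map}}.
#' @return a \code{torsion_map}, renormalized so its minimum is 0.
#' @export
read_torsion_map <- function(file) {
  lines <- readLines(file)
  hdr <- lines[seq_len(3)]
  get <- function(key) {
    ln <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (length(ln) != 1) stop("map file lacks header line '# ", key, ":'")
    trimws(sub(paste0("^#\\s*", key, ":"), "", ln))
  }
  linkage <- get("linkage")
  spacing <- as.numeric(get("spacing"))
  convention <- get("convention")
  if (convention != TORSION_CONVENTION)
    stop("unknown torsion convention tag: '", convention, "'")
  rows <- strsplit(trimws(lines[-seq_len(3)]), "\\s+")
  rows <- rows[lengths(rows) > 0]
  ncols <- unique(lengths(rows))
  if (length(ncols) != 1) stop("non-rectangular grid in ", file)
  grid <- matrix(as.numeric(unlist(rows)), nrow = length(rows), byrow = TRUE)
  if (anyNA(grid)) stop("non-numeric entries in grid file ", file)
  torsion_map(grid, linkage = linkage, spacing = spacing,
              convention = convention)
}

#' Interpolate a torsion map at arbitrary angles
#'
#' Bilinear interpolation on the periodic lattice; query angles are wrapped
#' into the map domain, so \code{map_energy(map, 180, psi)} equals
#' \code{map_energy(map, -180, psi)} exactly.
#'
#' @param map a \code{torsion_map}.
#' @param phi,psi angles in degrees (vectors recycle).
#' @return interpolated energies in kcal/mol above the map minimum.
#' @export
map_energy <- function(map, phi, psi) {
  n <- nrow(map$grid)
  h <- map$spacing
  fi <- (wrap_angle(phi) + 180) / h     # fractional row index, 0-based
  fj <- (wrap_angle(psi) + 180) / h
  i0 <- floor(fi); j0 <- floor(fj)
  wi <- fi - i0; wj <- fj - j0
  i0 <- (i0 %% n) + 1; j0 <- (j0 %% n) + 1
  i1 <- (i0 %% n) + 1; j1 <- (j0 %% n) + 1
  g <- map$grid
  as.numeric(g[cbind(i0, j0)] * (1 - wi) * (1 - wj) +
               g[cbind(i1, j0)] * wi * (1 - wj) +
               g[cbind(i0, j1)] * (1 - wi) * wj +
               g[cbind(i1, j1)] * wi * wj)
}

#' Default torsion-map cutoff: two contour intervals above the minimum
#'
#' The energy surfaces are contoured at 2 kcal/mol intervals; "well outside
#' the most favored regions" is taken to mean beyond the second contour,
#' hence a 4 kcal/mol default acceptance cutoff.
#' @export
DEFAULT_PHIPSI_CUTOFF <- 4

#' Classify the glycosidic linkages of a conformer as favored/disfavored
#'
#' A linkage is favored when its interpolated map energy is at most
#' \code{cutoff} kcal/mol above the map minimum; the conformer is accepted
#' when every linkage is favored.
#'
#' @param conf a \code{glycan_conformer}.
#' @param maps named list of \code{torsion_map}s keyed by linkage type
#'   (\code{"b13"}, \code{"b14"}).
#' @param cutoff acceptance cutoff in kcal/mol above the map minimum.
#' @return a list of class \code{favored_verdict}: per-linkage energies,
#'   per-linkage favored flags, and the model-level \code{accept}
#'   (conjunction of the flags).
#' @export
classify_linkages <- function(conf, maps, cutoff = DEFAULT_PHIPSI_CUTOFF) {
  tor <- measure_torsions(conf)
  types <- conf$sequence$linkages
  energies <- numeric(nrow(tor))
  for (i in seq_along(types)) {
    map <- maps[[types[i]]]
    if (is.null(map)) stop("no torsion map supplied for linkage type ", types[i])
    if (!identical(map$convention, conf$convention))
      stop("torsion convention mismatch between conformer ('",
           conf$convention, "') and map ('", map$convention, "')")
    energies[i] <- map_energy(map, tor[i, "phi"], tor[i, "psi"])
  }
  favored <- energies <= cutoff
  structure(list(energies = energies, favored = favored,
                 accept = all(favored), cutoff = cutoff),
            class = "favored_verdict")
}

#' @export
print.favored_verdict <- function(x, ...) {
  cat("<favored_verdict> cutoff ", x$cutoff, " kcal/mol: ",
      sum(x$favored), "/", length(x$favored), " linkages favored; model ",
      if (x$accept) "ACCEPTED" else "REJECTED", "\n", sep = "")
  invisible(x)
}

#' Smooth periodic basin surface on a grid
#'
#' Energy at (phi, psi) is \code{-sum_k depth_k * exp(((cos(phi - phi0_k) - 1)
#' + (cos(psi - psi0_k) - 1)) / w_k^2)} with \code{w_k} the basin width in
#' radians, evaluated on the lattice and shifted so the minimum is 0.  Used
#' for the shipped default maps and for test fixtures.
#'
#' @param basins data frame (or list of lists) with columns/fields
#'   \code{phi0}, \code{psi0}, \code{depth} (kcal/mol), \code{width}
#'   (degrees).
#' @param linkage linkage type tag for the resulting map.
#' @param spacing grid spacing in degrees.
#' @return a \code{torsion_map}.
#' @export
make_torsion_map_fixture <- function(basins, linkage = "b14", spacing = 10) {
  if (is.list(basins) && !is.data.frame(basins))
    basins <- do.call(rbind, lapply(basins, as.data.frame))
  if (nrow(basins) < 1) stop("at least one basin is required")
  ang <- seq(-180, 180 - spacing, by = spacing)
  grid <- matrix(0, length(ang), length(ang))
  for (k in seq_len(nrow(basins))) {
    w2 <- deg2rad(basins$width[k])^2
    dphi <- cos(deg2rad(outer(ang, rep(1, length(ang))) - basins$phi0[k])) - 1
    dpsi <- cos(deg2rad(outer(rep(1, length(ang)), ang) - basins$psi0[k])) - 1
    grid <- grid - basins$depth[k] * exp((dphi + dpsi) / w2)
  }
  torsion_map(grid, linkage = linkage, spacing = spacing)
}

# closed-form (continuous) version of the basin surface, pre-normalization;
# exported for use as an analytic cross-check of the gridded fixture
#' Analytic basin-surface energy (continuous form)
#' @param basins as in \code{\link{make_torsion_map_fixture}}.
#' @param phi,psi angles in degrees.
#' @return raw (un-normalized) energies in kcal/mol.
#' @export
basin_energy <- function(basins, phi, psi) {
  if (is.list(basins) && !is.data.frame(basins))
    basins <- do.call(rbind, lapply(basins, as.data.frame))
  e <- 0
  for (k in seq_len(nrow(basins))) {
    w2 <- deg2rad(basins$width[k])^2
    e <- e - basins$depth[k] *
      exp(((cos(deg2rad(phi - basins$phi0[k])) - 1) +
           (cos(deg2rad(psi - basins$psi0[k])) - 1)) / w2)
  }
  e
}

#' Default (surrogate) torsion maps for HA-type linkages
#'
#' Approximate two-basin surfaces standing in for molecular-dynamics-derived
#' phi/psi maps: a broad syn-phi main basin plus a shallower secondary basin
#' per linkage type.  These are documented approximations intended for
#' exploratory use; quantitative work should supply its own grids via
#' \code{\link{read_torsion_map}}.
#'
#' @param spacing grid spacing in degrees.
#' @return named list with elements \code{b13} and \code{b14}.
#' @export
default_torsion_maps <- function(spacing = 10) {
  b13 <- data.frame(phi0 = c(-120, 60), psi0 = c(60, -120),
                    depth = c(8, 3), width = c(35, 25))
  b14 <- data.frame(phi0 = c(-60, 120), psi0 = c(-120, 90),
                    depth = c(8, 3), width = c(35, 25))
  list(b13 = make_torsion_map_fixture(b13, "b13", spacing),
       b14 = make_torsion_map_fixture(b14, "b14", spacing))
}
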