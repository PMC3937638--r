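# Seed-deterministic synthetic data generators.  These fixtures let every
# analysis stage run with no external inputs: an idealized pseudo-receptor
# whose anchor residues are arranged around a known-good HA8 pose, peak-list
# panels whose class structure encodes known binding registers, and one-site
# titration series.  The receptor fixture is explicitly non-physical (anchor
# side chains only, no backbone); it is a test scaffold, with a real Link
# module coordinate file as the optional production input.

# torsions used for the fixture's reference HA8 pose: the main-basin minima
# of the default torsion maps
.fixture_torsions <- function(seq, maps) map_minimum_torsions(seq, maps)

# ring normal signed toward the face with fewer nearby ligand atoms
.away_normal <- function(conf, resno) {
  n <- ring_normal(conf, resno)
  ctr <- ring_centroid(conf, resno)
  xyz <- conformer_xyz(conf)
  rel <- sweep(xyz, 2, ctr)
  near <- rowSums(rel^2) < 64
  proj <- as.numeric(rel %*% n)
  if (sum(near & proj > 0.5) > sum(near & proj < -0.5)) -n else n
}

.ring_poly <- function(center, normal, radius, names) {
  ref <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit(cross3(normal, ref))
  e2 <- cross3(normal, e1)
  k <- seq_along(names) - 1
  ang <- 2 * pi * k / length(names)
  xyz <- t(vapply(ang, function(a)
    center + radius * (cos(a) * e1 + sin(a) * e2), numeric(3)))
  data.frame(elety = names, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

#' Synthetic receptor fixture with a known-good ligand pose
#'
#' Builds an HA8 octasaccharide at the default-map basin torsions and then
#' arranges pseudo-protein anchor side chains around it: a His45 imidazole
#' stacked 3.5 A over ring 1, Lys63/Lys11/Arg81 terminal amines next to the
#' ring 1/3/7 carboxylates, a Cys47-Cys68 disulfide pair under ring 2,
#' Tyr59/Tyr78 rings stacked on rings 5 and 6, and the Ile61 side chain by
#' the ring 4 N-acetyl methyl.  By construction the returned reference pose
#' satisfies every restraint with zero penalty, has no steric clashes, and
#' places rings 1-7 (but not ring 8) within 4.0 A of the receptor.
#'
#' @param seed integer; the construction is deterministic, so fixtures with
#'   equal seeds are identical.
#' @param maps torsion maps defining the reference-pose torsions (default
#'   \code{\link{default_torsion_maps}()}).
#' @return list of class \code{receptor_fixture}: \code{receptor},
#'   \code{pose} (the reference \code{glycan_conformer}), \code{torsions},
#'   \code{restraints}, \code{maps} and \code{sequence}.
#' @export
make_receptor_fixture <- function(seed = 1, maps = default_torsion_maps()) {
  set.seed(seed)
  seq <- parse_glycan("HA8^AN")
  torsions <- .fixture_torsions(seq, maps)
  conf <- build_conformer(seq, torsions)
  pco <- function(resno, atom) .conf_atom(conf, resno, atom)

  rows <- list()
  add <- function(resno, resid, df) {
    df$resno <- resno; df$resid <- resid
    rows[[length(rows) + 1]] <<- df
  }
  atom_row <- function(elety, xyz)
    data.frame(elety = elety, x = xyz[1], y = xyz[2], z = xyz[3],
               stringsAsFactors = FALSE)

  # His45 imidazole stacked over ring 1
  n1 <- .away_normal(conf, 1)
  c1 <- ring_centroid(conf, 1)
  add(45, "HIS", .ring_poly(c1 + 3.5 * n1, n1, 1.16,
                            c("CG", "ND1", "CD2", "CE1", "NE2")))
  # Lys63 amine by the ring 1 carboxylate
  o6a1 <- pco(1, "O6A")
  u <- unit(o6a1 - c1)
  add(63, "LYS", rbind(atom_row("NZ", o6a1 + 2.8 * u),
                       atom_row("CE", o6a1 + 4.3 * u)))
  # Cys47-Cys68 disulfide under ring 2
  n2 <- .away_normal(conf, 2)
  c2 <- ring_centroid(conf, 2)
  sg47 <- c2 + 3.5 * n2
  c3 <- ring_centroid(conf, 3)
  w <- unit((c3 - c2) - sum((c3 - c2) * n2) * n2)
  add(47, "CYS", atom_row("SG", sg47))
  add(68, "CYS", atom_row("SG", sg47 + 2.05 * (0.4 * w + 0.92 * n2)))
  # Lys11 amine by the ring 3 carboxylate
  o6a3 <- pco(3, "O6A")
  u3 <- unit(o6a3 - c3)
  add(11, "LYS", rbind(atom_row("NZ", o6a3 + 2.8 * u3),
                       atom_row("CE", o6a3 + 4.3 * u3)))
  # Ile61 by the ring 4 N-acetyl methyl
  c4 <- ring_centroid(conf, 4)
  c8r4 <- pco(4, "C8")
  u4 <- unit(c8r4 - c4)
  add(61, "ILE", rbind(atom_row("CD1", c8r4 + 3.8 * u4),
                       atom_row("CG1", c8r4 + 5.3 * u4)))
  # Tyr59/Tyr78 rings stacked on rings 5 and 6
  for (spec in list(list(59, 5), list(78, 6))) {
    nn <- .away_normal(conf, spec[[2]])
    cc <- ring_centroid(conf, spec[[2]])
    # bias the aromatic ring laterally away from the next sugar ring so its
    # rim stays clear of that ring's substituents
    cnext <- ring_centroid(conf, spec[[2]] + 1)
    lat <- (cc - cnext) - sum((cc - cnext) * nn) * nn
    ctr <- cc + 3.5 * nn + 1.2 * unit(lat)
    add(spec[[1]], "TYR",
        .ring_poly(ctr, nn, 1.39,
                   c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")))
  }
  # Arg81 guanidinium nitrogen by the ring 7 carboxylate, biased away from
  # ring 8 so the terminal ring stays out of contact range
  c7 <- ring_centroid(conf, 7)
  c8c <- ring_centroid(conf, 8)
  o6a7 <- pco(7, "O6A")
  u7 <- unit(unit(o6a7 - c7) + 0.8 * unit(c7 - c8c))
  add(81, "ARG", rbind(atom_row("NH1", o6a7 + 2.8 * u7),
                       atom_row("CZ", o6a7 + 4.2 * u7)))

  atoms <- do.call(rbind, rows)
  atoms$elem <- element_of(atoms$elety)
  atoms <- atoms[, c("elety", "resid", "resno", "x", "y", "z", "elem")]
  rec <- .receptor_from_frame(atoms, source = "synthetic fixture")

  restraints <- list(
    stacking_restraint(45, c("CG", "ND1", "CD2", "CE1", "NE2"),
                       ligand_ring = 1, target = 3.5, max_angle = 30),
    distance_restraint(61, "CD1", ligand_resno = 4, ligand_atom = "C8",
                       bound = 4.5))

  structure(list(receptor = rec, pose = conf, torsions = torsions,
                 restraints = restraints, maps = maps, sequence = seq,
                 seed = seed),
            class = "receptor_fixture")
}

# ---------------------------------------------------------------------------
# CSP panel synthesis

#' Canonical peak positions per reporter class
#'
#' Arbitrary but fixed shift positions used by the panel generator: each
#' reporter has a free-protein base position, and each peak class an offset
#' from it.  Offsets are spaced at least five significance thresholds apart
#' (1.2 ppm in 15N, 0.30 ppm in 1H), so class identity is unambiguous at
#' zero noise.
#'
#' @return named list: per reporter, \code{label} (assignment label),
#'   \code{base} \code{c(heavy, H)} and \code{classes} (named list of
#'   offsets).
#' @export
canonical_class_positions <- function() {
  list(
    Val62 = list(label = "V62N-H", base = c(121.30, 8.25),
                 classes = list(I = c(1.2, 0.30), II = c(2.4, 0.60))),
    Lys63 = list(label = "K63N-H", base = c(122.00, 8.40),
                 classes = list(III = c(1.2, 0.30), IV = c(2.4, 0.60),
                                V = c(3.6, 0.90))),
    Ala49 = list(label = "A49N-H", base = c(124.00, 8.25),
                 classes = list(IX = c(1.2, 0.30), X = c(2.4, 0.60),
                                unclassified = c(-1.2, -0.30))),
    His45 = list(label = "H45N-H", base = c(118.00, 8.60),
                 classes = list(VI = c(1.2, 0.30), VII = c(2.4, 0.60),
                                VIII = c(3.6, 0.90))))
}

#' Binding registers used for the synthetic ten-oligomer panel
#'
#' The groove offsets encoding how each member of the HA4-HA8 panel sits in
#' the binding site (two offsets = two coexisting registers).
#' @return named list of integer offset vectors.
#' @export
default_panel_truth <- function() {
  list("HA8^AN" = 0, "HA8^NA" = c(-1, 1), "HA7^AA" = 0, "HA7^NN" = c(-1, 1),
       "HA6^AN" = 0, "HA6^NA" = 1, "HA5^AA" = 2, "HA5^NN" = 1,
       "HA4^AN" = 2, "HA4^NA" = 1)
}

#' Synthesize reference/complex peak-list pairs from known registers
#'
#' For each oligomer, the reference list holds each reporter at its base
#' position and the complex list holds one peak per predicted class across
#' the truth registers, at the class's canonical position plus seeded
#' Gaussian jitter.  Oligomers bound in two registers therefore emit two
#' peaks for any reporter whose class differs between the registers.
#'
#' @param truth named list, oligomer specifier -> integer vector of groove
#'   offsets (default \code{\link{default_panel_truth}}).
#' @param noise Gaussian jitter sd in ppm; either a single value applied to
#'   both dimensions or \code{c(heavy =, H =)}.
#' @param seed RNG seed.
#' @param groove groove model.
#' @param rules reporter rules (reporters present in
#'   \code{\link{canonical_class_positions}} are emitted).
#' @return list of class \code{csp_panel}: per oligomer a list with
#'   \code{reference}, \code{complex} (peak lists), \code{truth_offsets}
#'   and \code{truth_classes}.
#' @export
make_csp_panel <- function(truth = default_panel_truth(), noise = 0,
                           seed = 1, groove = groove_model(),
                           rules = reporter_rules()) {
  set.seed(seed)
  canon <- canonical_class_positions()
  reporters <- intersect(names(rules), names(canon))
  if (length(noise) == 1) noise <- c(heavy = noise, H = noise)
  panel <- lapply(names(truth), function(spec) {
    seq <- parse_glycan(spec)
    regs <- lapply(truth[[spec]], function(o) .register(seq, o, groove))
    classes <- lapply(reporters, function(rep) {
      unique(vapply(regs, function(r)
        rules[[rep]](r$occupied, r$reducing_position), character(1)))
    })
    names(classes) <- reporters
    ref_lab <- vapply(reporters, function(r) canon[[r]]$label, character(1))
    ref <- peak_list(ref_lab,
                     vapply(reporters, function(r) canon[[r]]$base[1],
                            numeric(1)),
                     vapply(reporters, function(r) canon[[r]]$base[2],
                            numeric(1)))
    lab <- character(0); w1 <- numeric(0); w2 <- numeric(0)
    for (rep in reporters) {
      cls <- classes[[rep]]
      for (k in seq_along(cls)) {
        off <- canon[[rep]]$classes[[cls[k]]]
        if (is.null(off))
          stop("no canonical position for class '", cls[k],
               "' of reporter ", rep)
        lab <- c(lab, paste0(canon[[rep]]$label,
                             if (k > 1) paste0("_", k) else ""))
        w1 <- c(w1, canon[[rep]]$base[1] + off[1] +
                  stats::rnorm(1, 0, noise[["heavy"]]))
        w2 <- c(w2, canon[[rep]]$base[2] + off[2] +
                  stats::rnorm(1, 0, noise[["H"]]))
      }
    }
    list(reference = ref, complex = peak_list(lab, w1, w2),
         truth_offsets = truth[[spec]], truth_classes = classes)
  })
  names(panel) <- names(truth)
  structure(panel, class = "csp_panel")
}

#' Recover observed reporter classes from a reference/complex pair
#'
#' Each complex peak is assigned to its reporter by label and to the
#' nearest canonical class in threshold-normalized shift space.  Peaks
#' whose nearest class lies beyond \code{max_norm_dist} are reported in
#' \code{unassigned} rather than silently dropped, so noise-induced
#' degradation of the panel is visible.
#'
#' @param reference,complexed peak lists.
#' @param max_norm_dist assignment radius in threshold-normalized units
#'   (shift differences divided by the per-dimension significance
#'   thresholds).
#' @return list with \code{observed} (reporter -> class labels, the
#'   "unclassified" pseudo-class removed) and \code{unassigned} (labels of
#'   unassignable peaks).
#' @export
observed_classes <- function(reference, complexed, max_norm_dist = 6) {
  canon <- canonical_class_positions()
  observed <- list()
  unassigned <- character(0)
  for (i in seq_len(nrow(complexed))) {
    lab <- complexed$label[i]
    rep <- NULL
    for (r in names(canon))
      if (startsWith(lab, canon[[r]]$label)) rep <- r
    if (is.null(rep)) { unassigned <- c(unassigned, lab); next }
    dd <- c(complexed$w1[i], complexed$w2[i]) - canon[[rep]]$base
    best <- NULL
    for (cl in names(canon[[rep]]$classes)) {
      off <- canon[[rep]]$classes[[cl]]
      nd <- sqrt(((dd[1] - off[1]) / CSP_THRESHOLDS[["heavy"]])^2 +
                   ((dd[2] - off[2]) / CSP_THRESHOLDS[["H"]])^2)
      if (is.null(best) || nd < best$nd) best <- list(cl = cl, nd = nd)
    }
    if (best$nd > max_norm_dist) {
      unassigned <- c(unassigned, lab)
    } else if (best$cl != "unclassified") {
      observed[[rep]] <- sort(unique(c(observed[[rep]], best$cl)))
    }
  }
  list(observed = observed, unassigned = unassigned)
}

# ---------------------------------------------------------------------------
# ITC dataset synthesis

#' Synthesize a panel of one-site titration series
#'
#' One series per panel member (binding heats plus a constant dilution
#' heat, plus seeded Gaussian noise) and a blank series of pure dilution
#' heats, in the format \code{\link{fit_one_site}} consumes.
#'
#' @param panel data frame with columns \code{oligomer}, \code{N},
#'   \code{Kb_1e5}, \code{dH} (default: the shipped reference panel rows
#'   with complete parameters).
#' @param protocol an \code{\link{itc_protocol}}.
#' @param noise_sd heat noise sd in ucal.
#' @param seed RNG seed.
#' @param dilution_heat constant per-injection dilution heat in ucal.
#' @return list of class \code{itc_dataset}: \code{series} (named list of
#'   \code{itc_series}), \code{blank}, and \code{truth} (the generating
#'   parameters).
#' @export
make_itc_dataset <- function(panel = NULL, protocol = itc_protocol(),
                             noise_sd = 0, seed = 1, dilution_heat = -0.25) {
  if (is.null(panel)) {
    panel <- itc_reference_panel()
    panel <- panel[!is.na(panel$dH), c("oligomer", "N", "Kb_1e5", "dH")]
  }
  series <- list()
  for (i in seq_len(nrow(panel))) {
    p <- binding_params(panel$N[i], panel$Kb_1e5[i] * 1e5, panel$dH[i])
    s <- simulate_titration(p, protocol, noise_sd = noise_sd,
                            seed = seed + i)
    series[[panel$oligomer[i]]] <- itc_series(as.numeric(s) + dilution_heat,
                                              protocol)
  }
  nblank <- length(protocol$injection_volumes_ul)
  set.seed(seed)
  blank <- rep(dilution_heat, nblank) +
    if (noise_sd > 0) stats::rnorm(nblank, 0, noise_sd) else 0
  structure(list(series = series, blank = itc_series(blank, protocol),
                 truth = panel),
            class = "itc_dataset")
}

#' Write an ITC series as CSV
#' @param series an \code{itc_series}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_itc_csv <- function(series, path) {
  utils::write.csv(data.frame(injection = seq_along(series),
                              heat_ucal = as.numeric(series)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read an ITC series from CSV
#' @param path CSV with columns \code{injection}, \code{heat_ucal}.
#' @param protocol the matching \code{\link{itc_protocol}}.
#' @return an \code{itc_series}.
#' @export
read_itc_csv <- function(path, protocol) {
  df <- utils::read.csv(path)
  itc_series(df$heat_ucal, protocol)
}
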