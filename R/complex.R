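# Restraint-driven modeling of receptor/oligosaccharide complexes: clash
# scoring, torsion + rigid-body simulated annealing, ensemble generation
# with geometry/torsion-map filtering, and ring-contact reporting.

K_CLASH <- 10   # kcal/(mol A^2)-equivalent weight of the clash penalty
W_MAP <- 0.5    # weight of the torsion-map term in the annealing objective

#' Steric clash score between receptor and ligand
#'
#' A receptor/ligand heavy-atom pair clashes when its distance is below
#' \code{scale * (r1 + r2)} with \code{r1, r2} the van der Waals radii.
#' Pairs referenced by a restraint are excluded.  The penalty is the
#' quadratic overlap sum \code{K_CLASH * sum((threshold - d)^2)}.
#'
#' @param rec a \code{receptor}.
#' @param conf a placed \code{glycan_conformer}.
#' @param scale unitless radius-sum scale (default 0.7).
#' @param restraints restraints whose atom pairs are exempt.
#' @return list with \code{count} (number of clashing pairs) and
#'   \code{penalty}.
#' @export
clash_score <- function(rec, conf, scale = 0.7, restraints = list()) {
  rxyz <- receptor_xyz(rec)
  lxyz <- conformer_xyz(conf)
  rr <- rec$atoms$radius
  lr <- conf$atoms$radius
  d2 <- outer(rowSums(rxyz^2), rowSums(lxyz^2), "+") - 2 * rxyz %*% t(lxyz)
  d2[d2 < 0] <- 0
  thr <- scale * outer(rr, lr, "+")
  hit <- d2 < thr^2
  if (length(restraints) > 0) {
    ex <- restrained_pairs(restraints, rec, conf)
    if (nrow(ex) > 0) hit[ex] <- FALSE
  }
  n <- sum(hit)
  pen <- if (n > 0) K_CLASH * sum((thr[hit] - sqrt(d2[hit]))^2) else 0
  list(count = n, penalty = pen)
}

.model_energy <- function(rec, conf, restraints, maps, clash_scale) {
  re <- restraint_energy(rec, conf, restraints)
  cl <- clash_score(rec, conf, scale = clash_scale, restraints = restraints)
  tor <- conf$torsions
  me <- 0
  if (length(maps) > 0 && nrow(tor) > 0) {
    for (i in seq_len(nrow(tor))) {
      map <- maps[[conf$sequence$linkages[i]]]
      if (!is.null(map))
        me <- me + map_energy(map, tor[i, "phi"], tor[i, "psi"])
    }
  }
  list(restraint = re, clash_count = cl$count, clash_penalty = cl$penalty,
       map = me, total = re + cl$penalty + W_MAP * me)
}

.build_pose <- function(seq, torsions, rotation, translation) {
  conf <- build_conformer(seq, torsions)
  transform_conformer(conf, rotation, translation)
}

# map-minimum torsions for a sequence, used as the default starting state
map_minimum_torsions <- function(seq, maps) {
  t(vapply(seq$linkages, function(lt) {
    map <- maps[[lt]]
    if (is.null(map)) return(c(phi = -60, psi = -60))
    idx <- which(map$grid == min(map$grid), arr.ind = TRUE)[1, ]
    ang <- seq(-180, 180 - map$spacing, by = map$spacing)
    c(phi = ang[idx[1]], psi = ang[idx[2]])
  }, numeric(2)))
}

#' Heuristic initial pose for annealing
#'
#' Builds the ligand at its map-minimum torsions, aligns ring 1 with the
#' first stacking restraint (centroid at the target distance along the
#' receptor ring normal, planes parallel) and picks the spin about the
#' stacking axis that minimizes the total restraint energy.
#'
#' @param rec a \code{receptor}.
#' @param seq a \code{glycan_sequence}.
#' @param restraints restraint list (the first stacking restraint anchors
#'   the placement).
#' @param maps torsion maps keyed by linkage type.
#' @return list with \code{torsions}, \code{rotation}, \code{translation}.
#' @export
initial_pose <- function(rec, seq, restraints, maps) {
  torsions <- map_minimum_torsions(seq, maps)
  conf <- build_conformer(seq, torsions)
  st <- Filter(function(r) inherits(r, "stacking_restraint"), restraints)
  if (length(st) == 0)
    return(list(torsions = torsions, rotation = diag(3),
                translation = c(0, 0, 0)))
  st <- st[[1]]
  rxyz <- .resolve_receptor_xyz(rec, st$receptor_resno, st$receptor_atoms)
  rc <- colMeans(rxyz)
  rn <- plane_normal(rxyz)
  # put the ligand ring on the side of the receptor ring with fewer
  # receptor atoms (the exposed face)
  others <- receptor_xyz(rec)
  side <- sum(as.numeric(sweep(others, 2, rc) %*% rn) > 0.5)
  if (side > nrow(others) / 2) rn <- -rn
  lc <- ring_centroid(conf, st$ligand_ring)
  ln <- ring_normal(conf, st$ligand_ring)
  ax <- cross3(ln, rn)
  rot <- if (vnorm(ax) < 1e-8) diag(3) else
    rotation_about_axis(ax, rad2deg(atan2(vnorm(ax), sum(ln * rn))))
  best <- NULL
  for (spin in seq(0, 355, by = 5)) {
    r2 <- rotation_about_axis(rn, spin) %*% rot
    tr <- rc + st$target * rn - as.numeric(r2 %*% lc)
    pose <- .build_pose(seq, torsions, r2, tr)
    e <- restraint_energy(rec, pose, restraints) +
      clash_score(rec, pose, restraints = restraints)$penalty
    if (is.null(best) || e < best$e)
      best <- list(e = e, rotation = r2, translation = tr)
  }
  list(torsions = torsions, rotation = best$rotation,
       translation = best$translation)
}

#' Simulated-annealing refinement of one complex model
#'
#' Minimizes restraint energy + clash penalty + torsion-map energy over the
#' glycosidic torsions and the rigid-body placement of the ligand, with the
#' receptor fixed.  Moves perturb one torsion, rotate the ligand about its
#' ring-1 centroid, or translate it; Metropolis acceptance under a geometric
#' cooling schedule.  Fully deterministic for a given seed.
#'
#' @param rec a \code{receptor} (never modified).
#' @param seq a \code{glycan_sequence} or specifier string.
#' @param restraints restraint list.
#' @param maps torsion maps keyed by linkage type.
#' @param seed integer RNG seed.
#' @param init optional starting state (list with \code{torsions},
#'   \code{rotation}, \code{translation}); default
#'   \code{\link{initial_pose}}.
#' @param n_steps annealing steps.
#' @param n_polish additional greedy (descent-only) refinement steps run
#'   from the best state found by annealing.
#' @param t_start,t_end start/end temperatures of the geometric schedule.
#' @param clash_scale clash radius-sum scale.
#' @param restraint_tol convergence threshold on the final restraint energy;
#'   models above it are returned flagged, not dropped.
#' @param jitter if TRUE (ensemble use), the starting state is perturbed
#'   slightly (seeded) so different seeds explore different basins.
#' @return an object of class \code{complex_model}: the placed conformer,
#'   rigid-body parameters, score components, and a \code{converged} flag.
#' @export
anneal_model <- function(rec, seq, restraints, maps, seed = 1, init = NULL,
                         n_steps = 600, n_polish = 200, t_start = 3,
                         t_end = 0.02, clash_scale = 0.7, restraint_tol = 0.1,
                         jitter = TRUE) {
  if (is.character(seq)) seq <- parse_glycan(seq)
  set.seed(seed)
  if (is.null(init)) init <- initial_pose(rec, seq, restraints, maps)
  state <- init
  if (jitter) {
    state$torsions <- state$torsions +
      matrix(stats::rnorm(length(state$torsions), 0, 3), nrow(state$torsions))
    state$rotation <- rotation_about_axis(stats::rnorm(3),
                                          stats::rnorm(1, 0, 2)) %*% state$rotation
    state$translation <- state$translation + stats::rnorm(3, 0, 0.2)
  }
  pose <- .build_pose(seq, state$torsions, state$rotation, state$translation)
  en <- .model_energy(rec, pose, restraints, maps, clash_scale)
  best <- list(state = state, energy = en)
  cool <- (t_end / t_start)^(1 / max(1, n_steps - 1))
  temp <- t_start
  # ring-1 centroid in the canonical build frame: residue 1 is anchored
  # there, so this point is invariant under torsion changes
  ring1 <- ring_centroid(build_conformer(seq, state$torsions), 1)
  for (step in seq_len(n_steps)) {
    frac <- step / n_steps
    cand <- state
    u <- stats::runif(1)
    if (u < 0.45 && nrow(state$torsions) > 0) {
      i <- sample.int(nrow(state$torsions), 1)
      j <- sample.int(2, 1)
      cand$torsions[i, j] <- cand$torsions[i, j] +
        stats::rnorm(1, 0, 8 * (1 - frac) + 1.5)
    } else if (u < 0.75) {
      ang <- stats::rnorm(1, 0, 3 * (1 - frac) + 0.3)
      rotm <- rotation_about_axis(stats::rnorm(3), ang)
      ctr <- as.numeric(state$rotation %*% ring1) + state$translation
      cand$rotation <- rotm %*% state$rotation
      cand$translation <- ctr - as.numeric(cand$rotation %*% ring1)
    } else {
      cand$translation <- state$translation +
        stats::rnorm(3, 0, 0.25 * (1 - frac) + 0.03)
    }
    cpose <- .build_pose(seq, cand$torsions, cand$rotation, cand$translation)
    cen <- .model_energy(rec, cpose, restraints, maps, clash_scale)
    if (cen$total <= en$total ||
        stats::runif(1) < exp((en$total - cen$total) / temp)) {
      state <- cand
      en <- cen
      if (en$total < best$energy$total) best <- list(state = state, energy = en)
    }
    temp <- temp * cool
  }
  # greedy polish: small moves, descent only, from the best state found
  state <- best$state
  en <- best$energy
  for (step in seq_len(n_polish)) {
    cand <- state
    u <- stats::runif(1)
    if (u < 0.45 && nrow(state$torsions) > 0) {
      i <- sample.int(nrow(state$torsions), 1)
      j <- sample.int(2, 1)
      cand$torsions[i, j] <- cand$torsions[i, j] + stats::rnorm(1, 0, 1)
    } else if (u < 0.75) {
      rotm <- rotation_about_axis(stats::rnorm(3), stats::rnorm(1, 0, 0.3))
      ctr <- as.numeric(state$rotation %*% ring1) + state$translation
      cand$rotation <- rotm %*% state$rotation
      cand$translation <- ctr - as.numeric(cand$rotation %*% ring1)
    } else {
      cand$translation <- state$translation + stats::rnorm(3, 0, 0.03)
    }
    cpose <- .build_pose(seq, cand$torsions, cand$rotation, cand$translation)
    cen <- .model_energy(rec, cpose, restraints, maps, clash_scale)
    if (cen$total < en$total) {
      state <- cand
      en <- cen
    }
  }
  best <- list(state = state, energy = en)
  fpose <- .build_pose(seq, best$state$torsions, best$state$rotation,
                       best$state$translation)
  fen <- .model_energy(rec, fpose, restraints, maps, clash_scale)
  structure(list(receptor = rec, conformer = fpose,
                 rotation = best$state$rotation,
                 translation = best$state$translation,
                 torsions = measure_torsions(fpose),
                 scores = fen, seed = seed,
                 converged = fen$restraint < restraint_tol,
                 clash_scale = clash_scale),
            class = "complex_model")
}

#' @export
print.complex_model <- function(x, ...) {
  cat("<complex_model> ", x$conformer$sequence$spec, " on ",
      nrow(x$receptor$atoms), "-atom receptor (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  restraint %.4f  clash %d (penalty %.3f)  map %.3f  total %.3f\n",
              x$scores$restraint, x$scores$clash_count,
              x$scores$clash_penalty, x$scores$map, x$scores$total))
  cat("  converged:", x$converged, "\n")
  invisible(x)
}

# largest deviation of any glycosidic C1-Og bond from its template value
glycosidic_bond_deviation <- function(model) {
  conf <- model$conformer
  seq <- conf$sequence
  n <- n_residues(seq)
  if (n < 2) return(0)
  dev <- 0
  for (i in seq_len(n - 1)) {
    link <- .link_atoms(seq$linkages[i])
    tpl <- mono_template(seq$residues[i])
    ref <- vnorm(as.numeric(template_xyz(tpl, "C1")) -
                   as.numeric(template_xyz(tpl, "O1")))
    d <- vnorm(.conf_atom(conf, i, "C1") - .conf_atom(conf, i + 1, link$Ox))
    dev <- max(dev, abs(d - ref))
  }
  dev
}

#' Generate and filter an ensemble of complex models
#'
#' Runs \code{\link{anneal_model}} once per seed (cycling over the supplied
#' receptor members) and rejects models that fail geometry sanity
#' (glycosidic bond-length deviation > \code{bond_tol}), retain residual
#' clashes, fail to satisfy the restraints, or carry glycosidic angles
#' outside the favored torsion-map regions.
#'
#' @param receptors a \code{receptor} or list of receptors (e.g. members of
#'   an NMR ensemble).
#' @param seq sequence or specifier.
#' @param restraints restraint list.
#' @param maps torsion maps.
#' @param n_models number of annealing runs (seeds \code{1..n_models} offset
#'   by \code{seed_base}).
#' @param cutoff phi/psi acceptance cutoff in kcal/mol
#'   (\code{Inf} disables the torsion-map filter).
#' @param seed_base added to each model index to form its seed.
#' @param bond_tol glycosidic bond-length tolerance in Angstrom.
#' @param init optional common starting state passed to every run.
#' @param keep_all if TRUE, all annealed models (accepted or not) are
#'   returned in \code{$models}, enabling re-filtering at other cutoffs.
#' @param ... further arguments to \code{\link{anneal_model}}.
#' @return list of class \code{model_ensemble}: \code{accepted} (list of
#'   \code{complex_model}), \code{report} (data frame: seed, accepted,
#'   reason), plus the inputs used.
#' @export
generate_ensemble <- function(receptors, seq, restraints, maps,
                              n_models = 20, cutoff = DEFAULT_PHIPSI_CUTOFF,
                              seed_base = 0, bond_tol = 0.05, init = NULL,
                              keep_all = FALSE, ...) {
  if (inherits(receptors, "receptor")) receptors <- list(receptors)
  if (is.character(seq)) seq <- parse_glycan(seq)
  accepted <- list()
  models <- list()
  rows <- list()
  for (i in seq_len(n_models)) {
    rec <- receptors[[(i - 1) %% length(receptors) + 1]]
    model <- anneal_model(rec, seq, restraints, maps, seed = seed_base + i,
                          init = init, ...)
    reason <- "accepted"
    if (glycosidic_bond_deviation(model) > bond_tol) {
      reason <- "distorted glycosidic bond"
    } else if (model$scores$clash_count > 0) {
      reason <- sprintf("%d residual clash(es)", model$scores$clash_count)
    } else if (!model$converged) {
      reason <- sprintf("unresolved restraints (energy %.3f)",
                        model$scores$restraint)
    } else if (is.finite(cutoff)) {
      verdict <- classify_linkages(model$conformer, maps, cutoff = cutoff)
      if (!verdict$accept)
        reason <- sprintf("glycosidic angles outside favored regions (max %.2f kcal/mol)",
                          max(verdict$energies))
    }
    ok <- reason == "accepted"
    if (ok) accepted[[length(accepted) + 1]] <- model
    if (keep_all) models[[i]] <- model
    rows[[i]] <- data.frame(seed = seed_base + i, accepted = ok,
                            reason = reason, stringsAsFactors = FALSE)
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seed = integer(0), accepted = logical(0),
               reason = character(0))
  if (n_models > 0 && length(accepted) == 0)
    warning("all ", n_models, " models were rejected")
  structure(list(accepted = accepted, report = report, sequence = seq,
                 cutoff = cutoff,
                 models = if (keep_all) models else NULL),
            class = "model_ensemble")
}

#' @export
print.model_ensemble <- function(x, ...) {
  cat("<model_ensemble> ", x$sequence$spec, ": ", length(x$accepted), "/",
      nrow(x$report), " models accepted (phi/psi cutoff ",
      x$cutoff, " kcal/mol)\n", sep = "")
  bad <- x$report[!x$report$accepted, ]
  if (nrow(bad) > 0)
    for (i in seq_len(nrow(bad)))
      cat("  seed ", bad$seed[i], ": ", bad$reason[i], "\n", sep = "")
  invisible(x)
}

#' Per-ring receptor contacts of a complex model
#'
#' A ring is in contact when any of its heavy atoms lies within
#' \code{cutoff} of any receptor heavy atom.
#'
#' @param model a \code{complex_model}.
#' @param cutoff contact distance in Angstrom (default 4.0).
#' @return list with \code{contact} (per-ring logical vector) and
#'   \code{count}.
#' @export
ring_contacts <- function(model, cutoff = 4.0) {
  rxyz <- receptor_xyz(model$receptor)
  conf <- model$conformer
  n <- n_residues(conf$sequence)
  contact <- logical(n)
  for (r in seq_len(n)) {
    lxyz <- conformer_xyz(conf, resno = r)
    d2 <- outer(rowSums(rxyz^2), rowSums(lxyz^2), "+") - 2 * rxyz %*% t(lxyz)
    contact[r] <- min(d2) < cutoff^2
  }
  list(contact = contact, count = sum(contact))
}

#' Write an ensemble of accepted models as a multi-MODEL PDB
#'
#' Each accepted model contributes one MODEL block holding the receptor
#' (chain A) followed by the ligand (chain S).
#'
#' @param ensemble a \code{model_ensemble}.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_ensemble_pdb <- function(ensemble, file) {
  out <- character(0)
  for (i in seq_along(ensemble$accepted)) {
    model <- ensemble$accepted[[i]]
    tf1 <- tempfile(fileext = ".pdb")
    tf2 <- tempfile(fileext = ".pdb")
    write_receptor_pdb(model$receptor, tf1)
    write_conformer_pdb(model$conformer, tf2)
    body <- c(grep("^(ATOM|HETATM)", readLines(tf1), value = TRUE),
              grep("^(ATOM|HETATM)", readLines(tf2), value = TRUE))
    unlink(c(tf1, tf2))
    out <- c(out, sprintf("MODEL     %4d", i), body, "ENDMDL")
  }
  writeLines(c(out, "END"), file)
  invisible(file)
}
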