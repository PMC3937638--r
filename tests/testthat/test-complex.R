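# Receptor handling, restraints, clash scoring, annealing and ensembles.

test_that("receptor PDB round trip preserves anchors and model selection works", {
  fx <- fixture()
  f <- tempfile(fileext = ".pdb")
  write_receptor_pdb(fx$receptor, f)
  required <- list(list(resno = 45, elety = c("CG", "ND1", "CD2", "CE1",
                                              "NE2")),
                   list(resno = 63, elety = "NZ"),
                   list(resno = 11, elety = "NZ"),
                   list(resno = 59, elety = "CZ"),
                   list(resno = 78, elety = "CZ"),
                   list(resno = 81, elety = "NH1"),
                   list(resno = 61, elety = "CD1"),
                   list(resno = 47, elety = "SG"),
                   list(resno = 68, elety = "SG"))
  rec <- load_receptor(f, model_index = 1, required = required)
  expect_equal(nrow(rec$atoms), nrow(fx$receptor$atoms))
  expect_error(load_receptor(f, model_index = 5), "out of range")
  required_bad <- list(list(resno = 99, elety = "NZ"))
  expect_error(load_receptor(f, required = required_bad),
               "99:NZ")
  unlink(f)
})

test_that("restraint energies match their closed forms and an independent oracle", {
  fx <- fixture()
  # reference pose: every restraint exactly satisfied
  expect_equal(restraint_energy(fx$receptor, fx$pose, fx$restraints), 0)

  # closed form: centroid distance 5.0, parallel planes, k = 1 -> 2.25
  st <- fx$restraints[[1]]
  rxyz <- receptor_xyz(fx$receptor, resno = 45)
  rn <- plane_normal(rxyz)
  shifted <- transform_conformer(fx$pose, diag(3), -1.5 * rn)
  d <- sqrt(sum((ring_centroid(shifted, 1) - colMeans(rxyz))^2))
  expect_equal(d, 5.0, tolerance = 1e-6)
  expect_equal(restraint_energy(fx$receptor, shifted, fx$restraints[1]),
               (5.0 - 3.5)^2, tolerance = 1e-6)

  # independent sum-of-penalties oracle over random placements
  set.seed(14)
  for (rep in 1:25) {
    rot <- rotation_about_axis(rnorm(3), runif(1, -180, 180))
    tra <- rnorm(3, 0, 8)
    pose <- transform_conformer(fx$pose, rot, tra)
    got <- restraint_energy(fx$receptor, pose, fx$restraints)
    # oracle, coded from the definitions
    rc <- colMeans(rxyz)
    lc <- ring_centroid(pose, 1)
    ln <- ring_normal(pose, 1)
    theta <- acos(min(1, abs(sum(rn * ln)))) * 180 / pi
    e1 <- max(0, sqrt(sum((lc - rc)^2)) - 3.5)^2 +
      0.01 * max(0, theta - 30)^2
    cd1 <- receptor_xyz(fx$receptor, resno = 61, elety = "CD1")
    me <- unlist(pose$atoms[pose$atoms$resno == 4 &
                              pose$atoms$atom == "C8", c("x", "y", "z")])
    e2 <- max(0, sqrt(sum((as.numeric(cd1) - me)^2)) - 4.5)^2
    expect_equal(got, e1 + e2, tolerance = 1e-9)
  }
})

test_that("clash counts match a brute-force all-pairs scan", {
  fx <- fixture()
  # far translation: no clashes, no contacts
  far <- transform_conformer(fx$pose, diag(3), c(50, 0, 0))
  expect_equal(clash_score(fx$receptor, far)$count, 0)
  model <- structure(list(receptor = fx$receptor, conformer = far),
                     class = "complex_model")
  expect_equal(ring_contacts(model)$count, 0)

  set.seed(3)
  for (rep in 1:30) {
    pose <- transform_conformer(fx$pose,
                                rotation_about_axis(rnorm(3),
                                                    runif(1, -180, 180)),
                                rnorm(3, 0, 4))
    got <- clash_score(fx$receptor, pose)
    expect_identical(got$count, oracle_clash_count(fx$receptor, pose))
    expect_gte(got$penalty, 0)
  }
})

test_that("a pair closer than the scaled radius sum counts as one clash", {
  # isolated carbon pair 1.0 A apart, radius sum 3.4, scale 0.7:
  # 1.0 < 0.7 * 3.4 = 2.38 -> exactly one clash
  lig <- structure(list(atoms = data.frame(
    resno = 1, residue = "GlcUA", resname = "BDP", atom = "C1",
    elem = "C", x = 0, y = 0, z = 0, radius = 1.7, glyco = FALSE,
    stringsAsFactors = FALSE)), class = "glycan_conformer")
  rec <- hagroove:::.receptor_from_frame(
    data.frame(elety = "CB", resid = "ALA", resno = 1,
               x = 1.0, y = 0, z = 0, elem = "C", stringsAsFactors = FALSE))
  cs <- clash_score(rec, lig, scale = 0.7)
  expect_equal(cs$count, 1L)
  # at scale 0.25 the threshold drops to 0.85 A and the clash disappears
  expect_equal(clash_score(rec, lig, scale = 0.25)$count, 0L)
})

test_that("annealing is seed-deterministic and respects a degenerate objective", {
  fx <- fixture()
  init <- list(torsions = fx$torsions, rotation = diag(3),
               translation = c(0, 0, 0))
  m1 <- anneal_model(fx$receptor, fx$sequence, fx$restraints, fx$maps,
                     seed = 5, init = init, n_steps = 120, n_polish = 30)
  m2 <- anneal_model(fx$receptor, fx$sequence, fx$restraints, fx$maps,
                     seed = 5, init = init, n_steps = 120, n_polish = 30)
  expect_identical(conformer_xyz(m1$conformer), conformer_xyz(m2$conformer))
  expect_identical(m1$scores, m2$scores)

  # no restraints + flat maps: the objective reduces to the clash term
  m3 <- anneal_model(fx$receptor, fx$sequence, list(), flat_maps(),
                     seed = 2, init = init, n_steps = 60, n_polish = 10)
  expect_equal(m3$scores$restraint, 0)
  expect_equal(m3$scores$map, 0)
  expect_equal(m3$scores$total, m3$scores$clash_penalty)
})

test_that("the receptor is never modified by modeling operations", {
  fx <- fixture()
  before <- receptor_checksum(fx$receptor)
  init <- list(torsions = fx$torsions, rotation = diag(3),
               translation = c(0, 0, 0))
  invisible(anneal_model(fx$receptor, fx$sequence, fx$restraints, fx$maps,
                         seed = 1, init = init, n_steps = 80, n_polish = 10))
  invisible(clash_score(fx$receptor, fx$pose))
  invisible(restraint_energy(fx$receptor, fx$pose, fx$restraints))
  expect_identical(receptor_checksum(fx$receptor), before)
})

test_that("ensembles filter on geometry and torsion maps; empty runs are empty", {
  fx <- fixture()
  init <- list(torsions = fx$torsions, rotation = diag(3),
               translation = c(0, 0, 0))
  ens <- generate_ensemble(fx$receptor, fx$sequence, fx$restraints, fx$maps,
                           n_models = 4, init = init, n_steps = 250,
                           n_polish = 120, keep_all = TRUE)
  expect_gte(length(ens$accepted), 3)
  for (m in ens$accepted) {
    expect_equal(m$scores$clash_count, 0)
    expect_lt(m$scores$restraint, 0.1)
    expect_true(classify_linkages(m$conformer, fx$maps)$accept)
  }
  # cutoff = Inf disables the torsion-map filter: accepted set grows or stays
  ens_inf <- generate_ensemble(fx$receptor, fx$sequence, fx$restraints,
                               fx$maps, n_models = 4, init = init,
                               n_steps = 250, n_polish = 120, cutoff = Inf)
  expect_gte(length(ens_inf$accepted), length(ens$accepted))

  ens0 <- generate_ensemble(fx$receptor, fx$sequence, fx$restraints,
                            fx$maps, n_models = 0, init = init)
  expect_length(ens0$accepted, 0)
  expect_equal(nrow(ens0$report), 0)
})

test_that("ring contacts are monotone in the cutoff", {
  fx <- fixture()
  model <- structure(list(receptor = fx$receptor, conformer = fx$pose),
                     class = "complex_model")
  counts <- vapply(seq(3, 6, by = 0.5),
                   function(ct) ring_contacts(model, cutoff = ct)$count,
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
  # brute-force distance check at 4.0
  rxyz <- receptor_xyz(fx$receptor)
  manual <- vapply(seq_len(8), function(r) {
    lxyz <- conformer_xyz(fx$pose, resno = r)
    dmin <- min(apply(lxyz, 1, function(p)
      min(sqrt(rowSums(sweep(rxyz, 2, p)^2)))))
    dmin < 4.0
  }, logical(1))
  expect_identical(ring_contacts(model, 4.0)$contact, manual)
})
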