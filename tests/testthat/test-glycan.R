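# Oligosaccharide parsing and the torsion-parameterized geometry engine.

test_that("specifier grammar produces the right residue sequences", {
  s <- parse_glycan("HA8^AN")
  expect_equal(s$residues[1], "GlcUA")
  expect_equal(s$residues[8], "GlcNAc")
  expect_equal(s$linkages, rep(c("b13", "b14"), length.out = 7))

  # hybrid naming: chondroitin half at the NON-reducing end for HA4C4
  h <- parse_glycan("HA4C4")
  expect_equal(h$residues[c(2, 4)], rep("GalNAc", 2))
  expect_equal(h$residues[c(6, 8)], rep("GlcNAc", 2))
  r <- parse_glycan("C4HA4")
  expect_equal(r$residues[c(2, 4)], rep("GlcNAc", 2))
  expect_equal(r$residues[c(6, 8)], rep("GalNAc", 2))

  c8 <- parse_glycan("C8^AN")
  expect_equal(c8$residues[c(2, 4, 6, 8)], rep("GalNAc", 4))
  expect_equal(c8$residues[c(1, 3, 5, 7)], rep("GlcUA", 4))

  # caret optional, case-insensitive family tag
  expect_equal(parse_glycan("HA6NA")$residues[1], "GlcNAc")
})

test_that("impossible or malformed specifiers are rejected with a message", {
  expect_error(parse_glycan("HA8^AA"), "parity-impossible")
  expect_error(parse_glycan("HA7^AN"), "parity-impossible")
  expect_error(parse_glycan("XYZ12"), "unparseable")
  expect_error(parse_glycan("HA1^AN"), "at least 2")
})

test_that("residue parity alternates from the non-reducing terminus", {
  for (spec in c("HA8^AN", "HA8^NA", "HA7^AA", "HA7^NN", "HA5^NN",
                 "C8^NA", "HA4C4", "C4HA4")) {
    s <- parse_glycan(spec)
    first_uronic <- s$residues[1] == "GlcUA"
    for (i in seq_along(s$residues)) {
      expected <- if (first_uronic) i %% 2 == 1 else i %% 2 == 0
      expect_identical(s$residues[i] == "GlcUA", expected, label = spec)
    }
  }
})

test_that("build -> measure reproduces every torsion to 1e-6 degrees", {
  set.seed(101)
  for (spec in c("HA8^AN", "HA5^NN", "HA4C4", "C8^AN")) {
    s <- parse_glycan(spec)
    for (rep in 1:25) {
      tor <- matrix(runif(2 * (n_residues(s) - 1), -180, 180), ncol = 2)
      conf <- build_conformer(s, tor)
      err <- max(abs(wrap_angle(measure_torsions(conf) - wrap_angle(tor))))
      expect_lt(err, 1e-6)
    }
  }
  # boundary cases
  z <- build_conformer("HA4^AN", matrix(0, 3, 2))
  expect_equal(max(abs(measure_torsions(z))), 0, tolerance = 1e-9)
  m <- build_conformer("HA4^AN", matrix(c(-80, -120), 3, 2, byrow = TRUE))
  expect_equal(unname(measure_torsions(m)[1, ]), c(-80, -120),
               tolerance = 1e-9)
})

test_that("rings stay rigid under any torsions and the glycosidic bond is fixed", {
  set.seed(7)
  s <- parse_glycan("HA6^AN")
  ref <- build_conformer(s, matrix(0, 5, 2))
  for (rep in 1:10) {
    tor <- matrix(runif(10, -180, 180), ncol = 2)
    conf <- build_conformer(s, tor)
    for (i in seq_len(6)) {
      a <- conf$atoms[conf$atoms$resno == i, ]
      b <- ref$atoms[ref$atoms$resno == i, ]
      b <- b[match(a$atom, b$atom), ]
      da <- dist(as.matrix(a[, c("x", "y", "z")]))
      db <- dist(as.matrix(b[, c("x", "y", "z")]))
      expect_lt(max(abs(da - db)), 1e-6)
    }
    # glycosidic C1-O bond length equals the template C1-O1 value
    for (i in seq_len(5)) {
      ox <- if (s$linkages[i] == "b13") "O3" else "O4"
      c1 <- unlist(conf$atoms[conf$atoms$resno == i &
                                conf$atoms$atom == "C1", c("x", "y", "z")])
      og <- unlist(conf$atoms[conf$atoms$resno == i + 1 &
                                conf$atoms$atom == ox, c("x", "y", "z")])
      expect_equal(sqrt(sum((c1 - og)^2)), 1.41, tolerance = 1e-6)
    }
  }
})

test_that("a chain of n rings carries n-1 glycosidic oxygens and chair rings", {
  for (n in c(4, 6, 8)) {
    conf <- build_conformer(paste0("HA", n, "^AN"),
                            matrix(-60, n - 1, 2))
    expect_equal(sum(conf$atoms$glyco), n - 1)
    for (r in seq_len(n)) {
      ring <- conformer_xyz(conf, resno = r,
                            atoms = c("C1", "C2", "C3", "C4", "C5", "O5"))
      expect_equal(abs(ring_pucker(ring)), 0.25, tolerance = 1e-6)
    }
  }
})

test_that("a psi rotation moves the downstream subtree exactly as a rigid rotation", {
  # independent oracle: rotating residues 2..n about the Og->Cx axis of
  # linkage 1 by delta-psi must reproduce the conformer built with the
  # changed psi
  s <- parse_glycan("HA6^AN")
  tor <- matrix(c(-80, -120), 5, 2, byrow = TRUE)
  conf <- build_conformer(s, tor)
  tor2 <- tor
  tor2[1, 2] <- tor2[1, 2] + 180
  conf2 <- build_conformer(s, tor2)
  # centroid distance ring1 -> ring3 must change
  d1 <- sqrt(sum((ring_centroid(conf, 3) - ring_centroid(conf, 1))^2))
  d2 <- sqrt(sum((ring_centroid(conf2, 3) - ring_centroid(conf2, 1))^2))
  expect_gt(abs(d1 - d2), 0.5)
  # oracle rotation of the subtree
  og <- unlist(conf$atoms[conf$atoms$resno == 2 & conf$atoms$atom == "O3",
                          c("x", "y", "z")])
  cx <- unlist(conf$atoms[conf$atoms$resno == 2 & conf$atoms$atom == "C3",
                          c("x", "y", "z")])
  sub <- conf$atoms$resno >= 2
  rotated <- oracle_rotate(as.matrix(conf$atoms[sub, c("x", "y", "z")]),
                           og, cx - og, 180)
  expect_equal(unname(rotated),
               unname(as.matrix(conf2$atoms[sub, c("x", "y", "z")])),
               tolerance = 1e-6)
})

test_that("dihedral measurement agrees with an independently coded oracle", {
  set.seed(33)
  for (i in 1:50) {
    p <- matrix(rnorm(12), 4, 3)
    expect_equal(dihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                 oracle_dihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                 tolerance = 1e-9)
  }
})

test_that("torsion list length mismatches and missing atoms error clearly", {
  expect_error(build_conformer("HA6^AN", matrix(0, 3, 2)),
               "does not match linkage count")
  conf <- build_conformer("HA4^AN", matrix(0, 3, 2))
  conf$atoms <- conf$atoms[!(conf$atoms$resno == 2 &
                               conf$atoms$atom == "C3"), ]
  expect_error(measure_torsions(conf), "linkage 1-2")
})

test_that("conformers survive a PDB write/read round trip", {
  tor <- matrix(c(-70, -100), 7, 2, byrow = TRUE)
  conf <- build_conformer("HA4C4", tor)
  f <- tempfile(fileext = ".pdb")
  write_conformer_pdb(conf, f)
  lines <- readLines(f)
  expect_true(any(grepl("A2G", lines)))
  expect_true(any(grepl("BDP", lines)))
  back <- read_conformer_pdb(f, "HA4C4")
  # PDB has 3 decimal places; torsions survive to ~0.1 degree
  expect_equal(unname(back$torsions), unname(conf$torsions),
               tolerance = 0.1)
  unlink(f)
})
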