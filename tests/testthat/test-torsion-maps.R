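# Periodic phi/psi energy maps: normalization, interpolation, file format
# and the favored/disfavored classifier.

test_that("maps are normalized so the minimum is zero", {
  m0 <- torsion_map(matrix(0, 36, 36), "b14")
  expect_true(all(m0$grid == 0))
  g <- matrix(0, 36, 36)
  g[5, 9] <- -5
  m <- torsion_map(g, "b13")
  expect_equal(m$grid[5, 9], 0)
  expect_true(all(m$grid[-((9 - 1) * 36 + 5)] == 5))
  expect_error(torsion_map(matrix(NA_real_, 36, 36), "b13"), "finite")
})

test_that("interpolation hits grid nodes and averages between them", {
  basins <- data.frame(phi0 = -80, psi0 = -120, depth = 6, width = 30)
  m <- make_torsion_map_fixture(basins, "b14", spacing = 10)
  ang <- seq(-180, 170, by = 10)
  set.seed(4)
  for (k in 1:25) {
    i <- sample(36, 1); j <- sample(36, 1)
    expect_equal(map_energy(m, ang[i], ang[j]), m$grid[i, j],
                 tolerance = 1e-12)
  }
  # midpoint of four nodes = mean of the nodes under bilinear interpolation
  expect_equal(map_energy(m, -75, -115),
               mean(m$grid[cbind(c(11, 12, 11, 12), c(7, 7, 8, 8))]),
               tolerance = 1e-12)
})

test_that("the grid is periodic: +180 and -180 give identical energies", {
  m <- default_torsion_maps()$b14
  set.seed(11)
  psi <- runif(50, -180, 180)
  expect_equal(map_energy(m, rep(180, 50), psi),
               map_energy(m, rep(-180, 50), psi), tolerance = 1e-12)
  phi <- runif(50, -180, 180)
  expect_equal(map_energy(m, phi, rep(180, 50)),
               map_energy(m, phi, rep(-180, 50)), tolerance = 1e-12)
  # wrap-around oracle: energy at x equals energy at x +- 360
  x <- runif(20, -180, 180); y <- runif(20, -180, 180)
  expect_equal(map_energy(m, x + 360, y - 360), map_energy(m, x, y),
               tolerance = 1e-12)
})

test_that("map files round-trip and malformed files are rejected", {
  m <- default_torsion_maps(spacing = 20)$b13
  f <- tempfile(fileext = ".dat")
  write_torsion_map(m, f)
  m2 <- read_torsion_map(f)
  expect_equal(m2$grid, m$grid, tolerance = 1e-8)
  expect_identical(m2$linkage, "b13")
  expect_identical(m2$spacing, 20)
  expect_equal(min(m2$grid), 0)

  lines <- readLines(f)
  bad <- tempfile()
  writeLines(c(lines[1:3], "1 2 3", "1 2"), bad)
  expect_error(read_torsion_map(bad), "non-rectangular")
  writeLines(sub("^# convention:.*", "# convention: mystery", lines), bad)
  expect_error(read_torsion_map(bad), "unknown torsion convention")
  unlink(c(f, bad))
})

test_that("conformers at map minima are favored; forced maxima are rejected", {
  maps <- default_torsion_maps()
  s <- parse_glycan("HA8^AN")
  tor <- t(vapply(s$linkages, function(lt) {
    idx <- which(maps[[lt]]$grid == 0, arr.ind = TRUE)[1, ]
    ang <- seq(-180, 170, by = 10)
    c(ang[idx[1]], ang[idx[2]])
  }, numeric(2)))
  good <- classify_linkages(build_conformer(s, tor), maps)
  expect_true(good$accept)
  expect_true(all(good$favored))
  expect_equal(max(good$energies), 0, tolerance = 1e-6)

  # push one linkage to the map maximum
  mx <- which(maps$b13$grid == max(maps$b13$grid), arr.ind = TRUE)[1, ]
  ang <- seq(-180, 170, by = 10)
  tor[1, ] <- c(ang[mx[1]], ang[mx[2]])
  bad <- classify_linkages(build_conformer(s, tor), maps,
                           cutoff = max(maps$b13$grid) - 1)
  expect_false(bad$accept)
  expect_false(bad$favored[1])
})

test_that("classification agrees with a nearest-node oracle away from the cutoff", {
  maps <- default_torsion_maps()
  s <- parse_glycan("HA6^AN")
  ang <- seq(-180, 170, by = 10)
  cutoff <- 4
  set.seed(21)
  checked <- 0
  for (rep in 1:200) {
    tor <- matrix(runif(10, -180, 180), ncol = 2)
    conf <- build_conformer(s, tor)
    verdict <- classify_linkages(conf, maps, cutoff = cutoff)
    # nearest-node oracle with an interpolation tolerance band: skip
    # linkages whose nearest-node energy is within the band of the cutoff
    node_e <- vapply(seq_len(5), function(i) {
      ii <- which.min(abs(wrap_angle(ang - tor[i, 1])))
      jj <- which.min(abs(wrap_angle(ang - tor[i, 2])))
      maps[[s$linkages[i]]]$grid[ii, jj]
    }, numeric(1))
    band <- 1.0   # generous bound on |bilinear - nearest node| at 10 deg
    if (any(abs(node_e - cutoff) < band)) next
    expect_identical(verdict$accept, all(node_e <= cutoff))
    checked <- checked + 1
  }
  expect_gt(checked, 50)
})

test_that("raising the cutoff never turns an accepted model into a rejected one", {
  maps <- default_torsion_maps()
  set.seed(5)
  for (rep in 1:40) {
    conf <- build_conformer("HA5^AA", matrix(runif(8, -180, 180), ncol = 2))
    verdicts <- vapply(c(1, 2, 4, 8, 16),
                       function(ct) classify_linkages(conf, maps, ct)$accept,
                       logical(1))
    expect_true(all(diff(as.integer(verdicts)) >= 0))
  }
  # the map minimum location is favored for any cutoff >= 0
  m <- maps$b13
  idx <- which(m$grid == 0, arr.ind = TRUE)[1, ]
  ang <- seq(-180, 170, by = 10)
  expect_equal(map_energy(m, ang[idx[1]], ang[idx[2]]), 0, tolerance = 1e-12)
})

test_that("convention mismatches are a hard error", {
  maps <- default_torsion_maps()
  maps$b13$convention <- "some other convention"
  conf <- build_conformer("HA4^AN", matrix(-60, 3, 2))
  expect_error(classify_linkages(conf, maps), "convention mismatch")
})

test_that("basin fixture surfaces match the analytic formula", {
  basins <- data.frame(phi0 = c(-80, 60), psi0 = c(-120, 100),
                       depth = c(6, 3), width = c(30, 25))
  m <- make_torsion_map_fixture(basins, "b14", spacing = 5)
  ang <- seq(-180, 175, by = 5)
  raw_min <- min(outer(ang, ang, function(p, q) basin_energy(basins, p, q)))
  set.seed(9)
  for (k in 1:100) {
    i <- sample(length(ang), 1); j <- sample(length(ang), 1)
    expect_equal(m$grid[i, j],
                 basin_energy(basins, ang[i], ang[j]) - raw_min,
                 tolerance = 1e-9)
  }
  # two equal basins give two zero-energy nodes
  eq <- make_torsion_map_fixture(
    data.frame(phi0 = c(-90, 90), psi0 = c(-90, 90),
               depth = c(5, 5), width = c(20, 20)), "b13", spacing = 10)
  expect_equal(sum(abs(eq$grid) < 1e-9), 2)
})
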