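# Shared fixtures, built once per test run.  The receptor fixture and the
# default maps are deterministic, so caching them is safe.

.cache <- new.env(parent = emptyenv())

fixture <- function() {
  if (is.null(.cache$fx)) .cache$fx <- make_receptor_fixture(seed = 1)
  .cache$fx
}

flat_maps <- function() {
  list(b13 = torsion_map(matrix(0, 36, 36), "b13"),
       b14 = torsion_map(matrix(0, 36, 36), "b14"))
}

# independent dihedral computation (textbook atan2 form, coded separately
# from the package's geometry module) used as an oracle in geometry tests
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cx <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cx(b1, b2); n2 <- cx(b2, b3)
  m1 <- cx(n1, b2 / sqrt(sum(b2^2)))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  ((ang + 180) %% 360) - 180
}

# Rodrigues rotation of points about an axis through `origin`, coded
# independently of the package's rotation helper
oracle_rotate <- function(xyz, origin, axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  rel <- sweep(xyz, 2, origin)
  t(apply(rel, 1, function(v) {
    v * cos(th) + c(u[2] * v[3] - u[3] * v[2],
                    u[3] * v[1] - u[1] * v[3],
                    u[1] * v[2] - u[2] * v[1]) * sin(th) +
      u * sum(u * v) * (1 - cos(th))
  })) + matrix(origin, nrow(xyz), 3, byrow = TRUE)
}

# brute-force receptor/ligand clash count: plain double loop
oracle_clash_count <- function(rec, conf, scale = 0.7, exclude = NULL) {
  n <- 0L
  for (i in seq_len(nrow(rec$atoms))) {
    for (j in seq_len(nrow(conf$atoms))) {
      if (!is.null(exclude) &&
          any(exclude[, 1] == i & exclude[, 2] == j)) next
      d <- sqrt(sum((c(rec$atoms$x[i], rec$atoms$y[i], rec$atoms$z[i]) -
                       c(conf$atoms$x[j], conf$atoms$y[j],
                         conf$atoms$z[j]))^2))
      if (d < scale * (rec$atoms$radius[i] + conf$atoms$radius[j]))
        n <- n + 1L
    }
  }
  n
}
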