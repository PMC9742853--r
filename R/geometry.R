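# Internal-coordinate geometry: NeRF atom placement and torsion measurement.
# These primitives underpin the fixture generators and the sidechain builder.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v * v))
unitv <- function(v) v / vnorm(v)

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Natural extension reference frame: place atom D given positions of A, B, C,
# the C-D bond length, the B-C-D angle (deg) and the A-B-C-D torsion (deg).
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- deg2rad(angle); tor <- deg2rad(torsion)
  bc <- unitv(c - b)
  n <- unitv(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Signed dihedral angle A-B-C-D in degrees, in (-180, 180].
dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, unitv(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  ang <- rad2deg(atan2(y, x))
  if (ang <= -180) ang + 360 else ang
}

bond_angle <- function(a, b, c) {
  u <- unitv(a - b); v <- unitv(c - b)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

# Ideal C-beta position from backbone N, CA, C (preserves L-chirality).
ideal_cbeta <- function(n, ca, c) {
  b <- ca - n
  cc <- c - ca
  a <- vcross(b, cc)
  -0.58273431 * a + 0.56802827 * b - 0.54067466 * cc + ca
}

# Deterministic near-uniform unit sphere points (golden-angle spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}
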