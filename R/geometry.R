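# Internal 3-D geometry helpers shared by the fixture builder, the secondary
# structure assigner, the restraint engine and the loop sampler.  All angles
# returned in degrees unless noted.

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## wrap an angle in degrees into (-180, 180]
wrap_deg <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

#' @noRd
angle_deg <- function(a, b, c) {
  u <- unit(a - b)
  v <- unit(c - b)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

#' Dihedral angle a-b-c-d in degrees, IUPAC sign convention.
#' @noRd
dihedral_deg <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, unit(b2))
  rad2deg(atan2(sum(m1 * n2), sum(n1 * n2)))
}

## Rodrigues rotation matrix for angle theta (radians) about unit axis k.
rotation_matrix <- function(axis, theta) {
  k <- unit(axis)
  ct <- cos(theta)
  st <- sin(theta)
  K <- matrix(c(0, k[3L], -k[2L],
                -k[3L], 0, k[1L],
                k[2L], -k[1L], 0), 3L, 3L)
  diag(3L) * ct + st * K + (1 - ct) * (k %o% k)
}

## Rotate rows of matrix `xyz` about the line through `point` with direction
## `axis` by `theta` radians.
rotate_about_axis <- function(xyz, point, axis, theta) {
  R <- rotation_matrix(axis, theta)
  sweep(sweep(xyz, 2L, point) %*% t(R), 2L, point, `+`)
}

#' Place atom D given A, B, C using internal coordinates (NeRF).
#'
#' @param a,b,c positions of the three reference atoms
#' @param bond length C-D in Angstrom
#' @param angle B-C-D in degrees
#' @param torsion A-B-C-D in degrees
#' @noRd
place_atom <- function(a, b, c, bond, angle, torsion) {
  th <- deg2rad(angle)
  ph <- deg2rad(torsion)
  bc <- unit(c - b)
  n <- unit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d_local <- c(-bond * cos(th),
               bond * sin(th) * cos(ph),
               -bond * sin(th) * sin(ph))
  c + bc * d_local[1L] + m * d_local[2L] + n * d_local[3L]
}

## Cyclic-coordinate-descent loop closure.
##
## `coords`: matrix of the mobile atoms (loop backbone plus the rebuilt copy
## of the downstream anchor atoms, which occupy rows `target_rows`).
## `pivots`: list of rotatable bonds, each list(p1 = , p2 = , moved = rows
## rotated when that bond turns).  `targets`: fixed positions the rows in
## `target_rows` should reach.  Returns list(coords, rmsd, iterations).
ccd_close <- function(coords, pivots, target_rows, targets,
                      tol = 0.08, max_iter = 200L) {
  rms <- function(x) sqrt(mean(rowSums((x[target_rows, , drop = FALSE] - targets)^2)))
  it <- 0L
  r <- rms(coords)
  while (r > tol && it < max_iter) {
    for (pv in pivots) {
      p1 <- coords[pv$p1, ]
      ax <- coords[pv$p2, ] - p1
      if (vnorm(ax) < 1e-9) next
      ax <- unit(ax)
      mob <- intersect(pv$moved, target_rows)
      if (!length(mob)) next
      ## closed-form optimal rotation about this bond (Canutescu & Dunbrack)
      aa <- 0; bb <- 0
      for (k in seq_along(target_rows)) {
        row <- target_rows[k]
        if (!(row %in% pv$moved)) next
        m <- coords[row, ] - p1
        t <- targets[k, ] - p1
        m_par <- sum(m * ax) * ax
        r_perp <- m - m_par
        t_perp <- t - m_par
        aa <- aa + sum(r_perp * t_perp)
        bb <- bb + sum(vcross(ax, r_perp) * t_perp)
      }
      if (abs(aa) < 1e-12 && abs(bb) < 1e-12) next
      theta <- atan2(bb, aa)
      coords[pv$moved, ] <- rotate_about_axis(coords[pv$moved, , drop = FALSE],
                                              p1, ax, theta)
    }
    r <- rms(coords)
    it <- it + 1L
  }
  list(coords = coords, rmsd = r, iterations = it)
}
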