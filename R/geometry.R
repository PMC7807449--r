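# Geometry primitives shared by the metrics: minimum-image arithmetic,
# dihedral angles, torsion-driven chain construction, and a periodic 2-D
# Voronoi tessellation built by bisector half-plane clipping.

min_image <- function(d, box) d - box * round(d / box)

# All-pairs minimum-image distances between rows of a (n x k) and b (m x k)
# under periodic box of length k. Returns n x m matrix.
pdist_min_image <- function(a, b, box) {
  n <- nrow(a)
  m <- nrow(b)
  out <- matrix(0, n, m)
  for (k in seq_len(ncol(a))) {
    d <- outer(a[, k], b[, k], "-")
    d <- d - box[k] * round(d / box[k])
    out <- out + d * d
  }
  sqrt(out)
}

# row-wise minimum of a distance matrix without apply() overhead
row_mins <- function(m) {
  out <- m[, 1]
  for (k in seq_len(ncol(m))[-1]) out <- pmin(out, m[, k])
  out
}

cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

unit3 <- function(v) v / sqrt(sum(v * v))

# Torsion angle (degrees, in [-180, 180]) of the path a-b-c-d.
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit3(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# Dihedral angles (degrees) for every consecutive quadruple of rows of a
# coordinate matrix; vectorised over the chain.
chain_dihedrals <- function(xyz) {
  n <- nrow(xyz)
  if (n < 4) return(numeric(0))
  b1 <- xyz[2:(n - 2), , drop = FALSE] - xyz[1:(n - 3), , drop = FALSE]
  b2 <- xyz[3:(n - 1), , drop = FALSE] - xyz[2:(n - 2), , drop = FALSE]
  b3 <- xyz[4:n, , drop = FALSE] - xyz[3:(n - 1), , drop = FALSE]
  cr <- function(u, v) {
    cbind(
      u[, 2] * v[, 3] - u[, 3] * v[, 2],
      u[, 3] * v[, 1] - u[, 1] * v[, 3],
      u[, 1] * v[, 2] - u[, 2] * v[, 1]
    )
  }
  n1 <- cr(b1, b2)
  n2 <- cr(b2, b3)
  b2u <- b2 / sqrt(rowSums(b2^2))
  m1 <- cr(n1, b2u)
  atan2(rowSums(m1 * n2), rowSums(n1 * n2)) * 180 / pi
}

# Natural-extension (NeRF) placement of a linear chain: fixed bond length
# and bond angle, per-step torsions (degrees). Returns an n x 3 matrix
# starting at `origin` extending along `direction`. The torsion of atoms
# (i-3..i) equals torsions[i-3].
build_chain <- function(n, torsions, origin = c(0, 0, 0),
                        direction = c(0, 0, -1),
                        bond = 0.153, angle = 111) {
  stopifnot(n >= 1, length(torsions) >= max(0, n - 3))
  xyz <- matrix(0, n, 3)
  dir1 <- unit3(direction)
  xyz[1, ] <- origin
  if (n == 1) return(xyz)
  xyz[2, ] <- origin + bond * dir1
  if (n == 2) return(xyz)
  # arbitrary perpendicular for the second bond's bend plane
  ref <- if (abs(dir1[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  perp <- unit3(cross3(dir1, ref))
  th <- angle * pi / 180
  bend <- unit3(cross3(perp, dir1))
  xyz[3, ] <- xyz[2, ] + bond * (cos(pi - th) * dir1 + sin(pi - th) * bend)
  if (n == 3) return(xyz)
  for (i in 4:n) {
    a <- xyz[i - 3, ]
    b <- xyz[i - 2, ]
    cc <- xyz[i - 1, ]
    tau <- torsions[i - 3] * pi / 180
    bc <- unit3(cc - b)
    nv <- unit3(cross3(b - a, cc - b))
    mv <- cross3(nv, bc)
    d_local <- c(
      -bond * cos(th),
      bond * sin(th) * cos(tau),
      bond * sin(th) * sin(tau)
    )
    xyz[i, ] <- cc + d_local[1] * bc + d_local[2] * mv + d_local[3] * nv
  }
  xyz
}

# --- periodic 2-D Voronoi tessellation -------------------------------------

# Clip a convex polygon (rows = vertices, counter-clockwise) by the
# half-plane {x : (x - mid) . nrm <= 0}.
clip_halfplane <- function(poly, mid, nrm) {
  f <- (poly[, 1] - mid[1]) * nrm[1] + (poly[, 2] - mid[2]) * nrm[2]
  inside <- f <= 0
  if (all(inside)) return(poly)
  if (!any(inside)) return(poly[0, , drop = FALSE])
  n <- nrow(poly)
  nxt <- c(2:n, 1)
  out <- matrix(NA_real_, n + 4, 2)
  k <- 0L
  for (i in seq_len(n)) {
    j <- nxt[i]
    if (inside[i]) {
      k <- k + 1L
      out[k, ] <- poly[i, ]
    }
    if (inside[i] != inside[j]) {
      t <- f[i] / (f[i] - f[j])
      k <- k + 1L
      out[k, ] <- poly[i, ] + t * (poly[j, ] - poly[i, ])
    }
  }
  out[seq_len(k), , drop = FALSE]
}

polygon_area <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  abs(sum(poly[, 1] * poly[j, 2] - poly[j, 1] * poly[, 2])) / 2
}

#' Periodic Voronoi cell areas in the plane
#'
#' Computes the area of each generator's Voronoi cell under periodic
#' boundary conditions by clipping an initial box-sized polygon with the
#' perpendicular bisectors against all periodic images of the other
#' generators (and the generator's own images). The cell areas of a leaflet
#' tile it exactly, so they sum to the box area.
#'
#' @param points Numeric `n x 2` matrix of generator xy positions (nm).
#' @param box Length-2 numeric, periodic box lengths (nm).
#' @return Numeric vector of cell areas (nm^2), one per generator.
#' @export
voronoi_areas_periodic <- function(points, box) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 1) stop("no generator points", call. = FALSE)
  box <- as.numeric(box)
  offs <- as.matrix(expand.grid(dx = c(-1, 0, 1), dy = c(-1, 0, 1)))
  imgs <- do.call(rbind, lapply(seq_len(nrow(offs)), function(k) {
    cbind(points[, 1] + offs[k, 1] * box[1], points[, 2] + offs[k, 2] * box[2])
  }))
  self_center <- which(offs[, 1] == 0 & offs[, 2] == 0)
  areas <- numeric(n)
  half <- max(box) # generous initial square half-width
  for (i in seq_len(n)) {
    p <- points[i, ]
    poly <- cbind(
      p[1] + c(-half, half, half, -half),
      p[2] + c(-half, -half, half, half)
    )
    d2 <- (imgs[, 1] - p[1])^2 + (imgs[, 2] - p[2])^2
    ord <- order(d2)
    ord <- ord[d2[ord] > 1e-24] # drop the generator itself
    for (j in ord) {
      dj <- sqrt(d2[j])
      # early exit: no further neighbour can cut the polygon
      rmax2 <- max((poly[, 1] - p[1])^2 + (poly[, 2] - p[2])^2)
      if ((dj / 2)^2 > rmax2) break
      q <- imgs[j, ]
      poly <- clip_halfplane(poly, (p + q) / 2, q - p)
      if (nrow(poly) < 3) break
    }
    if (nrow(poly) < 3) {
      stop("degenerate Voronoi cell (collinear or coincident generators)",
        call. = FALSE
      )
    }
    areas[i] <- polygon_area(poly)
  }
  areas
}
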