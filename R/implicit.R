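# Implicit-surface machinery for the parametric bifurcation: each branch is a
# straight-axis canal (distance to the axis minus a radius profile evaluated
# at the foot of the perpendicular), the vessel is their smooth union, and
# the open ends are closed by cap planes. The surface is F(x) = 0 with
# F < 0 inside; a smooth union can never self-intersect.

# distance-to-canal field for a straight branch from `base` along unit `dir`
# of length L with radius profile rfun(s), s = axial coordinate in [0, L]
.canal_field <- function(pts, base, dir, L, rfun) {
  rel <- sweep(pts, 2, base)
  s <- drop(rel %*% dir)
  sc <- pmin(pmax(s, 0), L)
  perp2 <- rowSums(rel^2) - s^2
  dperp <- sqrt(pmax(perp2, 0))
  # off the segment ends, measure from the end disk
  dax <- pmax(s - L, -s, 0)
  sqrt(dperp^2 + dax^2) - rfun(sc)
}

# polynomial smooth minimum with blend width k (k = 0 gives min)
.smin <- function(a, b, k) {
  if (k <= 0) return(pmin(a, b))
  h <- pmax(k - abs(a - b), 0) / k
  pmin(a, b) - h * h * k * 0.25
}

# marching tetrahedra over a box grid; fn takes an N x 3 matrix and returns
# signed values (negative inside). Vertices are optionally projected onto
# fn = 0 by bisection along their grid edge, so vertex positions carry the
# accuracy of the implicit function, not of the grid.
.iso_surface <- function(fn, x, y, z, project = TRUE, bisect_iters = 40L) {
  nx <- length(x); ny <- length(y); nz <- length(z)
  nodes <- as.matrix(expand.grid(x = x, y = y, z = z, KEEP.OUT.ATTRS = FALSE))
  dimnames(nodes) <- NULL
  vals <- fn(nodes)
  stopifnot(length(vals) == nrow(nodes))
  # exact zeros (symmetry-aligned nodes) would put whole tet faces on the
  # iso-level and crack the surface; nudge them to the outside
  vals[vals == 0] <- 1e-12 * max(abs(vals))
  # the iso-surface must not touch the grid boundary (else it cannot close)
  ii <- rep.int(seq_len(nx), ny * nz)
  jj <- rep.int(rep(seq_len(ny), each = nx), nz)
  kk <- rep(seq_len(nz), each = nx * ny)
  bnd <- ii == 1L | ii == nx | jj == 1L | jj == ny | kk == 1L | kk == nz
  if (min(vals[bnd]) < 0) stop("implicit surface reaches the grid boundary; enlarge the box")

  # cell base corners
  ci <- seq_len(nx - 1L); cj <- seq_len(ny - 1L); ck <- seq_len(nz - 1L)
  base <- as.vector(outer(outer(ci, (cj - 1L) * nx, "+"), (ck - 1L) * nx * ny, "+"))
  voff <- c(0L, 1L, nx, nx + 1L, nx * ny, nx * ny + 1L, nx * ny + nx, nx * ny + nx + 1L)
  # Kuhn decomposition: six tets sharing the 0-7 diagonal
  tets <- rbind(c(1L, 2L, 4L, 8L), c(1L, 2L, 6L, 8L), c(1L, 3L, 4L, 8L),
                c(1L, 3L, 7L, 8L), c(1L, 5L, 6L, 8L), c(1L, 5L, 7L, 8L))

  tri_keys <- list(); tri_ref <- list()
  nnodes <- nrow(nodes)
  ekey <- function(a, b) {
    lo <- pmin(a, b); hi <- pmax(a, b)
    (lo - 1) * nnodes + hi        # < 2^53 for any realistic grid
  }
  for (tt in seq_len(nrow(tets))) {
    n1 <- base + voff[tets[tt, 1]]; n2 <- base + voff[tets[tt, 2]]
    n3 <- base + voff[tets[tt, 3]]; n4 <- base + voff[tets[tt, 4]]
    neg <- cbind(vals[n1] < 0, vals[n2] < 0, vals[n3] < 0, vals[n4] < 0)
    code <- neg[, 1] + 2L * neg[, 2] + 4L * neg[, 3] + 8L * neg[, 4]
    act <- which(code > 0L & code < 15L)
    if (length(act) == 0L) next
    nn <- cbind(n1, n2, n3, n4)
    for (cd in sort(unique(code[act]))) {
      rows <- act[code[act] == cd]
      negm <- c(bitwAnd(cd, 1L) > 0, bitwAnd(cd, 2L) > 0,
                bitwAnd(cd, 4L) > 0, bitwAnd(cd, 8L) > 0)
      negi <- which(negm); posi <- which(!negm)
      if (length(negi) == 1L || length(negi) == 3L) {
        apexv <- if (length(negi) == 1L) negi else posi
        others <- setdiff(1:4, apexv)
        va <- nn[rows, apexv]
        k1 <- ekey(va, nn[rows, others[1]])
        k2 <- ekey(va, nn[rows, others[2]])
        k3 <- ekey(va, nn[rows, others[3]])
        tri_keys[[length(tri_keys) + 1L]] <- cbind(k1, k2, k3)
        # inside reference point: a negative vertex (apex if 1-neg, else any)
        refn <- if (length(negi) == 1L) va else nn[rows, negi[1]]
        tri_ref[[length(tri_ref) + 1L]] <- refn
      } else {
        nA <- nn[rows, negi[1]]; nB <- nn[rows, negi[2]]
        pA <- nn[rows, posi[1]]; pB <- nn[rows, posi[2]]
        q11 <- ekey(nA, pA); q12 <- ekey(nA, pB)
        q22 <- ekey(nB, pB); q21 <- ekey(nB, pA)
        tri_keys[[length(tri_keys) + 1L]] <- cbind(q11, q12, q22)
        tri_keys[[length(tri_keys) + 1L]] <- cbind(q11, q22, q21)
        tri_ref[[length(tri_ref) + 1L]] <- nA
        tri_ref[[length(tri_ref) + 1L]] <- nA
      }
    }
  }
  if (length(tri_keys) == 0L) stop("no iso-surface found: check the implicit function")
  K <- do.call(rbind, tri_keys)
  refn <- unlist(tri_ref)

  keys <- sort(unique(as.vector(K)))
  faces <- matrix(match(as.vector(K), keys), ncol = 3)

  # vertex positions on their grid edges
  loN <- (keys - 1) %/% nnodes + 1     # node index of the smaller endpoint
  hiN <- keys - (loN - 1) * nnodes
  # ensure A is the inside endpoint
  swap <- vals[loN] >= 0
  A <- ifelse(swap, hiN, loN); B <- ifelse(swap, loN, hiN)
  PA <- nodes[A, , drop = FALSE]; PB <- nodes[B, , drop = FALSE]
  fA <- vals[A]; fB <- vals[B]
  t <- fA / (fA - fB)
  if (project) {
    tlo <- rep(0, length(keys)); thi <- rep(1, length(keys))
    for (it in seq_len(bisect_iters)) {
      tm <- (tlo + thi) / 2
      fm <- fn(PA + tm * (PB - PA))
      neg <- fm < 0
      tlo[neg] <- tm[neg]; thi[!neg] <- tm[!neg]
    }
    t <- (tlo + thi) / 2
  }
  V <- PA + t * (PB - PA)

  # consistent outward orientation via the per-triangle inside reference
  A3 <- V[faces[, 1], , drop = FALSE]
  B3 <- V[faces[, 2], , drop = FALSE]
  C3 <- V[faces[, 3], , drop = FALSE]
  nrm <- cbind((B3[, 2] - A3[, 2]) * (C3[, 3] - A3[, 3]) -
                 (B3[, 3] - A3[, 3]) * (C3[, 2] - A3[, 2]),
               (B3[, 3] - A3[, 3]) * (C3[, 1] - A3[, 1]) -
                 (B3[, 1] - A3[, 1]) * (C3[, 3] - A3[, 3]),
               (B3[, 1] - A3[, 1]) * (C3[, 2] - A3[, 2]) -
                 (B3[, 2] - A3[, 2]) * (C3[, 1] - A3[, 1]))
  cent <- (A3 + B3 + C3) / 3
  outward <- rowSums(nrm * (cent - nodes[refn, , drop = FALSE])) < 0
  faces[outward, c(2, 3)] <- faces[outward, c(3, 2)]
  nrm[outward, ] <- -nrm[outward, ]
  nl <- sqrt(rowSums(nrm^2))
  degen <- nl < .Machine$double.eps
  if (any(degen)) {
    # zero-area slivers (vertices collapsed onto a near-zero grid node) are
    # kept -- removing faces would open the surface; give them the outward
    # direction of their inside reference point
    dref <- cent[degen, , drop = FALSE] - nodes[refn[degen], , drop = FALSE]
    dl <- sqrt(rowSums(dref^2))
    dl[dl < .Machine$double.xmin] <- 1
    nrm[degen, ] <- dref / dl
    nl[degen] <- 1
  }
  list(vertices = V, faces = faces, normals = nrm / nl)
}

#' Watertightness check for a triangle mesh
#'
#' A closed manifold surface has every undirected edge shared by exactly two
#' faces: no boundary edges, no non-manifold edges.
#'
#' @param mesh list with `vertices` and `faces`.
#' @return list with `watertight` (logical), `n_boundary_edges`,
#'   `n_nonmanifold_edges`.
#' @export
mesh_is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  list(watertight = all(cnt == 2L),
       n_boundary_edges = sum(cnt == 1L),
       n_nonmanifold_edges = sum(cnt > 2L))
}
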