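# P1 finite-element assembly on tetrahedral meshes (shared by the electric,
# thermal and flow solvers).

# Geometric stiffness parts: row/col index vectors and the 16 per-element
# integrals V * (grad phi_i . grad phi_j), so that a stiffness matrix with any
# per-element coefficient is one sparseMatrix() call away.
.stiffness_parts <- function(mesh) {
  el <- mesh$elems; M <- nrow(el)
  gx <- mesh$gx; gy <- mesh$gy; gz <- mesh$gz; v <- mesh$vol
  I <- J <- integer(16 * M); S <- numeric(16 * M)
  k <- 0L
  for (i in 1:4) for (j in 1:4) {
    idx <- k * M + seq_len(M)
    I[idx] <- el[, i]; J[idx] <- el[, j]
    S[idx] <- v * (gx[, i] * gx[, j] + gy[, i] * gy[, j] + gz[, i] * gz[, j])
    k <- k + 1L
  }
  list(I = I, J = J, S = S, M = M, n = max(el))
}

.assemble_from_parts <- function(parts, coef) {
  Matrix::sparseMatrix(i = parts$I, j = parts$J,
                       x = rep.int(coef, 16) * parts$S,
                       dims = c(parts$n, parts$n))
}

# Advection matrix entries int phi_i (w . grad phi_j) with per-element
# velocity w (M x 3) and coefficient (e.g. rho*c), plus optional streamline
# (SUPG-type) stabilization tau * (w.grad phi_i)(w.grad phi_j).
.assemble_advection <- function(mesh, w, coef, stabilize = TRUE) {
  el <- mesh$elems; M <- nrow(el); v <- mesh$vol
  gx <- mesh$gx; gy <- mesh$gy; gz <- mesh$gz
  wg <- matrix(0, M, 4)                 # w . grad phi_j
  for (j in 1:4) wg[, j] <- w[, 1] * gx[, j] + w[, 2] * gy[, j] + w[, 3] * gz[, j]
  sa <- rowSums(abs(wg))                # ~ 2|w|/h
  tau <- ifelse(sa > 0, 1 / sa, 0)
  I <- J <- integer(16 * M); X <- numeric(16 * M)
  k <- 0L
  for (i in 1:4) for (j in 1:4) {
    idx <- k * M + seq_len(M)
    I[idx] <- el[, i]; J[idx] <- el[, j]
    x <- coef * v * wg[, j] / 4
    if (stabilize) x <- x + coef * v * tau * wg[, i] * wg[, j]
    X[idx] <- x
    k <- k + 1L
  }
  n <- max(el)
  Matrix::sparseMatrix(i = I, j = J, x = X, dims = c(n, n))
}

# int phi_i d(phi_j)/d(x_c): pressure-gradient / divergence coupling blocks.
.assemble_gradient <- function(mesh, dim) {
  el <- mesh$elems; M <- nrow(el); v <- mesh$vol
  g <- switch(dim, mesh$gx, mesh$gy, mesh$gz)
  I <- J <- integer(16 * M); X <- numeric(16 * M)
  k <- 0L
  for (i in 1:4) for (j in 1:4) {
    idx <- k * M + seq_len(M)
    I[idx] <- el[, i]; J[idx] <- el[, j]
    X[idx] <- v * g[, j] / 4
    k <- k + 1L
  }
  n <- max(el)
  Matrix::sparseMatrix(i = I, j = J, x = X, dims = c(n, n))
}

# Lumped nodal volumes, optionally restricted to an element subset.
.nodal_volumes <- function(mesh, subset = NULL) {
  el <- mesh$elems; v <- mesh$vol
  if (!is.null(subset)) { el <- el[subset, , drop = FALSE]; v <- v[subset] }
  n <- mesh$n_nodes %||% max(mesh$elems)
  as.numeric(Matrix::sparseMatrix(i = as.vector(el), j = rep(1L, 4 * nrow(el)),
                                  x = rep(v / 4, 4), dims = c(n, 1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Volume-weighted nodal average of an element field, restricted to the
# elements in `subset` (used to nodalise |E| without averaging across
# conductivity jumps).
.nodal_field <- function(mesh, val_elem, subset = NULL) {
  el <- mesh$elems; v <- mesh$vol
  if (!is.null(subset)) { el <- el[subset, , drop = FALSE]; v <- v[subset]
                          val_elem <- val_elem[subset] }
  n <- mesh$n_nodes %||% max(mesh$elems)
  num <- as.numeric(Matrix::sparseMatrix(i = as.vector(el), j = rep(1L, 4 * nrow(el)),
                                         x = rep(v / 4 * val_elem, 4), dims = c(n, 1)))
  den <- as.numeric(Matrix::sparseMatrix(i = as.vector(el), j = rep(1L, 4 * nrow(el)),
                                         x = rep(v / 4, 4), dims = c(n, 1)))
  out <- rep(NA_real_, n)
  ok <- den > 0
  out[ok] <- num[ok] / den[ok]
  out
}

# Gradient of a nodal field, per element (M x 3).
.element_gradient <- function(mesh, u) {
  el <- mesh$elems
  u1 <- u[el[, 1]]; u2 <- u[el[, 2]]; u3 <- u[el[, 3]]; u4 <- u[el[, 4]]
  cbind(mesh$gx[, 1] * u1 + mesh$gx[, 2] * u2 + mesh$gx[, 3] * u3 + mesh$gx[, 4] * u4,
        mesh$gy[, 1] * u1 + mesh$gy[, 2] * u2 + mesh$gy[, 3] * u3 + mesh$gy[, 4] * u4,
        mesh$gz[, 1] * u1 + mesh$gz[, 2] * u2 + mesh$gz[, 3] * u3 + mesh$gz[, 4] * u4)
}

# Dirichlet elimination solve: K x = rhs with x[fixed] = vals.
# `cache` is an environment used to re-use the symbolic Cholesky factor across
# repeated solves with an identical sparsity pattern.
.dirichlet_solve <- function(K, rhs, fixed, vals, cache = NULL) {
  n <- nrow(K)
  free <- setdiff(seq_len(n), fixed)
  xd <- numeric(n); xd[fixed] <- vals
  b <- rhs[free] - as.numeric(K[free, fixed, drop = FALSE] %*% vals)
  Kff <- K[free, free]
  Kff <- Matrix::forceSymmetric(Kff)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  if (is.null(cache$chol)) cache$chol <- Matrix::Cholesky(Kff, LDL = FALSE)
  else cache$chol <- Matrix::update(cache$chol, Kff)
  xf <- as.numeric(Matrix::solve(cache$chol, b))
  xd[free] <- xf
  xd
}

# Boundary faces of a set of tets: triangles occurring exactly once, with the
# owner element index.
.boundary_faces <- function(elems) {
  M <- nrow(elems)
  fi <- rbind(elems[, c(1, 2, 3)], elems[, c(1, 2, 4)],
              elems[, c(1, 3, 4)], elems[, c(2, 3, 4)])
  owner <- rep(seq_len(M), 4)
  fs <- t(apply(fi, 1, sort))
  key <- paste(fs[, 1], fs[, 2], fs[, 3])
  cnt <- table(key)
  once <- names(cnt)[cnt == 1]
  keep <- key %in% once
  list(faces = fi[keep, , drop = FALSE], owner = owner[keep])
}

# Areas and outward unit normals of boundary faces (outward w.r.t. the owner
# element).
.face_geometry <- function(nodes, faces, owner, elems) {
  p1 <- nodes[faces[, 1], , drop = FALSE]
  p2 <- nodes[faces[, 2], , drop = FALSE]
  p3 <- nodes[faces[, 3], , drop = FALSE]
  e1 <- p2 - p1; e2 <- p3 - p1
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  A2 <- sqrt(nx^2 + ny^2 + nz^2)
  nrm <- cbind(nx, ny, nz) / A2
  # orient outward: flip if pointing toward the opposite vertex of the owner tet
  ctr <- (p1 + p2 + p3) / 3
  opp <- matrix(0, nrow(faces), 3)
  for (r in seq_len(nrow(faces))) {
    vids <- setdiff(elems[owner[r], ], faces[r, ])
    opp[r, ] <- nodes[vids[1], ]
  }
  flip <- rowSums(nrm * (opp - ctr)) > 0
  nrm[flip, ] <- -nrm[flip, ]
  list(area = A2 / 2, normal = nrm, centroid = ctr)
}
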