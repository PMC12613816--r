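# Rigid-body geometry used by overlay, screening and the generators.

# Least-squares rigid superposition (Kabsch). P, Q: n x 3 matrices.
# Returns rotation R and translation t with fitted = P %*% R + t
# (row-vector convention), plus the post-fit RMSD.
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3L)
  pc <- colMeans(P); qc <- colMeans(Q)
  Pc <- sweep(P, 2, pc); Qc <- sweep(Q, 2, qc)
  A <- crossprod(Pc, Qc)
  sv <- svd(A)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  t <- qc - as.numeric(pc %*% R)
  fitted <- sweep(P %*% R, 2, t, "+")
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(R = R, t = t, rmsd = rmsd, fitted = fitted)
}

# Degeneracy check: points effectively collinear (rank < 2 after
# centering) leave the rotation under-determined.
isCollinear <- function(P, tol = 1e-8) {
  Pc <- sweep(as.matrix(P), 2, colMeans(P))
  sv <- svd(Pc, nu = 0, nv = 0)
  sv$d[2] <= tol * max(sv$d[1], 1)
}

applyRigid <- function(P, R, t) sweep(as.matrix(P) %*% R, 2, t, "+")

# Uniform random rotation matrix (QR of a Gaussian matrix, det +1).
randomRotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qr_)
  R <- R %*% diag(sign(diag(qr.R(qr_))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

vecNorm <- function(v) sqrt(sum(v^2))

unitVec <- function(v) {
  n <- vecNorm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

# Best-fit plane normal of a point set (smallest principal axis).
planeNormal <- function(P) {
  Pc <- sweep(as.matrix(P), 2, colMeans(P))
  sv <- svd(Pc, nu = 0)
  sv$v[, 3]
}

# Angle between two vectors in degrees, in [0, 180].
vecAngle <- function(a, b) {
  ca <- sum(a * b) / (vecNorm(a) * vecNorm(b))
  acos(pmin(1, pmax(-1, ca))) * 180 / pi
}

# All pairwise distances between row sets A (n x 3) and B (m x 3).
crossDist <- function(A, B) {
  A <- matrix(as.numeric(as.matrix(A)), ncol = 3)
  B <- matrix(as.numeric(as.matrix(B)), ncol = 3)
  sqrt(pmax(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B),
            0))
}
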