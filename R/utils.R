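# Small numerical helpers shared across modules.

#' Cross product of two 3-vectors
#' @param a,b numeric 3-vectors
#' @return numeric 3-vector `a x b`
#' @keywords internal
cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Skew-symmetric (cross-product) matrix of a 3-vector
#' @param v numeric 3-vector
#' @return 3x3 matrix `S` with `S %*% x == v x x`
#' @keywords internal
skew3 <- function(v) {
  matrix(c(0, v[3L], -v[2L],
           -v[3L], 0, v[1L],
           v[2L], -v[1L], 0), 3L, 3L)
}

# Elementary rotation matrices (radians).
rot_x <- function(a) {
  c_ <- cos(a); s_ <- sin(a)
  matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3L, 3L)
}
rot_y <- function(a) {
  c_ <- cos(a); s_ <- sin(a)
  matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3L, 3L)
}
rot_z <- function(a) {
  c_ <- cos(a); s_ <- sin(a)
  matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3L, 3L)
}

#' Rotation about an arbitrary unit axis (Rodrigues)
#' @keywords internal
rot_axis <- function(axis, a) {
  K <- skew3(axis)
  diag(3L) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

#' Intrinsic XYZ Euler rotation
#' @param e numeric 3-vector of angles, radians
#' @keywords internal
rot_xyz <- function(e) rot_x(e[1L]) %*% rot_y(e[2L]) %*% rot_z(e[3L])

#' Rigid (orthogonal Procrustes / Kabsch) alignment
#'
#' Finds rotation `R` and translation `t` minimizing `sum ||R a_i + t - b_i||^2`.
#'
#' @param A,B 3 x n matrices of paired points (columns)
#' @param w optional weights per point
#' @return list with `R` (3x3, proper rotation) and `t` (3-vector)
#' @keywords internal
procrustes_fit <- function(A, B, w = NULL) {
  n <- ncol(A)
  if (is.null(w)) w <- rep(1, n)
  w <- w / sum(w)
  ca <- drop(A %*% w)
  cb <- drop(B %*% w)
  Ac <- A - ca
  Bc <- B - cb
  H <- (Ac * rep(w, each = 3L)) %*% t(Bc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  list(R = R, t = cb - drop(R %*% ca))
}

#' Moore-Penrose pseudo-inverse solve via SVD
#'
#' Minimum-norm least squares solution of `A x = y`.
#' @keywords internal
pinv_solve <- function(A, y, tol = 1e-12) {
  sv <- svd(A)
  d <- sv$d
  keep <- d > tol * max(d)
  drop(sv$v[, keep, drop = FALSE] %*%
         ((t(sv$u[, keep, drop = FALSE]) %*% y) / d[keep]))
}

#' Central finite differences of a trajectory
#'
#' First and second time derivatives of a T x n matrix, central in the
#' interior, one-sided (first order) at the two endpoint frames.
#'
#' @param x T x n matrix
#' @param dt time step, seconds
#' @return list with `d1` and `d2`, both T x n
#' @keywords internal
traj_derivatives <- function(x, dt) {
  x <- as.matrix(x)
  T_ <- nrow(x)
  stopifnot(T_ >= 3L)
  d1 <- x * 0
  d2 <- x * 0
  i <- 2:(T_ - 1L)
  d1[i, ] <- (x[i + 1L, , drop = FALSE] - x[i - 1L, , drop = FALSE]) / (2 * dt)
  d2[i, ] <- (x[i + 1L, , drop = FALSE] - 2 * x[i, , drop = FALSE] +
                x[i - 1L, , drop = FALSE]) / dt^2
  d1[1L, ] <- (x[2L, ] - x[1L, ]) / dt
  d1[T_, ] <- (x[T_, ] - x[T_ - 1L, ]) / dt
  d2[1L, ] <- d2[2L, ]
  d2[T_, ] <- d2[T_ - 1L, ]
  list(d1 = d1, d2 = d2)
}

#' Smoothstep weight (C1), 0 below `a`, 1 above `b`
#' @keywords internal
smoothstep <- function(x, a, b) {
  t <- pmin(pmax((x - a) / (b - a), 0), 1)
  t * t * (3 - 2 * t)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Wrap a function returning list(value, grad) for optimizers that call
# fn and gr separately at the same point.
cache_fn_gr <- function(fg) {
  last_x <- NULL; last <- NULL
  ev <- function(x) {
    if (is.null(last_x) || !identical(x, last_x)) {
      last <<- fg(x); last_x <<- x
    }
    last
  }
  list(fn = function(x) ev(x)$value, gr = function(x) ev(x)$grad)
}
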