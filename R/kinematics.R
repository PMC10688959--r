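# Forward kinematics and analytic Jacobians.
#
# The compiled skeleton is a chain of elementary 1-DOF elements; FK runs a
# single pass over them, tracking each element's world rotation, origin and
# the world direction of its DOF axis.  Marker positions are the segment
# frame applied to the elementwise-scaled local offset s (.) p.

# Full FK pass.  Returns, for every element: world rotation R (3x3xE),
# origin x (3xE, the point the DOF acts through), world DOF axis w (3xE);
# and for every segment: frame rotation Rseg, origin xseg; plus marker
# world positions (3xM).
forward_kinematics_full <- function(skel, q) {
  cmp <- skel$cmp
  if (length(q) != cmp$nq)
    stop("pose dimension ", length(q), " does not match skeleton (",
         cmp$nq, ")")
  E <- cmp$E
  R <- array(0, c(3L, 3L, E))
  x <- matrix(0, 3L, E)
  w <- matrix(0, 3L, E)
  sc <- skel$scales
  tpre <- cmp$tpre; tpre_seg <- cmp$tpre_seg
  post <- cmp$post; post_seg <- cmp$post_seg
  type <- cmp$type; axis <- cmp$axis; parent <- cmp$parent
  for (e in seq_len(E)) {
    p <- parent[e]
    if (p == 0L) { Rp <- diag(3L); xp <- c(0, 0, 0) }
    else {
      Rp <- R[, , p]
      xp <- x[, p]
      ps <- post_seg[p]
      if (ps > 0L) xp <- xp + Rp %*% (post[, p] * sc[, ps])
    }
    t <- tpre[, e]
    if (tpre_seg[e] > 0L) t <- t * sc[, tpre_seg[e]]
    a <- axis[, e]
    if (type[e] == "p") {
      x[, e] <- xp + Rp %*% (t + a * q[e])
      R[, , e] <- Rp
    } else {
      x[, e] <- xp + Rp %*% t
      R[, , e] <- Rp %*% rot_for_axis(a, q[e])
    }
    w[, e] <- Rp %*% a
  }
  S <- cmp$S
  xseg <- matrix(0, 3L, S)
  Rseg <- array(0, c(3L, 3L, S))
  M <- cmp$n_markers
  markers <- matrix(0, 3L, M)
  for (s in seq_len(S)) {
    e <- cmp$seg_elem[s]
    Re <- R[, , e]
    Rseg[, , s] <- Re
    xs <- x[, e]
    if (post_seg[e] == s) xs <- xs + drop(Re %*% (post[, e] * sc[, s]))
    xseg[, s] <- xs
    mi <- cmp$seg_marker_idx[[s]]
    if (length(mi))
      markers[, mi] <- (Re %*% (cmp$marker_off[, mi, drop = FALSE] *
                                  sc[, s])) + xs
  }
  list(R = R, x = x, w = w, xseg = xseg, Rseg = Rseg, markers = markers)
}

# J^T r accumulators computed without materializing the Jacobians.
# rmat: 3 x M residual matrix with zero columns for invisible markers.
# Returns the pullbacks of the stacked marker residual onto q, s, p.
marker_pullback <- function(skel, fk, rmat, wrt = c("q", "s", "p")) {
  cmp <- skel$cmp
  E <- cmp$E
  # subtree sums: S_e = sum of residuals of markers at or below elem e,
  # X_e = sum of marker_pos x residual (for rotational columns)
  Sr <- matrix(0, 3L, E)
  Xr <- matrix(0, 3L, E)
  need_q <- "q" %in% wrt
  for (s in seq_len(cmp$S)) {
    mi <- cmp$seg_marker_idx[[s]]
    if (!length(mi)) next
    e <- cmp$seg_elem[s]
    rs <- rmat[, mi, drop = FALSE]
    Sr[, e] <- Sr[, e] + rowSums(rs)
    if (need_q) {
      mp <- fk$markers[, mi, drop = FALSE]
      Xr[1L, e] <- Xr[1L, e] + sum(mp[2L, ] * rs[3L, ] - mp[3L, ] * rs[2L, ])
      Xr[2L, e] <- Xr[2L, e] + sum(mp[3L, ] * rs[1L, ] - mp[1L, ] * rs[3L, ])
      Xr[3L, e] <- Xr[3L, e] + sum(mp[1L, ] * rs[2L, ] - mp[2L, ] * rs[1L, ])
    }
  }
  for (e in rev(seq_len(E))) {
    p <- cmp$parent[e]
    if (p > 0L) {
      Sr[, p] <- Sr[, p] + Sr[, e]
      if (need_q) Xr[, p] <- Xr[, p] + Xr[, e]
    }
  }
  out <- list()
  if (need_q) {
    gq <- numeric(E)
    for (e in seq_len(E)) {
      w <- fk$w[, e]
      if (cmp$type[e] == "p") gq[e] <- sum(w * Sr[, e])
      else gq[e] <- sum(w * (Xr[, e] - cross3(fk$x[, e], Sr[, e])))
    }
    out$q <- gq
  }
  if ("s" %in% wrt) {
    gs <- matrix(0, 3L, cmp$S)
    for (e in seq_len(E)) {
      ts <- cmp$tpre_seg[e]
      if (ts > 0L) {
        p <- cmp$parent[e]
        Rp <- if (p == 0L) diag(3L) else fk$R[, , p]
        gs[, ts] <- gs[, ts] + cmp$tpre[, e] * drop(crossprod(Rp, Sr[, e]))
      }
      ps <- cmp$post_seg[e]
      if (ps > 0L)
        gs[, ps] <- gs[, ps] +
          cmp$post[, e] * drop(crossprod(fk$R[, , e], Sr[, e]))
    }
    for (s in seq_len(cmp$S)) {
      mi <- cmp$seg_marker_idx[[s]]
      if (!length(mi)) next
      gs[, s] <- gs[, s] + rowSums(
        cmp$marker_off[, mi, drop = FALSE] *
          crossprod(fk$Rseg[, , s], rmat[, mi, drop = FALSE]))
    }
    out$s <- as.numeric(gs)
  }
  if ("p" %in% wrt) {
    gp <- matrix(0, 3L, cmp$n_markers)
    for (s in seq_len(cmp$S)) {
      mi <- cmp$seg_marker_idx[[s]]
      if (!length(mi)) next
      gp[, mi] <- skel$scales[, s] *
        crossprod(fk$Rseg[, , s], rmat[, mi, drop = FALSE])
    }
    out$p <- as.numeric(gp)
  }
  out
}

post_vec <- function(cmp, sc, e, Re) {
  ps <- cmp$post_seg[e]
  if (ps == 0L) return(c(0, 0, 0))
  drop(Re %*% (cmp$post[, e] * sc[, ps]))
}

rot_for_axis <- function(a, q) {
  if (a[1L] == 1 && a[2L] == 0 && a[3L] == 0) return(rot_x(q))
  if (a[2L] == 1 && a[1L] == 0 && a[3L] == 0) return(rot_y(q))
  if (a[3L] == 1 && a[1L] == 0 && a[2L] == 0) return(rot_z(q))
  rot_axis(a, q)
}

#' Forward kinematics: world marker positions
#'
#' Transforms every marker's scaled local offset through the joint chain at
#' pose `q`.
#'
#' @param skel a `bm_skeleton`
#' @param q generalized coordinate vector (length `n_dof(skel)`)
#' @return 3 x M matrix of world marker positions (columns named by label)
#' @export
forward_kinematics <- function(skel, q) {
  fk <- forward_kinematics_full(skel, q)
  colnames(fk$markers) <- skel$cmp$marker_lab
  fk$markers
}

#' Analytic marker Jacobians
#'
#' Partial derivatives of all stacked world marker positions (3M rows,
#' ordered x,y,z per marker) with respect to the generalized coordinates
#' `q`, the per-axis segment scales `s` (column-major over the 3 x S scale
#' matrix) and the local marker offsets `p` (column-major over 3 x M).
#'
#' @param skel a `bm_skeleton`
#' @param q generalized coordinates
#' @param fk optional precomputed result of `forward_kinematics_full`
#' @param wrt character subset of `c("q", "s", "p")`
#' @return list with matrices `Jq` (3M x nq), `Js` (3M x 3S), `Jp`
#'   (3M x 3M, block diagonal), any subset per `wrt`
#' @export
marker_jacobians <- function(skel, q, fk = NULL,
                             wrt = c("q", "s", "p")) {
  cmp <- skel$cmp
  if (is.null(fk)) fk <- forward_kinematics_full(skel, q)
  M <- cmp$n_markers
  out <- list()
  rows3 <- function(i) (3L * (i - 1L) + 1L):(3L * i)

  if ("q" %in% wrt) {
    Jq <- matrix(0, 3L * M, cmp$nq)
    for (e in seq_len(cmp$E)) {
      ms <- which(cmp$anc[e, cmp$marker_seg])
      if (!length(ms)) next
      w <- fk$w[, e]
      idx <- rep(3L * (ms - 1L), each = 3L) + 1:3
      if (cmp$type[e] == "p") {
        Jq[idx, e] <- w
      } else {
        D <- fk$markers[, ms, drop = FALSE] - fk$x[, e]
        Jq[idx, e] <- rbind(w[2L] * D[3L, ] - w[3L] * D[2L, ],
                            w[3L] * D[1L, ] - w[1L] * D[3L, ],
                            w[1L] * D[2L, ] - w[2L] * D[1L, ])
      }
    }
    out$Jq <- Jq
  }

  if ("s" %in% wrt) {
    # every scaled translation on the path contributes R_frame %*% e_k * len_k
    Js <- matrix(0, 3L * M, 3L * cmp$S)
    scol <- function(s, k) 3L * (s - 1L) + k
    for (e in seq_len(cmp$E)) {
      ms <- which(cmp$anc[e, cmp$marker_seg])
      if (!length(ms)) next
      ts <- cmp$tpre_seg[e]
      if (ts > 0L && any(cmp$tpre[, e] != 0)) {
        p <- cmp$parent[e]
        Rp <- if (p == 0L) diag(3L) else fk$R[, , p]
        for (k in 1:3) {
          if (cmp$tpre[k, e] == 0) next
          v <- Rp[, k] * cmp$tpre[k, e]
          for (i in ms) Js[rows3(i), scol(ts, k)] <-
              Js[rows3(i), scol(ts, k)] + v
        }
      }
      ps <- cmp$post_seg[e]
      if (ps > 0L && any(cmp$post[, e] != 0)) {
        # post translation moves the child segment frame and everything below
        ms2 <- which(cmp$anc[e, cmp$marker_seg])
        for (k in 1:3) {
          if (cmp$post[k, e] == 0) next
          v <- fk$R[, k, e] * cmp$post[k, e]
          for (i in ms2) Js[rows3(i), scol(ps, k)] <-
              Js[rows3(i), scol(ps, k)] + v
        }
      }
    }
    for (i in seq_len(M)) {
      s <- cmp$marker_seg[i]
      for (k in 1:3) Js[rows3(i), scol(s, k)] <-
          Js[rows3(i), scol(s, k)] + fk$Rseg[, k, s] * cmp$marker_off[k, i]
    }
    out$Js <- Js
  }

  if ("p" %in% wrt) {
    Jp <- matrix(0, 3L * M, 3L * M)
    for (i in seq_len(M)) {
      s <- cmp$marker_seg[i]
      Jp[rows3(i), rows3(i)] <-
        fk$Rseg[, , s] %*% diag(skel$scales[, s], 3L)
    }
    out$Jp <- Jp
  }
  out
}

# world COM of each segment (3 x S) given an FK pass
segment_coms <- function(skel, fk) {
  cmp <- skel$cmp
  out <- matrix(0, 3L, cmp$S)
  for (s in seq_len(cmp$S))
    out[, s] <- fk$xseg[, s] +
      fk$Rseg[, , s] %*% (skel$scales[, s] * cmp$com_local[, s])
  out
}

#' Whole-body center of mass
#'
#' Mass-weighted mean of the scaled segment COM positions.
#'
#' @param skel a `bm_skeleton`
#' @param q generalized coordinates (or a T x nq matrix for a trajectory)
#' @return 3-vector (or T x 3 matrix), meters
#' @export
com_position <- function(skel, q) {
  if (is.matrix(q)) {
    out <- t(apply(q, 1L, function(qt) com_position(skel, qt)))
    return(out)
  }
  fk <- forward_kinematics_full(skel, q)
  m <- skel$segment_masses
  drop(segment_coms(skel, fk) %*% (m / sum(m)))
}
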