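# Morphological skeleton (Zhang-Suen thinning) and skeleton path length.
# Hand-written because the imaging stack used elsewhere in the package offers
# erosion/dilation but no homotopic thinning.

shift_mat <- function(m, dx, dy) {
  n <- matrix(FALSE, nrow(m), ncol(m))
  xs <- seq_len(nrow(m)); ys <- seq_len(ncol(m))
  xs_src <- xs - dx; ys_src <- ys - dy
  okx <- xs_src >= 1 & xs_src <= nrow(m)
  oky <- ys_src >= 1 & ys_src <= ncol(m)
  n[xs[okx], ys[oky]] <- m[xs_src[okx], ys_src[oky]]
  n
}

# Zhang-Suen thinning of a logical matrix; returns a 1-px-wide skeleton.
skeletonize <- function(mask) {
  m <- mask
  # neighbour offsets in the P2..P9 clockwise order (N, NE, E, SE, S, SW, W, NW)
  offs <- list(c(0, -1), c(1, -1), c(1, 0), c(1, 1),
               c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      nb <- lapply(offs, function(o) shift_mat(m, o[1], o[2]))
      B <- Reduce(`+`, nb)
      seq9 <- c(nb, nb[1])
      A <- Reduce(`+`, lapply(1:8, function(i) !seq9[[i]] & seq9[[i + 1]]))
      if (step == 1) {
        cond <- !(nb[[1]] & nb[[3]] & nb[[5]]) & !(nb[[3]] & nb[[5]] & nb[[7]])
      } else {
        cond <- !(nb[[1]] & nb[[3]] & nb[[7]]) & !(nb[[1]] & nb[[5]] & nb[[7]])
      }
      del <- m & B >= 2 & B <= 6 & A == 1 & cond
      if (any(del)) { m[del] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

# Path length of a skeleton in pixel units: orthogonal links count 1,
# diagonal links sqrt(2), skipping diagonals bridged by an orthogonal pixel.
skeleton_length_px <- function(skel) {
  if (!any(skel)) return(0)
  right <- skel & shift_mat(skel, -1, 0)
  down <- skel & shift_mat(skel, 0, -1)
  o <- sum(right) + sum(down)
  dr <- skel & shift_mat(skel, -1, -1)   # neighbour at (+1,+1)
  dl <- skel & shift_mat(skel, 1, -1)    # neighbour at (-1,+1)
  # drop diagonals whose two endpoints share an orthogonal skeleton neighbour
  dr_bridged <- dr & (shift_mat(skel, -1, 0) | shift_mat(skel, 0, -1))
  dl_bridged <- dl & (shift_mat(skel, 1, 0) | shift_mat(skel, 0, -1))
  d <- sum(dr & !dr_bridged) + sum(dl & !dl_bridged)
  o + sqrt(2) * d
}

# Skeleton length of one labelled object, computed on its padded bounding box.
object_skeleton_length <- function(label_img, k) {
  w <- which(label_img == k, arr.ind = TRUE)
  if (nrow(w) == 0) return(0)
  xr <- max(1L, min(w[, 1]) - 1L):min(nrow(label_img), max(w[, 1]) + 1L)
  yr <- max(1L, min(w[, 2]) - 1L):min(ncol(label_img), max(w[, 2]) + 1L)
  crop <- label_img[xr, yr, drop = FALSE] == k
  skeleton_length_px(skeletonize(crop))
}
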