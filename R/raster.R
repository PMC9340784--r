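# Internal raster primitives: superellipse/ellipse rasterisation, 8-connected
# component labeling (raster-order labels), morphology wrappers and the
# 4-direction Crofton perimeter estimator.

# Squircle (superellipse, exponent 4) membership on the pixel grid.
# a, b are the semi-axes in pixels; centre defaults to the frame centre.
squircle_mask <- function(h, w, a, b, center = c((h + 1) / 2, (w + 1) / 2),
                          exponent = 4) {
  dy <- abs(seq_len(h) - center[1]) / b
  dx <- abs(seq_len(w) - center[2]) / a
  outer(dy^exponent, dx^exponent, `+`) <= 1
}

# Squircle area constant: area = k * a * b for exponent 4.
SQUIRCLE_K <- 4 * gamma(1.25)^2 / gamma(1.5)

# Linear (column-major) pixel indices of a rotated ellipse, clipped to frame.
ellipse_indices <- function(h, w, cy, cx, a, b, angle) {
  r <- ceiling(max(a, b)) + 1L
  rows <- max(1L, floor(cy - r)):min(h, ceiling(cy + r))
  cols <- max(1L, floor(cx - r)):min(w, ceiling(cx + r))
  if (!length(rows) || !length(cols)) return(integer(0))
  dy <- rows - cy
  dx <- cols - cx
  ca <- cos(angle); sa <- sin(angle)
  # u along semi-major a, v along semi-minor b
  u <- outer(dy * sa, dx * ca, `+`)
  v <- outer(dy * ca, dx * -sa, `+`)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  ij <- which(inside, arr.ind = TRUE)
  (cols[ij[, 2]] - 1L) * h + rows[ij[, 1]]
}

# 8-connected components, labeled 1..n in raster (row-major) order of each
# component's first pixel. Returns an integer matrix.
label_components8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  fg <- which(mask)
  if (!length(fg)) return(lab)
  rr <- ((fg - 1L) %% h) + 1L
  cc <- ((fg - 1L) %/% h) + 1L
  seeds <- fg[order(rr, cc)]  # row-major scan order
  nxt <- 0L
  for (s in seeds) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    lab[s] <- nxt
    frontier <- s
    while (length(frontier)) {
      fr <- ((frontier - 1L) %% h) + 1L
      fc <- ((frontier - 1L) %/% h) + 1L
      nb <- integer(0)
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        ok <- fr + dr >= 1L & fr + dr <= h & fc + dc >= 1L & fc + dc <= w
        if (any(ok)) nb <- c(nb, (fc[ok] + dc - 1L) * h + fr[ok] + dr)
      }
      nb <- unique(nb[mask[nb] & lab[nb] == 0L])
      lab[nb] <- nxt
      frontier <- nb
    }
  }
  lab
}

# 4-direction Crofton perimeter of a logical matrix (all foreground at once
# would merge regions; call per region). Counts boundary crossings along the
# horizontal, vertical and both diagonal line families of the pixel lattice:
#   P = pi/8 * (c0 + c90 + (c45 + c135) / sqrt(2))
crofton_perimeter <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  m <- matrix(FALSE, h + 2L, w + 2L)
  m[2:(h + 1L), 2:(w + 1L)] <- mask
  c0   <- sum(m[, -1] != m[, -ncol(m)])                    # along rows
  c90  <- sum(m[-1, ] != m[-nrow(m), ])                    # along columns
  c45  <- sum(m[-1, -1] != m[-nrow(m), -ncol(m)])          # "\" diagonal
  c135 <- sum(m[-1, -ncol(m)] != m[-nrow(m), -1])          # "/" diagonal
  pi / 8 * (c0 + c90 + (c45 + c135) / sqrt(2))
}

# Morphological closing with a disc brush of the given radius, then optional
# hole filling; operates on and returns logical matrices (EBImage backend).
close_and_fill <- function(mask, radius = 2, fill = TRUE) {
  if (radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
    mask <- EBImage::closing(mask * 1, brush)
  }
  if (fill) mask <- EBImage::fillHull(mask * 1)
  matrix(as.logical(as.numeric(mask) > 0.5), nrow(mask), ncol(mask))
}

# Drop 8-connected components smaller than min_px; returns list(mask, n_dropped,
# px_dropped).
drop_small_components <- function(mask, min_px) {
  if (min_px <= 1 || !any(mask)) {
    return(list(mask = mask, n_dropped = 0L, px_dropped = 0L))
  }
  lab <- label_components8(mask)
  sizes <- tabulate(lab[lab > 0L])
  small <- which(sizes < min_px)
  mask[lab %in% small] <- FALSE
  list(mask = mask, n_dropped = length(small),
       px_dropped = sum(sizes[small]))
}

jaccard <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
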