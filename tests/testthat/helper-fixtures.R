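# Shared fixture builders; everything is generated in code.

# Intensity frame from a matrix of 0-255 values.
fr <- function(m, scale = 1) field_frame(m, scale = scale)

# Binary mask with filled disks of radius `r` at the given 0-based centres.
disk_mask <- function(width, height, centres, r) {
  m <- matrix(FALSE, height, width)
  for (i in seq_len(nrow(centres))) {
    cx <- centres[i, 1]; cy <- centres[i, 2]
    for (x in max(0, floor(cx - r)):min(width - 1, ceiling(cx + r))) {
      for (y in max(0, floor(cy - r)):min(height - 1, ceiling(cy + r))) {
        if ((x - cx)^2 + (y - cy)^2 <= r^2) m[y + 1, x + 1] <- TRUE
      }
    }
  }
  m
}

# Independent brute-force neighbourhood counter: per-pixel vectorised
# distance test over all particles (a different computation path from
# the per-particle bounding-box used by local_counts()).
brute_local_counts <- function(ps, R) {
  w <- attr(ps, "width"); h <- attr(ps, "height")
  if (nrow(ps) == 0) return(matrix(0L, h, w))
  px <- rep(0:(w - 1), each = h)
  py <- rep(0:(h - 1), times = w)
  d2 <- outer(px, ps$x_px, `-`)^2 + outer(py, ps$y_px, `-`)^2
  matrix(as.integer(rowSums(d2 <= R^2)), h, w)
}

# Independent rasterised in-bounds fraction of the R-circle at one pixel.
brute_fraction <- function(x, y, width, height, R) {
  off <- expand.grid(dx = -floor(R):floor(R), dy = -floor(R):floor(R))
  off <- off[off$dx^2 + off$dy^2 <= R^2, ]
  inb <- (x + off$dx) >= 0 & (x + off$dx) < width &
         (y + off$dy) >= 0 & (y + off$dy) < height
  mean(inb)
}

# Nearest-truth subtype recovery for a classified stained field.
stain_recovery <- function(cells, truth) {
  stopifnot(nrow(cells) > 0)
  idx <- vapply(seq_len(nrow(cells)), function(i) {
    which.min((truth$x_px - cells$x_px[i])^2 + (truth$y_px - cells$y_px[i])^2)
  }, integer(1))
  mean(cells$subtype == truth$subtype[idx])
}
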