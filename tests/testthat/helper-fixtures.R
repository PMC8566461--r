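# Shared fixtures and independent oracles.

# concentric circular ROI (cell radius rc, nucleus rn) centered at `c0`
disc_roi <- function(rc = 100, rn = 30, c0 = c(rc + 10, rc + 10)) {
  cell_roi(circle_polygon(rc, c0), circle_polygon(rn, c0))
}

# radial distance of every pixel center from a point, as a matrix
pixel_radius <- function(width, height, center) {
  xs <- matrix(rep(seq_len(width) - 0.5, each = height), height, width)
  ys <- matrix(rep(seq_len(height) - 0.5, times = width), height, width)
  sqrt((xs - center[1])^2 + (ys - center[2])^2)
}

iou <- function(a, b) sum(a & b) / sum(a | b)

# independent Manders oracle: explicit double loop over pixels
manders_bruteforce <- function(ch1, ch2, mask, t1, t2, mode) {
  num1 <- den1 <- num2 <- den2 <- 0
  for (r in seq_len(nrow(ch1))) for (c in seq_len(ncol(ch1))) {
    if (!mask[r, c]) next
    a <- ch1[r, c]; b <- ch2[r, c]
    w1 <- if (mode == "pixel-count") 1 else a
    w2 <- if (mode == "pixel-count") 1 else b
    if (a > t1) { den1 <- den1 + w1; if (b > t2) num1 <- num1 + w1 }
    if (b > t2) { den2 <- den2 + w2; if (a > t1) num2 <- num2 + w2 }
  }
  c(m1 = num1 / den1, m2 = num2 / den2)
}

# closed-form mean step length of directed 2D motion with isotropic
# Gaussian jitter (Rice distribution mean), used as the tracking oracle
rician_mean_step <- function(v, sigma) {
  if (sigma == 0) return(v)
  z <- v^2 / (4 * sigma^2)
  sigma * sqrt(pi / 2) * exp(-z) *
    ((1 + 2 * z) * besselI(z, 0) + 2 * z * besselI(z, 1))
}

# per-cell perinuclear/peripheral labels for a simulated scene
scene_labels <- function(scene, tie_margin = 0.1) {
  vapply(scene$cells, function(cl) {
    masks <- build_compartment_masks(cl$roi, dim = dim(cl$images$cargo)[c(2, 1)])
    classify_cell(compartment_max(cl$images$cargo, masks), tie_margin)
  }, "")
}

# cell mask raster for one simulated cell
cell_mask_of <- function(cl, channel = "fa") {
  img <- cl$images[[channel]]
  traffickr:::rasterize_polygon(cl$roi$cell_outline, ncol(img), nrow(img))
}
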