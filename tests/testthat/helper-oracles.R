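# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (exhaustive enumeration, direct formulas) so they
# never share code with the implementation paths they check.

# grid + mask from a logical array
mk_mask <- function(v, spacing = c(1, 1, 1)) {
  binary_mask(v, image_grid(dim(v), spacing))
}

# random sparse mask with at least one voxel
random_mask <- function(shape, p = 0.05, spacing = c(1, 1, 1)) {
  v <- array(runif(prod(shape)) < p, dim = shape)
  if (!any(v)) v[sample(length(v), 1)] <- TRUE
  mk_mask(v, spacing)
}

# brute-force ellipsoidal Minkowski dilation: for every voxel, scan all
# source voxels and test the scaled-distance condition directly
brute_expand <- function(mask, m_ap, m_tr, m_cc) {
  sh <- dim(mask$voxels)
  sp <- mask$grid$spacing
  src <- which(mask$voxels)
  src_idx <- arrayInd(src, sh)
  out <- array(FALSE, dim = sh)
  mm <- c(m_cc, m_ap, m_tr)                 # internal axis order
  mm[mm == 0] <- 1e-12
  for (v in seq_len(prod(sh))) {
    p <- arrayInd(v, sh)
    d <- sweep(src_idx, 2, as.vector(p))
    s <- (d[, 1] * sp[1] / mm[1])^2 + (d[, 2] * sp[2] / mm[2])^2 +
         (d[, 3] * sp[3] / mm[3])^2
    if (any(s <= 1 + 1e-9)) out[v] <- TRUE
  }
  out
}

# brute-force center-to-nearest-source distance for every voxel
brute_distance <- function(mask) {
  sh <- dim(mask$voxels)
  sp <- mask$grid$spacing
  src_idx <- arrayInd(which(mask$voxels), sh)
  all_idx <- arrayInd(seq_len(prod(sh)), sh)
  out <- numeric(prod(sh))
  for (v in seq_len(prod(sh))) {
    d <- sweep(src_idx, 2, all_idx[v, ])
    out[v] <- sqrt(min((d[, 1] * sp[1])^2 + (d[, 2] * sp[2])^2 +
                         (d[, 3] * sp[3])^2))
  }
  array(out, dim = sh)
}

# direct linear-interpolation percentile (independent of stats::quantile)
brute_percentile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p / 100 + 1
  lo <- floor(h)
  if (lo == length(x)) return(x[lo])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

# naive connected-component sizes under 26-connectivity via repeated
# neighbourhood growth from each unvisited voxel
brute_component_sizes <- function(v) {
  sh <- dim(v)
  seen <- array(FALSE, dim = sh)
  sizes <- integer(0)
  idx_all <- which(v)
  for (start in idx_all) {
    if (seen[start]) next
    frontier <- start
    seen[start] <- TRUE
    n <- 1L
    while (length(frontier)) {
      nxt <- integer(0)
      for (f in frontier) {
        p <- arrayInd(f, sh)
        for (d1 in -1:1) for (d2 in -1:1) for (d3 in -1:1) {
          q <- p + c(d1, d2, d3)
          if (any(q < 1) || any(q > sh)) next
          qi <- q[1] + sh[1] * (q[2] - 1 + sh[2] * (q[3] - 1))
          if (v[qi] && !seen[qi]) {
            seen[qi] <- TRUE
            nxt <- c(nxt, qi)
            n <- n + 1L
          }
        }
      }
      frontier <- nxt
    }
    sizes <- c(sizes, n)
  }
  sizes
}

# linear dose ramp 0 -> dmax along the craniocaudal axis of a slab
ramp_fixture <- function(n = 50, dmax = 10, spacing = c(1, 1, 1)) {
  g <- image_grid(c(n, 5, 5), spacing)
  vals <- array(rep(seq(0, dmax, length.out = n), times = 25),
                dim = c(n, 5, 5))
  list(dose = dose_grid(vals, g),
       mask = binary_mask(array(TRUE, c(n, 5, 5)), g),
       grid = g)
}

# smooth random dose pair for gamma tests: sum of a few Gaussian blobs,
# the evaluated field mildly warped/scaled
smooth_dose_pair <- function(shape, spacing = c(2, 2, 2), px = 5,
                             nblob = 4, shift = c(0.6, -0.4, 0.3),
                             scale = 1.01) {
  g <- image_grid(shape, spacing)
  co <- adcboost:::coord_arrays(g)
  ref <- array(0, dim = shape)
  ext <- (shape - 1) * spacing
  for (b in seq_len(nblob)) {
    c0 <- runif(3, 0.25, 0.75) * ext
    s0 <- runif(1, 8, 20)
    ref <- ref + exp(-((co$cc - c0[1])^2 + (co$ap - c0[2])^2 +
                         (co$tr - c0[3])^2) / (2 * s0^2))
  }
  ref <- ref / max(ref) * px
  refd <- dose_grid(ref, g)
  evald <- perturb_dose(refd, shift_mm = shift, scale = scale)
  list(reference = refd, evaluated = evald, grid = g, px = px)
}
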