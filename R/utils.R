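## Internal numerics shared across modules: seeded child RNG streams,
## FFT-based smoothing and differentiation, array warping, 3D connected
## components and binary morphology.

# Child seed for stream k of master seed; keeps results < 2^31 and
# decorrelates streams. Streams: 1 mask, 2 scene noise, 3 blobs, 4 speckle,
# 5 bone, 6+ cohort animals.
childSeed <- function(seed, k) {
  s <- (as.double(seed) * 7919 + as.double(k) * 104729) %% 2147483629
  as.integer(s) + 1L
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# DFT sample frequencies (cycles per sample), fftfreq convention.
fftFreq <- function(n) {
  k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
  k / n
}

# Periodic Gaussian smoothing of a 3D array via the spectral transfer
# function exp(-2 pi^2 sigma^2 f^2) applied separably.
gaussianSmooth3D <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  d <- dim(arr)
  tf <- lapply(d, function(n) exp(-2 * pi^2 * sigma^2 * fftFreq(n)^2))
  H <- outer(outer(tf[[1]], tf[[2]]), tf[[3]])
  dim(H) <- d
  Re(fft(fft(arr) * H, inverse = TRUE)) / prod(d)
}

# Solve the periodic Poisson problem div(grad(phi)) = g (mean removed) in
# the discrete central-difference sense -- the symbol of the unit-spacing
# central difference is i*sin(2*pi*f) -- and return u = grad_h(phi) as a
# [d, 3] array. By construction the discrete central-difference divergence
# of u equals g up to the few unrepresentable pure-Nyquist modes; an
# affine dilation absorbs the mean of g.
poissonDisplacement <- function(g) {
  d <- dim(g)
  gm <- mean(g)
  g0 <- g - gm
  fx <- fftFreq(d[1]); fy <- fftFreq(d[2]); fz <- fftFreq(d[3])
  KX <- array(rep(sin(2 * pi * fx), times = d[2] * d[3]), d)
  KY <- array(rep(rep(sin(2 * pi * fy), each = d[1]), times = d[3]), d)
  KZ <- array(rep(sin(2 * pi * fz), each = d[1] * d[2]), d)
  k2 <- KX^2 + KY^2 + KZ^2
  G <- fft(g0)
  Phi <- -G / k2
  Phi[k2 == 0] <- 0
  u <- array(0, c(d, 3))
  u[, , , 1] <- Re(fft(1i * KX * Phi, inverse = TRUE)) / prod(d)
  u[, , , 2] <- Re(fft(1i * KY * Phi, inverse = TRUE)) / prod(d)
  u[, , , 3] <- Re(fft(1i * KZ * Phi, inverse = TRUE)) / prod(d)
  # affine part: div(alpha * x) = 3 alpha carries the mean expansion
  alpha <- gm / 3
  cx <- (d + 1) / 2
  X <- array(rep(seq_len(d[1]), times = d[2] * d[3]), d)
  Y <- array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), d)
  Z <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
  u[, , , 1] <- u[, , , 1] + alpha * (X - cx[1])
  u[, , , 2] <- u[, , , 2] + alpha * (Y - cx[2])
  u[, , , 3] <- u[, , , 3] + alpha * (Z - cx[3])
  u
}

# Central-difference gradient of a 3D scalar array along one axis, with
# one-sided differences at the ends; spacing in grid cells.
diffAxis <- function(arr, axis, spacing = 1) {
  d <- dim(arr)
  n <- d[axis]
  out <- array(0, d)
  idx <- function(i) {
    sl <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    sl[[axis]] <- i
    sl
  }
  if (n == 1L) return(out)
  hi <- idx(c(2:n, n)); lo <- idx(c(1, 1:(n - 1)))
  num <- do.call(`[`, c(list(arr), hi)) - do.call(`[`, c(list(arr), lo))
  den <- array(2 * spacing, d)
  den1 <- idx(1); denn <- idx(n)
  den <- do.call(`[<-`, c(list(den), den1, list(spacing)))
  den <- do.call(`[<-`, c(list(den), denn, list(spacing)))
  num / den
}

# det(I + grad(u)) - 1 for a displacement array u [d, 3] sampled on a grid
# with the given spacing (same length units as u).
jacobianExpansion <- function(u, spacing = c(1, 1, 1)) {
  J <- vector("list", 9)
  k <- 1
  for (i in 1:3) for (j in 1:3) {
    J[[k]] <- diffAxis(u[, , , i], j, spacing[j])
    k <- k + 1
  }
  a11 <- J[[1]] + 1; a12 <- J[[2]];     a13 <- J[[3]]
  a21 <- J[[4]];     a22 <- J[[5]] + 1; a23 <- J[[6]]
  a31 <- J[[7]];     a32 <- J[[8]];     a33 <- J[[9]] + 1
  a11 * (a22 * a33 - a23 * a32) -
    a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31) - 1
}

# Mask-aware derivative: central differences where both axis neighbours
# are inside the mask, one-sided where only one is, zero where neither.
diffAxisMasked <- function(arr, mask, axis, spacing = 1) {
  arr[!mask] <- 0
  hi <- shift3D(arr, axis, -1L, fill = 0)   # value at i+1
  lo <- shift3D(arr, axis, 1L, fill = 0)    # value at i-1
  mhi <- shift3D(mask, axis, -1L, fill = FALSE)
  mlo <- shift3D(mask, axis, 1L, fill = FALSE)
  hi[!mhi] <- arr[!mhi]
  lo[!mlo] <- arr[!mlo]
  steps <- (mhi + mlo)
  out <- array(0, dim(arr))
  nz <- steps > 0
  out[nz] <- (hi[nz] - lo[nz]) / (steps[nz] * spacing)
  out[!mask] <- 0
  out
}

# det(I + grad(u)) - 1 with derivatives confined to the mask.
jacobianExpansionMasked <- function(u, mask, spacing = c(1, 1, 1)) {
  J <- vector("list", 9)
  k <- 1
  for (i in 1:3) for (j in 1:3) {
    J[[k]] <- diffAxisMasked(u[, , , i], mask, j, spacing[j])
    k <- k + 1
  }
  a11 <- J[[1]] + 1; a12 <- J[[2]];     a13 <- J[[3]]
  a21 <- J[[4]];     a22 <- J[[5]] + 1; a23 <- J[[6]]
  a31 <- J[[7]];     a32 <- J[[8]];     a33 <- J[[9]] + 1
  a11 * (a22 * a33 - a23 * a32) -
    a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31) - 1
}

# Vectorised trilinear interpolation of arr at fractional 1-based
# coordinates (n x 3 matrix); out-of-range coordinates clamp to the border.
trilinear <- function(arr, coords) {
  d <- dim(arr)
  x <- pmin(pmax(coords[, 1], 1), d[1])
  y <- pmin(pmax(coords[, 2], 1), d[2])
  z <- pmin(pmax(coords[, 3], 1), d[3])
  x0 <- pmin(floor(x), d[1] - 1L); y0 <- pmin(floor(y), d[2] - 1L)
  z0 <- pmin(floor(z), d[3] - 1L)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  at <- function(i, j, k) arr[cbind(i, j, k)]
  c000 <- at(x0, y0, z0);     c100 <- at(x0 + 1, y0, z0)
  c010 <- at(x0, y0 + 1, z0); c110 <- at(x0 + 1, y0 + 1, z0)
  c001 <- at(x0, y0, z0 + 1); c101 <- at(x0 + 1, y0, z0 + 1)
  c011 <- at(x0, y0 + 1, z0 + 1); c111 <- at(x0 + 1, y0 + 1, z0 + 1)
  c00 <- c000 * (1 - fx) + c100 * fx
  c10 <- c010 * (1 - fx) + c110 * fx
  c01 <- c001 * (1 - fx) + c101 * fx
  c11 <- c011 * (1 - fx) + c111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  c0 * (1 - fz) + c1 * fz
}

# Bilinear interpolation on a 2D image at 1-based coordinates; returns
# `fill` outside the image.
bilinear <- function(img, x, y, fill = NA_real_) {
  d <- dim(img)
  inside <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2]
  out <- rep(fill, length(x))
  if (!any(inside)) return(out)
  x <- x[inside]; y <- y[inside]
  x0 <- pmin(floor(x), d[1] - 1L); y0 <- pmin(floor(y), d[2] - 1L)
  fx <- x - x0; fy <- y - y0
  v <- img[cbind(x0, y0)] * (1 - fx) * (1 - fy) +
    img[cbind(x0 + 1, y0)] * fx * (1 - fy) +
    img[cbind(x0, y0 + 1)] * (1 - fx) * fy +
    img[cbind(x0 + 1, y0 + 1)] * fx * fy
  out[inside] <- v
  out
}

# Label 6-connected components of a 3D logical array. Returns an integer
# array (0 = background) with labels ordered by decreasing size.
labelComponents3D <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  pos <- arrayInd(idx, d)
  key <- (pos[, 3] - 1) * (d[1] * d[2]) + (pos[, 2] - 1) * d[1] + pos[, 1]
  lookup <- integer(prod(d))
  lookup[key] <- seq_along(idx)
  edges <- NULL
  for (ax in 1:3) {
    nb <- pos
    nb[, ax] <- nb[, ax] + 1L
    ok <- nb[, ax] <= d[ax]
    nbkey <- (nb[ok, 3] - 1) * (d[1] * d[2]) + (nb[ok, 2] - 1) * d[1] +
      nb[ok, 1]
    j <- lookup[nbkey]
    keep <- j > 0L
    if (any(keep))
      edges <- rbind(edges, cbind(which(ok)[keep], j[keep]))
  }
  g <- igraph::graph_from_edgelist(
    rbind(edges, cbind(seq_along(idx), seq_along(idx))), directed = FALSE)
  comp <- igraph::components(g)$membership[seq_along(idx)]
  sizes <- sort(table(comp), decreasing = TRUE)
  relabel <- integer(max(comp))
  relabel[as.integer(names(sizes))] <- seq_along(sizes)
  lab[idx] <- relabel[comp]
  lab
}

# 6-connected binary dilation/erosion by r steps via array shifts.
shift3D <- function(arr, ax, by, fill = FALSE) {
  d <- dim(arr)
  out <- array(fill, d)
  src <- dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  if (by > 0) {
    dst[[ax]] <- (by + 1):d[ax]; src[[ax]] <- 1:(d[ax] - by)
  } else if (by < 0) {
    dst[[ax]] <- 1:(d[ax] + by); src[[ax]] <- (1 - by):d[ax]
  }
  do.call(`[<-`, c(list(out), dst,
                   list(do.call(`[`, c(list(arr), src)))))
}

binaryDilate <- function(mask, r = 1L) {
  for (i in seq_len(r)) {
    out <- mask
    for (ax in 1:3) {
      out <- out | shift3D(mask, ax, 1L) | shift3D(mask, ax, -1L)
    }
    mask <- out
  }
  mask
}

binaryErode <- function(mask, r = 1L) {
  for (i in seq_len(r)) {
    out <- mask
    for (ax in 1:3) {
      out <- out & shift3D(mask, ax, 1L, fill = FALSE) &
        shift3D(mask, ax, -1L, fill = FALSE)
    }
    mask <- out
  }
  mask
}

# Otsu threshold on a numeric vector (256-bin between-class variance).
otsuThreshold <- function(v) {
  r <- range(v)
  if (diff(r) == 0) stop("cannot threshold a constant image")
  h <- tabulate(pmin(as.integer((v - r[1]) / diff(r) * 256) + 1L, 256L), 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- r[1] + (seq_len(256) - 0.5) / 256 * diff(r)
  mu <- cumsum(p * mids)
  muT <- mu[256]
  sb <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

asVoxelGrid <- function(x, voxelSize = c(1, 1, 1)) {
  if (is(x, "VoxelGrid3D")) return(x)
  new("VoxelGrid3D", data = x, voxelSize = as.numeric(voxelSize))
}
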