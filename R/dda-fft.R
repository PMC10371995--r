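# FFT-accelerated interaction matvec: all dipoles live on a cuboid cubic
# lattice, so y = A x is a 3-D circular convolution with the
# displacement-indexed tensor kernel (zero-padded to twice the bounding
# box). This is what makes large prescribed-polarizability solves
# tractable; the O(N^2) table matvec in C++ remains for small systems.

.ddaKernelFFT <- function(lat, k, kernel = c("free", "filtered")) {
  kernel <- match.arg(kernel)
  dm <- lat$dims
  Lx <- dm[1]; Ly <- dm[2]; Lz <- dm[3]
  tab <- dda_build_table(Lx, Ly, Lz, lat$d, k,
                         if (kernel == "filtered") 1L else 0L)
  tabm <- matrix(tab, nrow = 6)
  Dx <- 2L * Lx; Dy <- 2L * Ly; Dz <- 2L * Lz
  # displacement -> circulant position (1-based) per axis
  wrap <- function(dd, D) (dd %% D) + 1L
  di <- rep(seq(-(Lx - 1L), Lx - 1L), times = (2 * Ly - 1) * (2 * Lz - 1))
  dj <- rep(rep(seq(-(Ly - 1L), Ly - 1L), each = 2 * Lx - 1),
            times = 2 * Lz - 1)
  dk <- rep(seq(-(Lz - 1L), Lz - 1L), each = (2 * Lx - 1) * (2 * Ly - 1))
  pos <- cbind(wrap(di, Dx), wrap(dj, Dy), wrap(dk, Dz))
  idx <- pos[, 1] + Dx * (pos[, 2] - 1L) + Dx * Dy * (pos[, 3] - 1L)
  lapply(1:6, function(cc) {
    K <- array(0+0i, c(Dx, Dy, Dz))
    K[idx] <- tabm[cc, ]
    stats::fft(K)
  })
}

.ddaFFTmatvec <- function(P, coords, kfft, dims) {
  Dx <- 2L * dims[1]; Dy <- 2L * dims[2]; Dz <- 2L * dims[3]
  gidx <- (coords[, 1] + 1L) + Dx * coords[, 2] + Dx * Dy * coords[, 3]
  nrm <- Dx * Dy * Dz
  Xf <- lapply(1:3, function(a) {
    X <- array(0+0i, c(Dx, Dy, Dz))
    X[gidx] <- P[, a]
    stats::fft(X)
  })
  # symmetric tensor component order: xx, xy, xz, yy, yz, zz
  comp <- list(c(1, 2, 3), c(2, 4, 5), c(3, 5, 6))
  out <- matrix(0+0i, nrow(P), 3)
  for (a in 1:3) {
    acc <- kfft[[comp[[a]][1]]] * Xf[[1]] +
      kfft[[comp[[a]][2]]] * Xf[[2]] +
      kfft[[comp[[a]][3]]] * Xf[[3]]
    y <- stats::fft(acc, inverse = TRUE) / nrm
    out[, a] <- y[gidx]
  }
  out
}

# COCG on the complex-symmetric block system (D + A) P = E using the FFT
# matvec; D given as N x 9 row-major blocks, E and x0 as N x 3.
.ddaCOCGfft <- function(lat, k, kernel, Dblocks, E, x0, tol = 1e-6,
                        maxit = 10000) {
  kfft <- .ddaKernelFFT(lat, k, kernel)
  coords <- lat$coords
  dims <- lat$dims
  applyD <- function(P) {
    cbind(Dblocks[, 1] * P[, 1] + Dblocks[, 2] * P[, 2] + Dblocks[, 3] * P[, 3],
          Dblocks[, 4] * P[, 1] + Dblocks[, 5] * P[, 2] + Dblocks[, 6] * P[, 3],
          Dblocks[, 7] * P[, 1] + Dblocks[, 8] * P[, 2] + Dblocks[, 9] * P[, 3])
  }
  applyM <- function(P) applyD(P) + .ddaFFTmatvec(P, coords, kfft, dims)
  nrm <- function(X) sqrt(sum(Mod(X)^2))
  En <- nrm(E)
  x <- x0
  r <- E - applyM(x)
  p <- r
  rr <- sum(r * r)
  it <- 0L
  relres <- nrm(r) / En
  while (it < maxit && relres > tol) {
    Ap <- applyM(p)
    pAp <- sum(p * Ap)
    if (Mod(pAp) < 1e-300) break
    a <- rr / pAp
    x <- x + a * p
    r <- r - a * Ap
    rr1 <- sum(r * r)
    p <- r + (rr1 / rr) * p
    rr <- rr1
    relres <- nrm(r) / En
    it <- it + 1L
  }
  true_rel <- nrm(E - applyM(x)) / En
  list(P = x, residual = true_rel, iterations = it,
       converged = true_rel <= tol)
}
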