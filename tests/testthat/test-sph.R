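test_that("kernel weight matches the closed form and its support", {
  k3d <- sphKernel(h = 1, normalization = "as_printed_3d")
  expect_equal(kernelWeight(0, k3d), 315 / (64 * pi))
  expect_equal(kernelWeight(1, k3d), 0)
  expect_equal(kernelWeight(2, k3d), 0)
  expect_error(sphKernel(h = -1), "positive")
  expect_error(kernelWeight(-0.1, k3d), "non-negative")
})

test_that("kernel feasibility: positive, even, compact, unit discrete sum", {
  for (nrm in c("renormalized_2d", "as_printed_3d")) {
    k <- sphKernel(h = 1, normalization = nrm)
    r <- seq(0, 2, length.out = 101)
    w <- kernelWeight(r, k)
    expect_true(all(w >= 0))
    expect_true(all(w[r >= 1] == 0))
    # evenness through the vector form of the gradient argument
    g1 <- kernelGradient(cbind(r, 0), k)
    g2 <- kernelGradient(cbind(-r, 0), k)
    expect_equal(g1, -g2)
  }
  # discrete unit integral over the support grid (renormalized form)
  k <- sphKernel(h = 1)
  off <- expand.grid(di = -2:2, dj = -2:2)
  rr <- 0.5 * sqrt(off$di^2 + off$dj^2)   # default half-pixel spacing
  expect_equal(sum(kernelWeight(rr, k)), 1, tolerance = 0.02)
})

test_that("kernel gradient matches central-difference differentiation", {
  for (exponentAsPrinted in c(FALSE, TRUE)) {
    k <- sphKernel(h = 1.3, normalization = "as_printed_3d",
                   exponentAsPrinted = exponentAsPrinted)
    radii <- seq(0.01, 1.28, length.out = 100)
    eps <- 1e-6
    for (r in radii) {
      num <- (kernelWeight(r + eps, k) - kernelWeight(r - eps, k)) / (2 * eps)
      ana <- kernelGradient(c(r, 0), k)[1]
      expect_equal(ana, num, tolerance = 1e-6)
    }
    # radial symmetry at the origin and beyond the support
    expect_equal(kernelGradient(c(0, 0), k), c(0, 0))
    expect_equal(kernelGradient(c(1.3, 0.2), k), c(0, 0))
  }
})

test_that("default cubic gradient reproduces the 945/(32 pi h^9) constant", {
  k <- sphKernel(h = 1, normalization = "as_printed_3d")
  r <- 0.5
  expected <- -(945 / (32 * pi)) * r * (1 - r^2)^2
  expect_equal(kernelGradient(c(r, 0), k)[1], expected)
})

test_that("SPH density reproduces constants and single-particle sums", {
  k <- sphKernel(h = 1)
  img <- matrix(77, 11, 11)
  rho <- sphDensity(img, k)
  expect_equal(rho[6, 6], 77, tolerance = 0.02 * 77)
  expect_identical(sphDensity(matrix(0, 7, 7), k), matrix(0, 7, 7))
  # single nonzero pixel: density is intensity times the kernel stencil
  img2 <- matrix(0, 5, 5); img2[3, 3] <- 10
  rho2 <- sphDensity(img2, k)
  expect_equal(rho2[3, 3], 10 * kernelWeight(0, k))
  expect_equal(rho2[3, 2], 10 * kernelWeight(0.5, k))
  expect_equal(rho2[2, 2], 10 * kernelWeight(0.5 * sqrt(2), k))
  expect_equal(rho2[1, 1], 0)  # outside the 3x3 support stencil
})

test_that("SPH normal field vanishes on constants and tracks edges", {
  k <- sphKernel(h = 1)
  nf <- sphNormalField(matrix(42, 16, 16), k)
  expect_equal(nf$magnitude, matrix(0, 16, 16))

  img <- stepImage(16, 16, 0, 100)
  nf <- sphNormalField(img, k)
  # magnitude peaks at the step columns, zero far away
  peak <- which.max(nf$magnitude[8, ])
  expect_true(peak %in% c(8, 9))
  expect_equal(nf$magnitude[8, 2], 0)
  expect_equal(nf$magnitude[8, 15], 0)

  # mirror image: negated horizontal component
  nfm <- sphNormalField(img[, 16:1], k)
  expect_equal(nfm$dc, -nf$dc[, 16:1])
  expect_equal(nfm$magnitude, nf$magnitude[, 16:1])
})

test_that("SPH gradients align with central differences on smooth ramps", {
  H <- 24; W <- 24
  rr <- matrix(seq_len(H), H, W); cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  ramp <- 2 * rr + 5 * cc
  nf <- sphNormalField(ramp, sphKernel(h = 1))
  interior <- as.matrix(expand.grid(5:(H - 4), 5:(W - 4)))
  gvec <- cbind(nf$dr[interior], nf$dc[interior])
  ref <- c(2, 5) / sqrt(29)
  cosim <- (gvec %*% ref) / sqrt(rowSums(gvec^2))
  expect_true(all(cosim > 0.95))
})

test_that("edge indicator maps magnitudes to (0, 1] monotonically", {
  expect_equal(edgeIndicator(matrix(0, 2, 2), p = 1, rescale = FALSE),
               matrix(1, 2, 2))
  expect_equal(edgeIndicator(matrix(1, 1, 1), p = 1, rescale = FALSE)[1],
               0.5)
  m <- matrix(seq(0, 4, length.out = 9), 3, 3)
  g1 <- edgeIndicator(m, p = 1, rescale = FALSE)
  g2 <- edgeIndicator(m, p = 2, rescale = FALSE)
  expect_true(all(g2[m >= 1] <= g1[m >= 1]))
  expect_true(all(diff(as.numeric(g1)[order(as.numeric(m))]) <= 0))
  # rescaled variant: 1 exactly at zero magnitude, insensitive to scale
  ga <- edgeIndicator(m)
  gb <- edgeIndicator(1000 * m)
  expect_equal(ga, gb)
  expect_equal(ga[1, 1], 1)
  expect_error(edgeIndicator(matrix(-1, 1, 1)), "non-negative")
})

test_that("SPH module is deterministic", {
  set.seed(3)
  img <- matrix(runif(400, 0, 255), 20, 20)
  a <- sphNormalField(img, sphKernel())
  b <- sphNormalField(img, sphKernel())
  expect_identical(a, b)
})
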