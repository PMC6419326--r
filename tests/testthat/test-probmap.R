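test_that("Gaussian models recover patch statistics", {
  img <- array(0, dim = c(60, 60, 3))
  img[, , 1] <- 100; img[, , 2] <- 150; img[, , 3] <- 200
  img[1:20, 1:20, ] <- 30
  fg <- patchSpec(0, 0, 15, 15, "foreground")
  bg <- patchSpec(40, 40, 15, 15, "background")
  m <- fitGaussianModels(img, fg, bg)
  expect_equal(unname(m@mean["foreground", ]), c(30, 30, 30))
  expect_equal(unname(m@mean["background", ]), c(100, 150, 200))
  # constant patches: sd floored
  expect_equal(unname(m@sd["foreground", ]), rep(1e-3, 3))
  # density at the mean is 1 / (sqrt(2 pi) sigma)
  expect_equal(leeac:::.gaussDensity(30, 30, 2), 1 / (sqrt(2 * pi) * 2))
  expect_error(fitGaussianModels(img, patchSpec(0, 0, 5, 5, "foreground"), bg),
               "100 pixels")
  expect_error(fitGaussianModels(img, patchSpec(55, 55, 15, 15, "foreground"),
                                 bg), "bounds")
})

test_that("seeded draws from a known normal recover mu and sigma", {
  set.seed(123)
  H <- 100; W <- 100
  img <- matrix(pmin(pmax(rnorm(H * W, 120, 15), 0), 255), H, W)
  fg <- patchSpec(0, 0, 100, 100, "foreground")
  # background patch from a second constant region pasted alongside
  img2 <- cbind(img, matrix(240, H, 20))
  m <- fitGaussianModels(img2, fg, patchSpec(0, 100, 100, 20, "background"))
  expect_lt(abs(m@mean["foreground", 1] - 120), 1)
  expect_lt(abs(m@sd["foreground", 1] - 15), 1)
})

test_that("pixel likelihood follows the two-class ratio and weights", {
  mu <- rbind(foreground = c(50, 50, 50), background = c(200, 200, 200))
  sd <- rbind(foreground = c(10, 10, 10), background = c(10, 10, 10))
  colnames(mu) <- colnames(sd) <- paste0("ch", 1:3)
  model <- new("GaussianChannelModel", mean = mu, sd = sd)
  img <- array(125, dim = c(4, 4, 3))   # equidistant: densities equal
  PF <- pixelLikelihood(img, model)
  expect_equal(PF, matrix(0.5, 4, 4))
  img[,,] <- 50                          # at the foreground mean
  expect_true(all(pixelLikelihood(img, model) > 1 - 1e-10))
  # P_F + P_B = 1 by construction for any weights
  set.seed(5)
  img[, , 1] <- runif(16, 0, 255)
  PF <- pixelLikelihood(img, model)
  mu2 <- mu[2:1, ]; sd2 <- sd[2:1, ]
  rownames(mu2) <- rownames(sd2) <- c("foreground", "background")
  PB <- pixelLikelihood(img, new("GaussianChannelModel", mean = mu2, sd = sd2))
  expect_equal(PF + PB, matrix(1, 4, 4), tolerance = 1e-9)
  expect_error(pixelLikelihood(img, model, weights = c(1, 1, 1)), "sum to 1")
  expect_error(pixelLikelihood(img, model, weights = c(1, 0)), "length")
})

test_that("per-channel likelihoods combine by the weighted mean", {
  # channels engineered to give per-channel P of 1, 0.5, 0
  mu <- rbind(foreground = c(0, 100, 255), background = c(255, 100, 0))
  sd <- rbind(foreground = c(5, 10, 5), background = c(5, 10, 5))
  colnames(mu) <- colnames(sd) <- paste0("ch", 1:3)
  model <- new("GaussianChannelModel", mean = mu, sd = sd)
  img <- array(0, dim = c(1, 1, 3))
  img[1, 1, ] <- c(0, 100, 0)   # fg-certain, ambiguous, bg-certain
  PF <- pixelLikelihood(img, model)
  expect_equal(PF[1, 1], 0.5, tolerance = 1e-9)
})

test_that("geodesic distance equals the Bellman-Ford oracle exactly", {
  set.seed(21)
  for (rep in 1:20) {
    P <- matrix(runif(144), 12, 12)
    seed <- matrix(0L, 12, 12)
    seed[sample(144, 1)] <- 1L
    D <- geodesicDistance(P, seed)
    Dref <- bellmanFordGeodesic(P, seed)
    expect_equal(D, Dref, tolerance = 1e-12)
  }
})

test_that("geodesic distance basics: zero at seeds, eps-paths on constants", {
  P <- matrix(0.4, 9, 9)
  seed <- matrix(0L, 9, 9); seed[5, 5] <- 1L
  D <- geodesicDistance(P, seed, eps = 1e-4)
  expect_equal(D[5, 5], 0)
  expect_equal(D[5, 9], 4e-4)            # four axis steps
  expect_equal(D[1, 1], 4 * sqrt(2) * 1e-4)  # four diagonal steps
  expect_true(all(D >= 0))
  expect_error(geodesicDistance(P, patchSpec(8, 8, 5, 5, "foreground")),
               "bounds")
})

test_that("raising an edge cost never shortens any distance", {
  set.seed(33)
  P <- matrix(runif(100), 10, 10)
  seed <- matrix(0L, 10, 10); seed[1, 1] <- 1L
  D1 <- geodesicDistance(P, seed)
  # raising every edge cost (larger eps regulariser) cannot shorten paths
  D2 <- geodesicDistance(P, seed, eps = 2e-4)
  expect_true(all(D2 >= D1 - 1e-15))
  # flattening the field to a constant removes all |dP| costs
  D3 <- geodesicDistance(matrix(0.5, 10, 10), seed)
  expect_true(all(D3 <= D1 + 1e-15))
})

test_that("probability combination honours the geodesic labeling rule", {
  PF <- matrix(0.42, 3, 3)
  DF <- matrix(1, 3, 3); DB <- matrix(1, 3, 3)
  expect_equal(combineProbability(PF, DF, DB), matrix(0.5, 3, 3))
  DF0 <- matrix(0, 3, 3)
  expect_equal(combineProbability(PF, DF0, DB), matrix(1, 3, 3))
  expect_equal(combineProbability(PF, DB, DF0), matrix(0, 3, 3))
  # both zero: fall back to the colour likelihood
  expect_equal(combineProbability(PF, DF0, DF0), PF)
  expect_error(combineProbability(PF, DF, matrix(1, 2, 2)), "shape")
})

test_that("probability minimization has the stated analytic values", {
  expect_equal(minimizeProb(matrix(0.7, 1, 1))[1], 0)
  expect_equal(minimizeProb(matrix(0.2, 1, 1))[1], 0.5)
  expect_equal(minimizeProb(matrix(0, 1, 1))[1], 0.98)
  # centre 0.5 baseline
  expect_equal(minimizeProb(matrix(0.5, 1, 1), center = 0.5)[1], 0)
  expect_error(minimizeProb(matrix(0.5, 1, 1), center = 1.2), "center")
  expect_error(minimizeProb(matrix(2, 1, 1)), "within")
})

test_that("fusion multiplies and optionally floors weak edges", {
  g <- matrix(0.8, 2, 2)
  prob <- matrix(c(0, 1, 0.5, 0.25), 2, 2)
  gnew <- fuseEdgeIndicator(g, prob)
  expect_equal(gnew, g * prob)
  thr <- fuseEdgeIndicator(g, prob, edgeThreshold = 0.3)
  expect_equal(thr[prob == 0.25], 0)       # 0.2 < 0.3 floored
  expect_equal(thr[prob == 1], 0.8)
  expect_error(fuseEdgeIndicator(g, matrix(1, 3, 3)), "shape")
})

test_that("two distinct colour regions are recovered by s > 0.5", {
  set.seed(77)
  H <- 64; W <- 64
  truth <- matrix(0L, H, W); truth[17:48, 17:48] <- 1L
  img <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) {
    base <- ifelse(truth == 1L, 80, 180)   # >= 6 sigma apart (sigma 8)
    img[, , ch] <- pmin(pmax(base + rnorm(H * W, 0, 8), 0), 255)
  }
  fg <- patchSpec(20, 20, 24, 24, "foreground")
  bg <- patchSpec(1, 1, 12, 12, "background")
  model <- fitGaussianModels(img, fg, bg)
  PF <- pixelLikelihood(img, model)
  DF <- geodesicDistance(PF, fg); DB <- geodesicDistance(PF, bg)
  s <- combineProbability(PF, DF, DB)
  acc <- mean((s > 0.5) == (truth == 1L))
  expect_gte(acc, 0.99)
})
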