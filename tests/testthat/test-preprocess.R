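test_that("intermeans threshold finds the two-class midpoint", {
  img <- matrix(c(rep(50, 32), rep(200, 32)), 8, 8)
  out <- intermeansThreshold(img)
  expect_equal(out$threshold, 125)
  expect_true(all(out$mask[img == 50] == 1L))
  expect_true(all(out$mask[img == 200] == 0L))

  # any threshold in (0, 255) separates these classes identically
  img2 <- matrix(c(0, 255, 0, 255), 2, 2)
  out2 <- intermeansThreshold(img2)
  expect_identical(out2$mask, matrix(c(1L, 0L, 1L, 0L), 2, 2))

  # darker class is the lesion by default; invert flips it
  expect_identical(intermeansThreshold(img, invert = TRUE)$mask,
                   1L - out$mask)
})

test_that("intermeans threshold is an idempotent fixed point", {
  set.seed(11)
  img <- matrix(c(rnorm(300, 60, 10), rnorm(212, 190, 12)), 32, 16)
  img <- pmin(pmax(img, 0), 255)
  t1 <- intermeansThreshold(img)$threshold
  lo <- mean(img[img <= t1]); hi <- mean(img[img > t1])
  expect_lt(abs((lo + hi) / 2 - t1), 0.5)
})

test_that("intermeans rejects constant images", {
  expect_error(intermeansThreshold(matrix(100, 8, 8)), "bimodal")
})

test_that("patch selection returns in-bounds, non-overlapping patches", {
  mask <- matrix(0L, 300, 300)
  mask[76:225, 76:225] <- 1L
  out <- selectPatches(mask, 70, 90)
  fg <- out$fg; bg <- out$bg
  # fg patch centred on the component centroid (150.5, 150.5)
  expect_equal(fg@row0 + 35, 150, tolerance = 1)
  expect_equal(fg@col0 + 45, 150, tolerance = 1)
  # fully inside the foreground square
  expect_gte(fg@row0 + 1, 76); expect_lte(fg@row0 + fg@height, 226)
  expect_gte(fg@col0 + 1, 76); expect_lte(fg@col0 + fg@width, 226)
  # bg patch entirely on background, in the frame, no overlap
  r <- bg@row0 + seq_len(bg@height); c <- bg@col0 + seq_len(bg@width)
  expect_true(all(mask[r, c] == 0L))
  sep <- fg@row0 + fg@height <= bg@row0 || bg@row0 + bg@height <= fg@row0 ||
         fg@col0 + fg@width <= bg@col0 || bg@col0 + bg@width <= fg@col0
  expect_true(sep)
})

test_that("patch selection names the missing class in errors", {
  expect_error(selectPatches(matrix(0L, 100, 100), 10, 10), "foreground")
  expect_error(selectPatches(matrix(1L, 100, 100), 10, 10), "background")
})

test_that("Perona-Malik leaves constant images unchanged and clips", {
  img <- matrix(128, 32, 32)
  expect_identical(peronaMalik(img), img)
  expect_error(peronaMalik(img, gamma = -1), "gamma")
  expect_error(peronaMalik(img, dt = 0.3), "dt")
})

test_that("Perona-Malik conduction coefficients are correct and decreasing", {
  # as-printed coefficient at zero gradient is exactly 1/2
  cAP <- function(d2, g) 1 / (1 + sqrt(1 + d2 / g^2))
  cCL <- function(d2, g) 1 / (1 + d2 / g^2)
  expect_equal(cAP(0, 15), 0.5)
  d <- seq(0, 100, by = 5)
  expect_true(all(diff(cAP(d^2, 15)) < 0))
  expect_true(all(diff(cCL(d^2, 15)) < 0))
  expect_true(all(cAP(d^2, 15) <= 0.5 & cAP(d^2, 15) > 0))
})

test_that("Perona-Malik matches an independent explicit scheme and
           preserves a strong step while removing noise", {
  set.seed(4)
  H <- 40; W <- 40
  img <- stepImage(H, W, 60, 200) + matrix(rnorm(H * W, 0, 6), H, W)
  img <- pmin(pmax(img, 0), 255)
  out <- peronaMalik(img, gamma = 15, nIter = 20, dt = 0.2)

  # independent straightforward re-implementation (scalar loops)
  ref <- img
  g2 <- 15^2
  for (it in 1:20) {
    nxt <- ref
    for (i in 1:H) for (j in 1:W) {
      dN <- ref[max(i - 1, 1), j] - ref[i, j]
      dS <- ref[min(i + 1, H), j] - ref[i, j]
      dW <- ref[i, max(j - 1, 1)] - ref[i, j]
      dE <- ref[i, min(j + 1, W)] - ref[i, j]
      cf <- function(d) 1 / (1 + sqrt(1 + d^2 / g2))
      nxt[i, j] <- ref[i, j] +
        0.2 * (cf(dN) * dN + cf(dS) * dS + cf(dW) * dW + cf(dE) * dE)
    }
    ref <- pmin(pmax(nxt, 0), 255)
  }
  expect_equal(out, ref, tolerance = 1e-12)
})

test_that("with gamma far below a step, the classic coefficient keeps the
           crest while flattening noise", {
  set.seed(4)
  H <- 40; W <- 40
  clean <- matrix(60, H, W); clean[, 21:40] <- 200   # 140-unit step
  img <- pmin(pmax(clean + matrix(rnorm(H * W, 0, 6), H, W), 0), 255)
  out <- peronaMalik(img, gamma = 8, nIter = 20, dt = 0.2,
                     variant = "classic")
  # edge crest within 2 intensity units (~1%) of the clean step value
  expect_lt(median(abs(out[, 21] - 200)), 2)
  expect_lt(median(abs(out[, 20] - 60)), 2)
  # flat-region noise variance drops by far more than half
  flat <- 5:15
  expect_lt(var(as.numeric(out[flat, flat])),
            0.5 * var(as.numeric(img[flat, flat])))
})

test_that("filtering commutes with intensity flip up to clipping", {
  set.seed(9)
  img <- matrix(runif(900, 40, 220), 30, 30)
  a <- peronaMalik(255 - img, nIter = 5)
  b <- 255 - peronaMalik(img, nIter = 5)
  expect_equal(a, b, tolerance = 1e-10)
})
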