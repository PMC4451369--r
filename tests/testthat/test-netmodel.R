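test_that("temporal simulation follows the one-step recursion exactly", {
  # geometric decay: c = 0.5, no input, no basal
  m <- PathwayModel(C = matrix(0.5), H = 0, B = matrix(1),
                    semantics = "temporal")
  y <- simulateTemporal(m, uSeries = matrix(0, 1, 5), y0 = 3)
  expect_equal(as.numeric(y), 3 * 0.5^(0:5))

  # fixed point H / (1 - c) = 2 stays put
  m2 <- PathwayModel(C = matrix(0.5), H = 1, B = matrix(0),
                     semantics = "temporal")
  y2 <- simulateTemporal(m2, uSeries = matrix(0, 1, 6), y0 = 2)
  expect_equal(as.numeric(y2), rep(2, 7))

  # random 3-node model vs an independently re-coded recursion
  set.seed(101)
  C <- rand_stable_matrix(3, 0.6)
  B <- matrix(rnorm(3), 3, 1)
  H <- rnorm(3)
  m3 <- PathwayModel(C = C, H = H, B = B, semantics = "temporal")
  U <- matrix(rnorm(20), 1, 20)
  y0 <- rnorm(3)
  got <- simulateTemporal(m3, uSeries = U, y0 = y0)
  ref <- matrix(0, 3, 21)
  ref[, 1] <- y0
  for (t in 1:20) ref[, t + 1] <- C %*% ref[, t] + H + B * U[1, t]
  expect_lt(max(abs(unname(got) - ref)), 1e-12)
})

test_that("noise is reproducible under a fixed seed and requires one", {
  m <- PathwayModel(C = matrix(0.5), H = 0, B = matrix(1),
                    semantics = "temporal")
  u <- matrix(0, 1, 10)
  a <- simulateTemporal(m, u, y0 = 1, noiseSigma = 0.3, seed = 7)
  b <- simulateTemporal(m, u, y0 = 1, noiseSigma = 0.3, seed = 7)
  expect_identical(a, b)
  expect_error(simulateTemporal(m, u, y0 = 1, noiseSigma = 0.3),
               "seed")
})

test_that("basal simulation is the input-free trajectory", {
  set.seed(11)
  C <- rand_stable_matrix(3, 0.5)
  m <- PathwayModel(C = C, H = rnorm(3), B = matrix(rnorm(3)),
                    semantics = "temporal")
  expect_identical(simulateBasal(m, y0 = 1:3, nSteps = 8),
                   simulateTemporal(m, uSeries = matrix(0, 1, 8), y0 = 1:3))
  # C = 0, H = 5, y0 = 0: 0, 5, 5, ...
  m5 <- PathwayModel(C = matrix(0), H = 5, B = matrix(0),
                     semantics = "temporal")
  expect_equal(as.numeric(simulateBasal(m5, y0 = 0, nSteps = 4)),
               c(0, rep(5, 4)))
})

test_that("driven minus basal trajectory equals the flow response", {
  # superposition of the linear recursion, checked over random models
  set.seed(202)
  for (trial in 1:20) {
    n <- sample(2:5, 1)
    C <- rand_stable_matrix(n, runif(1, 0.3, 0.9))
    B <- matrix(rnorm(n * 2), n, 2)
    m <- PathwayModel(C = C, H = rnorm(n), B = B, semantics = "temporal")
    U <- matrix(runif(2 * 15, -1, 1), 2, 15)
    y0 <- rnorm(n)
    diff <- simulateTemporal(m, U, y0 = y0) -
      simulateBasal(m, y0 = y0, nSteps = 15)
    fl <- flowResponse(extractPathwayChannel(m), U)
    expect_lt(max(abs(t(unname(diff)) - fl@values)), 1e-10)
  }
})

test_that("flow response reproduces the convolution sum", {
  # scalar impulse: 0, 1, 0.5, 0.25, ...
  m <- PathwayModel(C = matrix(0.5), B = matrix(1), semantics = "temporal")
  ch <- extractPathwayChannel(m)
  u <- matrix(c(1, 0, 0, 0), 1, 4)
  expect_equal(as.numeric(flowResponse(ch, u)@values), c(0, 1, 0.5, 0.25, 0.125))
  # zero input, zero flow
  expect_true(all(flowResponse(ch, matrix(0, 1, 6))@values == 0))
  # impulse through a MIMO system equals the matrix-power sequence D C^t B
  set.seed(33)
  C <- rand_stable_matrix(4, 0.8)
  B <- matrix(rnorm(4), 4, 1)
  ch4 <- make_channel(C, B)
  imp <- matrix(c(1, rep(0, 11)), 1, 12)
  fl <- flowResponse(ch4, imp)@values
  Ct <- diag(4)
  for (t in 1:12) {
    expect_lt(max(abs(fl[t + 1, ] - as.numeric(Ct %*% B))), 1e-12)
    Ct <- C %*% Ct
  }
  # random input matches an independent recursion of the flow equation
  U <- matrix(rnorm(50), 1, 50)
  got <- flowResponse(ch4, U)@values
  x <- numeric(4)
  for (t in 1:50) {
    x <- C %*% x + B * U[1, t]
    expect_lt(max(abs(got[t + 1, ] - as.numeric(x))), 1e-10)
  }
})

test_that("steady-state solve satisfies the fixed-point equation", {
  # identity inverse when C = 0
  m0 <- PathwayModel(C = matrix(0, 2, 2), H = c(1, 2),
                     B = matrix(c(1, 0, 0, 1), 2, 2), semantics = "static")
  expect_equal(unname(steadyStateSample(m0, u = c(3, 4), w = c(0.1, 0.2))),
               c(4.1, 6.2))
  # scalar 1/(1 - 0.5) = 2
  m1 <- PathwayModel(C = matrix(0.5), H = 0, B = matrix(1),
                     semantics = "static")
  expect_equal(unname(steadyStateSample(m1, u = 1)), 2)
  # residual check on a random 5-node model
  set.seed(55)
  C <- rand_stable_matrix(5, 0.6)
  m5 <- PathwayModel(C = C, H = rnorm(5), B = matrix(rnorm(10), 5, 2),
                     semantics = "static")
  u <- rnorm(2); w <- rnorm(5)
  y <- steadyStateSample(m5, u, w)
  resid <- (diag(5) - C) %*% y - m5@B %*% u - m5@H - w
  expect_lt(max(abs(resid)), 1e-10 * (1 + max(abs(y))))
  # singular (I - C) is rejected
  bad <- PathwayModel(C = diag(2), H = c(0, 0), B = matrix(0, 2, 1),
                      semantics = "static")
  expect_error(steadyStateSample(bad, u = 0), "non-invertible")
})

test_that("pathway channel extraction selects rows and columns correctly", {
  set.seed(9)
  C <- rand_stable_matrix(3, 0.5)
  B <- matrix(rnorm(6), 3, 2)
  m <- PathwayModel(C = C, B = B, semantics = "temporal",
                    nodeIds = c("a", "b", "c"), inputIds = c("u1", "u2"))
  full <- extractPathwayChannel(m)
  expect_equal(full@Asub, interactionMatrix(m))
  expect_equal(unname(full@Bsub), unname(B))
  expect_equal(full@Dout, diag(3))
  one <- extractPathwayChannel(m, target = "b")
  expect_equal(one@Dout, matrix(c(0, 1, 0), 1, 3))
  # column partition: per-input blocks reassemble B
  b1 <- extractPathwayChannel(m, input = "u1")@Bsub
  b2 <- extractPathwayChannel(m, input = 2)@Bsub
  expect_equal(unname(cbind(b1, b2)), unname(B))
  expect_error(extractPathwayChannel(m, target = "zz"), "unknown node")
  expect_error(extractPathwayChannel(m, input = "zz"), "unknown input")
})

test_that("GRN channel extraction is an exact decomposition", {
  A <- matrix(c(0, 0.2, 0.7, 0), 2, 2,
              dimnames = list(c("g1", "g2"), c("g1", "g2")))
  g <- GRNModel(A, semantics = "temporal")
  ch <- extractGrnChannel(g, source = "g2", target = "g1")
  expect_equal(unname(ch@Asub), matrix(c(0, 0.2, 0, 0), 2, 2))
  expect_equal(unname(ch@Bsub), matrix(c(0.7, 0), 2, 1))
  expect_equal(ch@Dout, matrix(c(1, 0), 1, 2))
  expect_false(ch@selfLoop)
  expect_true(extractGrnChannel(g, "g1", "g1")@selfLoop)

  # reconstruction identity A_sub + B_sub e_j' = A for random draws
  set.seed(77)
  for (trial in 1:25) {
    n <- sample(2:7, 1)
    A <- matrix(rnorm(n * n), n, n)
    gg <- GRNModel(A, semantics = "temporal")
    j <- sample.int(n, 1)
    chx <- extractGrnChannel(gg, source = j, target = sample.int(n, 1))
    ej <- matrix(0, 1, n); ej[1, j] <- 1
    expect_equal(unname(chx@Asub + chx@Bsub %*% ej), unname(A))
  }
})

test_that("dataset and simulation dimension mismatches raise structured errors", {
  m <- PathwayModel(C = matrix(0.5), B = matrix(1), semantics = "temporal")
  expect_error(simulateTemporal(m, uSeries = matrix(0, 2, 5)),
               "input signals")
  expect_error(simulateTemporal(m, uSeries = matrix(0, 1, 5), y0 = c(1, 2)),
               "y0")
  expect_error(flowResponse(extractPathwayChannel(m), matrix(0, 3, 4)),
               "channel inputs")
})

test_that("ExpressionDataset enforces its invariants", {
  v <- matrix(1:6, 2, 3, dimnames = list(c("a", "b"), NULL))
  expect_s4_class(ExpressionDataset(v, "temporal"), "ExpressionDataset")
  v_na <- v; v_na[1, 2] <- NA
  expect_error(ExpressionDataset(v_na, "temporal"), "finite|missing")
  v_dup <- v; rownames(v_dup) <- c("a", "a")
  expect_error(ExpressionDataset(v_dup, "temporal"), "duplicated")
  expect_error(ExpressionDataset(v, "temporal",
                                 inputs = matrix(1, 1, 2)),
               "observation count")
  expect_error(ExpressionDataset(v, "temporal",
                                 inhibitors = matrix(-1, 1, 3)),
               "nonnegative")
})
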