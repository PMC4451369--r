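test_that("a single RLS step matches the hand-computed update", {
  # zero regressor: state unchanged, innovation is the raw observation
  s <- rlsState(theta0 = c(0, 0), P0Scale = 1)
  s2 <- rlsStep(s, phi = c(0, 0), yObs = 3)
  expect_equal(s2@theta, c(0, 0))
  expect_equal(s2@P, diag(2))
  expect_equal(s2@innovations, 3)
  # scalar: P0 = 1, phi = 1, y = 3 -> P = 1/2, theta = 1.5
  s <- rlsState(0, 1)
  s2 <- rlsStep(s, 1, 3)
  expect_equal(as.numeric(s2@P), 0.5)
  expect_equal(s2@theta, 1.5)
  expect_error(rlsStep(s, NaN, 1), "non-finite")
  expect_error(rlsStep(s, c(1, 2), 1), "dimension mismatch")
})

test_that("one RLS pass equals the closed-form ridge solution", {
  set.seed(100)
  for (trial in 1:5) {
    p <- sample(2:6, 1)
    X <- matrix(rnorm(100 * p), 100, p)
    theta_true <- rnorm(p)
    y <- X %*% theta_true + rnorm(100, sd = 0.2)
    theta0 <- rnorm(p)
    P0 <- 50
    s <- rlsState(theta0, P0)
    for (k in 1:100) s <- rlsStep(s, X[k, ], y[k])
    ridge <- solve(crossprod(X) + diag(1 / P0, p),
                   crossprod(X, y) + theta0 / P0)
    expect_lt(max(abs(s@theta - ridge)) / max(abs(ridge)), 1e-8)
  }
})

test_that("P stays symmetric positive definite over many updates", {
  set.seed(4)
  p <- 5
  s <- rlsState(numeric(p), 1e3)
  X <- matrix(rnorm(2000 * p), 2000, p)
  y <- rnorm(2000)
  upd <- netflux:::.rls_pass(s@theta, s@P, X, y)
  expect_lt(max(abs(upd$P - t(upd$P))), 1e-10)
  expect_gt(min(eigen(upd$P, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("multi-round node fits converge to the least-squares solution", {
  # exact line y = 2x + 1
  x <- 0:3
  f <- rlsFitNode(cbind(x, 1), 2 * x + 1)
  expect_lt(max(abs(f$theta - c(2, 1))), 1e-6)
  expect_true(f$converged)
  # all-zero regressors: flagged, parameters untouched
  f0 <- rlsFitNode(matrix(0, 5, 3), rnorm(5), theta0 = 0)
  expect_equal(f0$theta, c(0, 0, 0))
  expect_true("no_information" %in% f0$flags)
  # noise-free random 5-parameter model recovered to 1e-6 relative
  set.seed(8)
  X <- matrix(rnorm(40 * 5), 40, 5)
  theta_true <- rnorm(5)
  f5 <- rlsFitNode(X, X %*% theta_true)
  expect_lt(max(abs(f5$theta - theta_true) / abs(theta_true)), 1e-6)
})

test_that("round-to-round parameter changes shrink on full-rank problems", {
  set.seed(15)
  X <- matrix(rnorm(30 * 4), 30, 4)
  y <- as.numeric(X %*% rnorm(4))
  theta <- rep(0, 4)
  changes <- numeric(6)
  for (r in 1:6) {
    f <- rlsFitNode(X, y, theta0 = theta, maxRounds = 1)
    changes[r] <- max(abs(f$theta - theta))
    theta <- f$theta
  }
  # geometric contraction until the change bottoms out at machine level
  active <- changes > 1e-13
  expect_true(all(diff(changes[active]) < 0))
  expect_lt(changes[6], 1e-8)
})

test_that("temporal pathway fits recover a known model from noise-free data", {
  sc <- SynthScenario(nNodes = 3, nInputs = 1, noiseSigma = 0,
                      nObservations = 31, seed = 301)
  truth <- randomStableNetwork(sc, "pathway")
  ds <- generateDataset(truth, sc)
  fit <- fitTemporalPathway(ds, config = rlsConfig(P0Scale = 1e6))
  est <- fittedModel(fit)
  expect_lt(max(abs(interactionMatrix(est) - interactionMatrix(truth))), 1e-6)
  expect_lt(max(abs(bindingMatrix(est) - bindingMatrix(truth))), 1e-6)
  expect_lt(max(abs(basalLevels(est) - basalLevels(truth))), 1e-6)
  expect_error(fitTemporalPathway(
    ExpressionDataset(matrix(1, 2, 1), "temporal")), "consecutive pairs")
})

test_that("constant datasets are reported as rank deficient", {
  v <- matrix(2, 3, 20, dimnames = list(c("a", "b", "c"), NULL))
  ds <- ExpressionDataset(v, "temporal")
  fit <- fitTemporalPathway(ds)
  expect_true(any(vapply(fitFlags(fit),
                         function(f) "rank_deficient" %in% f, logical(1))))
})

test_that("a true-sparsity mask reduces estimation error on noisy data", {
  sc <- SynthScenario(nNodes = 5, nInputs = 1, edgeDensity = 0.25,
                      noiseSigma = 0.1, nObservations = 200, seed = 77)
  truth <- randomStableNetwork(sc, "pathway")
  ds <- generateDataset(truth, sc)
  err <- function(fit) {
    est <- fittedModel(fit)
    sqrt(mean((interactionMatrix(est) - interactionMatrix(truth))^2))
  }
  e_masked <- err(fitTemporalPathway(ds, structureFromModel(truth)))
  e_full <- err(fitTemporalPathway(ds))
  expect_lt(e_masked, e_full)
})

test_that("masked static fits recover an identifiable DAG pathway exactly", {
  truth <- dag_static_pathway()
  sc <- SynthScenario(nNodes = 4, nInputs = 2, noiseSigma = 0,
                      nObservations = 60, mode = "sample", seed = 90)
  ds <- generateDataset(truth, sc)
  fit <- fitStaticPathway(ds, structureFromModel(truth))
  est <- fittedModel(fit)
  expect_lt(max(abs(interactionMatrix(est) - interactionMatrix(truth))), 1e-6)
  expect_lt(max(abs(bindingMatrix(est) - bindingMatrix(truth))), 1e-6)
  expect_lt(max(abs(basalLevels(est) - basalLevels(truth))), 1e-6)
  expect_equal(unname(interactionMatrix(est)["R1", "R1"]), 0) # diagonal fixed
})

test_that("a single static sample is flagged as underdetermined", {
  v <- matrix(rnorm(4), 4, 1, dimnames = list(paste0("n", 1:4), NULL))
  ds <- ExpressionDataset(v, "sample")
  fit <- fitStaticPathway(ds)
  expect_true(all(vapply(fitFlags(fit),
                         function(f) "underdetermined" %in% f, logical(1))))
})

test_that("including the static self-term warns loudly", {
  v <- matrix(rnorm(20), 2, 10, dimnames = list(c("a", "b"), NULL))
  ds <- ExpressionDataset(v, "sample")
  expect_warning(fitStaticPathway(ds, config = rlsConfig(
    includeStaticDiagonal = TRUE)), "trivially solvable")
})

test_that("GRN fits recover regulatory matrices", {
  # noise-free temporal recovery
  sc <- SynthScenario(nNodes = 3, nInputs = 0, edgeDensity = 0.9,
                      noiseSigma = 0, nObservations = 31, seed = 41)
  truth <- randomStableNetwork(sc, "grn")
  ds <- generateDataset(truth, sc)
  est <- fittedModel(fitGrn(ds, structureFromModel(truth),
                            config = rlsConfig(P0Scale = 1e6)))
  expect_lt(max(abs(interactionMatrix(est) - interactionMatrix(truth))), 1e-6)
  # all-zero dataset: A = 0, flagged
  z <- ExpressionDataset(matrix(0, 3, 10,
                                dimnames = list(paste0("g", 1:3), NULL)),
                         "temporal")
  fz <- fitGrn(z)
  expect_true(all(interactionMatrix(fittedModel(fz)) == 0))
  expect_true(all(vapply(fitFlags(fz),
                         function(f) "no_information" %in% f, logical(1))))
})

test_that("static single-edge GRN sign is recovered from noisy samples", {
  set.seed(12)
  ids <- c("g1", "g2")
  A <- matrix(0, 2, 2, dimnames = list(ids, ids))
  A["g2", "g1"] <- -0.6
  truth <- GRNModel(A, semantics = "static")
  # fixed points driven by per-sample disturbances, K = 200, sigma = 0.05
  V <- matrix(rnorm(2 * 200, sd = 0.05), 2, 200)
  X <- solve(diag(2) - A, V)
  rownames(X) <- ids
  ds <- ExpressionDataset(X, "sample")
  est <- fittedModel(fitGrn(ds, structureFromModel(truth)))
  expect_lt(interactionMatrix(est)["g2", "g1"], 0)
})

test_that("sample-mode shuffling is seeded and changes nothing asymptotically", {
  truth <- dag_static_pathway()
  sc <- SynthScenario(nNodes = 4, nInputs = 2, noiseSigma = 0,
                      nObservations = 60, mode = "sample", seed = 91)
  ds <- generateDataset(truth, sc)
  mask <- structureFromModel(truth)
  f1 <- fitStaticPathway(ds, mask, rlsConfig(shuffle = TRUE, seed = 5))
  f2 <- fitStaticPathway(ds, mask, rlsConfig(shuffle = TRUE, seed = 5))
  expect_identical(interactionMatrix(fittedModel(f1)),
                   interactionMatrix(fittedModel(f2)))
  expect_error(fitStaticPathway(ds, mask, rlsConfig(shuffle = TRUE)),
               "seed")
  # converged fits agree with the unshuffled order
  f3 <- fitStaticPathway(ds, mask)
  expect_lt(max(abs(interactionMatrix(fittedModel(f1)) -
                    interactionMatrix(fittedModel(f3)))), 1e-6)
})

test_that("residual diagnostics report orthogonal residuals for good fits", {
  # exact fit: residuals vanish, all correlations inside the band
  sc <- SynthScenario(nNodes = 3, nInputs = 1, noiseSigma = 0,
                      nObservations = 40, seed = 55)
  truth <- randomStableNetwork(sc, "pathway")
  ds <- generateDataset(truth, sc)
  fit <- fitTemporalPathway(ds)
  d <- residualDiagnostics(fit, ds)
  expect_lt(max(abs(d$residuals)), 1e-8)
  expect_equal(d$fraction, 1)
  # well-specified noisy fit: most |r| <= 0.2
  scn <- SynthScenario(nNodes = 4, nInputs = 2, noiseSigma = 0.1,
                       nObservations = 500, seed = 56)
  tn <- randomStableNetwork(scn, "pathway")
  dn <- generateDataset(tn, scn)
  dd <- residualDiagnostics(fitTemporalPathway(dn), dn)
  expect_gt(dd$fraction, 0.9)
  # wrong dataset is rejected
  expect_error(residualDiagnostics(fit, dn), "not produced from")
})

test_that("estimation error grows with the noise variance", {
  # the identification-error variance tracks the data noise variance
  rmse_at <- function(sigma) {
    sc <- SynthScenario(nNodes = 3, nInputs = 1, edgeDensity = 0.7,
                        noiseSigma = sigma, nObservations = 120, seed = 400)
    rep <- recoveryExperiment(sc, replicates = 8, type = "pathway",
                              computeGains = FALSE)
    mean(rep@paramRMSE^2)
  }
  errs <- vapply(c(0.05, 0.1, 0.2), rmse_at, numeric(1))
  expect_true(all(diff(errs) > 0))
})
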