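test_that("the bounded-real block matrix matches its definition", {
  # scalar boundary case: c = 0.5, b = 1, D = 1, P = 2, rho = 4
  blk <- brlMatrix(matrix(0.5), matrix(1), matrix(1), P = matrix(2),
                   rho = 4)
  expect_equal(blk, matrix(c(-0.5, 1, 1, -2), 2, 2))
  expect_equal(det(blk), 0)
  expect_lte(max(eigen(blk, symmetric = TRUE, only.values = TRUE)$values), 0)
  # zero system: block is -diag(P, rho I), strictly negative definite
  blk0 <- brlMatrix(matrix(0, 2, 2), matrix(0, 2, 1), matrix(0, 1, 2),
                    P = diag(2), rho = 1)
  expect_equal(blk0, -diag(3))
  # symmetric by construction for random inputs
  set.seed(60)
  A <- matrix(rnorm(9), 3, 3)
  B <- matrix(rnorm(6), 3, 2)
  P <- crossprod(matrix(rnorm(9), 3, 3)) + diag(3)
  blkr <- brlMatrix(A, B, diag(3), P, 2.5)
  expect_identical(blkr, t(blkr))
  expect_error(brlMatrix(A, B, diag(3), matrix(rnorm(9), 3, 3), 1),
               "symmetric")
})

test_that("scalar channels attain the closed-form gain |b|/(1-|c|)", {
  for (cc in c(0.5, -0.5, 0.9, -0.9)) {
    res <- minDynamicGain(scalar_channel(cc, 1))
    expect_equal(gain(res), 1 / (1 - abs(cc)), tolerance = 1e-4)
    expect_equal(rhoRaw(res), gain(res)^2, tolerance = 1e-4)
    expect_true(isFeasible(res))
    # oracle closed form: peak at omega = 0 (c > 0) or pi (c < 0)
    expect_equal(hinfOracle(scalar_channel(cc, 1)), 1 / (1 - abs(cc)),
                 tolerance = 1e-6)
  }
  # the boundary certificate: P ~ 2 and a near-singular block at the optimum
  res <- minDynamicGain(scalar_channel(0.5, 1))
  P <- certificate(res)
  expect_equal(as.numeric(P), 2, tolerance = 0.05)
  blk <- brlMatrix(matrix(0.5), matrix(1), matrix(1), P, rhoRaw(res))
  expect_lt(abs(det(blk)), 1e-3)
  expect_lte(max(eigen(blk, symmetric = TRUE, only.values = TRUE)$values),
             1e-6)
})

test_that("memoryless and two-node channels match their closed forms", {
  # A = 0: constant transfer B/z, gain = sigma_max(B)
  set.seed(71)
  B <- matrix(rnorm(8), 4, 2)
  ch <- make_channel(matrix(0, 4, 4), B)
  expect_equal(gain(minDynamicGain(ch)), max(svd(B)$d), tolerance = 1e-6)
  # C = [[0, 0.5], [0, 0]], B = (0, 1)', D = I: flat response sqrt(1.25)
  ch2 <- make_channel(matrix(c(0, 0, 0.5, 0), 2, 2), matrix(c(0, 1), 2, 1))
  expect_equal(gain(minDynamicGain(ch2)), sqrt(1.25), tolerance = 1e-6)
  expect_equal(hinfOracle(ch2), sqrt(1.25), tolerance = 1e-8)
})

test_that("unstable channels report infinite gain without raising", {
  ch <- scalar_channel(1.01, 1)
  res <- minDynamicGain(ch)
  expect_identical(gain(res), Inf)
  expect_false(isFeasible(res))
  expect_identical(hinfOracle(ch), Inf)
})

test_that("the LMI gain agrees with the frequency-sweep oracle", {
  set.seed(500)
  for (trial in 1:12) {
    ch <- rand_channel(sample(2:8, 1), radius = runif(1, 0.2, 0.9),
                       n_inputs = sample(1:3, 1),
                       unit_output = trial %% 2 == 0)
    g_lmi <- gain(minDynamicGain(ch))
    g_orc <- hinfOracle(ch)
    expect_lt(abs(g_lmi - g_orc) / g_orc, 1e-3)
  }
})

test_that("feasibility flips across the minimized bound", {
  set.seed(501)
  for (trial in 1:6) {
    ch <- rand_channel(sample(2:6, 1), radius = runif(1, 0.3, 0.85))
    rho_min <- rhoRaw(minDynamicGain(ch))
    expect_true(lmiFeasible(ch, rho_min * (1 + 1e-6)))
    expect_false(lmiFeasible(ch, rho_min * (1 - 1e-2)))
  }
})

test_that("the Lyapunov certificate certifies the bound", {
  set.seed(502)
  for (trial in 1:5) {
    ch <- rand_channel(sample(2:6, 1), radius = runif(1, 0.3, 0.8))
    res <- minDynamicGain(ch)
    P <- certificate(res)
    expect_gt(min(eigen(P, symmetric = TRUE, only.values = TRUE)$values), 0)
    # the block at a whisker above the optimum is negative semidefinite
    blk <- brlMatrix(ch@Asub, ch@Bsub, ch@Dout, P, rhoRaw(res) * (1 + 1e-4))
    expect_lte(max(eigen(blk, symmetric = TRUE, only.values = TRUE)$values),
               1e-8 * (1 + max(abs(blk))))
  }
})

test_that("static transfer solves the fixed-point channel", {
  # C = 0: transfer is D B
  m0 <- PathwayModel(C = matrix(0, 2, 2), B = matrix(c(1, 2), 2, 1),
                     semantics = "static")
  expect_equal(unname(transferValues(staticTransfer(m0))),
               matrix(c(1, 2), 2, 1))
  # scalar 1/(1 - 0.5) * 1 = 2
  m1 <- PathwayModel(C = matrix(0.5), B = matrix(1), semantics = "static")
  expect_equal(as.numeric(transferValues(staticTransfer(m1))), 2)
  # GRN chain g1 -> g2 -> g3 with weights 0.5, 0.4: transfer = 0.2
  ids <- paste0("g", 1:3)
  A <- matrix(0, 3, 3, dimnames = list(ids, ids))
  A["g2", "g1"] <- 0.5
  A["g3", "g2"] <- 0.4
  g <- GRNModel(A, semantics = "static")
  expect_equal(as.numeric(transferValues(
    staticTransfer(g, target = "g3", source = "g1"))), 0.2)
  # temporal models are rejected
  mt <- PathwayModel(C = matrix(0.5), B = matrix(1), semantics = "temporal")
  expect_error(staticTransfer(mt), "static semantics")
})

test_that("static transductivity is the largest singular value", {
  m <- PathwayModel(C = matrix(c(0, 0, 0.5, 0), 2, 2),
                    B = matrix(c(0, 1), 2, 1), semantics = "static")
  res <- staticTransductivity(m)
  expect_equal(gain(res), sqrt(1.25), tolerance = 1e-12)
  expect_identical(res@mode, "static_svd")
  expect_true(is.na(rhoRaw(res)))
  # single-edge GRN: gamma = |a|
  ids <- c("g1", "g2")
  A <- matrix(0, 2, 2, dimnames = list(ids, ids))
  A["g2", "g1"] <- 0.7
  g <- GRNModel(A, semantics = "static")
  expect_equal(gain(staticTransductivity(g, target = "g2", source = "g1")),
               0.7)
  # homogeneity: tripling B triples the gain exactly
  m3 <- PathwayModel(C = m@C, B = 3 * m@B, semantics = "static")
  expect_equal(gain(staticTransductivity(m3)), 3 * gain(res))
})

test_that("gains scale homogeneously and respect the selector bound", {
  set.seed(503)
  for (trial in 1:5) {
    n <- sample(2:6, 1)
    C <- rand_stable_matrix(n, runif(1, 0.3, 0.8))
    B <- matrix(rnorm(n * 2), n, 2)
    m <- PathwayModel(C = C, B = B, semantics = "temporal")
    g1 <- gain(minDynamicGain(extractPathwayChannel(m)))
    malpha <- PathwayModel(C = C, B = -2.5 * B, semantics = "temporal")
    g2 <- gain(minDynamicGain(extractPathwayChannel(malpha)))
    expect_equal(g2, 2.5 * g1, tolerance = 1e-6)
    # single-node outputs are bounded by the all-output gain
    gi <- gain(minDynamicGain(extractPathwayChannel(m, target = 1)))
    expect_lte(gi, g1 * (1 + 1e-6))
    # and the dynamic gain dominates the static DC value
    dc <- max(svd(solve(diag(n) - C, B))$d)
    expect_gte(g1 * (1 + 1e-6), dc)
  }
})

test_that("static tree-GRN transductivity is the path product", {
  set.seed(504)
  for (trial in 1:6) {
    tg <- rand_tree_grn(sample(4:9, 1))
    A <- interactionMatrix(tg$model)
    n <- nrow(A)
    i <- sample.int(n, 1)
    for (j in seq_len(n)) {
      if (i == j) next
      pp <- tree_path_product(A, j, i)
      tv <- as.numeric(transferValues(
        staticTransfer(tg$model, target = i, source = j)))
      if (is.na(pp)) {
        expect_lt(abs(tv), 1e-12)
      } else {
        expect_lt(abs(tv - pp), 1e-12)
        expect_lt(abs(gain(staticTransductivity(tg$model, target = i,
                                                source = j)) - abs(pp)),
                  1e-12)
      }
    }
  }
})

test_that("transductivity tables are consistent with single-channel calls", {
  truth <- dag_static_pathway()
  tt <- transductivityTable(truth, targets = c("K1", "TF1"))
  expect_equal(nrow(tt), 2)
  for (k in seq_len(nrow(tt)))
    expect_equal(tt$gain[k],
                 gain(staticTransductivity(truth, target = tt$target[k])))
  # per-input columns match the single-signal formula
  tpi <- transductivityTable(truth, targets = "TF1", perInput = TRUE)
  expect_equal(nrow(tpi), 2)
  for (k in seq_len(nrow(tpi)))
    expect_equal(tpi$gain[k],
                 gain(staticTransductivity(truth, target = "TF1",
                                           source = tpi$source[k])))
  # joint-signal gain dominates every single-input gain
  joint <- transductivityTable(truth, targets = "TF1")$gain
  expect_true(all(tpi$gain <= joint + 1e-12))
})

test_that("condition comparison flags exactly the perturbed channels", {
  # identical tables: zero differences, unit ratios
  truth <- dag_static_pathway()
  ta <- transductivityTable(truth)
  cmp0 <- compareConditions(ta, ta)
  expect_true(all(cmp0$diff == 0))
  expect_true(all(cmp0$ratio == 1))
  expect_true(all(cmp0$flag == "unchanged"))
  # halve one edge: only channels through it move (exact at sigma = 0)
  C2 <- interactionMatrix(truth)
  C2["TF1", "K1"] <- C2["TF1", "K1"] / 2
  perturbed <- PathwayModel(C = C2, H = basalLevels(truth),
                            B = bindingMatrix(truth), semantics = "static")
  cmp <- compareConditions(ta, transductivityTable(perturbed))
  affected <- cmp$target[cmp$flag != "unchanged"]
  expect_identical(sort(affected), "TF1")
  expect_equal(cmp$ratio[cmp$target == "TF1"], 0.5)
  # mismatched channel sets are rejected with the difference listed
  expect_error(compareConditions(ta, transductivityTable(
    perturbed, targets = c("K1", "TF1"))), "only in A")
})
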