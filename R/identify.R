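#' @include AllClasses.R AllGenerics.R
NULL

#' Configuration for recursive least-squares identification
#'
#' @param theta0 Initial parameter value(s); scalar recycled per node.
#' @param P0Scale Initial covariance scale: each refinement round starts
#'   from `P = P0Scale * I` (warm-started parameters, fresh confidence).
#'   The implied ridge prior weight is `1/P0Scale`.
#' @param maxRounds Maximum refinement rounds (full passes over the data,
#'   re-initializing theta from the previous round's result).
#' @param tol Max-norm parameter change between rounds declaring
#'   convergence.
#' @param shuffle Shuffle sample-mode observation order (seeded); RLS at a
#'   finite number of rounds depends on order, and samples are exchangeable.
#' @param seed Seed for `shuffle`.
#' @param includeStaticDiagonal Include the self-term `y_i` among the
#'   regressors of node `i` in static mode. The self-term makes the
#'   regression trivially solvable by `theta = e_i`, so the default
#'   excludes it (`c[i,i]` fixed at 0); enabling it emits a loud warning.
#' @return A list of class `rlsConfig`.
#' @export
rlsConfig <- function(theta0 = 0, P0Scale = 1e3, maxRounds = 50L,
                      tol = 1e-8, shuffle = FALSE, seed = NULL,
                      includeStaticDiagonal = FALSE) {
  stopifnot(P0Scale > 0, maxRounds >= 1L, tol > 0)
  structure(list(theta0 = theta0, P0Scale = P0Scale,
                 maxRounds = as.integer(maxRounds), tol = tol,
                 shuffle = isTRUE(shuffle), seed = seed,
                 includeStaticDiagonal = isTRUE(includeStaticDiagonal)),
            class = "rlsConfig")
}

# One full RLS pass; theta update uses the freshly updated P (gain
# K = P_new phi = P_old phi / (1 + phi' P_old phi)) and the innovation is
# computed against the pre-update parameters.
.rls_pass <- function(theta, P, X, y) {
  n <- nrow(X)
  innov <- numeric(n)
  for (k in seq_len(n)) {
    phi <- X[k, ]
    Pphi <- P %*% phi
    denom <- 1 + sum(phi * Pphi)
    eps <- y[k] - sum(phi * theta)
    K <- Pphi / denom
    P <- P - tcrossprod(K, Pphi)
    P <- (P + t(P)) / 2
    theta <- theta + as.numeric(K) * eps
    innov[k] <- eps
  }
  list(theta = theta, P = P, innovations = innov)
}

#' One recursive least-squares update
#'
#' Applies a single RLS update to the estimator state: innovation
#' `eps = y - phi' theta`, covariance update
#' `P <- P - P phi phi' P / (1 + phi' P phi)` (symmetrized), then parameter
#' update `theta <- theta + P phi eps` with the new `P`.
#'
#' @param state An [RLSState].
#' @param phi Regressor row (numeric vector, length p).
#' @param yObs Observed scalar response.
#' @return The updated [RLSState] with the innovation appended.
#' @examples
#' s <- rlsState(theta0 = 0, P0Scale = 1)
#' s <- rlsStep(s, phi = 1, yObs = 3)   # P = 1/2, theta = 1.5
#' s@theta
#' @export
rlsStep <- function(state, phi, yObs) {
  stopifnot(is(state, "RLSState"))
  phi <- as.numeric(phi)
  if (length(phi) != length(state@theta))
    stop("dimension mismatch on regressor phi")
  if (any(!is.finite(phi)) || !is.finite(yObs))
    stop("non-finite regressor or response in rlsStep")
  upd <- .rls_pass(state@theta, state@P, matrix(phi, 1), yObs)
  new("RLSState", theta = upd$theta, P = upd$P, round = state@round,
      innovations = c(state@innovations, upd$innovations))
}

.condition_number <- function(X) {
  if (!length(X) || all(X == 0)) return(Inf)
  d <- svd(X, nu = 0, nv = 0)$d
  if (min(d) <= 0) Inf else max(d) / min(d)
}

#' Fit one node's parameters by multi-round recursive least squares
#'
#' Runs repeated full RLS passes over the observations. Each round warm
#' starts from the previous round's parameters while the covariance is
#' reset to `P0Scale * I` (fresh confidence), until the max-norm parameter
#' change between rounds drops below `tol` or `maxRounds` is reached. A
#' single round equals the ridge-regularized batch solution with penalty
#' `P0^-1` centered at the round's initial parameters, so the rounds
#' converge to the least-squares solution on full-rank problems.
#'
#' @param regressors Numeric matrix (observations x parameters).
#' @param responses Numeric response vector.
#' @param theta0 Initial parameters (scalar recycled).
#' @param P0Scale,maxRounds,tol See [rlsConfig()].
#' @return List: `theta`, `rounds`, `finalChange`, `innovations` (last
#'   round), `conditioning` (regressor condition number), `flags`,
#'   `converged`.
#' @export
rlsFitNode <- function(regressors, responses, theta0 = 0, P0Scale = 1e3,
                       maxRounds = 50L, tol = 1e-8) {
  X <- as.matrix(regressors)
  y <- as.numeric(responses)
  if (nrow(X) != length(y))
    stop("dimension mismatch: regressor rows vs responses")
  if (nrow(X) < 1L) stop("at least one observation is required")
  stopifnot(P0Scale > 0)
  p <- ncol(X)
  theta <- rep_len(as.numeric(theta0), p)
  flags <- character(0)
  if (p == 0L || all(X == 0)) {
    return(list(theta = theta, rounds = 0L, finalChange = 0,
                innovations = y, conditioning = Inf,
                flags = "no_information", converged = FALSE))
  }
  kappa <- .condition_number(X)
  if (!is.finite(kappa) || kappa > 1e10) flags <- c(flags, "rank_deficient")
  if (nrow(X) < p) flags <- c(flags, "underdetermined")
  finalChange <- Inf
  rounds <- 0L
  innov <- numeric(0)
  for (r in seq_len(maxRounds)) {
    prev <- theta
    upd <- .rls_pass(theta, diag(P0Scale, p), X, y)
    theta <- upd$theta
    innov <- upd$innovations
    finalChange <- max(abs(theta - prev))
    rounds <- r
    if (finalChange < tol) break
  }
  list(theta = theta, rounds = rounds, finalChange = finalChange,
       innovations = innov, conditioning = kappa, flags = flags,
       converged = finalChange < tol)
}

# --- regression assembly ----------------------------------------------------

# Column plan for one node's regression. kind: pathway/grn; temporal flag
# decides the response alignment (y(t+1) vs y(k)) and whether an intercept
# and input columns are present (pathway only).
.node_column_plan <- function(dataset, node, kind, structure,
                              includeStaticDiagonal) {
  ids <- nodeIds(dataset)
  uids <- inputIds(dataset)
  mids <- inhibitorIds(dataset)
  temporal <- kind %in% c("pathway_temporal", "grn_temporal")
  pathway <- kind %in% c("pathway_temporal", "pathway_static")

  if (is.null(structure)) {
    node_regs <- ids
    in_regs <- if (pathway) uids else character(0)
    m_regs <- mids
  } else {
    e <- structure@edges
    node_regs <- ids[ids %in% e$from[e$to == node]]
    ib <- structure@inputBindings
    in_regs <- if (pathway) uids[uids %in% ib$input[ib$node == node]]
               else character(0)
    hb <- structure@inhibitorBindings
    m_regs <- mids[mids %in% hb$inhibitor[hb$node == node]]
  }
  if (!temporal && !includeStaticDiagonal)
    node_regs <- setdiff(node_regs, node)
  data.frame(
    kind = c(rep("node", length(node_regs)),
             rep("input", length(in_regs)),
             rep("inhibitor", length(m_regs)),
             if (pathway) "intercept" else character(0)),
    id = c(node_regs, in_regs, m_regs, if (pathway) "(basal)"),
    stringsAsFactors = FALSE)
}

# Build the regression (X, y) for one node under the column plan.
# Inhibitor regressors enter negated so their coefficients estimate the
# nonnegative entries of B_m directly.
.node_regression <- function(dataset, node, plan, temporal) {
  Y <- exprValues(dataset)
  U <- inputSeries(dataset)
  Mm <- inhibitorSeries(dataset)
  N <- ncol(Y)
  rows <- if (temporal) seq_len(N - 1) else seq_len(N)
  X <- matrix(0, length(rows), nrow(plan))
  for (cidx in seq_len(nrow(plan))) {
    X[, cidx] <- switch(plan$kind[cidx],
      node = Y[plan$id[cidx], rows],
      input = U[plan$id[cidx], rows],
      inhibitor = -Mm[plan$id[cidx], rows],
      intercept = 1)
  }
  y <- if (temporal) Y[node, rows + 1] else Y[node, rows]
  list(X = X, y = y)
}

.check_structure_nodes <- function(structure, dataset) {
  if (is.null(structure)) return(invisible(NULL))
  stopifnot(is(structure, "NetworkStructure"))
  bad <- setdiff(structure@nodes, nodeIds(dataset))
  if (length(bad))
    stop("structure declares nodes absent from the dataset: ",
         paste(bad, collapse = ", "))
  invisible(NULL)
}

# Shared engine for all four fit flavors.
.fit_network <- function(dataset, structure, config, kind) {
  stopifnot(is(dataset, "ExpressionDataset"))
  if (!inherits(config, "rlsConfig")) config <- do.call(rlsConfig, config)
  .check_structure_nodes(structure, dataset)
  temporal <- kind %in% c("pathway_temporal", "grn_temporal")
  pathway <- kind %in% c("pathway_temporal", "pathway_static")
  if (temporal && obsMode(dataset) != "temporal")
    stop("dataset must be in temporal mode for a temporal fit")
  if (!temporal && obsMode(dataset) != "sample")
    stop("dataset must be in sample mode for a static fit")
  N <- nObs(dataset)
  if (temporal && N < 2L)
    stop("temporal fit needs consecutive pairs (N >= 2)")
  if (!temporal && config$includeStaticDiagonal)
    warning("includeStaticDiagonal = TRUE: the self-term makes the static ",
            "regression trivially solvable (theta = e_i); the estimated ",
            "parameters are not meaningful", call. = FALSE)

  ids <- nodeIds(dataset)
  M <- length(ids)
  n_rows <- if (temporal) N - 1L else N
  perm <- seq_len(n_rows)
  if (config$shuffle) {
    if (is.null(config$seed))
      stop("shuffle = TRUE requires a seed in the rls configuration")
    set.seed(config$seed)
    perm <- sample.int(n_rows)
  }

  resid <- matrix(0, M, n_rows, dimnames = list(ids, NULL))
  convergence <- setNames(numeric(M), ids)
  conditioning <- setNames(numeric(M), ids)
  flags <- setNames(vector("list", M), ids)
  node_fits <- setNames(vector("list", M), ids)

  C <- matrix(0, M, M, dimnames = list(ids, ids))
  H <- setNames(numeric(M), ids)
  uids <- if (pathway) inputIds(dataset) else character(0)
  B <- matrix(0, M, length(uids), dimnames = list(ids, uids))
  mids <- inhibitorIds(dataset)
  Bm <- matrix(0, M, length(mids), dimnames = list(ids, mids))

  for (i in seq_len(M)) {
    node <- ids[i]
    plan <- .node_column_plan(dataset, node, kind, structure,
                              config$includeStaticDiagonal)
    reg <- .node_regression(dataset, node, plan, temporal)
    fit <- rlsFitNode(reg$X[perm, , drop = FALSE], reg$y[perm],
                      theta0 = config$theta0, P0Scale = config$P0Scale,
                      maxRounds = config$maxRounds, tol = config$tol)
    theta <- fit$theta
    node_flags <- fit$flags
    for (cidx in seq_len(nrow(plan))) {
      val <- theta[cidx]
      switch(plan$kind[cidx],
        node = { C[node, plan$id[cidx]] <- val },
        input = { B[node, plan$id[cidx]] <- val },
        inhibitor = {
          if (val < 0) {
            node_flags <- c(node_flags, "negative_inhibition_estimate")
            val <- 0
          }
          Bm[node, plan$id[cidx]] <- val
        },
        intercept = { H[node] <- val })
    }
    resid[i, ] <- reg$y - as.numeric(reg$X %*% theta)
    convergence[i] <- fit$finalChange
    conditioning[i] <- fit$conditioning
    flags[[i]] <- node_flags
    node_fits[[i]] <- list(theta = theta, plan = plan)
  }

  model <- if (pathway) {
    PathwayModel(C = C, H = H, B = B,
                 Bm = if (length(mids)) Bm else NULL,
                 semantics = if (temporal) "temporal" else "static",
                 nodeIds = ids, inputIds = uids, inhibitorIds = mids)
  } else {
    GRNModel(A = C, semantics = if (temporal) "temporal" else "static",
             Bm = if (length(mids)) Bm else NULL,
             nodeIds = ids, inhibitorIds = mids)
  }
  new("FitReport", model = model, residuals = resid,
      convergence = convergence, conditioning = conditioning, flags = flags,
      fitInfo = list(kind = kind, structure = structure, config = config,
                     nodeFits = node_fits))
}

#' Identify a temporal pathway model from time-course data
#'
#' Regresses each protein's next expression value on the current expression
#' of all proteins, the current extracellular inputs and a basal intercept
#' (inhibitor series, when present, enter negated), node by node via
#' multi-round recursive least squares, and assembles the interaction
#' matrix `C`, basal vector `H`, binding matrix `B` and inhibitory `B_m`.
#' With a [NetworkStructure] mask, only declared edges/bindings are
#' estimated (columns are removed from the regression rather than zeroed
#' afterwards); all other coefficients are fixed at zero.
#'
#' @param dataset An [ExpressionDataset] in temporal mode (N >= 2).
#' @param structure Optional [NetworkStructure] mask.
#' @param config An [rlsConfig()].
#' @return A [FitReport] carrying a temporal [PathwayModel].
#' @seealso [fitStaticPathway()], [fitGrn()], [residualDiagnostics()]
#' @export
fitTemporalPathway <- function(dataset, structure = NULL,
                               config = rlsConfig()) {
  .fit_network(dataset, structure, config, "pathway_temporal")
}

#' Identify a static pathway model from sample data
#'
#' For single-time-point multi-sample data, fits the fixed-point regression
#' of each protein's expression on the other proteins, the inputs and an
#' intercept. The self-term is excluded by default (`c[i,i] = 0`), because
#' including a node's own expression among its regressors admits the
#' trivial perfect fit; see [rlsConfig()]'s `includeStaticDiagonal`.
#'
#' @param dataset An [ExpressionDataset] in sample mode (K >= 1).
#' @inheritParams fitTemporalPathway
#' @return A [FitReport] carrying a static [PathwayModel].
#' @export
fitStaticPathway <- function(dataset, structure = NULL,
                             config = rlsConfig()) {
  .fit_network(dataset, structure, config, "pathway_static")
}

#' Identify a gene regulatory network model
#'
#' Fits the linear GRN model node by node: in temporal mode each gene's
#' next expression is regressed on the current expression of all genes
#' (`x(t+1) = A x(t)`); in sample mode the fixed-point regression is used
#' with the diagonal excluded, as in [fitStaticPathway()]. No basal or
#' exogenous-input terms are estimated; inhibitor series (microRNA
#' repression), when present in the dataset, enter negated and populate
#' `B_m`.
#'
#' @param dataset An [ExpressionDataset]; its mode selects the semantics.
#' @inheritParams fitTemporalPathway
#' @return A [FitReport] carrying a [GRNModel].
#' @export
fitGrn <- function(dataset, structure = NULL, config = rlsConfig()) {
  kind <- if (obsMode(dataset) == "temporal") "grn_temporal" else "grn_static"
  .fit_network(dataset, structure, config, kind)
}

#' Residual and orthogonality diagnostics of a fit
#'
#' Recomputes the per-node modeling-error series
#' \eqn{\hat w_i = y_i - \phi_i \hat\theta_i} and the Pearson correlation
#' between each residual series and each of that node's regressor series.
#' For a well-specified least-squares fit these correlations concentrate
#' near zero; the summary reports the fraction with `|r| <= 0.2`.
#'
#' @param report A [FitReport].
#' @param dataset The [ExpressionDataset] the report was fitted from.
#' @return List: `residuals` (matrix), `correlations` (per-node named
#'   vectors), `fraction` (share of correlations with `|r| <= 0.2`),
#'   `flags` (per-node; `"constant_series"` where a correlation was
#'   undefined and reported as 0).
#' @export
residualDiagnostics <- function(report, dataset) {
  stopifnot(is(report, "FitReport"), is(dataset, "ExpressionDataset"))
  info <- report@fitInfo
  temporal <- info$kind %in% c("pathway_temporal", "grn_temporal")
  ids <- nodeIds(dataset)
  if (!identical(ids, nodeIds(report@model)))
    stop("report was not produced from this dataset (node ids differ)")
  n_rows <- if (temporal) nObs(dataset) - 1L else nObs(dataset)
  if (n_rows != ncol(report@residuals))
    stop("report was not produced from this dataset (observation counts differ)")

  correlations <- setNames(vector("list", length(ids)), ids)
  flags <- setNames(vector("list", length(ids)), ids)
  resid <- matrix(0, length(ids), n_rows, dimnames = list(ids, NULL))
  all_r <- numeric(0)
  for (i in seq_along(ids)) {
    nf <- info$nodeFits[[ids[i]]]
    reg <- .node_regression(dataset, ids[i], nf$plan, temporal)
    w <- reg$y - as.numeric(reg$X %*% nf$theta)
    resid[i, ] <- w
    keep <- nf$plan$kind != "intercept"
    r <- setNames(numeric(sum(keep)), nf$plan$id[keep])
    fl <- character(0)
    cols <- which(keep)
    # an (almost) exactly-fit node has no residual signal to correlate:
    # orthogonality holds trivially and the correlation is reported as 0
    w_negligible <- sd(w) <= 1e-10 * (1 + sd(reg$y))
    if (w_negligible) fl <- c(fl, "negligible_residual")
    for (k in seq_along(cols)) {
      x <- reg$X[, cols[k]]
      if (sd(x) == 0 || sd(w) == 0 || w_negligible) {
        r[k] <- 0
        if (sd(x) == 0 || sd(w) == 0) fl <- c(fl, "constant_series")
      } else {
        r[k] <- cor(w, x)
      }
    }
    correlations[[i]] <- r
    flags[[i]] <- unique(fl)
    all_r <- c(all_r, r)
  }
  fraction <- if (length(all_r)) mean(abs(all_r) <= 0.2) else NA_real_
  list(residuals = resid, correlations = correlations, fraction = fraction,
       flags = flags)
}
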