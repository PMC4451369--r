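#' @import methods
#' @importFrom stats rnorm runif sd cor optimize quantile setNames
#' @importFrom utils read.delim write.table head
#' @importFrom SummarizedExperiment SummarizedExperiment assay
#' @importFrom S4Vectors metadata
NULL

.modes <- c("temporal", "sample")
.semantics <- c("temporal", "static")

# ---------------------------------------------------------------------------
# ExpressionDataset
# ---------------------------------------------------------------------------

#' ExpressionDataset: expression matrix with observation mode and inputs
#'
#' Container for a node x observation expression matrix (proteins or genes),
#' built on [SummarizedExperiment::SummarizedExperiment]. Observations are
#' either ordered equispaced time points (`mode = "temporal"`) or independent
#' samples at a single time point (`mode = "sample"`). Optional exogenous
#' blocks carry extracellular input signals (ligands) and nonnegative
#' inhibitor signals (methylation/microRNA series) measured over the same
#' observations.
#'
#' @slot obsMode `"temporal"` or `"sample"`.
#' @slot inputs Numeric matrix, input signals x observations (0 rows if none).
#' @slot inhibitors Nonnegative numeric matrix, inhibitor signals x
#'   observations (0 rows if none).
#'
#' @param values Numeric matrix (nodes x observations). Row names are the
#'   node ids; unnamed rows get `node1..nodeM`.
#' @param mode `"temporal"` or `"sample"`.
#' @param inputs,inhibitors Optional numeric matrices with the same number of
#'   columns as `values`; row names are the signal ids.
#'
#' @return An `ExpressionDataset`.
#' @examples
#' y <- matrix(rnorm(12), 3, 4, dimnames = list(c("R1", "K1", "TF1"), NULL))
#' u <- matrix(rnorm(4), 1, 4, dimnames = list("ligand", NULL))
#' ds <- ExpressionDataset(y, mode = "temporal", inputs = u)
#' nodeIds(ds)
#' @aliases ExpressionDataset-class
#' @export
ExpressionDataset <- function(values, mode = c("temporal", "sample"),
                              inputs = NULL, inhibitors = NULL) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)))
    rownames(values) <- paste0("node", seq_len(nrow(values)))
  inputs <- .as_signal_matrix(inputs, ncol(values), "input")
  inhibitors <- .as_signal_matrix(inhibitors, ncol(values), "inhibitor")
  se <- SummarizedExperiment(assays = list(expression = values))
  new("ExpressionDataset", se, obsMode = mode, inputs = inputs,
      inhibitors = inhibitors)
}

.as_signal_matrix <- function(x, n_obs, what) {
  if (is.null(x))
    return(matrix(numeric(0), nrow = 0, ncol = n_obs))
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(rownames(x)))
    rownames(x) <- paste0(what, seq_len(nrow(x)))
  x
}

setClass("ExpressionDataset",
  contains = "SummarizedExperiment",
  slots = c(obsMode = "character", inputs = "matrix", inhibitors = "matrix"))

setValidity("ExpressionDataset", function(object) {
  msg <- character(0)
  v <- assay(object, "expression")
  if (!length(object@obsMode) == 1L || !object@obsMode %in% .modes)
    msg <- c(msg, "obsMode must be 'temporal' or 'sample'")
  if (ncol(v) < 1L)
    msg <- c(msg, "at least one observation is required")
  if (anyNA(v) || any(!is.finite(v)))
    msg <- c(msg, "expression values must be finite with no missing entries")
  if (anyDuplicated(rownames(v)))
    msg <- c(msg, "duplicated node ids")
  for (nm in c("inputs", "inhibitors")) {
    m <- slot(object, nm)
    if (nrow(m) > 0L) {
      if (ncol(m) != ncol(v))
        msg <- c(msg, sprintf("%s must share the observation count (%d)",
                              nm, ncol(v)))
      if (anyNA(m) || any(!is.finite(m)))
        msg <- c(msg, sprintf("%s must be finite", nm))
      if (anyDuplicated(rownames(m)))
        msg <- c(msg, sprintf("duplicated %s ids", nm))
    }
  }
  if (nrow(object@inhibitors) > 0L && any(object@inhibitors < 0))
    msg <- c(msg, "inhibitor series must be nonnegative")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# NetworkStructure
# ---------------------------------------------------------------------------

#' NetworkStructure: directed topology restricting estimable parameters
#'
#' Edge list plus input/inhibitor bindings over a declared node universe,
#' standing in for curated pathway or regulatory topologies. Used as a mask
#' during identification: only declared edges/bindings are estimated, all
#' other coefficients are fixed at zero.
#'
#' @slot nodes Ordered character vector of node names.
#' @slot edges `data.frame(from, to, sign)` of directed edges
#'   (regulator `from` -> target `to`); `sign` in `{-1, 0, 1}` with 0 =
#'   unconstrained.
#' @slot inputBindings `data.frame(input, node)`.
#' @slot inhibitorBindings `data.frame(inhibitor, node)`.
#'
#' @param nodes Character vector of node names.
#' @param edges Two- or three-column data.frame (`from`, `to`, optional
#'   `sign`), or `NULL`.
#' @param inputBindings,inhibitorBindings Two-column data.frames
#'   (`input`/`inhibitor`, `node`), or `NULL`.
#' @return A `NetworkStructure`.
#' @examples
#' ns <- NetworkStructure(c("a", "b", "c"),
#'                        edges = data.frame(from = c("a", "b"),
#'                                           to = c("b", "c")))
#' @aliases NetworkStructure-class
#' @export
NetworkStructure <- function(nodes, edges = NULL, inputBindings = NULL,
                             inhibitorBindings = NULL) {
  new("NetworkStructure",
      nodes = as.character(nodes),
      edges = .norm_edges(edges),
      inputBindings = .norm_bindings(inputBindings, "input"),
      inhibitorBindings = .norm_bindings(inhibitorBindings, "inhibitor"))
}

.norm_edges <- function(edges) {
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L)
    return(data.frame(from = character(0), to = character(0),
                      sign = numeric(0)))
  edges <- as.data.frame(edges)
  if (!"sign" %in% names(edges)) edges$sign <- 0
  data.frame(from = as.character(edges$from), to = as.character(edges$to),
             sign = as.numeric(edges$sign))
}

.norm_bindings <- function(b, what) {
  if (is.null(b) || nrow(as.data.frame(b)) == 0L) {
    out <- data.frame(x = character(0), node = character(0))
    names(out)[1] <- what
    return(out)
  }
  b <- as.data.frame(b)
  out <- data.frame(x = as.character(b[[1]]), node = as.character(b[[2]]))
  names(out)[1] <- what
  out
}

setClass("NetworkStructure",
  slots = c(nodes = "character", edges = "data.frame",
            inputBindings = "data.frame", inhibitorBindings = "data.frame"))

setValidity("NetworkStructure", function(object) {
  msg <- character(0)
  if (anyDuplicated(object@nodes))
    msg <- c(msg, "duplicated node names")
  e <- object@edges
  if (nrow(e)) {
    bad <- setdiff(unique(c(e$from, e$to)), object@nodes)
    if (length(bad))
      msg <- c(msg, paste("edge endpoints not declared as nodes:",
                          paste(bad, collapse = ", ")))
    if (anyDuplicated(e[c("from", "to")]))
      msg <- c(msg, "duplicated edges")
    if (!all(e$sign %in% c(-1, 0, 1)))
      msg <- c(msg, "edge sign must be -1, 0 or 1")
  }
  for (nm in c("inputBindings", "inhibitorBindings")) {
    b <- slot(object, nm)
    if (nrow(b)) {
      bad <- setdiff(unique(b$node), object@nodes)
      if (length(bad))
        msg <- c(msg, sprintf("%s target not declared as node: %s", nm,
                              paste(bad, collapse = ", ")))
    }
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# PathwayModel
# ---------------------------------------------------------------------------

#' PathwayModel: linear model of coupling signal transduction pathways
#'
#' System matrices of the pathway model
#' \deqn{y(t+1) = C y(t) + H + B u(t) - B_m m(t) + w(t)}
#' (temporal semantics) or its fixed-point form
#' \eqn{y(k) = C y(k) + H + B u(k) + w(k)} (static semantics). `C` holds the
#' protein-protein interaction abilities, `H` the basal levels, `B` the
#' binding abilities of extracellular signals to (receptor) proteins, and
#' the optional nonnegative `B_m` the inhibitory bindings applied with an
#' explicit minus sign.
#'
#' @slot C Square interaction matrix (M x M).
#' @slot H Basal level vector (length M).
#' @slot B Input binding matrix (M x l).
#' @slot Bm Nonnegative inhibitory binding matrix (M x q, possibly 0 cols).
#' @slot semantics `"temporal"` or `"static"`.
#' @slot nodeIds,inputIds,inhibitorIds Identifier vectors.
#'
#' @param C,H,B,Bm Model matrices; `H` defaults to zeros, `B` to a 0-column
#'   matrix, `Bm` to a 0-column matrix.
#' @param semantics `"temporal"` or `"static"`.
#' @param nodeIds,inputIds,inhibitorIds Identifiers; defaulted from dimnames
#'   or generated.
#' @return A `PathwayModel`.
#' @examples
#' m <- PathwayModel(C = matrix(0.5), H = 0, B = matrix(1),
#'                   semantics = "temporal")
#' spectralRadius(m)
#' @aliases PathwayModel-class
#' @export
PathwayModel <- function(C, H = NULL, B = NULL, Bm = NULL,
                         semantics = c("temporal", "static"),
                         nodeIds = NULL, inputIds = NULL,
                         inhibitorIds = NULL) {
  semantics <- match.arg(semantics)
  C <- as.matrix(C); storage.mode(C) <- "double"
  M <- nrow(C)
  if (is.null(nodeIds))
    nodeIds <- if (!is.null(rownames(C))) rownames(C)
               else paste0("node", seq_len(M))
  if (is.null(H)) H <- numeric(M)
  if (is.null(B)) B <- matrix(numeric(0), nrow = M, ncol = 0)
  B <- as.matrix(B); storage.mode(B) <- "double"
  if (is.null(inputIds))
    inputIds <- if (!is.null(colnames(B))) colnames(B)
                else if (ncol(B)) paste0("input", seq_len(ncol(B)))
                else character(0)
  if (is.null(Bm)) Bm <- matrix(numeric(0), nrow = M, ncol = 0)
  Bm <- as.matrix(Bm); storage.mode(Bm) <- "double"
  if (is.null(inhibitorIds))
    inhibitorIds <- if (!is.null(colnames(Bm))) colnames(Bm)
                    else if (ncol(Bm)) paste0("inhibitor", seq_len(ncol(Bm)))
                    else character(0)
  dimnames(C) <- list(nodeIds, nodeIds)
  dimnames(B) <- list(nodeIds, inputIds)
  dimnames(Bm) <- list(nodeIds, inhibitorIds)
  # slot "C" would partial-match new()'s `Class` formal; assign slots directly
  obj <- new("PathwayModel")
  obj@C <- C
  obj@H <- as.numeric(H)
  obj@B <- B
  obj@Bm <- Bm
  obj@semantics <- semantics
  obj@nodeIds <- as.character(nodeIds)
  obj@inputIds <- as.character(inputIds)
  obj@inhibitorIds <- as.character(inhibitorIds)
  validObject(obj)
  obj
}

setClass("PathwayModel",
  slots = c(C = "matrix", H = "numeric", B = "matrix", Bm = "matrix",
            semantics = "character", nodeIds = "character",
            inputIds = "character", inhibitorIds = "character"))

setValidity("PathwayModel", function(object) {
  msg <- character(0)
  M <- nrow(object@C)
  if (ncol(object@C) != M) msg <- c(msg, "C must be square")
  if (length(object@H) != M) msg <- c(msg, "H length must match nrow(C)")
  if (nrow(object@B) != M) msg <- c(msg, "nrow(B) must match nrow(C)")
  if (nrow(object@Bm) != M) msg <- c(msg, "nrow(Bm) must match nrow(C)")
  if (length(object@nodeIds) != M) msg <- c(msg, "nodeIds length mismatch")
  if (length(object@inputIds) != ncol(object@B))
    msg <- c(msg, "inputIds length mismatch")
  if (length(object@inhibitorIds) != ncol(object@Bm))
    msg <- c(msg, "inhibitorIds length mismatch")
  if (!object@semantics %in% .semantics)
    msg <- c(msg, "semantics must be 'temporal' or 'static'")
  if (length(object@Bm) && any(object@Bm < 0))
    msg <- c(msg, "Bm must be entrywise nonnegative")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# GRNModel
# ---------------------------------------------------------------------------

#' GRNModel: linear gene regulatory network model
#'
#' Regulatory matrix `A` of the GRN model
#' \eqn{x(t+1) = A x(t) - B_m m(t) + v(t)} (temporal) or its sample-data
#' fixed-point form \eqn{x(k) = A x(k) + v(k)} (static). Entry `a[i, j]` is
#' the regulatory ability of gene `j` on gene `i`; by convention a positive
#' value marks gene `j` as an activator of gene `i` and a negative value as
#' an inhibitor (documented, not enforced). The optional nonnegative `B_m`
#' carries microRNA-mediated repressions.
#'
#' @slot A Square regulatory matrix (n x n).
#' @slot Bm Nonnegative repression matrix (n x q, possibly 0 cols).
#' @slot semantics `"temporal"` or `"static"`.
#' @slot nodeIds,inhibitorIds Identifier vectors.
#'
#' @param A Square numeric matrix.
#' @param semantics `"temporal"` or `"static"`.
#' @param Bm Optional nonnegative matrix (n x q).
#' @param nodeIds,inhibitorIds Identifiers; defaulted from dimnames.
#' @return A `GRNModel`.
#' @examples
#' g <- GRNModel(matrix(c(0, 0.2, 0.7, 0), 2, 2), semantics = "static")
#' @aliases GRNModel-class
#' @export
GRNModel <- function(A, semantics = c("temporal", "static"), Bm = NULL,
                     nodeIds = NULL, inhibitorIds = NULL) {
  semantics <- match.arg(semantics)
  A <- as.matrix(A); storage.mode(A) <- "double"
  n <- nrow(A)
  if (is.null(nodeIds))
    nodeIds <- if (!is.null(rownames(A))) rownames(A)
               else paste0("gene", seq_len(n))
  if (is.null(Bm)) Bm <- matrix(numeric(0), nrow = n, ncol = 0)
  Bm <- as.matrix(Bm); storage.mode(Bm) <- "double"
  if (is.null(inhibitorIds))
    inhibitorIds <- if (!is.null(colnames(Bm))) colnames(Bm)
                    else if (ncol(Bm)) paste0("inhibitor", seq_len(ncol(Bm)))
                    else character(0)
  dimnames(A) <- list(nodeIds, nodeIds)
  dimnames(Bm) <- list(nodeIds, inhibitorIds)
  new("GRNModel", A = A, Bm = Bm, semantics = semantics,
      nodeIds = as.character(nodeIds),
      inhibitorIds = as.character(inhibitorIds))
}

setClass("GRNModel",
  slots = c(A = "matrix", Bm = "matrix", semantics = "character",
            nodeIds = "character", inhibitorIds = "character"))

setValidity("GRNModel", function(object) {
  msg <- character(0)
  n <- nrow(object@A)
  if (ncol(object@A) != n) msg <- c(msg, "A must be square")
  if (length(object@nodeIds) != n) msg <- c(msg, "nodeIds length mismatch")
  if (nrow(object@Bm) != n) msg <- c(msg, "nrow(Bm) must match nrow(A)")
  if (!object@semantics %in% .semantics)
    msg <- c(msg, "semantics must be 'temporal' or 'static'")
  if (length(object@Bm) && any(object@Bm < 0))
    msg <- c(msg, "Bm must be entrywise nonnegative")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# IOSubsystem
# ---------------------------------------------------------------------------

#' IOSubsystem: an extracted input/output channel
#'
#' A single-channel state-space system `(A_sub, B_sub, D_out)` carved out of
#' a full network model: either extracellular signal(s) -> protein for a
#' pathway model, or gene `j` -> gene `i` for a GRN (where column `j` of the
#' regulatory matrix becomes the input vector and is zeroed in the state
#' matrix, so that `A_sub X + B_sub x_j` reproduces `A X` exactly). The
#' output selector `D_out` is either the identity (all nodes) or a unit row
#' picking one node.
#'
#' @slot Asub State matrix.
#' @slot Bsub Input matrix (one column per channel input).
#' @slot Dout Output selector (identity or unit row).
#' @slot source,target Human-readable channel endpoints.
#' @slot selfLoop `TRUE` for a gene self-channel (`i == j`).
#' @aliases IOSubsystem-class
#' @seealso [extractPathwayChannel()], [extractGrnChannel()]
#' @export
setClass("IOSubsystem",
  slots = c(Asub = "matrix", Bsub = "matrix", Dout = "matrix",
            source = "character", target = "character",
            selfLoop = "logical"))

setValidity("IOSubsystem", function(object) {
  msg <- character(0)
  n <- nrow(object@Asub)
  if (ncol(object@Asub) != n) msg <- c(msg, "Asub must be square")
  if (nrow(object@Bsub) != n) msg <- c(msg, "nrow(Bsub) must match Asub")
  if (ncol(object@Dout) != n) msg <- c(msg, "ncol(Dout) must match Asub")
  D <- object@Dout
  ok_identity <- nrow(D) == n && all(D == diag(n))
  ok_unit <- nrow(D) == 1L && sum(D == 1) == 1L && sum(D != 0) == 1L
  if (!(ok_identity || ok_unit))
    msg <- c(msg, "Dout must be the identity or a unit row selector")
  if (length(msg)) msg else TRUE
})

.io_subsystem <- function(Asub, Bsub, Dout, source, target,
                          selfLoop = FALSE) {
  new("IOSubsystem", Asub = as.matrix(Asub), Bsub = as.matrix(Bsub),
      Dout = as.matrix(Dout), source = source, target = target,
      selfLoop = selfLoop)
}

# ---------------------------------------------------------------------------
# FlowTrajectory
# ---------------------------------------------------------------------------

#' FlowTrajectory: an information-flow time course
#'
#' The input-driven component of the expression trajectory (basal effect
#' removed), i.e. the convolution response of a channel starting from a zero
#' initial condition.
#'
#' @slot times Integer time indices `0..T`.
#' @slot values Matrix, one row per time index, one column per channel
#'   output; the row at `t = 0` is zero.
#' @slot channel The [IOSubsystem] that generated the flow.
#' @aliases FlowTrajectory-class
#' @seealso [flowResponse()]
#' @export
setClass("FlowTrajectory",
  slots = c(times = "numeric", values = "matrix", channel = "IOSubsystem"))

setValidity("FlowTrajectory", function(object) {
  msg <- character(0)
  if (nrow(object@values) != length(object@times))
    msg <- c(msg, "values must have one row per time index")
  if (length(object@times) && object@times[1] == 0 &&
      any(object@values[1, ] != 0))
    msg <- c(msg, "flow at t = 0 must be the zero initial condition")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# RLSState
# ---------------------------------------------------------------------------

#' RLSState: running state of the recursive least-squares estimator
#'
#' Parameter vector `theta`, covariance-like matrix `P` (kept symmetric
#' positive definite by symmetrization at every update), the refinement
#' round counter and the innovation record.
#'
#' @slot theta Numeric parameter vector.
#' @slot P Symmetric positive-definite matrix.
#' @slot round Integer refinement-round counter.
#' @slot innovations Recorded prediction errors of the current round.
#' @aliases RLSState-class
#' @seealso [rlsStep()], [rlsFitNode()]
#' @export
setClass("RLSState",
  slots = c(theta = "numeric", P = "matrix", round = "integer",
            innovations = "numeric"))

setValidity("RLSState", function(object) {
  msg <- character(0)
  p <- length(object@theta)
  if (nrow(object@P) != p || ncol(object@P) != p)
    msg <- c(msg, "P must be p x p")
  if (p && max(abs(object@P - t(object@P))) > 1e-8 * (1 + max(abs(object@P))))
    msg <- c(msg, "P must be symmetric")
  if (length(msg)) msg else TRUE
})

#' Create a fresh RLS state
#'
#' @param theta0 Initial parameter vector.
#' @param P0Scale Scale of the initial covariance `P0 = P0Scale * I`
#'   (the implied ridge prior weight is `1/P0Scale`).
#' @return An [RLSState].
#' @export
rlsState <- function(theta0, P0Scale = 1e3) {
  p <- length(theta0)
  new("RLSState", theta = as.numeric(theta0),
      P = diag(P0Scale, p), round = 1L, innovations = numeric(0))
}

# ---------------------------------------------------------------------------
# FitReport
# ---------------------------------------------------------------------------

#' FitReport: identified model plus diagnostics
#'
#' Result of a node-by-node recursive least-squares identification:
#' the assembled model, the residual (modeling-error) matrix
#' \eqn{\hat w = y - \phi\hat\theta}, per-node convergence (final-round
#' max-norm parameter change), per-node regressor condition numbers and
#' flags, and enough fit metadata to rebuild the regressions for
#' [residualDiagnostics()].
#'
#' @slot model Fitted [PathwayModel] or [GRNModel].
#' @slot residuals Matrix (nodes x fitted observations).
#' @slot convergence Named numeric vector of final parameter changes.
#' @slot conditioning Named numeric vector of condition numbers.
#' @slot flags Named list of per-node character flags.
#' @slot fitInfo List: regression kind, structure mask, rls configuration.
#' @aliases FitReport-class
#' @export
setClass("FitReport",
  slots = c(model = "ANY", residuals = "matrix", convergence = "numeric",
            conditioning = "numeric", flags = "list", fitInfo = "list"))

# ---------------------------------------------------------------------------
# TransferMatrix
# ---------------------------------------------------------------------------

#' TransferMatrix: static input-to-output transfer
#'
#' The steady-state transfer `T = D (I - A)^-1 B` of a static channel; rows
#' are outputs, columns inputs.
#'
#' @slot values Numeric matrix of transfer coefficients.
#' @slot rowIds,colIds Output/input identifiers.
#' @aliases TransferMatrix-class
#' @seealso [staticTransfer()]
#' @export
setClass("TransferMatrix",
  slots = c(values = "matrix", rowIds = "character", colIds = "character"))

setValidity("TransferMatrix", function(object) {
  msg <- character(0)
  if (any(!is.finite(object@values)))
    msg <- c(msg, "transfer coefficients must be finite")
  if (nrow(object@values) != length(object@rowIds) ||
      ncol(object@values) != length(object@colIds))
    msg <- c(msg, "id lengths must match the matrix dimensions")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# TransductivityResult
# ---------------------------------------------------------------------------

#' TransductivityResult: a certified channel gain
#'
#' One transductivity value: the worst-case L2 gain of a channel. In dynamic
#' mode the gain is the square root of the minimized bounded-real-lemma
#' bound `rho`, with the optimal Lyapunov matrix as certificate; in static
#' mode it is the largest singular value (absolute value when scalar) of the
#' static transfer.
#'
#' @slot gain Nonnegative scalar, `Inf` for unstable channels.
#' @slot rhoRaw Minimized LMI bound (dynamic mode) or `NA` (static mode).
#' @slot certificate Optimal Lyapunov matrix `P` (dynamic mode) or 0 x 0.
#' @slot mode `"dynamic_lmi"` or `"static_svd"`.
#' @slot channel The [IOSubsystem] measured.
#' @slot feasible `FALSE` only for unstable (infinite-gain) channels.
#' @slot horizonNote Reminder that the bound holds for every finite horizon.
#' @aliases TransductivityResult-class
#' @seealso [minDynamicGain()], [staticTransductivity()]
#' @export
setClass("TransductivityResult",
  slots = c(gain = "numeric", rhoRaw = "numeric", certificate = "matrix",
            mode = "character", channel = "IOSubsystem",
            feasible = "logical", horizonNote = "character"))

setValidity("TransductivityResult", function(object) {
  msg <- character(0)
  if (length(object@gain) != 1L || is.na(object@gain) || object@gain < 0)
    msg <- c(msg, "gain must be a single nonnegative number (or Inf)")
  if (!object@mode %in% c("dynamic_lmi", "static_svd"))
    msg <- c(msg, "mode must be 'dynamic_lmi' or 'static_svd'")
  if (is.infinite(object@gain) && object@feasible)
    msg <- c(msg, "an infinite gain cannot be feasible")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# SynthScenario / RecoveryReport
# ---------------------------------------------------------------------------

#' SynthScenario: parameters of a synthetic-data experiment
#'
#' Describes one simulated study condition: network size and sparsity,
#' stability margin, coefficient/basal scales, noise level, dataset length,
#' observation mode and input excitation. The generators are pure functions
#' of the scenario (including its mandatory seed).
#'
#' @slot nNodes,nInputs Network and input dimensions.
#' @slot edgeDensity Off-diagonal edge probability in (0, 1].
#' @slot spectralRadiusTarget Spectral radius the coupling matrix is
#'   rescaled to, in (0, 1).
#' @slot coefficientScale,basalScale Magnitude scales for coefficients and
#'   basal levels.
#' @slot noiseSigma Standard deviation of the per-node Gaussian noise.
#' @slot nObservations Number of time points (temporal) or samples.
#' @slot mode `"temporal"` or `"sample"`.
#' @slot inputProcess One of `"impulse"`, `"step"`, `"iid_gaussian"`,
#'   `"sinusoid"`.
#' @slot seed Integer seed (mandatory).
#'
#' @param nNodes,nInputs,edgeDensity,spectralRadiusTarget,coefficientScale
#'   See slots.
#' @param basalScale,noiseSigma,nObservations,mode,inputProcess,seed
#'   See slots.
#' @return A `SynthScenario`.
#' @examples
#' sc <- SynthScenario(nNodes = 4, nInputs = 1, seed = 7)
#' @aliases SynthScenario-class
#' @export
SynthScenario <- function(nNodes = 6L, nInputs = 2L, edgeDensity = 0.3,
                          spectralRadiusTarget = 0.7, coefficientScale = 1,
                          basalScale = 0.5, noiseSigma = 0.1,
                          nObservations = 100L,
                          mode = c("temporal", "sample"),
                          inputProcess = c("iid_gaussian", "impulse",
                                           "step", "sinusoid"),
                          seed) {
  if (missing(seed) || is.null(seed))
    stop("a seed is mandatory for synthetic scenarios")
  new("SynthScenario", nNodes = as.integer(nNodes),
      nInputs = as.integer(nInputs), edgeDensity = edgeDensity,
      spectralRadiusTarget = spectralRadiusTarget,
      coefficientScale = coefficientScale, basalScale = basalScale,
      noiseSigma = noiseSigma, nObservations = as.integer(nObservations),
      mode = match.arg(mode), inputProcess = match.arg(inputProcess),
      seed = as.integer(seed))
}

setClass("SynthScenario",
  slots = c(nNodes = "integer", nInputs = "integer", edgeDensity = "numeric",
            spectralRadiusTarget = "numeric", coefficientScale = "numeric",
            basalScale = "numeric", noiseSigma = "numeric",
            nObservations = "integer", mode = "character",
            inputProcess = "character", seed = "integer"))

setValidity("SynthScenario", function(object) {
  msg <- character(0)
  if (object@nNodes < 1L) msg <- c(msg, "nNodes must be >= 1")
  if (object@nInputs < 0L) msg <- c(msg, "nInputs must be >= 0")
  if (object@edgeDensity <= 0 || object@edgeDensity > 1)
    msg <- c(msg, "edgeDensity must be in (0, 1]")
  if (object@spectralRadiusTarget <= 0 || object@spectralRadiusTarget >= 1)
    msg <- c(msg, "spectralRadiusTarget must be in (0, 1)")
  for (nm in c("coefficientScale", "basalScale", "noiseSigma")) {
    v <- slot(object, nm)
    if (!is.finite(v) || v < 0)
      msg <- c(msg, sprintf("%s must be finite and nonnegative", nm))
  }
  if (object@nObservations < 1L) msg <- c(msg, "nObservations must be >= 1")
  if (length(msg)) msg else TRUE
})

#' RecoveryReport: aggregate of a parameter/gain recovery experiment
#'
#' Per-parameter bias and root-mean-square error over replicates, true vs.
#' estimated channel gains, and any per-replicate errors, for one
#' [SynthScenario].
#'
#' @slot paramBias,paramRMSE Named numeric vectors over estimable
#'   parameters.
#' @slot gains data.frame: replicate, target, true and estimated gain.
#' @slot replicates Number of replicates attempted.
#' @slot scenario The generating [SynthScenario].
#' @slot errors List of per-replicate error messages (empty when clean).
#' @aliases RecoveryReport-class
#' @seealso [recoveryExperiment()]
#' @export
setClass("RecoveryReport",
  slots = c(paramBias = "numeric", paramRMSE = "numeric",
            gains = "data.frame", replicates = "integer",
            scenario = "SynthScenario", errors = "list"))

setValidity("RecoveryReport", function(object) {
  ok <- all(object@paramRMSE + 1e-12 >= abs(object@paramBias))
  if (!ok) "RMSE must dominate |bias| for every parameter" else TRUE
})
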