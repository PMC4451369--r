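#' @include AllClasses.R AllGenerics.R
NULL

.state_matrix <- function(model) {
  if (is(model, "PathwayModel")) model@C else model@A
}

.check_dim <- function(value, expected, axis) {
  if (value != expected)
    stop(sprintf("dimension mismatch on %s: got %d, expected %d",
                 axis, value, expected), call. = FALSE)
}

.noise_matrix <- function(M, Tlen, noiseSigma, seed) {
  if (noiseSigma < 0)
    stop("noiseSigma must be nonnegative", call. = FALSE)
  if (noiseSigma == 0)
    return(matrix(0, M, Tlen))
  if (is.null(seed))
    stop("a seed is required when noiseSigma > 0", call. = FALSE)
  set.seed(seed)
  matrix(rnorm(M * Tlen, sd = noiseSigma), M, Tlen)
}

#' Simulate a temporal network model forward in time
#'
#' Runs the one-step recursion of a temporal pathway model,
#' \deqn{y(t+1) = C y(t) + H + B u(t) - B_m m(t) + w(t),}
#' or of a temporal GRN model (no basal or exogenous-input terms),
#' \eqn{x(t+1) = A x(t) - B_m m(t) + v(t)}, with i.i.d. Gaussian noise
#' `w(t) ~ N(0, noiseSigma^2)` per node and per step. With `noiseSigma = 0`
#' the trajectory satisfies the recursion exactly.
#'
#' @param model A [PathwayModel] or [GRNModel] with temporal semantics.
#' @param uSeries Input matrix (inputs x T); ignored for GRN models. `NULL`
#'   means zero input over `nSteps` steps.
#' @param mSeries Optional inhibitor matrix (inhibitors x T).
#' @param y0 Initial state vector (defaults to zeros).
#' @param noiseSigma Noise standard deviation (>= 0).
#' @param seed Integer seed; mandatory when `noiseSigma > 0`.
#' @param nSteps Number of steps when no input/inhibitor series is given.
#' @return Numeric matrix (nodes x T+1), columns indexed `t = 0..T`.
#' @examples
#' m <- PathwayModel(C = matrix(0.5), H = 0, B = matrix(1),
#'                   semantics = "temporal")
#' simulateTemporal(m, uSeries = matrix(0, 1, 4), y0 = 3)
#' @seealso [simulateBasal()], [flowResponse()]
#' @export
simulateTemporal <- function(model, uSeries = NULL, mSeries = NULL,
                             y0 = NULL, noiseSigma = 0, seed = NULL,
                             nSteps = NULL) {
  stopifnot(is(model, "PathwayModel") || is(model, "GRNModel"))
  if (semantics(model) != "temporal")
    stop("simulateTemporal requires a model with temporal semantics")
  S <- .state_matrix(model)
  M <- nrow(S)
  is_pathway <- is(model, "PathwayModel")
  H <- if (is_pathway) model@H else numeric(M)
  B <- if (is_pathway) model@B else matrix(numeric(0), M, 0)
  Bm <- inhibitionMatrix(model)

  if (!is.null(uSeries)) {
    uSeries <- as.matrix(uSeries)
    .check_dim(nrow(uSeries), ncol(B), "input signals (rows of uSeries)")
  }
  if (!is.null(mSeries)) {
    mSeries <- as.matrix(mSeries)
    .check_dim(nrow(mSeries), ncol(Bm), "inhibitor signals (rows of mSeries)")
  }
  Tlen <- if (!is.null(uSeries)) ncol(uSeries)
          else if (!is.null(mSeries)) ncol(mSeries)
          else if (!is.null(nSteps)) as.integer(nSteps)
          else stop("provide uSeries, mSeries or nSteps")
  if (!is.null(uSeries) && !is.null(mSeries))
    .check_dim(ncol(mSeries), Tlen, "time steps (columns of mSeries)")
  if (is.null(uSeries)) uSeries <- matrix(0, ncol(B), Tlen)
  if (is.null(mSeries)) mSeries <- matrix(0, ncol(Bm), Tlen)

  if (is.null(y0)) y0 <- numeric(M)
  .check_dim(length(y0), M, "state vector y0")
  W <- .noise_matrix(M, Tlen, noiseSigma, seed)

  Y <- matrix(0, M, Tlen + 1, dimnames = list(nodeIds(model), 0:Tlen))
  Y[, 1] <- y0
  for (t in seq_len(Tlen)) {
    y <- S %*% Y[, t] + H + W[, t]
    if (ncol(B)) y <- y + B %*% uSeries[, t]
    if (ncol(Bm)) y <- y - Bm %*% mSeries[, t]
    Y[, t + 1] <- y
  }
  Y
}

#' Simulate the basal (input-free) trajectory
#'
#' The same recursion as [simulateTemporal()] with all inputs and
#' inhibitors held at zero: only the basal levels `H` and noise drive the
#' state. Subtracting this from the driven trajectory isolates the
#' information flow due to the inputs.
#'
#' @inheritParams simulateTemporal
#' @param nSteps Number of steps to simulate.
#' @return Numeric matrix (nodes x nSteps+1).
#' @export
simulateBasal <- function(model, y0 = NULL, nSteps, noiseSigma = 0,
                          seed = NULL) {
  simulateTemporal(model, uSeries = NULL, mSeries = NULL, y0 = y0,
                   noiseSigma = noiseSigma, seed = seed, nSteps = nSteps)
}

#' Information-flow response of a channel
#'
#' Computes the input-driven flow trajectory of an extracted channel from a
#' zero initial condition: the convolution sum
#' \deqn{\tilde y(t+1) = \sum_{j=0}^{t} C^{t-j} B u(j),}
#' evaluated recursively and passed through the output selector. This is
#' the trajectory whose worst-case energy ratio the transductivity bounds.
#'
#' @param channel An [IOSubsystem] (see [extractPathwayChannel()],
#'   [extractGrnChannel()]), or a temporal [PathwayModel] (full channel).
#' @param uSeries Input matrix (channel inputs x T).
#' @return A [FlowTrajectory]; its value at `t = 0` is zero.
#' @examples
#' m <- PathwayModel(C = matrix(0.5), B = matrix(1), semantics = "temporal")
#' ch <- extractPathwayChannel(m)
#' u <- matrix(c(1, 0, 0), 1, 3)     # impulse
#' flowResponse(ch, u)@values        # 0, 1, 0.5, 0.25
#' @export
flowResponse <- function(channel, uSeries) {
  if (is(channel, "PathwayModel"))
    channel <- extractPathwayChannel(channel)
  stopifnot(is(channel, "IOSubsystem"))
  uSeries <- as.matrix(uSeries)
  .check_dim(nrow(uSeries), ncol(channel@Bsub),
             "channel inputs (rows of uSeries)")
  Tlen <- ncol(uSeries)
  n <- nrow(channel@Asub)
  x <- numeric(n)
  out <- matrix(0, Tlen + 1, nrow(channel@Dout))
  for (t in seq_len(Tlen)) {
    x <- channel@Asub %*% x + channel@Bsub %*% uSeries[, t]
    out[t + 1, ] <- channel@Dout %*% x
  }
  new("FlowTrajectory", times = 0:Tlen, values = out, channel = channel)
}

#' Steady-state response of a static pathway model
#'
#' Solves the fixed-point equation of the static (sample-data) model,
#' \eqn{y = C y + H + B u + w}, i.e.
#' \eqn{y = (I - C)^{-1}(B u + H + w)}, by a linear solve.
#'
#' @param model A [PathwayModel] with static semantics.
#' @param u Input vector (length = number of inputs).
#' @param w Disturbance vector (defaults to zeros).
#' @return Named numeric state vector.
#' @export
steadyStateSample <- function(model, u = NULL, w = NULL) {
  stopifnot(is(model, "PathwayModel"))
  if (semantics(model) != "static")
    stop("steadyStateSample requires a model with static semantics")
  M <- nrow(model@C)
  if (is.null(u)) u <- numeric(ncol(model@B))
  if (is.null(w)) w <- numeric(M)
  .check_dim(length(u), ncol(model@B), "input vector u")
  .check_dim(length(w), M, "disturbance vector w")
  ImC <- diag(M) - model@C
  if (rcond(ImC) < 1e-12)
    stop("static model non-invertible: (I - C) is singular or ill-conditioned")
  rhs <- model@H + w
  if (ncol(model@B)) rhs <- rhs + model@B %*% u
  setNames(as.numeric(solve(ImC, rhs)), nodeIds(model))
}

.resolve_node <- function(ids, x, what) {
  if (is.numeric(x)) {
    x <- as.integer(x)
    if (x < 1L || x > length(ids))
      stop(sprintf("unknown %s index: %d", what, x), call. = FALSE)
    return(x)
  }
  i <- match(x, ids)
  if (is.na(i))
    stop(sprintf("unknown %s name: '%s'", what, x), call. = FALSE)
  i
}

#' Extract a signal-to-protein channel from a pathway model
#'
#' Builds the input/output subsystem used for transductivity computation:
#' the state matrix is the full interaction matrix `C`, the input matrix is
#' either the full binding matrix `B` (all extracellular signals) or the
#' binding vector of one signal, and the output selector is either the
#' identity (all proteins) or the unit row picking one protein.
#'
#' @param model A [PathwayModel].
#' @param target Node name/index, or `"all"` (identity output).
#' @param input Input name/index, or `"all"` (all signals).
#' @return An [IOSubsystem].
#' @export
extractPathwayChannel <- function(model, target = "all", input = "all") {
  stopifnot(is(model, "PathwayModel"))
  M <- nrow(model@C)
  if (identical(target, "all")) {
    D <- diag(M)
    tgt <- "all nodes"
  } else {
    i <- .resolve_node(nodeIds(model), target, "node")
    D <- matrix(0, 1, M)
    D[1, i] <- 1
    tgt <- nodeIds(model)[i]
  }
  if (identical(input, "all")) {
    Bsub <- model@B
    src <- "all signals"
  } else {
    l <- .resolve_node(inputIds(model), input, "input")
    Bsub <- model@B[, l, drop = FALSE]
    src <- inputIds(model)[l]
  }
  .io_subsystem(model@C, Bsub, D, source = src, target = tgt)
}

#' Extract a gene-to-gene channel from a GRN model
#'
#' Rearranges the GRN model so that gene `j`'s expression acts as the input
#' signal and gene `i`'s as the output: column `j` of the regulatory matrix
#' becomes the input vector `B_j` and is zeroed in the state matrix `A_j`,
#' so that `A_j X + B_j x_j` reproduces `A X` exactly for every state
#' (`A_j + B_j e_j' = A`). The output selector is the unit row `D_i`.
#' A self-channel (`i == j`) is permitted and flagged in the result.
#'
#' @param grn A [GRNModel].
#' @param source Regulator gene `j` (name or index).
#' @param target Target gene `i` (name or index).
#' @return An [IOSubsystem].
#' @examples
#' g <- GRNModel(matrix(c(0, 0.2, 0.7, 0), 2, 2,
#'                      dimnames = list(c("g1", "g2"), c("g1", "g2"))),
#'               semantics = "temporal")
#' extractGrnChannel(g, source = "g2", target = "g1")
#' @export
extractGrnChannel <- function(grn, source, target) {
  stopifnot(is(grn, "GRNModel"))
  j <- .resolve_node(nodeIds(grn), source, "node")
  i <- .resolve_node(nodeIds(grn), target, "node")
  A <- grn@A
  Bsub <- A[, j, drop = FALSE]
  Asub <- A
  Asub[, j] <- 0
  D <- matrix(0, 1, nrow(A))
  D[1, i] <- 1
  .io_subsystem(Asub, Bsub, D, source = nodeIds(grn)[j],
                target = nodeIds(grn)[i], selfLoop = i == j)
}
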