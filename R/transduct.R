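#' @include AllClasses.R AllGenerics.R linalg.R
NULL

.horizon_note <- paste("The certified bound holds for every finite horizon",
                       "(all inputs of bounded energy on [0, t_p], any t_p).")

#' Configuration for the dynamic-gain (LMI) solver
#'
#' @param epsP Strictness floor for the Lyapunov matrix (`P >= epsP * I`).
#' @param feasTol Tolerance on the maximum eigenvalue of the block matrix
#'   when certifying feasibility.
#' @param stabilityTol Channels with spectral radius `>= 1 - stabilityTol`
#'   are reported as unstable (infinite gain).
#' @param relTol Relative bisection tolerance on the gain level.
#' @param uctol Unit-circle tolerance of the spectral feasibility test.
#' @param certMargin Relative margin above the minimized bound at which the
#'   Lyapunov certificate is computed (the optimum itself sits on the
#'   feasibility boundary).
#' @param maxIter Bisection iteration cap.
#' @return A list of class `solverConfig`.
#' @export
solverConfig <- function(epsP = 1e-9, feasTol = 1e-8, stabilityTol = 1e-9,
                         relTol = 1e-8, uctol = 1e-6, certMargin = 1e-6,
                         maxIter = 200L) {
  structure(list(epsP = epsP, feasTol = feasTol, stabilityTol = stabilityTol,
                 relTol = relTol, uctol = uctol, certMargin = certMargin,
                 maxIter = as.integer(maxIter)),
            class = "solverConfig")
}

#' Bounded-real-lemma block matrix
#'
#' Assembles the symmetric block matrix of the discrete bounded real lemma
#' at level `rho`,
#' \deqn{\begin{bmatrix} A'PA - P + D'D & A'PB \\ B'PA & B'PB - \rho I
#'   \end{bmatrix},}
#' whose negative semidefiniteness for some `P > 0` certifies that the
#' channel's energy gain is at most `rho` (amplitude gain at most
#' `sqrt(rho)`).
#'
#' @param Asub,Bsub,Dout Channel matrices (state, input, output selector).
#' @param P Symmetric candidate Lyapunov matrix.
#' @param rho Candidate gain-squared level.
#' @return The symmetric block matrix.
#' @examples
#' brlMatrix(matrix(0.5), matrix(1), matrix(1), P = matrix(2), rho = 4)
#' @export
brlMatrix <- function(Asub, Bsub, Dout, P, rho) {
  Asub <- as.matrix(Asub); Bsub <- as.matrix(Bsub)
  Dout <- as.matrix(Dout); P <- as.matrix(P)
  n <- nrow(Asub)
  stopifnot(ncol(Asub) == n, nrow(Bsub) == n, ncol(Dout) == n,
            nrow(P) == n, ncol(P) == n)
  if (max(abs(P - t(P))) > 1e-8 * (1 + max(abs(P))))
    stop("P must be symmetric")
  r <- ncol(Bsub)
  tl <- t(Asub) %*% P %*% Asub - P + crossprod(Dout)
  tr <- t(Asub) %*% P %*% Bsub
  br <- t(Bsub) %*% P %*% Bsub - rho * diag(r)
  .sym(rbind(cbind(tl, tr), cbind(t(tr), br)))
}

#' Feasibility of the bounded-real LMI at a given level
#'
#' Decides whether some `P > 0` renders the [brlMatrix()] block negative
#' semidefinite at level `rho`, i.e. whether `sqrt(rho)` is an upper bound
#' on the channel gain. Feasibility is decided exactly through the spectral
#' characterization: `sqrt(rho)` must exceed the transfer gain at probe
#' frequencies and the associated symplectic pencil must have no
#' unit-circle generalized eigenvalues (no frequency at which a singular
#' value of the transfer crosses the level).
#'
#' @param channel An [IOSubsystem].
#' @param rho Candidate level (gain squared).
#' @param config A [solverConfig()].
#' @return Logical.
#' @export
lmiFeasible <- function(channel, rho, config = solverConfig()) {
  stopifnot(is(channel, "IOSubsystem"))
  if (rho < 0) return(FALSE)
  if (spectralRadius(channel@Asub) >= 1 - config$stabilityTol) return(FALSE)
  .gamma_feasible(channel@Asub, channel@Bsub, channel@Dout, sqrt(rho),
                  uctol = config$uctol)
}

#' Minimize the dynamic transductivity bound of a channel
#'
#' Computes the worst-case L2 gain of a stable channel as the square root
#' of the minimized bounded-real-lemma level: the smallest `rho` for which
#' the [brlMatrix()] LMI admits a Lyapunov matrix `P > 0`. The level is
#' found by bisection with the exact spectral feasibility test of
#' [lmiFeasible()], and the certificate `P` is recovered from the
#' associated Riccati equation just above the optimum (at the optimum the
#' block is negative semidefinite with a boundary zero eigenvalue).
#' Channels whose state matrix has spectral radius `>= 1` are reported as
#' infinite-gain and infeasible rather than raising, so batch tables run to
#' completion.
#'
#' @param channel An [IOSubsystem].
#' @param config A [solverConfig()].
#' @return A [TransductivityResult] with `mode = "dynamic_lmi"`: `gain` is
#'   `sqrt(rho_min)`, `rhoRaw` the minimized level, `certificate` the
#'   Lyapunov matrix.
#' @examples
#' m <- PathwayModel(C = matrix(0.5), B = matrix(1), semantics = "temporal")
#' res <- minDynamicGain(extractPathwayChannel(m))
#' gain(res)     # |b| / (1 - |c|) = 2
#' rhoRaw(res)   # 4
#' @seealso [hinfOracle()] for the independent frequency-sweep check.
#' @export
minDynamicGain <- function(channel, config = solverConfig()) {
  stopifnot(is(channel, "IOSubsystem"))
  A <- channel@Asub; B <- channel@Bsub; D <- channel@Dout
  empty_cert <- matrix(numeric(0), 0, 0)
  if (spectralRadius(A) >= 1 - config$stabilityTol) {
    return(new("TransductivityResult", gain = Inf, rhoRaw = Inf,
               certificate = empty_cert, mode = "dynamic_lmi",
               channel = channel, feasible = FALSE,
               horizonNote = "unstable channel: no finite gain"))
  }
  if (.zero_channel(A, B, D)) {
    n <- nrow(A)
    P <- tryCatch(.stein_solve(A, crossprod(D) + config$epsP * diag(n)),
                  error = function(e) diag(config$epsP, n))
    return(new("TransductivityResult", gain = 0, rhoRaw = 0,
               certificate = P, mode = "dynamic_lmi", channel = channel,
               feasible = TRUE, horizonNote = .horizon_note))
  }

  lo <- max(vapply(c(1 + 0i, -1 + 0i, 1i), function(z)
    .tf_sigma(A, B, D, z), numeric(1)))
  hi <- max(lo * 2, 1e-8)
  it <- 0L
  while (!.gamma_feasible(A, B, D, hi, config$uctol)) {
    hi <- hi * 4
    it <- it + 1L
    if (it > 80L) stop("dynamic gain upper bound search failed")
  }
  for (k in seq_len(config$maxIter)) {
    if (hi - lo <= config$relTol * hi) break
    mid <- (lo + hi) / 2
    if (.gamma_feasible(A, B, D, mid, config$uctol)) hi <- mid else lo <- mid
  }
  gamma <- hi
  rho <- gamma^2

  P <- NULL
  margin <- config$certMargin
  while (is.null(P) && margin <= 1e-2) {
    P <- .riccati_newton(A, B, crossprod(D), rho * (1 + margin))
    margin <- margin * 100
  }
  if (is.null(P)) {
    warning("Lyapunov certificate recovery failed; gain is still certified ",
            "by the feasibility bisection", call. = FALSE)
    P <- empty_cert
  } else {
    # keep P strictly positive definite (unobservable modes can leave it
    # singular); the offset preserves feasibility at the certified margin
    P <- P + config$epsP * diag(nrow(P))
  }
  new("TransductivityResult", gain = gamma, rhoRaw = rho, certificate = P,
      mode = "dynamic_lmi", channel = channel, feasible = TRUE,
      horizonNote = .horizon_note)
}

#' Independent frequency-sweep gain oracle
#'
#' Estimates the worst-case gain of a stable channel directly from its
#' frequency response: the maximum over `omega` in `[0, pi]` of the largest
#' singular value of `D (e^{i omega} I - A)^{-1} B`, computed on a uniform
#' grid and sharpened by local univariate optimization around the grid
#' maximum. Kept deliberately independent of the LMI route so the two can
#' cross-validate.
#'
#' @param channel An [IOSubsystem].
#' @param gridSize Number of grid frequencies (default 4096).
#' @param refine Refine around the grid maximum with [stats::optimize()].
#' @return The gain estimate; `Inf` for unstable channels.
#' @export
hinfOracle <- function(channel, gridSize = 4096L, refine = TRUE) {
  stopifnot(is(channel, "IOSubsystem"))
  A <- channel@Asub; B <- channel@Bsub; D <- channel@Dout
  if (spectralRadius(A) >= 1) return(Inf)
  if (!ncol(B) || !nrow(D)) return(0)
  omega <- seq(0, pi, length.out = gridSize)
  vals <- vapply(omega, function(w) .tf_sigma(A, B, D, exp(1i * w)),
                 numeric(1))
  k <- which.max(vals)
  best <- vals[k]
  if (refine) {
    lo <- omega[max(1L, k - 1L)]
    hi <- omega[min(gridSize, k + 1L)]
    if (hi > lo) {
      opt <- optimize(function(w) .tf_sigma(A, B, D, exp(1i * w)),
                      interval = c(lo, hi), maximum = TRUE,
                      tol = .Machine$double.eps^0.5)
      best <- max(best, opt$objective)
    }
  }
  best
}

.static_channel <- function(model, target, source) {
  if (is(model, "PathwayModel")) {
    extractPathwayChannel(model, target = target, input = source)
  } else if (is(model, "GRNModel")) {
    if (identical(source, "all"))
      stop("a GRN channel needs a single source gene")
    if (identical(target, "all"))
      stop("a GRN channel needs a single target gene")
    extractGrnChannel(model, source = source, target = target)
  } else {
    stop("model must be a PathwayModel or GRNModel")
  }
}

#' Static transfer matrix of a channel
#'
#' Computes the steady-state transfer `T = D (I - A)^{-1} B` of a static
#' channel by a linear solve (no explicit inverse): for a pathway model the
#' transduction function from the selected input(s) to the selected
#' output(s); for a GRN the gene-to-gene transfer with column `j` of the
#' regulatory matrix as input vector.
#'
#' @param model A static [PathwayModel] or [GRNModel].
#' @param target Node name/index or `"all"` (pathway only).
#' @param source Input name/index or `"all"` for a pathway; a source gene
#'   for a GRN.
#' @return A [TransferMatrix].
#' @examples
#' m <- PathwayModel(C = matrix(0.5), B = matrix(1), semantics = "static")
#' transferValues(staticTransfer(m))   # 1 / (1 - 0.5) = 2
#' @export
staticTransfer <- function(model, target = "all", source = "all") {
  if (semantics(model) != "static")
    stop("staticTransfer requires static semantics; use minDynamicGain for temporal models")
  ch <- .static_channel(model, target, source)
  n <- nrow(ch@Asub)
  ImA <- diag(n) - ch@Asub
  rc <- rcond(ImA)
  if (rc < 1e-12)
    stop(sprintf("static model non-invertible: (I - A) condition estimate %.3g exceeds 1e12",
                 1 / rc))
  Tm <- ch@Dout %*% solve(ImA, ch@Bsub)
  row_ids <- if (nrow(ch@Dout) == n) nodeIds(model) else ch@target
  col_ids <- if (is(model, "GRNModel")) ch@source
             else if (ncol(ch@Bsub) == length(inputIds(model)))
               inputIds(model)
             else ch@source
  new("TransferMatrix", values = Tm, rowIds = row_ids, colIds = col_ids)
}

#' Static transductivity of a channel
#'
#' The sample-data transductivity: the largest singular value of the static
#' transfer matrix (its absolute value when scalar). For a pathway this is
#' the signal transductivity from the selected extracellular signal(s) to
#' the selected protein(s); for a GRN the information transductivity from
#' gene `j` to gene `i`.
#'
#' @inheritParams staticTransfer
#' @return A [TransductivityResult] with `mode = "static_svd"` (`rhoRaw`
#'   is `NA`: no LMI is involved in static mode).
#' @export
staticTransductivity <- function(model, target = "all", source = "all") {
  Tm <- staticTransfer(model, target = target, source = source)
  g <- .sigma_max(Tm@values)
  ch <- .static_channel(model, target, source)
  new("TransductivityResult", gain = g, rhoRaw = NA_real_,
      certificate = matrix(numeric(0), 0, 0), mode = "static_svd",
      channel = ch, feasible = TRUE,
      horizonNote = "static (sample-data) gain: largest singular value of the transfer matrix")
}

.one_result <- function(model, target, source, config) {
  if (semantics(model) == "static") {
    staticTransductivity(model, target = target, source = source)
  } else {
    minDynamicGain(.static_channel(model, target, source), config)
  }
}

#' Transductivity table over channels of a model
#'
#' Computes one transductivity per requested (target, source) channel,
#' dispatching to the dynamic LMI engine for temporal models and to the
#' singular-value formula for static models. For a pathway model the
#' sources are the extracellular signals (jointly, or one column per input
#' with `perInput = TRUE`); for a GRN model every requested source gene is
#' paired with every requested target gene.
#'
#' @param model A [PathwayModel] or [GRNModel].
#' @param targets Target node names (default: all nodes).
#' @param sources Source genes for a GRN (default: all nodes); ignored for
#'   pathways unless `perInput`.
#' @param perInput Pathway models: one row per (target, input) pair instead
#'   of the joint all-signals gain.
#' @param config A [solverConfig()] for temporal models.
#' @return `data.frame` with columns `target`, `source`, `mode`, `gain`,
#'   `rho_raw`, `feasible`.
#' @export
transductivityTable <- function(model, targets = NULL, sources = NULL,
                                perInput = FALSE, config = solverConfig()) {
  stopifnot(is(model, "PathwayModel") || is(model, "GRNModel"))
  if (is.null(targets)) targets <- nodeIds(model)
  if (is(model, "PathwayModel")) {
    src_list <- if (perInput) inputIds(model) else "all"
  } else {
    src_list <- if (is.null(sources)) nodeIds(model) else sources
  }
  rows <- expand.grid(target = targets, source = src_list,
                      stringsAsFactors = FALSE)
  out <- vector("list", nrow(rows))
  for (k in seq_len(nrow(rows))) {
    res <- .one_result(model, rows$target[k], rows$source[k], config)
    out[[k]] <- data.frame(
      target = rows$target[k],
      source = if (identical(rows$source[k], "all")) "all signals"
               else rows$source[k],
      mode = res@mode, gain = res@gain, rho_raw = res@rhoRaw,
      feasible = res@feasible, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Differential comparison of two transductivity tables
#'
#' Joins two condition-specific tables (e.g. normal vs. disease) on their
#' channel set and reports, per channel, both gains, their difference and
#' ratio, and a gain/loss flag; rows are sorted by decreasing
#' `|log(ratio)|` so the most dysregulated channels come first. A zero
#' denominator yields ratio `Inf` with the raw gains still reported.
#'
#' @param tableA,tableB Tables from [transductivityTable()] over matching
#'   channel sets.
#' @param labels Length-2 condition labels (stored as an attribute).
#' @param ratioTol Relative deviation of the ratio from 1 beyond which a
#'   channel is flagged `"gain"` or `"loss"`.
#' @return `data.frame` with columns `target`, `source`, `gain_a`,
#'   `gain_b`, `diff`, `ratio`, `flag`.
#' @export
compareConditions <- function(tableA, tableB,
                              labels = c("condition_a", "condition_b"),
                              ratioTol = 1e-6) {
  keyA <- paste(tableA$target, tableA$source, sep = "\r")
  keyB <- paste(tableB$target, tableB$source, sep = "\r")
  if (!setequal(keyA, keyB) || anyDuplicated(keyA) || anyDuplicated(keyB)) {
    extraA <- setdiff(keyA, keyB)
    extraB <- setdiff(keyB, keyA)
    stop("channel sets differ between the two tables; only in A: {",
         paste(gsub("\r", " <- ", extraA), collapse = "; "),
         "}; only in B: {",
         paste(gsub("\r", " <- ", extraB), collapse = "; "), "}")
  }
  tableB <- tableB[match(keyA, keyB), ]
  ga <- tableA$gain
  gb <- tableB$gain
  ratio <- ifelse(ga == 0 & gb == 0, 1,
           ifelse(ga == 0, Inf, gb / ga))
  flag <- ifelse(ratio > 1 + ratioTol, "gain",
          ifelse(ratio < 1 - ratioTol, "loss", "unchanged"))
  out <- data.frame(target = tableA$target, source = tableA$source,
                    gain_a = ga, gain_b = gb, diff = gb - ga,
                    ratio = ratio, flag = flag, stringsAsFactors = FALSE)
  ord <- order(-abs(log(ifelse(out$ratio == 0, .Machine$double.xmin,
                               out$ratio))))
  out <- out[ord, ]
  rownames(out) <- NULL
  attr(out, "labels") <- labels
  out
}
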