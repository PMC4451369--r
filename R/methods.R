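#' @include AllClasses.R AllGenerics.R
NULL

# --- ExpressionDataset accessors -------------------------------------------

#' @rdname nodeIds
#' @export
setMethod("nodeIds", "ExpressionDataset",
          function(x) rownames(assay(x, "expression")))

#' @rdname exprValues
#' @export
setMethod("exprValues", "ExpressionDataset",
          function(x) assay(x, "expression"))

#' @rdname obsMode
#' @export
setMethod("obsMode", "ExpressionDataset", function(x) x@obsMode)

#' @rdname inputSeries
#' @export
setMethod("inputSeries", "ExpressionDataset", function(x) x@inputs)

#' @rdname inhibitorSeries
#' @export
setMethod("inhibitorSeries", "ExpressionDataset", function(x) x@inhibitors)

#' @rdname inputIds
#' @export
setMethod("inputIds", "ExpressionDataset", function(x) rownames(x@inputs))

#' @rdname inhibitorIds
#' @export
setMethod("inhibitorIds", "ExpressionDataset",
          function(x) rownames(x@inhibitors))

#' Number of observations in a dataset
#'
#' @param x An [ExpressionDataset].
#' @return Integer observation count.
#' @export
nObs <- function(x) ncol(exprValues(x))

setMethod("show", "ExpressionDataset", function(object) {
  v <- exprValues(object)
  cat(sprintf("ExpressionDataset: %d node(s) x %d %s observation(s)\n",
              nrow(v), ncol(v), obsMode(object)))
  cat(sprintf("  inputs: %d  inhibitors: %d\n",
              nrow(object@inputs), nrow(object@inhibitors)))
  cat("  nodes:", paste(head(rownames(v), 6), collapse = ", "),
      if (nrow(v) > 6) "..." else "", "\n")
})

# --- NetworkStructure accessors --------------------------------------------

#' @rdname nodeIds
#' @export
setMethod("nodeIds", "NetworkStructure", function(x) x@nodes)

#' Edge list of a network structure
#'
#' @param x A [NetworkStructure].
#' @return data.frame with columns `from`, `to`, `sign`.
#' @export
edges <- function(x) {
  stopifnot(is(x, "NetworkStructure"))
  x@edges
}

setMethod("show", "NetworkStructure", function(object) {
  cat(sprintf("NetworkStructure: %d node(s), %d edge(s), %d input binding(s), %d inhibitor binding(s)\n",
              length(object@nodes), nrow(object@edges),
              nrow(object@inputBindings), nrow(object@inhibitorBindings)))
})

# --- Model accessors --------------------------------------------------------

#' @rdname interactionMatrix
#' @export
setMethod("interactionMatrix", "PathwayModel", function(x) x@C)

#' @rdname interactionMatrix
#' @export
setMethod("interactionMatrix", "GRNModel", function(x) x@A)

#' @rdname basalLevels
#' @export
setMethod("basalLevels", "PathwayModel",
          function(x) setNames(x@H, x@nodeIds))

#' @rdname bindingMatrix
#' @export
setMethod("bindingMatrix", "PathwayModel", function(x) x@B)

#' @rdname inhibitionMatrix
#' @export
setMethod("inhibitionMatrix", "PathwayModel", function(x) x@Bm)

#' @rdname inhibitionMatrix
#' @export
setMethod("inhibitionMatrix", "GRNModel", function(x) x@Bm)

#' @rdname semantics
#' @export
setMethod("semantics", "PathwayModel", function(x) x@semantics)

#' @rdname semantics
#' @export
setMethod("semantics", "GRNModel", function(x) x@semantics)

#' @rdname nodeIds
#' @export
setMethod("nodeIds", "PathwayModel", function(x) x@nodeIds)

#' @rdname nodeIds
#' @export
setMethod("nodeIds", "GRNModel", function(x) x@nodeIds)

#' @rdname inputIds
#' @export
setMethod("inputIds", "PathwayModel", function(x) x@inputIds)

#' @rdname inhibitorIds
#' @export
setMethod("inhibitorIds", "PathwayModel", function(x) x@inhibitorIds)

#' @rdname inhibitorIds
#' @export
setMethod("inhibitorIds", "GRNModel", function(x) x@inhibitorIds)

#' @rdname spectralRadius
#' @export
setMethod("spectralRadius", "matrix", function(x) {
  if (!nrow(x)) return(0)
  max(Mod(eigen(x, only.values = TRUE)$values))
})

#' @rdname spectralRadius
#' @export
setMethod("spectralRadius", "PathwayModel",
          function(x) spectralRadius(x@C))

#' @rdname spectralRadius
#' @export
setMethod("spectralRadius", "GRNModel",
          function(x) spectralRadius(x@A))

.show_model <- function(object, label, S) {
  sr <- spectralRadius(S)
  cat(sprintf("%s (%s): %d node(s)\n", label, object@semantics, nrow(S)))
  if (object@semantics == "temporal") {
    cat(sprintf("  spectral radius: %.4g (%s)\n", sr,
                if (sr < 1) "stable" else "UNSTABLE"))
  } else {
    kap <- tryCatch(1 / rcond(diag(nrow(S)) - S), error = function(e) Inf)
    cat(sprintf("  (I - %s) condition estimate: %.3g (%s)\n",
                if (is(object, "PathwayModel")) "C" else "A", kap,
                if (is.finite(kap) && kap < 1e12) "invertible"
                else "NON-INVERTIBLE"))
  }
}

setMethod("show", "PathwayModel", function(object) {
  .show_model(object, "PathwayModel", object@C)
  cat(sprintf("  inputs: %d  inhibitors: %d\n",
              ncol(object@B), ncol(object@Bm)))
})

setMethod("show", "GRNModel", function(object) {
  .show_model(object, "GRNModel", object@A)
  cat(sprintf("  inhibitors: %d\n", ncol(object@Bm)))
})

setMethod("show", "IOSubsystem", function(object) {
  cat(sprintf("IOSubsystem: %s -> %s (%d states, %d input(s), %d output(s))%s\n",
              object@source, object@target, nrow(object@Asub),
              ncol(object@Bsub), nrow(object@Dout),
              if (isTRUE(object@selfLoop)) " [self-loop channel]" else ""))
})

setMethod("show", "FlowTrajectory", function(object) {
  cat(sprintf("FlowTrajectory: %s -> %s, t = %d..%d\n",
              object@channel@source, object@channel@target,
              min(object@times), max(object@times)))
})

# --- TransductivityResult accessors ----------------------------------------

#' @rdname gain
#' @export
setMethod("gain", "TransductivityResult", function(x) x@gain)

#' @rdname rhoRaw
#' @export
setMethod("rhoRaw", "TransductivityResult", function(x) x@rhoRaw)

#' @rdname certificate
#' @export
setMethod("certificate", "TransductivityResult", function(x) x@certificate)

#' @rdname isFeasible
#' @export
setMethod("isFeasible", "TransductivityResult", function(x) x@feasible)

setMethod("show", "TransductivityResult", function(object) {
  cat(sprintf("TransductivityResult [%s] %s -> %s\n", object@mode,
              object@channel@source, object@channel@target))
  cat(sprintf("  gain: %.6g  rho: %.6g  feasible: %s\n", object@gain,
              object@rhoRaw, object@feasible))
})

# --- FitReport accessors ----------------------------------------------------

#' @rdname fittedModel
#' @export
setMethod("fittedModel", "FitReport", function(x) x@model)

#' Residual (modeling-error) matrix of a fit
#'
#' The per-node modeling error \eqn{\hat w = y - \phi\hat\theta}, one row
#' per node, one column per fitted observation.
#'
#' @param object A [FitReport].
#' @param ... Ignored.
#' @return Numeric matrix.
#' @export
setMethod("residuals", "FitReport", function(object, ...) object@residuals)

#' @rdname fitFlags
#' @export
setMethod("fitFlags", "FitReport", function(x) x@flags)

setMethod("show", "FitReport", function(object) {
  m <- object@model
  cat(sprintf("FitReport: %s, %d node(s), %d observation row(s)\n",
              class(m), nrow(object@residuals), ncol(object@residuals)))
  cat(sprintf("  max final parameter change: %.3g\n",
              suppressWarnings(max(object@convergence))))
  nf <- sum(lengths(object@flags) > 0)
  if (nf) cat(sprintf("  %d node(s) flagged: see fitFlags()\n", nf))
})

setMethod("show", "TransferMatrix", function(object) {
  cat(sprintf("TransferMatrix: %d output(s) x %d input(s)\n",
              nrow(object@values), ncol(object@values)))
  print(object@values)
})

setMethod("show", "SynthScenario", function(object) {
  cat(sprintf("SynthScenario: %d node(s), %d input(s), %s mode, N = %d, sigma = %g, seed = %d\n",
              object@nNodes, object@nInputs, object@mode,
              object@nObservations, object@noiseSigma, object@seed))
})

setMethod("show", "RecoveryReport", function(object) {
  cat(sprintf("RecoveryReport: %d replicate(s), %d parameter(s)\n",
              object@replicates, length(object@paramRMSE)))
  cat(sprintf("  max parameter RMSE: %.3g  max |bias|: %.3g\n",
              suppressWarnings(max(object@paramRMSE)),
              suppressWarnings(max(abs(object@paramBias)))))
  if (length(object@errors))
    cat(sprintf("  %d replicate(s) errored\n", length(object@errors)))
})

#' Transfer coefficients of a TransferMatrix
#'
#' @param x A [TransferMatrix].
#' @return Numeric matrix with output/input ids as dimnames.
#' @export
transferValues <- function(x) {
  stopifnot(is(x, "TransferMatrix"))
  out <- x@values
  dimnames(out) <- list(x@rowIds, x@colIds)
  out
}

#' Channel of a transductivity result or flow trajectory
#'
#' @param x A [TransductivityResult] or [FlowTrajectory].
#' @return The underlying [IOSubsystem].
#' @export
channel <- function(x) x@channel
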