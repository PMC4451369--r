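#' @include AllClasses.R
NULL

#' Node identifiers of a dataset, model or structure
#'
#' @param x An object carrying named network nodes (an
#'   [ExpressionDataset], [PathwayModel], [GRNModel] or
#'   [NetworkStructure]).
#' @return Character vector of node identifiers.
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' Input-signal identifiers
#'
#' Identifiers of the extracellular input signals (ligands) attached to a
#' dataset or bound into a pathway model.
#'
#' @param x An [ExpressionDataset] or [PathwayModel].
#' @return Character vector (possibly empty).
#' @export
setGeneric("inputIds", function(x) standardGeneric("inputIds"))

#' Inhibitor-signal identifiers
#'
#' Identifiers of inhibitory signals (e.g. DNA methylation, histone
#' modification or microRNA series) entering the model through the
#' inhibition term \eqn{-B_m m(t)}.
#'
#' @param x An [ExpressionDataset], [PathwayModel] or [GRNModel].
#' @return Character vector (possibly empty).
#' @export
setGeneric("inhibitorIds", function(x) standardGeneric("inhibitorIds"))

#' Observation mode of a dataset
#'
#' @param x An [ExpressionDataset].
#' @return `"temporal"` (ordered, equispaced time points) or `"sample"`
#'   (independent samples at a single time point).
#' @export
setGeneric("obsMode", function(x) standardGeneric("obsMode"))

#' Expression values
#'
#' @param x An [ExpressionDataset].
#' @return Numeric matrix, nodes in rows and observations in columns.
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' Exogenous input series of a dataset
#'
#' @param x An [ExpressionDataset].
#' @return Numeric matrix (inputs x observations); zero rows when absent.
#' @export
setGeneric("inputSeries", function(x) standardGeneric("inputSeries"))

#' Inhibitor series of a dataset
#'
#' @param x An [ExpressionDataset].
#' @return Nonnegative numeric matrix (inhibitors x observations); zero rows
#'   when absent.
#' @export
setGeneric("inhibitorSeries", function(x) standardGeneric("inhibitorSeries"))

#' Interaction (coupling) matrix of a network model
#'
#' For a pathway model this is the protein-protein interaction matrix `C`
#' (entry `i,j` = interaction ability of protein `j` on protein `i`); for a
#' GRN model the regulatory matrix `A` (entry `i,j` = regulatory ability of
#' gene `j` on gene `i`, positive = activator, negative = inhibitor).
#'
#' @param x A [PathwayModel] or [GRNModel].
#' @return Square numeric matrix with node ids as dimnames.
#' @export
setGeneric("interactionMatrix", function(x) standardGeneric("interactionMatrix"))

#' Basal expression levels of a pathway model
#'
#' @param x A [PathwayModel].
#' @return Named numeric vector `H` of input-independent basal levels.
#' @export
setGeneric("basalLevels", function(x) standardGeneric("basalLevels"))

#' Input binding matrix of a pathway model
#'
#' @param x A [PathwayModel].
#' @return Numeric matrix `B` (nodes x inputs) of binding abilities.
#' @export
setGeneric("bindingMatrix", function(x) standardGeneric("bindingMatrix"))

#' Inhibitory binding matrix
#'
#' Entrywise-nonnegative matrix `B_m`; inhibitors enter the dynamics with an
#' explicit minus sign, as `-B_m m(t)`.
#'
#' @param x A [PathwayModel] or [GRNModel].
#' @return Numeric matrix (nodes x inhibitors); zero columns when absent.
#' @export
setGeneric("inhibitionMatrix", function(x) standardGeneric("inhibitionMatrix"))

#' Model semantics
#'
#' @param x A [PathwayModel] or [GRNModel].
#' @return `"temporal"` (one-step recursion) or `"static"` (fixed-point /
#'   steady-state interpretation).
#' @export
setGeneric("semantics", function(x) standardGeneric("semantics"))

#' Spectral radius
#'
#' Largest eigenvalue magnitude of the state matrix; strictly below one
#' means the temporal model is stable and all channel gains are finite.
#'
#' @param x A square numeric matrix, [PathwayModel] or [GRNModel].
#' @return Nonnegative scalar.
#' @export
setGeneric("spectralRadius", function(x) standardGeneric("spectralRadius"))

#' Transductivity (system gain) of a result
#'
#' @param x A [TransductivityResult].
#' @return Nonnegative scalar, possibly `Inf` for unstable channels.
#' @export
setGeneric("gain", function(x) standardGeneric("gain"))

#' Raw minimized LMI bound
#'
#' The minimized bound `rho` of the energy-ratio inequality; the reported
#' gain is its square root. `NA` in static mode, where the singular-value
#' formula is used directly.
#'
#' @param x A [TransductivityResult].
#' @return Scalar or `NA`.
#' @export
setGeneric("rhoRaw", function(x) standardGeneric("rhoRaw"))

#' Lyapunov certificate of a dynamic gain computation
#'
#' @param x A [TransductivityResult].
#' @return Symmetric positive-definite matrix `P` certifying the bound, or a
#'   0 x 0 matrix when unavailable (static mode, unstable channel).
#' @export
setGeneric("certificate", function(x) standardGeneric("certificate"))

#' Feasibility flag of a transductivity computation
#'
#' @param x A [TransductivityResult].
#' @return `TRUE` when a finite certified gain was found; `FALSE` for
#'   unstable channels (gain `Inf`).
#' @export
setGeneric("isFeasible", function(x) standardGeneric("isFeasible"))

#' Fitted model of a fit report
#'
#' @param x A [FitReport].
#' @return The fitted [PathwayModel] or [GRNModel].
#' @export
setGeneric("fittedModel", function(x) standardGeneric("fittedModel"))

#' Per-node fit flags
#'
#' @param x A [FitReport].
#' @return Named list of character flags (e.g. `"rank_deficient"`,
#'   `"no_information"`) per node; empty vectors for clean fits.
#' @export
setGeneric("fitFlags", function(x) standardGeneric("fitFlags"))
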