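#' @include AllClasses.R AllGenerics.R
NULL

.read_delim_matrix <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = sep, header = TRUE, row.names = NULL,
                   check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicated row id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  bad_num <- which(is.na(suppressWarnings(
    matrix(as.numeric(m), nrow(m), ncol(m)))) & !is.na(m), arr.ind = TRUE)
  if (nrow(bad_num))
    stop("non-numeric value at row '", ids[bad_num[1, 1]], "', column '",
         colnames(m)[bad_num[1, 2]], "'")
  storage.mode(m) <- "double"
  nas <- which(is.na(m), arr.ind = TRUE)
  if (nrow(nas)) {
    cells <- apply(nas, 1, function(rc)
      sprintf("(%s, %s)", ids[rc[1]], colnames(m)[rc[2]]))
    stop("missing values at: ", paste(head(cells, 10), collapse = ", "))
  }
  rownames(m) <- ids
  m
}

#' Read an expression matrix into an ExpressionDataset
#'
#' Parses a delimited text matrix (first column = row ids, header row
#' present). By microarray convention nodes are in rows and observations in
#' columns; set `orientation = "obs_in_rows"` to transpose. Rows named in
#' `inputIds`/`inhibitorIds` are split off into the exogenous blocks.
#' Malformed input (missing values, duplicate ids, non-numeric cells) is
#' rejected with the offending location, never coerced.
#'
#' @param path Path to a TSV/CSV file.
#' @param mode `"temporal"` or `"sample"`.
#' @param inputIds,inhibitorIds Row ids to treat as exogenous signals.
#' @param orientation `"nodes_in_rows"` (default) or `"obs_in_rows"`.
#' @param sep Field separator (tab by default).
#' @return An [ExpressionDataset].
#' @export
readExpressionMatrix <- function(path, mode = c("temporal", "sample"),
                                 inputIds = NULL, inhibitorIds = NULL,
                                 orientation = c("nodes_in_rows",
                                                 "obs_in_rows"),
                                 sep = "\t") {
  mode <- match.arg(mode)
  orientation <- match.arg(orientation)
  m <- .read_delim_matrix(path, sep = sep)
  if (orientation == "obs_in_rows") m <- t(m)
  missing_ids <- setdiff(c(inputIds, inhibitorIds), rownames(m))
  if (length(missing_ids))
    stop("declared signal id(s) absent from the file: ",
         paste(missing_ids, collapse = ", "))
  inputs <- if (length(inputIds)) m[inputIds, , drop = FALSE]
  inhibitors <- if (length(inhibitorIds)) m[inhibitorIds, , drop = FALSE]
  nodes <- setdiff(rownames(m), c(inputIds, inhibitorIds))
  ExpressionDataset(m[nodes, , drop = FALSE], mode = mode,
                    inputs = inputs, inhibitors = inhibitors)
}

#' Write an ExpressionDataset as delimited text
#'
#' Writes nodes (and any input/inhibitor signals, appended as extra rows)
#' in rows and observations in columns; round-trips bit-identically through
#' [readExpressionMatrix()] with the matching id lists.
#'
#' @param dataset An [ExpressionDataset].
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(dataset, path, sep = "\t") {
  stopifnot(is(dataset, "ExpressionDataset"))
  m <- rbind(exprValues(dataset), inputSeries(dataset),
             inhibitorSeries(dataset))
  # %.17g preserves doubles exactly across the write/read round trip
  txt <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))
  df <- data.frame(id = rownames(m), txt, check.names = FALSE)
  colnames(df) <- c("id", paste0("obs", seq_len(ncol(m))))
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a directed network structure from an edge-list file
#'
#' Format: an optional `@nodes` section (one node per line) declaring the
#' node universe, a default section of two/three-column edges
#' (`regulator<TAB>target[<TAB>sign]`), and optional `@input` /
#' `@inhibitor` sections of `signal<TAB>target` bindings. Without an
#' `@nodes` section (or the `nodes` argument) the universe is inferred
#' from the edges.
#'
#' @param path Path to the structure file.
#' @param nodes Optional explicit node universe.
#' @param sep Field separator.
#' @return A [NetworkStructure].
#' @export
readNetworkStructure <- function(path, nodes = NULL, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  section <- "edges"
  decl_nodes <- character(0)
  ed <- list(); ib <- list(); hb <- list()
  for (ln in lines) {
    if (startsWith(ln, "@")) {
      section <- sub("^@", "", ln)
      if (!section %in% c("nodes", "edges", "input", "inhibitor"))
        stop("unknown section '@", section, "' in ", path)
      next
    }
    parts <- strsplit(ln, sep, fixed = TRUE)[[1]]
    if (section == "nodes") {
      decl_nodes <- c(decl_nodes, parts[1])
    } else if (section == "edges") {
      if (length(parts) < 2)
        stop("malformed edge line: '", ln, "'")
      sgn <- 0
      if (length(parts) >= 3) {
        sgn <- suppressWarnings(as.numeric(parts[3]))
        if (is.na(sgn) || !sgn %in% c(-1, 0, 1))
          stop("malformed sign in edge line: '", ln, "'")
      }
      ed[[length(ed) + 1L]] <- data.frame(from = parts[1], to = parts[2],
                                          sign = sgn)
    } else if (section == "input") {
      ib[[length(ib) + 1L]] <- data.frame(input = parts[1], node = parts[2])
    } else {
      hb[[length(hb) + 1L]] <- data.frame(inhibitor = parts[1],
                                          node = parts[2])
    }
  }
  edges <- if (length(ed)) do.call(rbind, ed)
  universe <- if (!is.null(nodes)) nodes
              else if (length(decl_nodes)) decl_nodes
              else unique(c(edges$from, edges$to,
                            if (length(ib)) do.call(rbind, ib)$node,
                            if (length(hb)) do.call(rbind, hb)$node))
  NetworkStructure(universe, edges = edges,
                   inputBindings = if (length(ib)) do.call(rbind, ib),
                   inhibitorBindings = if (length(hb)) do.call(rbind, hb))
}

#' Write a flow trajectory (or trajectory matrix) as TSV
#'
#' First column `t`, one column per node/output thereafter.
#'
#' @param trajectory A [FlowTrajectory], or a nodes x (T+1) matrix from
#'   [simulateTemporal()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTrajectory <- function(trajectory, path) {
  if (is(trajectory, "FlowTrajectory")) {
    vals <- trajectory@values
    times <- trajectory@times
    cn <- paste0("out", seq_len(ncol(vals)))
  } else {
    vals <- t(as.matrix(trajectory))
    times <- seq_len(nrow(vals)) - 1
    cn <- colnames(vals)
    if (is.null(cn)) cn <- paste0("node", seq_len(ncol(vals)))
  }
  df <- data.frame(t = times, vals)
  colnames(df) <- c("t", cn)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a model to its JSON document
#'
#' Writes a `netflux-model-v1` JSON document: ids, semantics, model type
#' and row-major matrices, at full precision.
#'
#' @param model A [PathwayModel] or [GRNModel].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeModel <- function(model, path) {
  stopifnot(is(model, "PathwayModel") || is(model, "GRNModel"))
  S <- interactionMatrix(model)
  doc <- list(
    version = "netflux-model-v1",
    type = if (is(model, "PathwayModel")) "pathway" else "grn",
    semantics = semantics(model),
    node_ids = nodeIds(model),
    input_ids = if (is(model, "PathwayModel")) inputIds(model)
                else character(0),
    inhibitor_ids = inhibitorIds(model),
    C = apply(S, 1, identity, simplify = FALSE),
    H = if (is(model, "PathwayModel")) unname(model@H) else numeric(0),
    B = if (is(model, "PathwayModel"))
          apply(model@B, 1, identity, simplify = FALSE) else list(),
    B_m = apply(inhibitionMatrix(model), 1, identity, simplify = FALSE))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

.rows_to_matrix <- function(rows, nrow, ncol) {
  if (!length(rows) || ncol == 0) return(matrix(numeric(0), nrow, ncol))
  do.call(rbind, lapply(rows, function(r) as.numeric(unlist(r))))
}

#' Read a model from its JSON document
#'
#' @param path Path to a `netflux-model-v1` document written by
#'   [writeModel()].
#' @return A [PathwayModel] or [GRNModel].
#' @export
readModel <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$version, "netflux-model-v1"))
    stop("unsupported model document version: ", doc$version)
  ids <- as.character(unlist(doc$node_ids))
  n <- length(ids)
  mids <- as.character(unlist(doc$inhibitor_ids))
  S <- .rows_to_matrix(doc$C, n, n)
  Bm <- .rows_to_matrix(doc$B_m, n, length(mids))
  if (identical(doc$type, "grn")) {
    GRNModel(A = S, semantics = doc$semantics,
             Bm = if (length(mids)) Bm else NULL, nodeIds = ids,
             inhibitorIds = mids)
  } else {
    uids <- as.character(unlist(doc$input_ids))
    PathwayModel(C = S, H = as.numeric(unlist(doc$H)),
                 B = .rows_to_matrix(doc$B, n, length(uids)),
                 Bm = if (length(mids)) Bm else NULL,
                 semantics = doc$semantics, nodeIds = ids,
                 inputIds = uids, inhibitorIds = mids)
  }
}

#' Write a transductivity or comparison table as TSV
#'
#' Numeric columns are printed with 6 significant digits (use
#' [writeResultJSON()] for full precision).
#'
#' @param table A data.frame from [transductivityTable()] or
#'   [compareConditions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTransductivityTable <- function(table, path) {
  out <- table
  for (nm in names(out))
    if (is.numeric(out[[nm]])) out[[nm]] <- signif(out[[nm]], 6)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write transductivity results as JSON at full precision
#'
#' @param x A data.frame (table) or a single [TransductivityResult]
#'   (serialized with its certificate).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeResultJSON <- function(x, path) {
  doc <- if (is(x, "TransductivityResult")) {
    list(gain = x@gain, rho_raw = x@rhoRaw, mode = x@mode,
         feasible = x@feasible, source = x@channel@source,
         target = x@channel@target,
         certificate = apply(x@certificate, 1, identity, simplify = FALSE),
         horizon_note = x@horizonNote)
  } else {
    x
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
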