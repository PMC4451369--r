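# Shared fixture builders: everything is generated in code under fixed
# seeds; no stored data.

# A random stable state matrix with the requested spectral radius.
rand_stable_matrix <- function(n, radius = 0.7) {
  A <- matrix(rnorm(n * n), n, n)
  A * (radius / max(Mod(eigen(A, only.values = TRUE)$values)))
}

make_channel <- function(A, B, D = diag(nrow(as.matrix(A)))) {
  A <- as.matrix(A)
  new("IOSubsystem", Asub = A, Bsub = as.matrix(B), Dout = as.matrix(D),
      source = "test input", target = "test output", selfLoop = FALSE)
}

scalar_channel <- function(c, b) make_channel(matrix(c), matrix(b), matrix(1))

# Random single-input random-output channel; D is the identity or a unit row.
rand_channel <- function(n, radius = 0.7, n_inputs = 1, unit_output = FALSE) {
  A <- rand_stable_matrix(n, radius)
  B <- matrix(rnorm(n * n_inputs), n, n_inputs)
  D <- if (unit_output) {
    d <- matrix(0, 1, n)
    d[1, sample.int(n, 1)] <- 1
    d
  } else diag(n)
  make_channel(A, B, D)
}

# A random directed tree GRN (edges parent -> child, random weights);
# returns the static model and the edge weights keyed "parent->child".
rand_tree_grn <- function(n, weight_range = c(0.2, 0.9)) {
  A <- matrix(0, n, n)
  ids <- paste0("g", seq_len(n))
  weights <- c()
  for (child in 2:n) {
    parent <- sample.int(child - 1L, 1)
    w <- sample(c(-1, 1), 1) * runif(1, weight_range[1], weight_range[2])
    A[child, parent] <- w
    weights[paste0(ids[parent], "->", ids[child])] <- w
  }
  dimnames(A) <- list(ids, ids)
  list(model = GRNModel(A, semantics = "static"), weights = weights,
       ids = ids)
}

# Path product along the unique tree path j -> i (NA if no path).
tree_path_product <- function(A, j, i) {
  # parents are unique in a tree: walk up from i
  prod <- 1
  cur <- i
  repeat {
    parent <- which(A[cur, ] != 0)
    if (!length(parent)) return(NA_real_)
    prod <- prod * A[cur, parent]
    if (parent == j) return(prod)
    cur <- parent
  }
}

# DAG static pathway with receptor-only input bindings: identifiable from
# noise-free fixed points under its own structure mask.
dag_static_pathway <- function() {
  ids <- c("R1", "R2", "K1", "TF1")
  C <- matrix(0, 4, 4, dimnames = list(ids, ids))
  C["K1", "R1"] <- 0.6
  C["K1", "R2"] <- -0.4
  C["TF1", "K1"] <- 0.8
  B <- matrix(0, 4, 2, dimnames = list(ids, c("u1", "u2")))
  B["R1", "u1"] <- 1.2
  B["R2", "u2"] <- -0.9
  PathwayModel(C = C, H = c(1, 2, 0.5, -1), B = B, semantics = "static")
}
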