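# Internal linear-algebra helpers for the dynamic-gain machinery.

.sym <- function(M) (M + t(M)) / 2

.sigma_max <- function(M) {
  if (!length(M)) return(0)
  max(svd(M, nu = 0, nv = 0)$d)
}

# sigma_max of the transfer D (zI - A)^-1 B at a point z on the unit circle
.tf_sigma <- function(A, B, D, z) {
  if (!ncol(B) || !nrow(D)) return(0)
  n <- nrow(A)
  G <- D %*% solve(z * diag(n) - A, B)
  max(svd(G, nu = 0, nv = 0)$d)
}

# Generalized eigenvalues of the pencil (S, T) via a complex shift-invert:
# lambda = c + 1/mu for eigenvalues mu of (S - c T)^-1 T. Handles singular
# S and/or T (eigenvalues at 0 and infinity map to finite/zero mu).
.pencil_eigenvalues <- function(S, T) {
  shifts <- c(0.7310 + 0.5410i, -0.3170 + 0.8530i, 1.2410 - 0.6170i)
  for (cc in shifts) {
    M <- tryCatch(solve(S - cc * T, T), error = function(e) NULL)
    if (is.null(M)) next
    mu <- eigen(M, only.values = TRUE)$values
    lam <- rep(Inf + 0i, length(mu))
    nz <- Mod(mu) > 1e-14
    lam[nz] <- cc + 1 / mu[nz]
    return(lam)
  }
  stop("pencil eigenvalue computation failed: pencil appears singular")
}

# Exact feasibility of the bounded-real LMI at gain level gamma for the
# stable channel (A, B, D): the LMI admits P > 0 iff gamma exceeds the
# worst-case frequency gain, which holds iff gamma beats the gain at the
# probe frequencies AND the symplectic pencil has no unit-circle
# generalized eigenvalues (no frequency where a singular value of the
# transfer crosses gamma).
.gamma_feasible <- function(A, B, D, gamma, uctol = 1e-6) {
  if (!ncol(B) || !nrow(D)) return(gamma > 0)
  if (gamma <= 0) return(FALSE)
  for (z in c(1 + 0i, -1 + 0i, 1i)) {
    if (gamma <= .tf_sigma(A, B, D, z)) return(FALSE)
  }
  n <- nrow(A)
  Q <- crossprod(D)
  S <- rbind(cbind(A, matrix(0, n, n)),
             cbind(-Q, diag(n)))
  T <- rbind(cbind(diag(n), -tcrossprod(B) / gamma^2),
             cbind(matrix(0, n, n), t(A)))
  lam <- tryCatch(.pencil_eigenvalues(S, T), error = function(e) NULL)
  # a numerically singular pencil indicates gamma sits on a singular-value
  # crossing; treat as infeasible (bisection then moves above it)
  if (is.null(lam)) return(FALSE)
  fin <- is.finite(Mod(lam))
  !any(abs(Mod(lam[fin]) - 1) < uctol)
}

# TRUE when the channel transfer is identically zero: the first n Markov
# parameters D A^k B vanish (Cayley-Hamilton closes the rest).
.zero_channel <- function(A, B, D, tol = 1e-14) {
  if (!ncol(B) || !nrow(D)) return(TRUE)
  scale <- max(1, .sigma_max(B) * max(1, .sigma_max(A))^nrow(A))
  Mk <- B
  for (k in seq_len(nrow(A) + 1L)) {
    if (.sigma_max(D %*% Mk) > tol * scale) return(FALSE)
    Mk <- A %*% Mk
  }
  TRUE
}

# Stein (discrete Lyapunov) equation X = t(Acl) %*% X %*% Acl + Q via
# Kronecker vectorization; dimensions here are small (n <= ~15).
.stein_solve <- function(Acl, Q) {
  n <- nrow(Acl)
  K <- diag(n * n) - kronecker(t(Acl), t(Acl))
  X <- matrix(solve(K, as.vector(Q)), n, n)
  .sym(X)
}

# Stabilizing solution of the H-infinity-type Riccati equation
#   X = A'XA + Q + A'XB (rho I - B'XB)^-1 B'XA,   rho I - B'XB > 0,
# by Newton/Hewer iteration from X = 0 (closed loop = A, stable by
# precondition). Exists iff rho strictly exceeds the squared channel gain;
# the solution satisfies the bounded-real LMI block with equality in its
# Schur complement, so it serves as the Lyapunov certificate.
.riccati_newton <- function(A, B, Q, rho, max_iter = 150L, tol = 1e-12) {
  n <- nrow(A)
  r <- ncol(B)
  X <- matrix(0, n, n)
  for (k in seq_len(max_iter)) {
    W <- rho * diag(r) - t(B) %*% X %*% B
    ew <- eigen(.sym(W), symmetric = TRUE, only.values = TRUE)$values
    if (min(ew) <= 0)
      return(NULL)
    Fk <- solve(.sym(W), t(B) %*% X %*% A)
    Acl <- A + B %*% Fk
    if (spectralRadius(Acl) >= 1)
      return(NULL)
    Xn <- tryCatch(.stein_solve(Acl, Q - rho * crossprod(Fk)),
                   error = function(e) NULL)
    if (is.null(Xn) || any(!is.finite(Xn)))
      return(NULL)
    delta <- max(abs(Xn - X)) / (1 + max(abs(Xn)))
    X <- Xn
    if (delta < tol) break
  }
  W <- rho * diag(r) - t(B) %*% X %*% B
  if (min(eigen(.sym(W), symmetric = TRUE, only.values = TRUE)$values) <= 0)
    return(NULL)
  .sym(X)
}
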