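#' Transition rate matrix for a categorical master equation
#'
#' Validates and wraps a square matrix `L` generating the linear master
#' equation `dp/dt = L p`. Columns must sum to zero (probability
#' conservation) and off-diagonal entries must be non-negative.
#'
#' @param entries square numeric matrix of rates (per unit time).
#' @param labels optional state names; taken from `dimnames` if present.
#' @return an object of class `rate_matrix`.
#' @examples
#' rate_matrix(matrix(c(-1, 1, 1, -1), 2))
#' @export
rate_matrix <- function(entries, labels = NULL) {
  entries <- as.matrix(entries)
  n <- nrow(entries)
  if (ncol(entries) != n) stop("rate_matrix: matrix must be square")
  if (any(!is.finite(entries))) stop("rate_matrix: non-finite entries")
  offdiag <- entries; diag(offdiag) <- 0
  if (any(offdiag < -1e-12))
    stop("rate_matrix: off-diagonal entries must be non-negative")
  cs <- colSums(entries)
  if (any(abs(cs) > 1e-9 * max(1, max(abs(entries)))))
    stop("rate_matrix: columns must sum to zero (max |colsum| = ",
         signif(max(abs(cs)), 3), ")")
  if (is.null(labels)) {
    labels <- colnames(entries)
    if (is.null(labels)) labels <- paste0("s", seq_len(n))
  }
  dimnames(entries) <- list(labels, labels)
  structure(list(entries = entries, labels = labels), class = "rate_matrix")
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat("<rate_matrix,", nrow(x$entries), "states>\n")
  print(x$entries)
  invisible(x)
}

rm_entries <- function(L) if (inherits(L, "rate_matrix")) L$entries else as.matrix(L)

#' Random rate matrices for simulation studies
#'
#' Draws a dense irreducible rate matrix with off-diagonal entries uniform on
#' `[0.1, 1]` (so the stationary distribution is unique and strictly
#' positive). With `detailed_balance = TRUE` the rates are constructed as
#' `L_ij = W_ij * pi_i` for a symmetric positive `W` and a random positive
#' `pi`, which satisfies `L_ij pi_j = L_ji pi_i` exactly, giving a reversible
#' chain whose flow decomposition has no solenoidal part.
#'
#' @param n number of states.
#' @param detailed_balance logical; draw a reversible chain.
#' @return a `rate_matrix`.
#' @export
random_rate_matrix <- function(n, detailed_balance = FALSE) {
  stopifnot(n >= 2)
  if (detailed_balance) {
    p <- stats::runif(n, 0.2, 1); p <- p / sum(p)
    W <- matrix(stats::runif(n * n, 0.1, 1), n)
    W <- (W + t(W)) / 2
    L <- W * p            # L_ij = W_ij * p_i
  } else {
    L <- matrix(stats::runif(n * n, 0.1, 1), n)
  }
  diag(L) <- 0
  diag(L) <- -colSums(L)
  rate_matrix(L)
}

#' Steady state of a master equation
#'
#' The stationary distribution is the normalized right singular vector of `L`
#' whose singular value is zero. The singular spectrum is also used as a
#' diagnostic: exactly one singular value below `tol` times the largest one
#' must be present, otherwise the matrix is rejected as invalid (none) or as
#' a reducible chain with several stationary distributions (more than one).
#'
#' @param L a `rate_matrix` (or plain matrix with zero column sums).
#' @param tol relative singular-value threshold for the null space.
#' @return a `catdist` with `||L p||_inf <= 1e-8`.
#' @examples
#' steady_state(rate_matrix(matrix(c(-2, 2, 1, -1), 2)))
#' @export
steady_state <- function(L, tol = 1e-10) {
  M <- rm_entries(L)
  sv <- svd(M)
  small <- which(sv$d < tol * max(sv$d))
  if (length(small) == 0)
    stop("steady_state: no singular value near zero; ",
         "not a valid rate matrix")
  if (length(small) > 1)
    stop("steady_state: ", length(small), " singular values near zero; ",
         "the chain is reducible and the steady state is not unique")
  v <- sv$v[, small]
  if (sum(v) < 0) v <- -v
  if (any(v < -1e-8))
    stop("steady_state: null vector has mixed signs; not a valid rate matrix")
  v <- pmax(v, 0)
  p <- v / sum(v)
  if (max(abs(M %*% p)) > 1e-8)
    stop("steady_state: residual ||L p||_inf = ", signif(max(abs(M %*% p)), 3),
         " exceeds 1e-8")
  catdist(p, labels = if (inherits(L, "rate_matrix")) L$labels else NULL)
}

#' Solenoidal/dissipative decomposition of a rate matrix
#'
#' Splits the generator as `L = (Q - Gamma) Lambda`, with
#' `Lambda = diag(p_inf)^{-1}`, `A = L Lambda^{-1}`, skew-symmetric
#' `Q = (A - A^T)/2` and symmetric `Gamma = -(A + A^T)/2`. `Q` drives the
#' solenoidal (free-energy-conserving) component of the flow and `Gamma` the
#' dissipative (free-energy-descending) component, in analogy with the
#' Helmholtz decomposition of continuous flows. Detailed balance is
#' equivalent to `Q = 0`.
#'
#' @param L a `rate_matrix`.
#' @param p_inf stationary distribution; computed from `L` if missing. Must
#'   be strictly positive, since `Lambda` inverts it.
#' @return an object of class `flow_decomposition` with elements `Q`,
#'   `Gamma`, `Lambda`, `A` and `p_inf`.
#' @export
decompose <- function(L, p_inf = NULL) {
  M <- rm_entries(L)
  if (is.null(p_inf)) p_inf <- steady_state(L)
  p <- if (inherits(p_inf, "catdist")) p_inf$probs else as.numeric(p_inf)
  if (any(p <= 0))
    stop("decompose: p_inf has zero entries; Lambda = diag(p_inf)^{-1} ",
         "is undefined")
  A <- M %*% diag(p, nrow = length(p))     # A = L Lambda^{-1}
  Q <- (A - t(A)) / 2
  Gamma <- -(A + t(A)) / 2
  structure(list(Q = Q, Gamma = Gamma, Lambda = diag(1 / p, nrow = length(p)),
                 A = A, p_inf = p),
            class = "flow_decomposition")
}

#' @export
print.flow_decomposition <- function(x, ...) {
  cat("<flow_decomposition,", nrow(x$Q), "states; ||Q|| =",
      signif(max(abs(x$Q)), 3), ">\n")
  invisible(x)
}

#' Read/write rate matrices as delimited text
#'
#' Plain delimited numeric text with a header row of state labels, so rate
#' matrices can be exchanged with other tools.
#'
#' @param path file path.
#' @param sep field separator.
#' @return `read_rate_matrix` returns a `rate_matrix`.
#' @export
read_rate_matrix <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  rate_matrix(as.matrix(df), labels = colnames(df))
}

#' @rdname read_rate_matrix
#' @param L a `rate_matrix` to write.
#' @export
write_rate_matrix <- function(L, path, sep = ",") {
  M <- rm_entries(L)
  df <- as.data.frame(M)
  colnames(df) <- if (inherits(L, "rate_matrix")) L$labels else colnames(M)
  utils::write.table(format(df, digits = 17, trim = TRUE), path, sep = sep,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
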