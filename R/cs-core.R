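# Centrosymmetric matrix primitives: the exchange matrix J_n, the generalized
# Fourier matrices S_n, and the block diagonalization F_n(A) = S_n^{-1} A S_n
# together with its Markov/rate condition transfer.

# Structural tolerance for exactly-entered matrices; pipelines that have gone
# through floating-point arithmetic use `tol_float`.
tol_exact <- 1e-12
tol_float <- 1e-9

#' Exchange (anti-identity) matrix
#'
#' The matrix `J_n` with ones on the anti-diagonal (`i + j = n + 1`) and zeros
#' elsewhere. `J_n` is an involution (`J %*% J == I`) and conjugation by it
#' characterizes centrosymmetry: a square matrix `A` is centrosymmetric exactly
#' when `J %*% A %*% J == A`.
#'
#' @param n Matrix order, a positive integer.
#' @return An `n x n` numeric 0/1 matrix.
#' @examples
#' exchange_matrix(2)
#' @export
exchange_matrix <- function(n) {
  n <- check_order(n)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n), n:1)] <- 1
  J
}

#' Test a matrix for centrosymmetry
#'
#' A real square matrix `A = (a_ij)` is centrosymmetric (CS) when it is
#' symmetric about its center: `a[i, j] == a[n + 1 - i, n + 1 - j]` for all
#' `i, j`. CS Markov matrices are the transition matrices of strand-symmetric
#' substitution models, where the symmetry encodes the complementarity of the
#' two DNA strands.
#'
#' @param A A real square matrix.
#' @param tol Absolute tolerance on the entrywise symmetry defect.
#' @return `TRUE` or `FALSE`.
#' @examples
#' is_centrosymmetric(diag(4))
#' @export
is_centrosymmetric <- function(A, tol = tol_exact) {
  A <- check_square(A)
  n <- nrow(A)
  max(abs(A - A[n:1, n:1, drop = FALSE])) <= tol
}

#' Markov and rate matrix predicates
#'
#' A Markov (transition) matrix is non-negative with rows summing to one; a
#' rate matrix has rows summing to zero and non-negative off-diagonal entries.
#'
#' @param A A real square matrix.
#' @param tol Absolute tolerance on row sums and entry signs.
#' @return `TRUE` or `FALSE`.
#' @export
is_markov_matrix <- function(A, tol = tol_float) {
  A <- check_square(A)
  all(A >= -tol) && max(abs(rowSums(A) - 1)) <= tol
}

#' @rdname is_markov_matrix
#' @export
is_rate_matrix <- function(A, tol = tol_float) {
  A <- check_square(A)
  offdiag <- A[row(A) != col(A)]
  all(offdiag >= -tol) && max(abs(rowSums(A))) <= tol
}

#' Generalized Fourier matrix
#'
#' The recursively bordered matrix `S_n` (with `S_1 = (1)`,
#' `S_2 = rbind(c(1, 1), c(1, -1))`, and `S_n` obtained by bordering
#' `S_{n-2}` with a symmetric first/last row and column) conjugates every
#' centrosymmetric matrix into a two-block diagonal form. For even `n` the
#' inverse is simply `S_n / 2`.
#'
#' @param n Matrix order, a positive integer.
#' @return A list of class `fourier_matrix` with components `n`, `S` and
#'   `S_inv`.
#' @examples
#' fourier_matrix(4)$S
#' @export
fourier_matrix <- function(n) {
  n <- check_order(n)
  key <- as.character(n)
  hit <- .fourier_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- structure(list(n = n, S = build_fourier(n),
                        S_inv = build_fourier_inv(n)),
                   class = "fourier_matrix")
  .fourier_cache[[key]] <- out
  out
}

.fourier_cache <- new.env(parent = emptyenv())

build_fourier <- function(n) {
  if (n == 1L) return(matrix(1, 1, 1))
  if (n == 2L) return(matrix(c(1, 1, 1, -1), 2, 2, byrow = TRUE))
  inner <- build_fourier(n - 2L)
  S <- matrix(0, n, n)
  S[1, 1] <- 1; S[1, n] <- 1
  S[n, 1] <- 1; S[n, n] <- -1
  S[2:(n - 1), 2:(n - 1)] <- inner
  S
}

build_fourier_inv <- function(n) {
  if (n == 1L) return(matrix(1, 1, 1))
  if (n %% 2L == 0L) return(build_fourier(n) / 2)
  inner <- build_fourier_inv(n - 2L)
  S <- matrix(0, n, n)
  S[1, 1] <- 0.5; S[1, n] <- 0.5
  S[n, 1] <- 0.5; S[n, n] <- -0.5
  S[2:(n - 1), 2:(n - 1)] <- inner
  S
}

#' Block-diagonalize a centrosymmetric matrix
#'
#' Computes `F_n(A) = S_n^{-1} A S_n`, which for a CS matrix is block diagonal
#' with an upper block `A1` of size `ceiling(n/2)` and a lower block `A2` of
#' size `floor(n/2)`. If `A` is Markov (rate), `A1` is Markov (rate) as well;
#' `A2` carries the remaining spectrum. The transform is exact in rational
#' arithmetic, so only floating-point round-off has to be absorbed by `tol`.
#'
#' @param A A centrosymmetric matrix.
#' @param tol Tolerance for the centrosymmetry check and the off-block
#'   residual.
#' @return A list of class `block_pair` with components `upper`, `lower`, `n`,
#'   and logical flags `upper_markov`, `upper_rate` inherited from `A`.
#' @examples
#' M <- k3p_matrix(0.65, 0.2, 0.1, 0.05)
#' block_transform(M)
#' @export
block_transform <- function(A, tol = tol_float) {
  A <- check_square(A)
  n <- nrow(A)
  if (!is_centrosymmetric(A, tol = tol)) {
    defect <- max(abs(A - A[n:1, n:1, drop = FALSE]))
    stop("matrix is not centrosymmetric: max |a[i,j] - a[n+1-i,n+1-j]| = ",
         format(defect), " exceeds tol = ", format(tol))
  }
  FM <- fourier_matrix(n)
  B <- FM$S_inv %*% A %*% FM$S
  k <- ceiling(n / 2)
  upper <- B[seq_len(k), seq_len(k), drop = FALSE]
  lower <- B[seq.int(k + 1L, length.out = n - k),
             seq.int(k + 1L, length.out = n - k), drop = FALSE]
  off <- B
  off[seq_len(k), seq_len(k)] <- 0
  if (n > k) off[(k + 1L):n, (k + 1L):n] <- 0
  if (max(abs(off)) > 1e-10 * max(1, max(abs(A)))) {
    stop("off-block residual ", format(max(abs(off))),
         " after Fourier conjugation; input violates centrosymmetry")
  }
  structure(list(upper = upper, lower = lower, n = n,
                 upper_markov = is_markov_matrix(upper, tol = tol),
                 upper_rate = is_rate_matrix(upper, tol = tol)),
            class = "block_pair")
}

#' Reassemble a centrosymmetric matrix from its Fourier blocks
#'
#' Computes `S_n diag(upper, lower) S_n^{-1}`, the inverse of
#' [block_transform()]. The result is always centrosymmetric; it is Markov
#' (rate) exactly when the upper block is Markov (rate) and the entrywise
#' compatibility inequalities between the two blocks hold, which the returned
#' flags report.
#'
#' @param upper The upper block, size `ceiling(n/2)`.
#' @param lower The lower block, size `floor(n/2)`.
#' @param n Order of the assembled matrix.
#' @param tol Tolerance used when evaluating the Markov/rate flags.
#' @return The assembled `n x n` matrix with attributes `is_markov` and
#'   `is_rate`.
#' @export
inverse_block_transform <- function(upper, lower, n, tol = tol_float) {
  n <- check_order(n)
  upper <- check_square(upper)
  lower <- check_square(lower)
  k <- ceiling(n / 2)
  if (nrow(upper) != k || nrow(lower) != n - k) {
    stop("block sizes (", nrow(upper), ", ", nrow(lower),
         ") do not match order n = ", n,
         " (expected ", k, " and ", n - k, ")")
  }
  FM <- fourier_matrix(n)
  C <- matrix(0, n, n)
  C[seq_len(k), seq_len(k)] <- upper
  if (n > k) C[(k + 1L):n, (k + 1L):n] <- lower
  A <- FM$S %*% C %*% FM$S_inv
  attr(A, "is_markov") <- is_markov_matrix(A, tol = tol)
  attr(A, "is_rate") <- is_rate_matrix(A, tol = tol)
  A
}

#' Construct a Kimura 3-parameter Markov matrix
#'
#' Helper building the 4x4 K3P matrix with first row `(a, b, c, d)`; the other
#' rows follow from the K3P symmetry (`m11 = m22` etc.). Every K3P matrix is
#' centrosymmetric.
#'
#' @param a,b,c,d First-row entries; they should be non-negative and sum to 1
#'   for a Markov matrix.
#' @return A 4x4 matrix.
#' @export
k3p_matrix <- function(a, b, c, d) {
  matrix(c(a, b, c, d,
           b, a, d, c,
           c, d, a, b,
           d, c, b, a), 4, 4, byrow = TRUE)
}

#' Read and write matrices as headerless CSV
#'
#' Plain-text interchange format used by the command-line interface: one matrix
#' row per line, comma-separated decimal floats, no header. The reader rejects
#' ragged and non-square input; the writer uses 17 significant digits so that
#' values round-trip exactly.
#'
#' @param path File path.
#' @param A Matrix to write.
#' @return `read_matrix_csv` returns a numeric matrix; `write_matrix_csv`
#'   returns `path` invisibly.
#' @export
read_matrix_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty matrix file: ", path)
  rows <- lapply(strsplit(lines, ","), function(x) as.numeric(trimws(x)))
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L) {
    stop("ragged rows in ", path, ": row lengths ",
         paste(unique(lens), collapse = ", "))
  }
  A <- do.call(rbind, rows)
  if (anyNA(A)) stop("non-numeric entries in ", path)
  if (nrow(A) != ncol(A)) {
    stop("matrix in ", path, " is not square: ", nrow(A), " x ", ncol(A))
  }
  unname(A)
}

#' @rdname read_matrix_csv
#' @export
write_matrix_csv <- function(A, path) {
  A <- check_square(A)
  lines <- apply(A, 1, function(r) paste(formatC(r, digits = 17, format = "g"),
                                         collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

check_square <- function(A) {
  if (!is.matrix(A)) A <- as.matrix(A)
  if (!is.numeric(A)) stop("matrix entries must be numeric")
  if (nrow(A) != ncol(A)) {
    stop("expected a square matrix, got ", nrow(A), " x ", ncol(A))
  }
  unname(A)
}

check_order <- function(n) {
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != round(n)) {
    stop("matrix order n must be a positive integer, got ", deparse(n))
  }
  as.integer(n)
}

check_cs_markov <- function(A, tol = tol_float, what = "input") {
  A <- check_square(A)
  if (!is_centrosymmetric(A, tol = tol)) {
    stop(what, " must be centrosymmetric")
  }
  if (!is_markov_matrix(A, tol = tol)) {
    stop(what, " must be a Markov matrix (non-negative, rows summing to 1)")
  }
  A
}
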