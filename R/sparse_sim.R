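#' Nonnegative l1-regularised sparse code of one annotation profile
#'
#' Solves
#' \deqn{\hat\gamma = \arg\min_{\gamma \ge 0}
#'   \tfrac12 \| y - D^T \gamma \|_2^2 + \lambda \|\gamma\|_1}
#' where `y` is one gene's annotation profile and the rows of `D` are the
#' profiles of the candidate reconstructing genes. The l1 penalty drives most
#' coefficients exactly to zero, so the nonzero entries of \eqn{\gamma} pick
#' out a small semantic neighbourhood and double as similarity weights. The
#' solver is cyclic coordinate descent on the Gram form of the problem with
#' clipping at zero; at the solution every coordinate satisfies the KKT
#' conditions \eqn{\gamma_j > 0 \Rightarrow g_j + \lambda = 0} and
#' \eqn{\gamma_j = 0 \Rightarrow g_j + \lambda \ge 0}, where `g` is the
#' gradient of the smooth part.
#'
#' @param y numeric vector of length `|T|` (one row of the propagated
#'   annotation matrix).
#' @param D numeric or sparse matrix, one candidate profile per row.
#' @param lambda positive regularisation scalar; 0.5 by default, with stable
#'   behaviour across 0.1 to 1.
#' @param maxit,tol coordinate-descent sweep limit and convergence tolerance
#'   on the largest coordinate move.
#' @return An object of class `sparse_code`: list with `coefficients`
#'   (nonnegative, length `nrow(D)`), `lambda`, `objective` (the achieved
#'   penalised objective) and `nnz` (coefficients above 1e-10).
#' @export
solve_sparse_code <- function(y, D, lambda = 0.5, maxit = 1000L,
                              tol = 1e-10) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0) {
    stop("`lambda` must be a positive scalar", call. = FALSE)
  }
  y <- as.numeric(y)
  if (!all(is.finite(y))) stop("non-finite values in `y`", call. = FALSE)
  D <- Matrix::Matrix(D, sparse = TRUE)
  if (nrow(D) < 1L) stop("`D` needs at least one row", call. = FALSE)
  if (ncol(D) != length(y)) stop("dimension mismatch", call. = FALSE)

  G <- as.matrix(Matrix::tcrossprod(D))
  if (!all(is.finite(G))) stop("non-finite values in `D`", call. = FALSE)
  b <- as.numeric(D %*% y)
  gamma <- cpp_nnlasso(G, b, lambda, as.integer(maxit), tol)
  obj <- sparse_objective(gamma, G, b, sum(y^2), lambda)
  structure(list(coefficients = gamma, lambda = lambda, objective = obj,
                 nnz = sum(gamma > 1e-10)),
            class = "sparse_code")
}

sparse_objective <- function(gamma, G, b, yy, lambda) {
  0.5 * (yy - 2 * sum(b * gamma) + sum(gamma * (G %*% gamma))) +
    lambda * sum(gamma)
}

#' @exportS3Method base::print
print.sparse_code <- function(x, ...) {
  cat("sparse_code: ", length(x$coefficients), " coefficients, ",
      x$nnz, " nonzero, lambda = ", x$lambda,
      ", objective = ", format(x$objective, digits = 6), "\n", sep = "")
  invisible(x)
}

#' @export
coef.sparse_code <- function(object, ...) object$coefficients

#' Sparse-representation semantic similarity between genes
#'
#' Each gene's propagated annotation profile is reconstructed as a
#' nonnegative sparse combination of the other genes' profiles
#' ([solve_sparse_code()]); the coefficient \eqn{\gamma_i(j)} measures how
#' much gene j contributes to reconstructing gene i, and is taken as the
#' semantic similarity S(i, j) (with the index shift across the removed
#' row). The self-similarity is set to 0 -- a gene must not vote on its own
#' annotations -- and S is symmetrised as \eqn{(S + S^T)/2}. Because every
#' subproblem shares the same Gram matrix up to one deleted row/column, the
#' full N-by-N Gram matrix is computed once and reused.
#'
#' @param A a propagated [annotation_matrix()] (or a plain numeric matrix,
#'   one gene per row).
#' @param lambda regularisation scalar passed to the solver; default 0.5.
#' @param maxit,tol solver controls, see [solve_sparse_code()].
#' @return A symmetric nonnegative N-by-N matrix with zero diagonal and gene
#'   ids as dimnames.
#' @export
semantic_similarity <- function(A, lambda = 0.5, maxit = 1000L,
                                tol = 1e-10) {
  M <- if (inherits(A, "gene_term_matrix")) A$M else Matrix::Matrix(A)
  if (nrow(M) < 2L) stop("need at least two genes", call. = FALSE)
  if (!is.numeric(lambda) || lambda <= 0) {
    stop("`lambda` must be a positive scalar", call. = FALSE)
  }
  Gfull <- as.matrix(Matrix::tcrossprod(M))
  C <- cpp_sparse_codes(Gfull, lambda, as.integer(maxit), tol)
  S <- (C + t(C)) / 2
  diag(S) <- 0
  dimnames(S) <- list(rownames(M), rownames(M))
  S
}

#' Aggregate neighbourhood votes for annotated terms
#'
#' The vote for term t on gene i is the similarity-weighted count of genes
#' carrying t:
#' \deqn{V_{SR}(i,t) = \sum_j S(i,j) A(j,t),}
#' a weighted k-nearest-neighbour tally in which the neighbourhood is picked
#' out by the nonzero entries of S(i, .). Terms annotated to a gene but
#' rarely to its semantic neighbours receive low votes and are candidate
#' noisy annotations. No thresholding is applied here.
#'
#' @param S similarity matrix from [semantic_similarity()].
#' @param A propagated [annotation_matrix()] with the same gene order.
#' @return Dense numeric genes-by-terms matrix of votes.
#' @export
aggregate_votes <- function(S, A) {
  M <- if (inherits(A, "gene_term_matrix")) A$M else A
  if (nrow(S) != nrow(M) || ncol(S) != nrow(M)) {
    stop("gene dimension mismatch between S and A", call. = FALSE)
  }
  if (!is.null(rownames(M)) && !is.null(rownames(S)) &&
      !identical(rownames(S), rownames(M))) {
    stop("gene order of S and A differ", call. = FALSE)
  }
  V <- as.matrix(S %*% M)
  dimnames(V) <- list(rownames(M), colnames(M))
  V
}
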