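#' Fit a noisy-annotation scoring model
#'
#' The one-stop fitting function. From one branch's direct annotation
#' records it builds the direct and true-path-propagated gene-term matrices,
#' the sparse-representation semantic similarity between genes, the
#' similarity-weighted neighbourhood votes, and the evidence-weighted
#' propagated matrix, and fuses the two signals into a per-annotation score
#' \eqn{V(i,t) = \alpha V_{SR}(i,t) + (1-\alpha) A_{ec}(i,t)}. Low-scoring
#' annotated entries are the candidate noisy annotations; use
#' [predict.goanoise()] to extract them.
#'
#' Evidence-code weights can be supplied ready-made (`weights`) or estimated
#' from one or more archived release pairs (`history`): the per-code
#' noisy-annotation ratios of the last `l` pairs are averaged and codes at
#' or above the branch-mean ratio are down-weighted to `theta`.
#'
#' @param records direct annotation records of one branch ([parse_gaf()]
#'   output or equivalent); terms must live in `dag`.
#' @param dag a [go_dag].
#' @param weights an [evidence_weights()] table, or `NULL` to estimate from
#'   `history`.
#' @param history list of release pairs, each a `list(old = , new = )` of
#'   annotation records (oldest pair first), used when `weights` is `NULL`.
#' @param alpha fusion weight, default 0.2.
#' @param theta evidence down-weight in (0, 1), default 0.5.
#' @param lambda sparse-representation regularisation, default 0.5.
#' @param l number of release pairs averaged, default all of `history`.
#' @return An object of class `goanoise`: list with the fitted matrices
#'   (`A_direct`, `A`, `S`, `V_sr`, `A_ec`, `V`), the `weights` table, the
#'   `dag`, and the parameters.
#' @seealso [predict.goanoise()], [evaluate_predictions()]
#' @export
goanoise <- function(records, dag, weights = NULL, history = NULL,
                     alpha = 0.2, theta = 0.5, lambda = 0.5,
                     l = length(history)) {
  stopifnot(inherits(dag, "go_dag"))
  if (is.null(weights)) {
    if (!length(history)) {
      stop("supply either `weights` or `history` release pairs",
           call. = FALSE)
    }
    tables <- lapply(history, function(pair) {
      noise_ratio_table(pair$old, pair$new, shared = dag$terms)
    })
    weights <- evidence_weights(average_ratios(tables, l = l),
                                theta = theta)
  }

  A_direct <- annotation_matrix(records, term_order = dag$terms)
  A <- propagate_annotations(A_direct, dag)
  S <- semantic_similarity(A, lambda = lambda)
  V_sr <- aggregate_votes(S, A)
  A_ec <- propagate_weights(weight_annotations(A_direct, weights), dag)
  V <- fuse_scores(V_sr, A_ec, alpha = alpha)

  structure(list(A_direct = A_direct, A = A, S = S, V_sr = V_sr,
                 A_ec = A_ec, V = V, weights = weights, dag = dag,
                 alpha = alpha, theta = theta, lambda = lambda),
            class = "goanoise")
}

#' @exportS3Method base::print
print.goanoise <- function(x, ...) {
  cat("Noisy-annotation model (", x$dag$branch, " branch)\n", sep = "")
  cat("  genes:", length(x$A$genes), "  terms:", length(x$A$terms),
      " (roots excluded)\n")
  cat("  alpha =", x$alpha, " theta =", x$theta, " lambda =", x$lambda,
      "\n")
  cat("  down-weighted evidence codes:",
      paste(x$weights$code[x$weights$weight < 1], collapse = " "), "\n")
  invisible(x)
}

#' @exportS3Method base::summary
summary.goanoise <- function(object, ...) {
  ann <- Matrix::nnzero(object$A$M)
  res <- list(
    branch = object$dag$branch,
    n_genes = length(object$A$genes),
    n_terms = length(object$A$terms),
    n_annotations = ann,
    density = ann / prod(dim(object$A$M)),
    mean_similarity_nnz = mean(rowSums(object$S > 1e-10)),
    tau = attr(object$weights, "tau"),
    weights = object$weights[object$weights$observed, , drop = FALSE],
    alpha = object$alpha, theta = object$theta, lambda = object$lambda)
  class(res) <- "summary.goanoise"
  res
}

#' @exportS3Method base::print
print.summary.goanoise <- function(x, ...) {
  cat("Noisy-annotation model summary (", x$branch, ")\n", sep = "")
  cat(sprintf("  %d genes x %d terms, %d propagated annotations (%.2f%%)\n",
              x$n_genes, x$n_terms, x$n_annotations, 100 * x$density))
  cat(sprintf("  mean semantic neighbourhood size: %.1f genes\n",
              x$mean_similarity_nnz))
  cat(sprintf("  alpha = %g, theta = %g, lambda = %g, tau = %.4g\n",
              x$alpha, x$theta, x$lambda, x$tau))
  cat("  observed evidence codes:\n")
  print.data.frame(x$weights, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.goanoise <- function(object, ...) object$S

#' Extract noisy-annotation predictions from a fitted model
#'
#' Two selection protocols are available. `mode = "q"` (the evaluation
#' protocol) flags, per gene, the `q` annotated terms with the smallest
#' fused scores; `mode = "threshold"` (the production protocol) flags every
#' annotated entry with fused score below `v_cut`. In both modes descendant
#' terms of flagged annotations that are themselves annotated to the gene
#' are flagged too (true path rule).
#'
#' @param object a fitted [goanoise] model.
#' @param mode `"q"` or `"threshold"`.
#' @param q per-gene number of direct selections (scalar or named by gene);
#'   required for `mode = "q"`.
#' @param v_cut fused-score cutoff for `mode = "threshold"`; default 0.45.
#' @param expand apply descendant expansion (default `TRUE`).
#' @param ... unused.
#' @return A `noise_prediction` data frame.
#' @export
predict.goanoise <- function(object, mode = c("q", "threshold"), q = NULL,
                             v_cut = 0.45, expand = TRUE, ...) {
  mode <- match.arg(mode)
  if (mode == "q") {
    if (is.null(q)) stop("`q` is required in q-mode", call. = FALSE)
    sel <- select_noisy(object$V, object$A, q)
    if (expand) sel <- expand_descendants(sel, object$A, object$dag,
                                          object$V)
    sel
  } else {
    threshold_noisy(object$V, object$A, object$dag, v_cut = v_cut)
  }
}

#' Per-gene ranking of annotated terms by fused score
#'
#' @param object a fitted [goanoise] model.
#' @param gene a gene id.
#' @return Data frame `term`, `score`, ascending by score (ties by term
#'   id).
#' @export
rank_annotations <- function(object, gene) {
  stopifnot(inherits(object, "goanoise"))
  g <- match(gene, object$A$genes)
  if (is.na(g)) stop("unknown gene: ", gene, call. = FALSE)
  ann <- which(object$A$M[g, ] != 0)
  terms <- object$A$terms[ann]
  sc <- object$V[g, ann]
  ord <- order(sc, terms)
  data.frame(term = terms[ord], score = unname(sc[ord]))
}
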