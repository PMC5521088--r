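#' Fuse neighbourhood votes with evidence weights
#'
#' \deqn{V(i,t) = \alpha V_{SR}(i,t) + (1-\alpha) A_{ec}(i,t)}
#' combines the similarity-weighted neighbourhood vote with the propagated
#' evidence weight. At `alpha = 0` the score reduces to the evidence-only
#' ranking (EC); at `alpha = 1` to the vote-only ranking (SR). The default
#' `alpha = 0.2` gives most of the mass to the evidence weight while letting
#' neighbourhood disagreement break ties among equally weighted annotations.
#'
#' @param v_sr vote matrix from [aggregate_votes()].
#' @param a_ec propagated-weighted [gene_term_matrix] from
#'   [propagate_weights()] (or a plain matrix), same gene/term order.
#' @param alpha fusion weight in \[0, 1\].
#' @return Dense numeric genes-by-terms matrix of fused scores.
#' @export
fuse_scores <- function(v_sr, a_ec, alpha = 0.2) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1) {
    stop("`alpha` must lie in [0, 1]", call. = FALSE)
  }
  E <- if (inherits(a_ec, "gene_term_matrix")) a_ec$M else a_ec
  if (!all(dim(v_sr) == dim(E))) stop("shape mismatch", call. = FALSE)
  V <- alpha * v_sr + (1 - alpha) * as.matrix(E)
  dimnames(V) <- dimnames(v_sr)
  V
}

new_noise_prediction <- function(gene = character(), term = character(),
                                 score = numeric(), rank = integer(),
                                 inherited = logical()) {
  structure(data.frame(gene = gene, term = term, score = score,
                       rank = rank, inherited = inherited,
                       stringsAsFactors = FALSE),
            class = c("noise_prediction", "data.frame"))
}

#' Select the q lowest-scoring annotated terms per gene
#'
#' Only terms actually annotated to a gene (A(i, t) = 1) compete: ranking
#' within the gene's own annotations avoids penalising genes that simply
#' have few semantic neighbours and hence uniformly low votes. Per gene the
#' `q` annotated terms with the smallest fused scores are flagged noisy;
#' ties are broken lexicographically by term id so selections are
#' deterministic. Requesting more terms than the gene has annotations
#' selects them all.
#'
#' @param V fused score matrix from [fuse_scores()].
#' @param A binary propagated [gene_term_matrix] (same shape).
#' @param q either a single nonnegative integer or a named vector/list
#'   mapping gene id to its q (genes absent get 0).
#' @return A `noise_prediction` data frame: `gene`, `term`, `score`, `rank`
#'   (of the term in the gene's ascending score order), `inherited`
#'   (all `FALSE` here; see [expand_descendants()]).
#' @export
select_noisy <- function(V, A, q) {
  M <- if (inherits(A, "gene_term_matrix")) A$M else A
  if (!all(dim(V) == dim(M))) stop("shape mismatch", call. = FALSE)
  genes <- rownames(M)
  qvec <- q_per_gene(q, genes)

  out <- vector("list", length(genes))
  terms <- colnames(M)
  for (g in seq_along(genes)) {
    qi <- qvec[[g]]
    if (qi <= 0L) next
    ann <- which(M[g, ] != 0)
    if (!length(ann)) next
    sc <- V[g, ann]
    ord <- order(sc, terms[ann])
    take <- seq_len(min(qi, length(ann)))
    sel <- ann[ord][take]
    out[[g]] <- data.frame(gene = genes[[g]], term = terms[sel],
                           score = V[g, sel], rank = take,
                           inherited = FALSE, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(new_noise_prediction())
  rownames(res) <- NULL
  class(res) <- c("noise_prediction", "data.frame")
  res
}

q_per_gene <- function(q, genes) {
  if (length(q) == 1L && is.null(names(q))) {
    return(rep(as.integer(q), length(genes)))
  }
  q <- unlist(q)
  out <- q[genes]
  out[is.na(out)] <- 0L
  as.integer(out)
}

#' Expand a noisy selection to annotated descendants
#'
#' By the true path rule a term not annotated to a gene implies none of its
#' descendants are either, so once a term is flagged noisy every descendant
#' term still annotated to the gene is flagged too. Added rows carry
#' `inherited = TRUE` and the descendant's own fused score when available.
#' The operation is idempotent.
#'
#' @param selection a `noise_prediction` from [select_noisy()] (or
#'   [threshold_noisy()]).
#' @param A binary propagated [gene_term_matrix].
#' @param dag the [go_dag].
#' @param V optional fused score matrix used to score the added rows
#'   (`NA` otherwise).
#' @return The enlarged `noise_prediction`.
#' @export
expand_descendants <- function(selection, A, dag, V = NULL) {
  M <- if (inherits(A, "gene_term_matrix")) A$M else A
  if (!NROW(selection)) return(selection)
  direct <- selection[!selection$inherited, , drop = FALSE]
  extra <- vector("list", NROW(direct))
  have <- paste(selection$gene, selection$term, sep = "\r")
  terms <- colnames(M)
  for (r in seq_len(NROW(direct))) {
    g <- direct$gene[[r]]
    dn <- go_descendants(dag, direct$term[[r]])
    dn <- dn[dn %in% terms]
    if (!length(dn)) next
    ann <- dn[M[g, dn] != 0]
    if (!length(ann)) next
    ann <- ann[!paste(g, ann, sep = "\r") %in% have]
    if (!length(ann)) next
    have <- c(have, paste(g, ann, sep = "\r"))
    extra[[r]] <- data.frame(
      gene = g, term = ann,
      score = if (is.null(V)) NA_real_ else V[g, ann],
      rank = NA_integer_, inherited = TRUE, stringsAsFactors = FALSE)
  }
  extra <- do.call(rbind, extra)
  if (is.null(extra)) return(selection)
  res <- rbind(as.data.frame(selection), extra)
  rownames(res) <- NULL
  class(res) <- c("noise_prediction", "data.frame")
  res
}

#' Flag annotations below a fixed fused-score cutoff
#'
#' Production-mode selection: every annotated entry with fused score
#' V(i, t) < `v_cut` is flagged noisy, then the flags are expanded to
#' annotated descendants. Under the default parameterisation
#' (`alpha = 0.2`, `theta = 0.5`) the 0.45 cutoff is equivalent to flagging
#' the entries attaining the gene's lowest evidence weight whose vote
#' component satisfies V_SR < 0.25, since the evidence component alone is at
#' least 0.4 for down-weighted and 0.8 for full-weight annotations.
#'
#' @param V fused score matrix.
#' @param A binary propagated [gene_term_matrix].
#' @param dag the [go_dag] (for descendant expansion).
#' @param v_cut score cutoff; default 0.45.
#' @return A `noise_prediction`.
#' @export
threshold_noisy <- function(V, A, dag, v_cut = 0.45) {
  if (!is.numeric(v_cut) || length(v_cut) != 1L || v_cut < 0 ||
      v_cut > max(1, max(V, 0))) {
    stop("`v_cut` outside a sensible range", call. = FALSE)
  }
  M <- if (inherits(A, "gene_term_matrix")) A$M else A
  if (!all(dim(V) == dim(M))) stop("shape mismatch", call. = FALSE)
  genes <- rownames(M); terms <- colnames(M)
  out <- vector("list", length(genes))
  for (g in seq_along(genes)) {
    ann <- which(M[g, ] != 0)
    if (!length(ann)) next
    sc <- V[g, ann]
    flag <- sc < v_cut
    if (!any(flag)) next
    ord <- order(sc, terms[ann])
    rank <- match(ann, ann[ord])
    out[[g]] <- data.frame(gene = genes[[g]], term = terms[ann[flag]],
                           score = sc[flag], rank = rank[flag],
                           inherited = FALSE, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- new_noise_prediction() else {
    rownames(res) <- NULL
    class(res) <- c("noise_prediction", "data.frame")
  }
  expand_descendants(res, A, dag, V)
}

#' Baseline noisy-annotation selectors
#'
#' `baseline_random()` picks q annotated terms per gene uniformly without
#' replacement. `baseline_lf()` picks the q annotated terms with the lowest
#' frequency (column sum of A) across all genes, breaking frequency ties
#' uniformly at random. Both apply descendant expansion, mirroring the main
#' selector, and are fully reproducible from `seed`.
#'
#' @param A binary propagated [gene_term_matrix].
#' @param dag the [go_dag].
#' @param q per-gene selection size, as in [select_noisy()].
#' @param seed integer seed driving all randomness.
#' @return A `noise_prediction`.
#' @export
baseline_random <- function(A, dag, q, seed = 1L) {
  M <- if (inherits(A, "gene_term_matrix")) A$M else A
  genes <- rownames(M); terms <- colnames(M)
  qvec <- q_per_gene(q, genes)
  out <- vector("list", length(genes))
  set.seed(seed)
  for (g in seq_along(genes)) {
    qi <- qvec[[g]]
    if (qi <= 0L) next
    ann <- which(M[g, ] != 0)
    if (!length(ann)) next
    take <- min(qi, length(ann))
    sel <- sort(sample(ann, take))
    out[[g]] <- data.frame(gene = genes[[g]], term = terms[sel],
                           score = NA_real_, rank = seq_len(take),
                           inherited = FALSE, stringsAsFactors = FALSE)
  }
  finish_baseline(out, M, dag)
}

#' @rdname baseline_random
#' @export
baseline_lf <- function(A, dag, q, seed = 1L) {
  M <- if (inherits(A, "gene_term_matrix")) A$M else A
  genes <- rownames(M); terms <- colnames(M)
  freq <- Matrix::colSums(M != 0)
  qvec <- q_per_gene(q, genes)
  out <- vector("list", length(genes))
  set.seed(seed)
  for (g in seq_along(genes)) {
    qi <- qvec[[g]]
    if (qi <= 0L) next
    ann <- which(M[g, ] != 0)
    if (!length(ann)) next
    # random keys break ties among equal frequencies
    ord <- order(freq[ann], stats::runif(length(ann)))
    take <- seq_len(min(qi, length(ann)))
    sel <- ann[ord][take]
    out[[g]] <- data.frame(gene = genes[[g]], term = terms[sel],
                           score = freq[sel], rank = take,
                           inherited = FALSE, stringsAsFactors = FALSE)
  }
  finish_baseline(out, M, dag)
}

finish_baseline <- function(out, M, dag) {
  res <- do.call(rbind, out)
  if (is.null(res)) return(new_noise_prediction())
  rownames(res) <- NULL
  class(res) <- c("noise_prediction", "data.frame")
  expand_descendants(res, M, dag)
}

#' @exportS3Method base::print
print.noise_prediction <- function(x, ...) {
  cat("noise_prediction: ", NROW(x), " flagged annotation(s) on ",
      length(unique(x$gene)), " gene(s) (",
      sum(x$inherited), " inherited)\n", sep = "")
  if (NROW(x)) print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}
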