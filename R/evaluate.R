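#' Derive noisy-annotation labels from a release pair
#'
#' Operational ground truth: a propagated annotation present in the
#' historical matrix but absent from the recent one is labelled noisy.
#' Both matrices must be built over the same (shared) term universe; genes
#' appearing only in the recent release carry no labels.
#'
#' @param A_hist,A_recent propagated [gene_term_matrix] objects over
#'   identical term sets.
#' @return An object of class `noise_labels`: named list mapping each
#'   historical gene to its (possibly empty) character vector of noisy
#'   terms, with attribute `q_true` (named integer vector of label counts).
#' @export
noise_labels <- function(A_hist, A_recent) {
  Mh <- if (inherits(A_hist, "gene_term_matrix")) A_hist$M else A_hist
  Mr <- if (inherits(A_recent, "gene_term_matrix")) A_recent$M else A_recent
  if (!identical(colnames(Mh), colnames(Mr))) {
    stop("term universes differ between the two releases", call. = FALSE)
  }
  terms <- colnames(Mh)
  labels <- vector("list", nrow(Mh))
  names(labels) <- rownames(Mh)
  for (g in seq_len(nrow(Mh))) {
    hist_terms <- terms[Mh[g, ] != 0]
    gene <- rownames(Mh)[[g]]
    r <- match(gene, rownames(Mr))
    labels[[g]] <- if (is.na(r)) hist_terms else {
      hist_terms[Mr[r, match(hist_terms, terms)] == 0]
    }
  }
  structure(labels, q_true = lengths(labels), class = "noise_labels")
}

#' @exportS3Method base::print
print.noise_labels <- function(x, ...) {
  q <- attr(x, "q_true")
  cat("noise_labels: ", sum(q), " noisy annotation(s) on ", sum(q > 0),
      " of ", length(x), " gene(s)\n", sep = "")
  invisible(x)
}

#' Confusion counts and precision/recall/F1 for one gene
#'
#' \eqn{p = TP/(TP+FP)}, \eqn{r = TP/(TP+FN)},
#' \eqn{F1 = 2pr/(p+r)} (0 when \eqn{p + r = 0}; undefined ratios with an
#' empty denominator are 0).
#'
#' @param selected character vector of terms flagged noisy for the gene.
#' @param labels character vector of the gene's true noisy terms.
#' @return Named numeric vector `tp`, `fp`, `fn`, `p`, `r`, `f1`.
#' @export
score_gene <- function(selected, labels) {
  tp <- length(intersect(selected, labels))
  fp <- length(setdiff(selected, labels))
  fn <- length(setdiff(labels, selected))
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(tp = tp, fp = fp, fn = fn, p = p, r = r, f1 = f1)
}

#' Bootstrap evaluation of noisy-annotation predictions
#'
#' Per-gene precision/recall/F1 are computed over the evaluated genes --
#' those with at least one true noisy label; genes with none make no
#' prediction under the q protocol, so their undefined ratios are excluded
#' from the averages. Each bootstrap replicate resamples
#' `floor(fraction * N)` evaluated genes without replacement and averages
#' the per-gene metrics; the report is mean and standard deviation over
#' replicates. `fraction = 1, reps = 1` reproduces the plain averages.
#'
#' @param predictions a `noise_prediction` data frame.
#' @param labels a [noise_labels] object.
#' @param fraction genes sampled per replicate; default 0.85.
#' @param reps bootstrap replicates; default 500.
#' @param seed integer seed.
#' @return An object of class `noise_eval`: list with `per_gene` (data
#'   frame gene/tp/fp/fn/p/r/f1), `precision`, `recall`, `f1` (each
#'   `c(mean, sd)`), `n_genes`, `fraction`, `reps`.
#' @export
evaluate_predictions <- function(predictions, labels, fraction = 0.85,
                                 reps = 500L, seed = 1L) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("`fraction` must lie in (0, 1]", call. = FALSE)
  }
  q_true <- attr(labels, "q_true")
  eval_genes <- names(labels)[q_true > 0]
  sel <- split(predictions$term, predictions$gene)
  per_gene <- t(vapply(eval_genes, function(g) {
    score_gene(sel[[g]], labels[[g]])
  }, numeric(6)))
  per_gene <- data.frame(gene = eval_genes, per_gene,
                         stringsAsFactors = FALSE)

  n <- length(eval_genes)
  take <- max(1L, floor(fraction * n))
  set.seed(seed)
  reps <- as.integer(reps)
  boot <- matrix(NA_real_, reps, 3L,
                 dimnames = list(NULL, c("p", "r", "f1")))
  for (b in seq_len(reps)) {
    idx <- if (take == n) seq_len(n) else sample(n, take)
    boot[b, ] <- c(mean(per_gene$p[idx]), mean(per_gene$r[idx]),
                   mean(per_gene$f1[idx]))
  }
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  structure(list(
    per_gene = per_gene,
    precision = c(mean = mean(boot[, "p"]), sd = sd0(boot[, "p"])),
    recall = c(mean = mean(boot[, "r"]), sd = sd0(boot[, "r"])),
    f1 = c(mean = mean(boot[, "f1"]), sd = sd0(boot[, "f1"])),
    n_genes = n, fraction = fraction, reps = reps),
    class = "noise_eval")
}

#' @exportS3Method base::print
print.noise_eval <- function(x, ...) {
  cat(sprintf(
    "Evaluation over %d gene(s), %d bootstrap replicate(s) of %.0f%%:\n",
    x$n_genes, x$reps, 100 * x$fraction))
  for (m in c("precision", "recall", "f1")) {
    cat(sprintf("  %-9s %6.2f +/- %.2f %%\n", m, 100 * x[[m]][["mean"]],
                100 * x[[m]][["sd"]]))
  }
  invisible(x)
}

#' Majority-vote function prediction from a PPI network
#'
#' Predicts the annotation score of gene i for term t as the fraction of
#' i's interaction partners annotated with t; genes without partners score
#' zero everywhere. Used to measure whether removing noisy annotations from
#' the gene-term matrix improves downstream function prediction.
#'
#' @param ppi two-column data frame (or matrix) of interacting gene-id
#'   pairs; extra columns are ignored. Edges touching genes absent from `A`
#'   are dropped.
#' @param A propagated [gene_term_matrix] supplying the votes.
#' @return Dense genes-by-terms score matrix in \[0, 1\] over `A`'s genes.
#' @export
majority_vote <- function(ppi, A) {
  M <- if (inherits(A, "gene_term_matrix")) A$M else A
  genes <- rownames(M)
  e1 <- as.character(ppi[[1L]]); e2 <- as.character(ppi[[2L]])
  keep <- e1 %in% genes & e2 %in% genes & e1 != e2
  if (!any(keep)) stop("no PPI edge joins two annotated genes",
                       call. = FALSE)
  i <- match(c(e1[keep], e2[keep]), genes)
  j <- match(c(e2[keep], e1[keep]), genes)
  dup <- duplicated(paste(i, j))
  W <- Matrix::sparseMatrix(i = i[!dup], j = j[!dup], x = 1,
                            dims = c(length(genes), length(genes)))
  deg <- Matrix::rowSums(W)
  scores <- as.matrix(W %*% M)
  nz <- deg > 0
  scores[nz, ] <- scores[nz, , drop = FALSE] / deg[nz]
  dimnames(scores) <- dimnames(as.matrix(M))
  scores
}

#' Function-prediction metrics
#'
#' Standard protein-function evaluation over a score matrix against a
#' binary truth matrix: micro- and macro-averaged F1 at score threshold
#' 0.5; average precision and AUROC averaged over terms with at least one
#' positive and one negative; Fmax, the protein-centric F-measure maximised
#' over score thresholds; and Smin, the minimum over thresholds of
#' \eqn{\sqrt{ru^2 + mi^2}} with remaining uncertainty and misinformation
#' weighted by term information content \eqn{-\log f_t} (\eqn{f_t} the
#' term's annotation frequency in the truth).
#'
#' @param scores genes-by-terms numeric score matrix.
#' @param truth binary matrix (or propagated [gene_term_matrix]) of the
#'   same shape.
#' @param thresholds score grid for Fmax/Smin; default `seq(0, 1, 0.01)`.
#' @return One-row data frame: `micro_f1`, `macro_f1`, `avg_prec`,
#'   `avg_auroc`, `fmax`, `smin`.
#' @export
function_pred_metrics <- function(scores, truth,
                                  thresholds = seq(0, 1, 0.01)) {
  Tm <- if (inherits(truth, "gene_term_matrix")) as.matrix(truth$M) else
    as.matrix(truth)
  Tm <- (Tm != 0) * 1
  if (!all(dim(scores) == dim(Tm))) stop("shape mismatch", call. = FALSE)

  pred <- scores >= 0.5
  tp <- sum(pred & Tm == 1); fp <- sum(pred & Tm == 0)
  fn <- sum(!pred & Tm == 1)
  micro_f1 <- f1_of(tp, fp, fn)

  term_pos <- colSums(Tm)
  usable <- term_pos > 0 & term_pos < nrow(Tm)
  degenerate <- term_pos == 0
  if (any(degenerate)) {
    warning(sum(degenerate), " all-zero truth term(s) dropped from ",
            "per-term averages", call. = FALSE)
  }
  macro <- vapply(which(term_pos > 0), function(t) {
    f1_of(sum(pred[, t] & Tm[, t] == 1), sum(pred[, t] & Tm[, t] == 0),
          sum(!pred[, t] & Tm[, t] == 1))
  }, numeric(1))
  macro_f1 <- mean(macro)

  ap <- vapply(which(term_pos > 0), function(t) {
    average_precision(scores[, t], Tm[, t])
  }, numeric(1))
  auroc <- vapply(which(usable), function(t) {
    auroc_rank(scores[, t], Tm[, t])
  }, numeric(1))

  ic <- -log(pmax(term_pos, 0.5) / nrow(Tm))
  fmax <- 0; smin <- Inf
  for (th in thresholds) {
    P <- scores >= th
    # protein-centric precision/recall over proteins with a prediction
    npred <- rowSums(P)
    tp_i <- rowSums(P & Tm == 1)
    prec_i <- ifelse(npred > 0, tp_i / npred, NA_real_)
    rec_i <- ifelse(rowSums(Tm) > 0, tp_i / rowSums(Tm), NA_real_)
    pr <- mean(prec_i[npred > 0])
    rc <- mean(rec_i[!is.na(rec_i)])
    if (!is.nan(pr) && !is.na(pr) && (pr + rc) > 0) {
      fmax <- max(fmax, 2 * pr * rc / (pr + rc))
    }
    miss <- (!P) & Tm == 1
    wrong <- P & Tm == 0
    ru <- mean(as.numeric(miss %*% ic))
    mi <- mean(as.numeric(wrong %*% ic))
    smin <- min(smin, sqrt(ru^2 + mi^2))
  }
  data.frame(micro_f1 = micro_f1, macro_f1 = macro_f1,
             avg_prec = mean(ap), avg_auroc = mean(auroc),
             fmax = fmax, smin = smin)
}

f1_of <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  if (p + r > 0) 2 * p * r / (p + r) else 0
}

# area under the ROC curve via the rank (Mann-Whitney) formula
auroc_rank <- function(score, label) {
  pos <- label == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(score)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

average_precision <- function(score, label) {
  ord <- order(score, decreasing = TRUE)
  lab <- label[ord]
  hits <- cumsum(lab)
  prec_at <- hits / seq_along(lab)
  sum(prec_at[lab == 1]) / sum(lab)
}
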