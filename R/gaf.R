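#' The 21 GO evidence codes
#'
#' Experimental (EXP, IDA, IPI, IMP, IGI, IEP), computational (ISS, ISO, ISA,
#' ISM, IGC, IBA, IBD, IKR, IRD, RCA), author-statement (TAS, NAS) and
#' curatorial (IC, ND) codes, plus IEA (inferred from electronic annotation),
#' the only code not reviewed by a curator.
#'
#' @export
GO_EVIDENCE_CODES <- c(
  "EXP", "IDA", "IPI", "IMP", "IGI", "IEP",
  "ISS", "ISO", "ISA", "ISM", "IGC", "IBA", "IBD", "IKR", "IRD", "RCA",
  "TAS", "NAS", "IC", "ND", "IEA")

GAF_ASPECTS <- c(P = "BP", C = "CC", F = "MF")

#' Parse a GAF annotation file
#'
#' Reads a Gene Association File (GAF 2.0/2.1/2.2; 17 tab-separated columns,
#' comment lines starting with `!`; plain or gzip-compressed) and returns the
#' direct annotation records of one branch. Gene identity is the DB Object ID
#' (column 2); the symbol (column 3) is kept as metadata. NOT-qualified
#' records are negative annotations, not annotations, and are dropped by
#' default; ND records only ever annotate branch roots and are likewise
#' dropped. Records with an unrecognised evidence code, or with a term
#' outside `allowed_terms`, are excluded.
#'
#' @param path path to a GAF file.
#' @param branch one of `"BP"`, `"CC"`, `"MF"`.
#' @param allowed_terms optional character vector restricting the term
#'   universe (e.g. [shared_terms()] of two ontology releases).
#' @param drop_not,drop_nd filter switches, both `TRUE` by default.
#' @return A data frame with columns `gene`, `symbol`, `term`, `evidence`,
#'   `aspect`, `qualifier`, one row per record.
#' @export
parse_gaf <- function(path, branch = c("BP", "CC", "MF"),
                      allowed_terms = NULL, drop_not = TRUE, drop_nd = TRUE) {
  branch <- match.arg(branch)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (!length(lines)) {
    return(annotation_records(character(), character(), character(),
                              character(), character(), character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- nf < 15L
  if (any(bad)) {
    warning(sum(bad), " malformed GAF line(s) skipped", call. = FALSE)
    fields <- fields[!bad]
  }
  get <- function(i) vapply(fields, `[[`, "", i)
  rec <- annotation_records(
    gene = get(2L), symbol = get(3L), term = get(5L),
    evidence = get(7L), aspect = unname(GAF_ASPECTS[get(9L)]),
    qualifier = get(4L))

  rec <- rec[!is.na(rec$aspect) & rec$aspect == branch, , drop = FALSE]
  if (drop_not) {
    rec <- rec[!grepl("(^|\\|)NOT($|\\|)", rec$qualifier), , drop = FALSE]
  }
  unknown <- !rec$evidence %in% GO_EVIDENCE_CODES
  if (any(unknown)) {
    warning(sum(unknown), " record(s) with unknown evidence code dropped",
            call. = FALSE)
    rec <- rec[!unknown, , drop = FALSE]
  }
  if (drop_nd) rec <- rec[rec$evidence != "ND", , drop = FALSE]
  if (!is.null(allowed_terms)) {
    rec <- rec[rec$term %in% allowed_terms, , drop = FALSE]
  }
  rownames(rec) <- NULL
  rec
}

annotation_records <- function(gene, symbol, term, evidence, aspect,
                               qualifier) {
  data.frame(gene = gene, symbol = symbol, term = term, evidence = evidence,
             aspect = aspect, qualifier = qualifier,
             stringsAsFactors = FALSE)
}

#' Gene-by-term annotation matrices
#'
#' `annotation_matrix()` builds the direct binary matrix A^d from annotation
#' records: entry (i, t) is 1 iff at least one record links gene i to term t.
#' Duplicate gene-term pairs collapse to a single entry carrying the union of
#' their evidence codes. Gene order is sorted-unique gene ids and term order
#' is the supplied `term_order`, so matrices built from the same inputs are
#' identical across runs.
#'
#' @param records a data frame of annotation records ([parse_gaf()] output or
#'   equivalent, columns `gene`, `term`, `evidence`).
#' @param term_order character vector fixing the column order; defaults to
#'   sorted-unique terms of `records`.
#' @return An object of class `gene_term_matrix`: a list with sparse matrix
#'   `M` (`Matrix::dgCMatrix`), `genes`, `terms`, `form` and, for direct
#'   forms, `evidence` (data frame gene/term/evidence of the collapsed
#'   pairs).
#' @export
annotation_matrix <- function(records, term_order = NULL) {
  if (!NROW(records)) stop("no annotation records", call. = FALSE)
  if (is.null(term_order)) term_order <- sort(unique(records$term))
  stray <- setdiff(records$term, term_order)
  if (length(stray)) {
    stop("records contain terms outside `term_order` (e.g. ", stray[[1L]],
         ")", call. = FALSE)
  }
  genes <- sort(unique(records$gene))
  key <- paste(records$gene, records$term, sep = "\r")
  first <- !duplicated(key)
  pairs <- records[first, c("gene", "term")]
  ev <- lapply(split(records$evidence, key)[key[first]], unique)

  M <- Matrix::sparseMatrix(
    i = match(pairs$gene, genes), j = match(pairs$term, term_order),
    x = 1, dims = c(length(genes), length(term_order)),
    dimnames = list(genes, term_order))
  new_gene_term_matrix(M, form = "direct",
                       evidence = data.frame(gene = pairs$gene,
                                             term = pairs$term,
                                             codes = I(unname(ev))))
}

new_gene_term_matrix <- function(M, form, evidence = NULL) {
  structure(list(M = methods::as(M, "CsparseMatrix"),
                 genes = rownames(M), terms = colnames(M),
                 form = form, evidence = evidence),
            class = "gene_term_matrix")
}

#' @exportS3Method base::print
print.gene_term_matrix <- function(x, ...) {
  cat("gene_term_matrix (", x$form, "): ", length(x$genes), " genes x ",
      length(x$terms), " terms, ",
      format(100 * Matrix::nnzero(x$M) / prod(dim(x$M)), digits = 3),
      "% nonzero\n", sep = "")
  invisible(x)
}

#' @export
dim.gene_term_matrix <- function(x) dim(x$M)

#' Propagate direct annotations to ancestors (true path rule)
#'
#' Annotation to a term implies annotation to every ancestor along any path
#' of the ontology, so the propagated matrix A has A(i, s) = 1 iff s is a
#' direct term of gene i or an ancestor of one. Branch roots are excluded
#' from the result: every annotated gene hits the root trivially, so a root
#' can never be an informative (or noisy) annotation.
#'
#' @param direct a direct-form [annotation_matrix()].
#' @param dag the [go_dag] the terms live in.
#' @return A `gene_term_matrix` of form `"propagated"` whose columns are the
#'   non-root terms of `dag` (in `dag$terms` order).
#' @export
propagate_annotations <- function(direct, dag) {
  stopifnot(inherits(direct, "gene_term_matrix"), inherits(dag, "go_dag"))
  if (direct$form != "direct") stop("`direct` must be a direct-form matrix",
                                    call. = FALSE)
  missing <- setdiff(direct$terms, dag$terms)
  if (length(missing)) {
    stop("term(s) absent from the ontology (e.g. ", missing[[1L]], ")",
         call. = FALSE)
  }
  keep <- setdiff(dag$terms, dag$root)
  R <- reachability_matrix(dag, from = direct$terms, to = keep)
  P <- direct$M %*% R
  P@x <- rep(1, length(P@x))
  P <- Matrix::drop0(P)
  new_gene_term_matrix(P, form = "propagated")
}

# term-by-term 0/1 matrix: R[t, s] = 1 iff s == t or s is an ancestor of t
reachability_matrix <- function(dag, from, to) {
  i <- integer(0); j <- integer(0)
  to_idx <- stats::setNames(seq_along(to), to)
  for (k in seq_along(from)) {
    t <- from[[k]]
    up <- c(t, dag$anc[[t]])
    hit <- to_idx[up[up %in% to]]
    i <- c(i, rep.int(k, length(hit)))
    j <- c(j, unname(hit))
  }
  Matrix::sparseMatrix(i = i, j = j, x = 1,
                       dims = c(length(from), length(to)),
                       dimnames = list(from, to))
}

#' Write and read noisy-annotation predictions
#'
#' Predictions are serialised as a TSV with one row per flagged (gene, term)
#' pair: gene, term, fused score, rank of the term within the gene's
#' ascending score order, and whether the flag is a direct selection or a
#' descendant expansion. Rows are ordered by gene id, then score, then term
#' id, so output is byte-identical across runs.
#'
#' @param predictions a `noise_prediction` data frame (see
#'   [select_noisy()]).
#' @param path output path.
#' @export
write_predictions <- function(predictions, path) {
  df <- as.data.frame(predictions)
  df <- df[order(df$gene, df$score, df$term), , drop = FALSE]
  df$score <- formatC(df$score, format = "g", digits = 15)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(gene = "character",
                                         term = "character"))
  class(df) <- c("noise_prediction", class(df))
  df
}
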