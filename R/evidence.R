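#' Per-evidence-code noisy-annotation ratios from a release pair
#'
#' A direct (gene, term) annotation carrying evidence code c in the older
#' release is counted noisy when the pair is absent from the newer release's
#' direct annotations; the estimated ratio for c is
#' \deqn{r_{ec}(c) = \bar N(c) / N(c),}
#' the noisy count over the total count of code-c annotations. Presence in
#' the newer release is judged on the (gene, term) pair regardless of code,
#' so an annotation that merely changed evidence code is not counted noisy.
#' Both record sets are restricted to the term universe shared by the two
#' contemporaneous ontology releases, so removals driven by ontology
#' restructuring do not inflate the ratios. Codes with no annotations in the
#' older release are reported with ratio 0 and `observed = FALSE`.
#'
#' @param records_old,records_new annotation records of one branch
#'   ([parse_gaf()] output or equivalent).
#' @param shared character vector of retained term ids ([shared_terms()]).
#' @return Data frame with one row per evidence code: `code`, `n` (total
#'   direct pairs), `n_noisy`, `ratio`, `observed`.
#' @export
noise_ratio_table <- function(records_old, records_new, shared) {
  if (!length(shared)) stop("`shared` term set is empty", call. = FALSE)
  old <- records_old[records_old$term %in% shared, , drop = FALSE]
  new <- records_new[records_new$term %in% shared, , drop = FALSE]
  new_pairs <- unique(paste(new$gene, new$term, sep = "\r"))

  key <- paste(old$gene, old$term, sep = "\r")
  # one row per (gene, term, code); duplicates collapse
  keep <- !duplicated(paste(key, old$evidence, sep = "\r"))
  key <- key[keep]
  code <- old$evidence[keep]
  noisy <- !key %in% new_pairs

  n <- table(factor(code, levels = GO_EVIDENCE_CODES))
  n_noisy <- table(factor(code[noisy], levels = GO_EVIDENCE_CODES))
  n <- as.integer(n); n_noisy <- as.integer(n_noisy)
  data.frame(code = GO_EVIDENCE_CODES, n = n, n_noisy = n_noisy,
             ratio = ifelse(n > 0, n_noisy / pmax(n, 1L), 0),
             observed = n > 0L, stringsAsFactors = FALSE)
}

#' Average noise ratios over successive release pairs
#'
#' \deqn{\tilde r(c) = \frac1l \sum_{m} r^m(c)}
#' over the last `l` release-pair ratio tables; a code unobserved in some
#' pair contributes its flagged zero. A large averaged ratio marks a code
#' whose annotations change frequently across releases and are therefore
#' likely to contain noise.
#'
#' @param ratio_tables list of [noise_ratio_table()] outputs, oldest first.
#' @param l number of most recent tables to average; default 1.
#' @return Data frame `code`, `r_tilde`, `observed` (observed in at least
#'   one averaged table).
#' @export
average_ratios <- function(ratio_tables, l = 1L) {
  if (l < 1L || l > length(ratio_tables)) {
    stop("`l` must be between 1 and the number of ratio tables",
         call. = FALSE)
  }
  use <- ratio_tables[seq(length(ratio_tables) - l + 1L,
                          length(ratio_tables))]
  r <- rowMeans(vapply(use, function(tab) {
    tab$ratio[match(GO_EVIDENCE_CODES, tab$code)]
  }, numeric(length(GO_EVIDENCE_CODES))))
  obs <- Reduce(`|`, lapply(use, function(tab) {
    tab$observed[match(GO_EVIDENCE_CODES, tab$code)]
  }))
  data.frame(code = GO_EVIDENCE_CODES, r_tilde = unname(r),
             observed = obs, stringsAsFactors = FALSE)
}

#' Assign per-code annotation weights
#'
#' Codes whose averaged noise ratio reaches the threshold \eqn{\tau} -- the
#' mean of \eqn{\tilde r} over codes actually observed in the branch -- are
#' unstable, and their annotations are down-weighted to \eqn{\theta < 1};
#' stable codes keep weight 1. Ties \eqn{\tilde r = \tau} fall on the
#' down-weighted side. Codes never observed keep weight 1 by convention
#' (there is no evidence against them) with a warning.
#'
#' @param r_tilde output of [average_ratios()] (or a [noise_ratio_table()],
#'   whose `ratio` column is then used directly).
#' @param theta down-weight in (0, 1); default 0.5.
#' @return An object of class `evidence_weights`: data frame `code`,
#'   `r_tilde`, `observed`, `weight`, with attributes `tau` and `theta`.
#' @export
evidence_weights <- function(r_tilde, theta = 0.5) {
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0 || theta >= 1) {
    stop("`theta` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!NROW(r_tilde)) stop("empty ratio table", call. = FALSE)
  if (is.null(r_tilde$r_tilde)) r_tilde$r_tilde <- r_tilde$ratio
  obs <- r_tilde$observed
  if (is.null(obs)) obs <- rep(TRUE, NROW(r_tilde))
  if (!any(obs)) stop("no observed evidence codes", call. = FALSE)
  tau <- mean(r_tilde$r_tilde[obs])
  weight <- ifelse(obs & r_tilde$r_tilde >= tau, theta, 1)
  if (any(!obs)) {
    warning(sum(!obs), " evidence code(s) unobserved; weight 1 by ",
            "convention", call. = FALSE)
  }
  structure(data.frame(code = r_tilde$code, r_tilde = r_tilde$r_tilde,
                       observed = obs, weight = weight,
                       stringsAsFactors = FALSE),
            tau = tau, theta = theta, class = c("evidence_weights",
                                                "data.frame"))
}

#' Weight direct annotations by their evidence codes
#'
#' Every direct entry is multiplied by the weight of its evidence code; when
#' a gene-term pair carries several codes the maximal weight is used, since
#' corroboration by any stable source makes the annotation stable.
#'
#' @param direct a direct-form [annotation_matrix()] with its evidence map.
#' @param weights an [evidence_weights()] table.
#' @return A `gene_term_matrix` of form `"direct_weighted"` (entries in
#'   `(0, 1]` at the direct support).
#' @export
weight_annotations <- function(direct, weights) {
  stopifnot(inherits(direct, "gene_term_matrix"))
  if (direct$form != "direct" || is.null(direct$evidence)) {
    stop("`direct` must be a direct-form matrix with an evidence map",
         call. = FALSE)
  }
  wmap <- stats::setNames(weights$weight, weights$code)
  ev <- direct$evidence
  w <- vapply(ev$codes, function(codes) {
    wk <- wmap[codes]
    if (anyNA(wk)) {
      warning("evidence code(s) missing from the weight table default to 1",
              call. = FALSE)
      wk[is.na(wk)] <- 1
    }
    max(wk)
  }, numeric(1))
  M <- Matrix::sparseMatrix(
    i = match(ev$gene, direct$genes), j = match(ev$term, direct$terms),
    x = w, dims = dim(direct$M),
    dimnames = list(direct$genes, direct$terms))
  out <- new_gene_term_matrix(M, form = "direct_weighted",
                              evidence = direct$evidence)
  out
}

#' Propagate annotation weights to ancestor terms
#'
#' Extends the evidence-weighted direct matrix over the ontology by the true
#' path rule with a max rule:
#' \deqn{A_{ec}(i,s) = \max\{A^d_{ec}(i,t) : t = s \text{ or } s \in anc(t)\},}
#' so an ancestor annotation is never weighted below any descendant that
#' supports it -- an ancestor term is more general and at least as easy to
#' verify as its descendants. Branch roots are excluded as in
#' [propagate_annotations()].
#'
#' @param direct_weighted output of [weight_annotations()].
#' @param dag the [go_dag].
#' @return A `gene_term_matrix` of form `"propagated_weighted"` whose
#'   support equals the binary propagated matrix (minus roots).
#' @export
propagate_weights <- function(direct_weighted, dag) {
  stopifnot(inherits(direct_weighted, "gene_term_matrix"),
            inherits(dag, "go_dag"))
  if (direct_weighted$form != "direct_weighted") {
    stop("`direct_weighted` must come from weight_annotations()",
         call. = FALSE)
  }
  missing <- setdiff(direct_weighted$terms, dag$terms)
  if (length(missing)) {
    stop("term(s) absent from the ontology (e.g. ", missing[[1L]], ")",
         call. = FALSE)
  }
  keep <- setdiff(dag$terms, dag$root)
  Md <- direct_weighted$M
  tri <- Matrix::summary(Md)
  keep_idx <- stats::setNames(seq_along(keep), keep)

  n_up <- integer(nrow(tri)); ups <- vector("list", nrow(tri))
  for (r in seq_len(NROW(tri))) {
    t <- direct_weighted$terms[[tri$j[[r]]]]
    up <- c(t, dag$anc[[t]])
    hit <- keep_idx[up[up %in% keep]]
    ups[[r]] <- unname(hit)
    n_up[[r]] <- length(hit)
  }
  i <- rep.int(tri$i, n_up)
  j <- unlist(ups, use.names = FALSE)
  x <- rep.int(tri$x, n_up)
  # max over contributing direct annotations per (gene, ancestor) cell
  if (length(i)) {
    key <- paste(i, j, sep = "\r")
    xmax <- tapply(x, key, max)
    ij <- do.call(rbind, strsplit(names(xmax), "\r", fixed = TRUE))
    ii <- as.integer(ij[, 1L]); jj <- as.integer(ij[, 2L])
    xx <- as.numeric(xmax)
  } else {
    ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  }
  M <- Matrix::sparseMatrix(
    i = ii, j = jj, x = xx,
    dims = c(length(direct_weighted$genes), length(keep)),
    dimnames = list(direct_weighted$genes, keep))
  new_gene_term_matrix(M, form = "propagated_weighted")
}

#' Serialise an evidence weight table
#'
#' Writes (or reads back) the per-code table as TSV: branch, code, n,
#' n_noisy, r, r_tilde, w; `tau` and `theta` are carried in a comment
#' header.
#'
#' @param weights an [evidence_weights()] object.
#' @param path file path.
#' @param branch branch label recorded in the file.
#' @param ratios optional [noise_ratio_table()] supplying n / n_noisy / r
#'   columns.
#' @export
write_evidence_weights <- function(weights, path, branch = "BP",
                                   ratios = NULL) {
  df <- data.frame(branch = branch, code = weights$code,
                   n = NA_integer_, n_noisy = NA_integer_, r = NA_real_,
                   r_tilde = weights$r_tilde, w = weights$weight)
  if (!is.null(ratios)) {
    m <- match(df$code, ratios$code)
    df$n <- ratios$n[m]; df$n_noisy <- ratios$n_noisy[m]
    df$r <- ratios$ratio[m]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tau=%.15g theta=%.15g", attr(weights, "tau"),
                     attr(weights, "theta")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
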