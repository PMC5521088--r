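#' Configuration for the synthetic ontology/annotation generator
#'
#' The generator emulates the archived-release setting the method is built
#' for: a layered is_a DAG standing in for one GO branch; genes organised in
#' functional clusters, each owning a coherent subset of terms, so that
#' semantic neighbourhoods carry signal; direct annotations tagged with
#' evidence codes; a fraction of off-profile annotations (a gene annotated
#' to a term outside its cluster's subset) acting as the true injected
#' noise; and a recent release derived from the historical one by removing
#' each annotation with a per-evidence-code probability, with off-profile
#' annotations removed at an elevated rate so that injected noise and
#' release-pair removals are coupled, as they are for real unstable
#' annotations.
#'
#' Default conditions: 300 genes x 400 terms in 5 layers, 10 clusters,
#' 8 direct annotations per gene, 10% off-profile noise; evidence codes
#' drawn from \{IEA, IDA, TAS, IMP\} with electronic annotations dominant
#' and strongly over-represented among off-profile records; removal rates
#' IEA 0.2, IDA 0.05, TAS 0.1, IMP 0.05 and 0.8 for off-profile records.
#'
#' @param n_terms,n_layers,parents_per_term DAG shape: total term count,
#'   number of layers (root = layer 1), and the maximum number of parents a
#'   term draws from the layer above (each term draws 1 to
#'   `parents_per_term`).
#' @param n_genes,directs_per_gene,n_clusters annotation shape.
#' @param profile_noise probability that a direct annotation is replaced by
#'   an off-profile term.
#' @param code_mix,noise_code_mix named probability vectors over evidence
#'   codes for on-profile and off-profile annotations.
#' @param removal_rates named per-code probability of removing an
#'   on-profile record in the recent release.
#' @param noise_removal removal probability for off-profile records.
#' @param branch branch label stamped on the synthetic data.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_terms = 400L, n_layers = 5L,
                       parents_per_term = 2L,
                       n_genes = 300L, directs_per_gene = 8L,
                       n_clusters = 10L, profile_noise = 0.1,
                       code_mix = c(IEA = 0.5, IDA = 0.2, TAS = 0.15,
                                    IMP = 0.15),
                       noise_code_mix = c(IEA = 0.8, IDA = 0.05,
                                          TAS = 0.1, IMP = 0.05),
                       removal_rates = c(IEA = 0.2, IDA = 0.05,
                                         TAS = 0.1, IMP = 0.05),
                       noise_removal = 0.8,
                       branch = "BP") {
  stopifnot(n_layers >= 2L, n_terms > n_layers,
            all(code_mix >= 0), all(noise_code_mix >= 0),
            all(removal_rates >= 0 & removal_rates <= 1),
            noise_removal >= 0, noise_removal <= 1,
            profile_noise >= 0, profile_noise <= 1)
  structure(list(
    n_terms = as.integer(n_terms), n_layers = as.integer(n_layers),
    parents_per_term = as.integer(parents_per_term),
    n_genes = as.integer(n_genes),
    directs_per_gene = as.integer(directs_per_gene),
    n_clusters = as.integer(n_clusters), profile_noise = profile_noise,
    code_mix = code_mix / sum(code_mix),
    noise_code_mix = noise_code_mix / sum(noise_code_mix),
    removal_rates = removal_rates, noise_removal = noise_removal,
    branch = branch), class = "sim_config")
}

sim_term_ids <- function(n) sprintf("GO:9%06d", seq_len(n))

#' Generate a layered random ontology DAG
#'
#' Layer 1 is the root; the remaining terms are split evenly over layers 2
#' to `n_layers`, and each term draws 1 to `parents_per_term` distinct
#' parents uniformly from the layer above. The construction is acyclic and
#' rooted by design and fully reproducible from `seed`.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return A [go_dag].
#' @export
generate_dag <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_terms
  set.seed(seed)
  ids <- sim_term_ids(n)
  n_rest <- n - 1L
  per_layer <- diff(round(seq(0, n_rest,
                              length.out = cfg$n_layers)))
  if (any(per_layer < 1L)) stop("infeasible DAG shape", call. = FALSE)
  layer <- c(1L, rep(seq_len(cfg$n_layers - 1L) + 1L, per_layer))
  parents <- vector("list", n)
  names(parents) <- ids
  parents[[1L]] <- character()
  for (k in 2L:n) {
    above <- ids[layer == layer[[k]] - 1L]
    np <- sample(seq_len(min(cfg$parents_per_term, length(above))), 1L)
    parents[[k]] <- sample(above, np)
  }
  go_dag(ids, parents, branch = cfg$branch, root = ids[[1L]])
}

#' Generate cluster-structured direct annotations
#'
#' Non-root terms are partitioned at random into `n_clusters` coherent
#' subsets; each gene belongs to one cluster and draws its
#' `directs_per_gene` direct terms from the cluster subset, except that with
#' probability `profile_noise` a draw is replaced by a term from another
#' cluster's subset. These off-profile annotations are the injected "true
#' noise". Evidence codes are drawn from `code_mix` (on-profile) or
#' `noise_code_mix` (off-profile).
#'
#' @param dag a [go_dag] from [generate_dag()].
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return List with `records` (annotation records plus an `off_profile`
#'   flag column), `clusters` (named gene-to-cluster vector) and
#'   `cluster_terms` (list of term subsets).
#' @export
generate_annotations <- function(dag, cfg, seed = 1L) {
  stopifnot(inherits(dag, "go_dag"), inherits(cfg, "sim_config"))
  set.seed(seed)
  pool <- setdiff(dag$terms, dag$root)
  cluster_terms <- split(sample(pool),
                         rep_len(seq_len(cfg$n_clusters), length(pool)))
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  cluster <- stats::setNames(
    rep_len(seq_len(cfg$n_clusters), cfg$n_genes), genes)

  rows <- vector("list", cfg$n_genes)
  for (g in seq_len(cfg$n_genes)) {
    own <- cluster_terms[[cluster[[g]]]]
    other <- setdiff(pool, own)
    k <- min(cfg$directs_per_gene, length(own))
    terms <- sample(own, k)
    off <- stats::runif(k) < cfg$profile_noise
    if (any(off)) terms[off] <- sample(other, sum(off))
    code <- character(k)
    if (any(!off)) code[!off] <- sample(names(cfg$code_mix), sum(!off),
                                        replace = TRUE,
                                        prob = cfg$code_mix)
    if (any(off)) code[off] <- sample(names(cfg$noise_code_mix), sum(off),
                                      replace = TRUE,
                                      prob = cfg$noise_code_mix)
    rows[[g]] <- data.frame(gene = genes[[g]], symbol = genes[[g]],
                            term = terms, evidence = code,
                            aspect = cfg$branch, qualifier = "",
                            off_profile = off, stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  list(records = records, clusters = cluster,
       cluster_terms = cluster_terms)
}

#' Derive a historical/recent release pair with known removals
#'
#' The historical release is the input record set; the recent release drops
#' each record independently -- off-profile records with probability
#' `noise_removal`, others with the per-code `removal_rates` (codes without
#' a configured rate are never removed). The removed set is returned as
#' ground truth for ratio-recovery checks.
#'
#' @param records annotation records, optionally with an `off_profile`
#'   column (absent means all on-profile).
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return List `historical`, `recent` (record data frames) and `removed`
#'   (the dropped rows of `historical`).
#' @export
make_release_pair <- function(records, cfg, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  unseen <- setdiff(names(cfg$removal_rates), records$evidence)
  if (length(unseen)) {
    warning("removal rate(s) for evidence code(s) not present: ",
            paste(unseen, collapse = ", "), call. = FALSE)
  }
  p <- cfg$removal_rates[records$evidence]
  p[is.na(p)] <- 0
  off <- if (is.null(records$off_profile)) rep(FALSE, NROW(records)) else
    records$off_profile
  p[off] <- cfg$noise_removal
  drop <- stats::runif(NROW(records)) < p
  list(historical = records,
       recent = records[!drop, , drop = FALSE],
       removed = records[drop, , drop = FALSE])
}

#' Write synthetic data as OBO and GAF files
#'
#' `write_obo()` emits a minimal OBO 1.2 file (one `[Term]` stanza per term
#' with `is_a` lines) and `write_gaf()` a GAF 2.1 file with placeholder
#' database `SIM`, so the parsers can be exercised end to end on synthetic
#' data. Output is byte-identical for identical inputs.
#'
#' @param dag a [go_dag].
#' @param records annotation records.
#' @param path output path.
#' @export
write_obo <- function(dag, path) {
  ns <- names(GO_NAMESPACES)[match(dag$branch, GO_NAMESPACES)]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (t in dag$terms) {
    writeLines(c("[Term]", paste0("id: ", t), paste0("name: ", t),
                 paste0("namespace: ", ns),
                 paste0("is_a: ", dag$parents[[t]]), ""), con)
  }
  for (t in dag$obsolete) {
    writeLines(c("[Term]", paste0("id: ", t), paste0("name: ", t),
                 paste0("namespace: ", ns), "is_obsolete: true", ""), con)
  }
  invisible(path)
}

#' @rdname write_obo
#' @export
write_gaf <- function(records, path) {
  aspect <- names(GAF_ASPECTS)[match(records$aspect, GAF_ASPECTS)]
  lines <- sprintf(
    "SIM\t%s\t%s\t%s\t%s\tSIM:0000001\t%s\t\t%s\t%s\t\tprotein\ttaxon:0000\t20160501\tSIM\t\t",
    records$gene, records$symbol, records$qualifier, records$term,
    records$evidence, aspect, records$symbol)
  writeLines(c("!gaf-version: 2.1", lines), path)
  invisible(path)
}
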