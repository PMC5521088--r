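# Independent oracles and shared fixtures. The oracles deliberately use
# different algorithms from the package internals: projected gradient
# instead of coordinate descent, repeated BFS instead of closure by
# topological dynamic programming, and per-gene set unions instead of a
# sparse matrix product.

# projected-gradient solver for min 0.5||y - D'g||^2 + lambda||g||_1, g >= 0
pg_nnlasso <- function(y, D, lambda, iters = 50000L, tol = 1e-12) {
  D <- as.matrix(D)
  G <- D %*% t(D)
  b <- as.numeric(D %*% y)
  L <- max(sum(abs(G)), 1e-12) # crude Lipschitz bound via matrix norm
  step <- 1 / L
  g <- rep(0, nrow(D))
  for (k in seq_len(iters)) {
    gn <- pmax(0, g - step * (as.numeric(G %*% g) - b + lambda))
    if (max(abs(gn - g)) < tol) {
      g <- gn
      break
    }
    g <- gn
  }
  g
}

pg_objective <- function(g, y, D, lambda) {
  r <- as.numeric(y) - as.numeric(t(as.matrix(D)) %*% g)
  0.5 * sum(r^2) + lambda * sum(g)
}

# KKT residual of the nonnegative lasso at gamma (max violation)
kkt_residual <- function(g, y, D, lambda, zero_tol = 1e-10) {
  D <- as.matrix(D)
  grad <- as.numeric(D %*% (t(D) %*% g) - D %*% as.numeric(y))
  active <- g > zero_tol
  max(c(0,
        abs(grad[active] + lambda),
        pmax(0, -(grad[!active] + lambda))))
}

# naive ancestors by repeated breadth-first search over parent edges
bfs_ancestors <- function(parents, term) {
  seen <- character(0)
  frontier <- parents[[term]]
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(parents[frontier])), seen)
  }
  seen
}

# brute-force true-path propagation: per gene, union of ancestor-closures
brute_propagate <- function(records, dag) {
  keep <- setdiff(dag$terms, dag$root)
  genes <- sort(unique(records$gene))
  M <- matrix(0, length(genes), length(keep),
              dimnames = list(genes, keep))
  for (r in seq_len(nrow(records))) {
    up <- c(records$term[[r]], bfs_ancestors(dag$parents, records$term[[r]]))
    up <- intersect(up, keep)
    M[records$gene[[r]], up] <- 1
  }
  M
}

# diamond: t3 is_a t1, t3 is_a t2, t1/t2 is_a root
diamond_dag <- function() {
  go_dag(c("GO:0000001", "GO:0000002", "GO:0000003", "GO:0000004"),
         parents = list(
           "GO:0000001" = character(),
           "GO:0000002" = "GO:0000001",
           "GO:0000003" = "GO:0000001",
           "GO:0000004" = c("GO:0000002", "GO:0000003")),
         branch = "BP", root = "GO:0000001")
}

# records constructor for terse fixtures
rec <- function(gene, term, evidence = "IDA", qualifier = "") {
  data.frame(gene = gene, symbol = gene, term = term, evidence = evidence,
             aspect = "BP", qualifier = qualifier, stringsAsFactors = FALSE)
}

# random layered DAG + records, small scale, for property sweeps
random_fixture <- function(seed, n_terms = 30L, n_genes = 8L,
                           directs = 3L) {
  cfg <- sim_config(n_terms = n_terms, n_layers = 3L, n_genes = n_genes,
                    directs_per_gene = directs, n_clusters = 2L)
  dag <- generate_dag(cfg, seed = seed)
  ann <- generate_annotations(dag, cfg, seed = seed + 1L)
  list(cfg = cfg, dag = dag, records = ann$records)
}

# three genes, one removed annotation: g2 loses GO:0000002
boot_fixture <- function() {
  dag <- diamond_dag()
  Ah <- propagate_annotations(
    annotation_matrix(rbind(rec("g1", "GO:0000004"),
                            rec("g2", "GO:0000002"),
                            rec("g3", "GO:0000003")),
                      term_order = dag$terms), dag)
  Ar <- propagate_annotations(
    annotation_matrix(rbind(rec("g1", "GO:0000004"),
                            rec("g3", "GO:0000003")),
                      term_order = dag$terms), dag)
  list(dag = dag, Ah = Ah, labels = noise_labels(Ah, Ar))
}

gaf_line <- function(gene, term, evidence, aspect = "P", qualifier = "") {
  paste("SIM", gene, gene, qualifier, term, "SIM:1", evidence, "", aspect,
        gene, "", "protein", "taxon:0", "20150501", "SIM", "", "",
        sep = "\t")
}
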