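#' Gene Ontology branch graphs
#'
#' A `go_dag` holds the terms of one GO branch (BP, CC or MF) together with
#' the child-to-parent containment edges (`is_a`, and optionally `part_of`)
#' restricted to that branch. Ancestor and descendant closures are
#' precomputed at construction so lookups are O(1).
#'
#' @param terms character vector of term identifiers.
#' @param parents named list: for each term, the character vector of its
#'   direct parents (empty for the root). Names must cover `terms`.
#' @param branch one of `"BP"`, `"CC"`, `"MF"`.
#' @param root identifier of the branch root. If `NULL`, the unique term
#'   without parents is used.
#' @param obsolete character vector of obsolete term identifiers; obsolete
#'   terms carry no edges and are excluded from `terms`.
#' @param alt_ids named character vector mapping alternate ids to primary ids.
#'
#' @return An object of class `go_dag` with components `branch`, `terms`,
#'   `parents`, `children`, `root`, `obsolete`, `alt_ids`, and precomputed
#'   closures `anc` and `desc` (named lists of character vectors, excluding
#'   the term itself).
#' @export
go_dag <- function(terms, parents, branch = c("BP", "CC", "MF"),
                   root = NULL, obsolete = character(),
                   alt_ids = character()) {
  branch <- match.arg(branch)
  terms <- unique(as.character(terms))
  terms <- setdiff(terms, obsolete)
  parents <- lapply(parents[intersect(names(parents), terms)], function(p) {
    intersect(unique(as.character(p)), terms)
  })
  missing <- setdiff(terms, names(parents))
  parents[missing] <- replicate(length(missing), character(), simplify = FALSE)
  parents <- parents[terms]

  ord <- topo_order(terms, parents)

  if (is.null(root)) {
    known <- GO_BRANCH_ROOTS[[branch]]
    if (known %in% terms) root <- known
  }
  if (is.null(root)) {
    rootless <- terms[vapply(parents, length, 1L) == 0L]
    if (length(rootless) != 1L) {
      stop("cannot infer a unique root (", length(rootless),
           " parentless terms); supply `root`", call. = FALSE)
    }
    root <- rootless
  }

  # ancestor closure by dynamic programming along the topological order
  anc <- vector("list", length(terms))
  names(anc) <- terms
  for (t in ord) {
    p <- parents[[t]]
    anc[[t]] <- unique(c(p, unlist(anc[p], use.names = FALSE)))
  }

  children <- invert_edges(parents, terms)
  desc <- vector("list", length(terms))
  names(desc) <- terms
  for (t in rev(ord)) {
    ch <- children[[t]]
    desc[[t]] <- unique(c(ch, unlist(desc[ch], use.names = FALSE)))
  }

  non_root <- setdiff(terms, root)
  orphan <- non_root[!vapply(anc[non_root], function(a) root %in% a, TRUE)]
  if (length(orphan)) {
    warning(length(orphan), " term(s) have no path to the root (e.g. ",
            orphan[[1L]], ")", call. = FALSE)
  }

  structure(
    list(branch = branch, terms = terms, parents = parents,
         children = children, root = root,
         obsolete = unique(as.character(obsolete)),
         alt_ids = alt_ids, anc = anc, desc = desc),
    class = "go_dag")
}

# Kahn topological sort; errors on cycles.
topo_order <- function(terms, parents) {
  indeg <- vapply(parents, length, 1L)
  children <- invert_edges(parents, terms)
  queue <- terms[indeg == 0L]
  ord <- character(0)
  while (length(queue)) {
    t <- queue[[1L]]; queue <- queue[-1L]
    ord <- c(ord, t)
    for (ch in children[[t]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) != length(terms)) {
    stop("cycle detected in ontology graph", call. = FALSE)
  }
  ord
}

invert_edges <- function(parents, terms) {
  children <- replicate(length(terms), character(), simplify = FALSE)
  names(children) <- terms
  for (t in names(parents)) {
    for (p in parents[[t]]) children[[p]] <- c(children[[p]], t)
  }
  children
}

#' @exportS3Method base::print
print.go_dag <- function(x, ...) {
  cat("GO DAG (", x$branch, "): ", length(x$terms), " terms, ",
      sum(vapply(x$parents, length, 1L)), " edges, root ", x$root,
      if (length(x$obsolete)) paste0(", ", length(x$obsolete), " obsolete"),
      "\n", sep = "")
  invisible(x)
}

check_term <- function(dag, term) {
  if (!term %in% dag$terms) {
    if (term %in% names(dag$alt_ids)) return(dag$alt_ids[[term]])
    stop("unknown term: ", term, call. = FALSE)
  }
  term
}

#' Ancestors and descendants of a term
#'
#' All terms reachable from `term` by following child-to-parent
#' (`go_ancestors`) or parent-to-child (`go_descendants`) edges; the term
#' itself is never included. Alternate ids are resolved to their primary id.
#'
#' @param dag a [go_dag].
#' @param term a term identifier present in `dag`.
#' @return Character vector of term identifiers (possibly empty).
#' @export
go_ancestors <- function(dag, term) {
  stopifnot(inherits(dag, "go_dag"))
  dag$anc[[check_term(dag, term)]]
}

#' @rdname go_ancestors
#' @export
go_descendants <- function(dag, term) {
  stopifnot(inherits(dag, "go_dag"))
  dag$desc[[check_term(dag, term)]]
}

#' Terms shared by two releases of a branch ontology
#'
#' Annotation-release comparisons are restricted to terms present and
#' non-obsolete in both the historical and the recent ontology file, so that
#' removals caused by ontology restructuring are not mistaken for noisy
#' annotations.
#'
#' @param dag_old,dag_new two [go_dag] objects for the same branch.
#' @return Character vector of term identifiers.
#' @export
shared_terms <- function(dag_old, dag_new) {
  stopifnot(inherits(dag_old, "go_dag"), inherits(dag_new, "go_dag"))
  if (dag_old$branch != dag_new$branch) {
    stop("branch mismatch: ", dag_old$branch, " vs ", dag_new$branch,
         call. = FALSE)
  }
  intersect(dag_old$terms, dag_new$terms)
}

GO_BRANCH_ROOTS <- c(BP = "GO:0008150", CC = "GO:0005575",
                     MF = "GO:0003674")

GO_NAMESPACES <- c(biological_process = "BP",
                   cellular_component = "CC",
                   molecular_function = "MF")

#' Parse an OBO ontology file into a branch DAG
#'
#' Reads an OBO 1.2/1.4 flat file and returns the sub-ontology of one branch.
#' `is_a` edges are always kept; `part_of` relationships are kept by default
#' since annotation to a part implies annotation to the whole, while
#' regulates-type relations are not containment relations and are ignored.
#' Edges whose parent lies in another branch are dropped, and obsolete terms
#' are recorded but excluded from the graph.
#'
#' @param path path to an OBO file (plain or gzip-compressed).
#' @param branch one of `"BP"`, `"CC"`, `"MF"`.
#' @param relations relationship types treated as containment edges.
#' @return A [go_dag].
#' @export
parse_obo <- function(path, branch = c("BP", "CC", "MF"),
                      relations = c("is_a", "part_of")) {
  branch <- match.arg(branch)
  lines <- readLines(path, warn = FALSE)

  starts <- grep("^\\[", lines)
  term_starts <- starts[lines[starts] == "[Term]"]
  if (!length(term_starts)) stop("no [Term] stanzas in ", path, call. = FALSE)
  ends <- c(starts[-1L] - 1L, length(lines))
  stanza_end <- ends[match(term_starts, starts)]

  ids <- character(0); ns <- character(0)
  parents <- list(); obsolete <- character(0)
  alt_from <- character(0); alt_to <- character(0)

  for (k in seq_along(term_starts)) {
    block <- lines[(term_starts[[k]] + 1L):stanza_end[[k]]]
    id <- sub("^id: *", "", grep("^id: ", block, value = TRUE)[1L])
    if (is.na(id)) next
    namespace <- sub("^namespace: *", "",
                     grep("^namespace: ", block, value = TRUE)[1L])
    if (is.na(namespace) || !namespace %in% names(GO_NAMESPACES)) {
      warning("term ", id, " has unknown namespace; skipped", call. = FALSE)
      next
    }
    if (GO_NAMESPACES[[namespace]] != branch) next
    if (any(grepl("^is_obsolete: *true", block))) {
      obsolete <- c(obsolete, id)
      next
    }
    p <- character(0)
    if ("is_a" %in% relations) {
      isa <- grep("^is_a: ", block, value = TRUE)
      p <- c(p, sub("^is_a: *(\\S+).*$", "\\1", isa))
    }
    rel <- setdiff(relations, "is_a")
    if (length(rel)) {
      pat <- paste0("^relationship: *(", paste(rel, collapse = "|"), ") ")
      rl <- grep(pat, block, value = TRUE)
      p <- c(p, sub("^relationship: *\\S+ +(\\S+).*$", "\\1", rl))
    }
    alts <- sub("^alt_id: *", "", grep("^alt_id: ", block, value = TRUE))
    alt_from <- c(alt_from, alts)
    alt_to <- c(alt_to, rep(id, length(alts)))
    ids <- c(ids, id)
    ns <- c(ns, namespace)
    parents[[id]] <- p
  }

  alt_ids <- stats::setNames(alt_to, alt_from)
  go_dag(ids, parents, branch = branch, obsolete = obsolete,
         alt_ids = alt_ids)
}
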