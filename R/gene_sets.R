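# Immune-gene set construction: either a plain gene list, or the closure
# of Gene Ontology terms at or below a set of immune-related roots plus
# the genes annotated to them.  Reachability runs on an igraph DAG built
# from child->parent edges; tests validate it against a boolean
# matrix-closure oracle.

#' Default immune-related GO root terms
#'
#' Immune system process, immune response, cytokine-mediated signaling,
#' interferon-gamma-mediated signaling, interleukin-1-mediated signaling
#' and the JAK-STAT cascade.
#'
#' @return Character vector of six GO term ids.
#' @export
go_immune_roots <- function() {
  c("GO:0002376", "GO:0006955", "GO:0019221",
    "GO:0060333", "GO:0070102", "GO:0007259")
}

#' Parse an OBO v1.2 ontology file
#'
#' Minimal stanza parser retaining term ids, names, `is_a` parents and
#' `relationship:` edges.  Obsolete terms are dropped.
#'
#' @param path OBO file path.
#' @return List with `terms` (data frame `id`, `name`) and `edges`
#'   (data frame `child`, `parent`, `relation`).
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- which(lines == "[Term]")
  if (length(starts) == 0L) .err_input("no [Term] stanzas in '", path, "'")
  bounds <- c(starts, length(lines) + 1L)
  terms <- list()
  edges <- list()
  for (i in seq_along(starts)) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    block <- block[nzchar(block) & !startsWith(block, "[")]
    get1 <- function(key) {
      v <- sub(paste0("^", key, ": *"), "",
               grep(paste0("^", key, ":"), block, value = TRUE))
      if (length(v) == 0L) NA_character_ else v[1]
    }
    id <- get1("id")
    if (is.na(id)) next
    if (identical(get1("is_obsolete"), "true")) next
    terms[[length(terms) + 1L]] <- data.frame(
      id = id, name = ifelse(is.na(get1("name")), id, get1("name")),
      stringsAsFactors = FALSE)
    isa <- sub(" !.*$", "", sub("^is_a: *", "",
               grep("^is_a:", block, value = TRUE)))
    for (p in isa) {
      edges[[length(edges) + 1L]] <- data.frame(
        child = id, parent = p, relation = "is_a",
        stringsAsFactors = FALSE)
    }
    rel <- sub(" !.*$", "", sub("^relationship: *", "",
               grep("^relationship:", block, value = TRUE)))
    for (r in rel) {
      parts <- strsplit(trimws(r), " +")[[1]]
      if (length(parts) >= 2L) {
        edges[[length(edges) + 1L]] <- data.frame(
          child = id, parent = parts[2], relation = parts[1],
          stringsAsFactors = FALSE)
      }
    }
  }
  list(terms = do.call(rbind, c(terms, list(data.frame(
         id = character(), name = character(), stringsAsFactors = FALSE)))),
       edges = do.call(rbind, c(edges, list(data.frame(
         child = character(), parent = character(), relation = character(),
         stringsAsFactors = FALSE)))))
}

#' Parse a GAF 2.x gene-annotation file
#'
#' Reads the gene symbol (column 3), GO term (column 5) and evidence code
#' (column 7) of every non-comment row.
#'
#' @param path GAF path.
#' @param evidence_include Optional character vector; when given, only
#'   annotations with these evidence codes are kept.
#' @return Data frame `gene`, `term`, `evidence`.
#' @export
read_gaf <- function(path, evidence_include = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (length(lines) == 0L) {
    return(data.frame(gene = character(), term = character(),
                      evidence = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 7L)) {
    .err_input("GAF rows need at least 7 columns in '", path, "'")
  }
  out <- data.frame(gene = vapply(fields, `[[`, character(1), 3L),
                    term = vapply(fields, `[[`, character(1), 5L),
                    evidence = vapply(fields, `[[`, character(1), 7L),
                    stringsAsFactors = FALSE)
  if (!is.null(evidence_include)) {
    out <- out[out$evidence %in% evidence_include, , drop = FALSE]
  }
  out
}

#' Build an ontology graph from parsed OBO and GAF tables
#'
#' @param obo Result of [read_obo()].
#' @param annotations Result of [read_gaf()] (or any data frame with
#'   `gene` and `term`).  Annotations to unknown terms are dropped with a
#'   warning.
#' @return List with `terms`, `edges`, `annotations`.
#' @export
ontology_graph <- function(obo, annotations) {
  known <- annotations$term %in% obo$terms$id
  if (any(!known)) {
    warning(sum(!known), " annotation(s) to terms absent from the ",
            "ontology were dropped")
    annotations <- annotations[known, , drop = FALSE]
  }
  list(terms = obo$terms, edges = obo$edges, annotations = annotations)
}

#' Descendant closure of ontology roots
#'
#' Returns the roots plus every term from which a root is reachable by
#' following child-to-parent edges of the selected relations -- i.e. all
#' terms at or below the roots in the acyclic graph.
#'
#' @param graph Ontology graph from [ontology_graph()] (annotations may be
#'   empty).
#' @param roots Character vector of root term ids; unknown roots are an
#'   error.
#' @param relations Relations to traverse (default `is_a` only; add
#'   `"part_of"` to widen the closure).
#' @return Character vector of term ids (sorted).
#' @export
descendant_closure <- function(graph, roots, relations = "is_a") {
  unknown <- setdiff(roots, graph$terms$id)
  if (length(unknown) > 0L) {
    .err_input("unknown root term(s): ", paste(unknown, collapse = ", "))
  }
  e <- graph$edges[graph$edges$relation %in% relations, , drop = FALSE]
  vids <- unique(c(graph$terms$id, e$child, e$parent))
  g <- igraph::graph_from_data_frame(
    e[, c("child", "parent")], directed = TRUE,
    vertices = data.frame(name = vids, stringsAsFactors = FALSE))
  if (!igraph::is_dag(g)) {
    .err_input("cycle detected in the ontology over relations: ",
               paste(relations, collapse = ", "))
  }
  below <- unique(unlist(lapply(roots, function(r) {
    names(igraph::subcomponent(g, r, mode = "in"))
  })))
  sort(unique(c(roots, below)))
}

#' Genes annotated to any term of a set
#'
#' @param graph Ontology graph from [ontology_graph()].
#' @param term_set Character vector of term ids.
#' @return Sorted character vector of unique gene symbols.
#' @export
genes_for_terms <- function(graph, term_set) {
  sort(unique(graph$annotations$gene[graph$annotations$term %in% term_set]))
}

#' Immune gene set from OBO + GAF
#'
#' Convenience wrapper: closure of `roots` over the ontology, then all
#' genes annotated at or below them.
#'
#' @param obo_path OBO file path.
#' @param gaf_path GAF file path.
#' @param roots Root GO terms (default [go_immune_roots()], intersected
#'   with the terms actually present in the ontology).
#' @param relations Relations to traverse.
#' @return Character vector of gene symbols.
#' @export
immune_gene_set <- function(obo_path, gaf_path, roots = NULL,
                            relations = "is_a") {
  obo <- read_obo(obo_path)
  graph <- ontology_graph(obo, read_gaf(gaf_path))
  if (is.null(roots)) {
    roots <- intersect(go_immune_roots(), graph$terms$id)
    if (length(roots) == 0L) {
      .err_input("none of the default immune GO roots are present in '",
                 obo_path, "'; pass roots explicitly")
    }
  }
  genes_for_terms(graph, descendant_closure(graph, roots, relations))
}

#' Read a plain newline-delimited gene list
#'
#' Blank lines and `#` comments are ignored; entries are trimmed and
#' deduplicated.  This bypasses the ontology path entirely.
#'
#' @param path Text file path.
#' @return Character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x) & !startsWith(x, "#")])
}
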