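#' Build a protein-protein interaction network over a protein set
#'
#' Reads an undirected edge list (two-column TSV, or SIF with the relation in
#' the middle column), restricts it to the supplied protein set, and
#' summarizes connectivity: connected components over nodes with degree >= 1,
#' singletons, and the connected fraction of the full set.
#'
#' @param proteins character vector: the protein set of interest (e.g. all
#'   proteins with >= 2 regulated phosphopeptides).
#' @param edge_list path to the edge file. Lines with two whitespace- or
#'   tab-separated fields are edges `A B`; three fields are SIF `A rel B`.
#'   Blank lines are ignored; anything else is a parse error reporting the
#'   line number.
#' @return an object of class `"interaction_graph"`: list with `graph`
#'   (igraph), `nodes`, `edges` (two-column data frame), `components`
#'   (list of character vectors over connected nodes, largest first),
#'   `singletons`, `degree` (named), `n_connected`, `fraction_connected`
#'   (`n_connected / length(proteins)`), `n_dropped_edges` (edges with an
#'   endpoint outside `proteins`).
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("A\tB", "B\tC", "D\tE"), f)
#' net <- build_interaction_network(c("A", "B", "C", "D", "E", "F"), f)
#' net$fraction_connected
#' @export
build_interaction_network <- function(proteins, edge_list) {
  proteins <- unique(as.character(proteins))
  lines <- readLines(edge_list)
  keep <- nzchar(trimws(lines))
  pairs <- matrix(character(), ncol = 2)
  for (i in which(keep)) {
    tok <- strsplit(trimws(lines[i]), "[\t ]+")[[1]]
    pair <- if (length(tok) == 2L) tok
            else if (length(tok) == 3L) tok[c(1L, 3L)]
            else abort(paste0("malformed edge at line ", i, ": ", lines[i]),
                       class = "crmp2screen_parse_error")
    pairs <- rbind(pairs, pair)
  }
  in_set <- nrow(pairs) > 0 &
    (pairs[, 1] %in% proteins & pairs[, 2] %in% proteins)
  n_dropped <- sum(!in_set)
  edges <- unique(data.frame(from = pairs[in_set, 1], to = pairs[in_set, 2],
                             stringsAsFactors = FALSE))
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = proteins)
  g <- igraph::simplify(g)
  deg <- igraph::degree(g)
  comp <- igraph::components(g)
  membership <- comp$membership[deg >= 1]
  components <- split(names(membership), membership)
  components <- components[order(-vapply(components, length, 1L))]
  names(components) <- NULL
  n_connected <- sum(deg >= 1)
  structure(list(
    graph = g,
    nodes = proteins,
    edges = edges,
    components = components,
    singletons = names(deg)[deg == 0],
    degree = deg,
    n_connected = n_connected,
    fraction_connected = if (length(proteins)) n_connected / length(proteins) else 0,
    n_dropped_edges = n_dropped
  ), class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat("Protein interaction network\n")
  cat("  proteins:", length(x$nodes), " edges:", nrow(x$edges),
      " dropped edges:", x$n_dropped_edges, "\n")
  cat("  connected:", x$n_connected,
      sprintf("(%.1f%%)", 100 * x$fraction_connected),
      " components:", length(x$components), "\n")
  invisible(x)
}

#' Write network components as TSV
#'
#' One row per connected protein: `protein`, `component` (1 = largest),
#' `degree`.
#'
#' @param network an `interaction_graph`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_network_components <- function(network, path) {
  rows <- do.call(rbind, lapply(seq_along(network$components), function(i) {
    data.frame(protein = network$components[[i]], component = i)
  }))
  if (is.null(rows)) {
    rows <- data.frame(protein = character(), component = integer())
  }
  rows$degree <- as.integer(network$degree[rows$protein])
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
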