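# Patient similarity network construction.
#
# A `psn_network` stores nodes and an edge table (u, v, weight) with u < v
# lexicographically and rows sorted, so serializations are reproducible.

new_psn_network <- function(nodes, edges) {
  nodes <- sort(unique(as.character(nodes)))
  if (nrow(edges) > 0) {
    u <- pmin(edges$u, edges$v)
    v <- pmax(edges$u, edges$v)
    edges <- data.frame(u = u, v = v, weight = edges$weight,
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$u, edges$v), , drop = FALSE]
    rownames(edges) <- NULL
    stopifnot(all(edges$u != edges$v),
              all(edges$weight >= 0 & edges$weight <= 1))
  } else {
    edges <- data.frame(u = character(0), v = character(0),
                        weight = numeric(0), stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges), class = "psn_network")
}

#' @export
print.psn_network <- function(x, ...) {
  cat(sprintf("Patient similarity network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges) > 0) {
    cat(sprintf("  weight range: [%.3f, %.3f]\n",
                min(x$edges$weight), max(x$edges$weight)))
  }
  invisible(x)
}

#' Jaccard similarity of two symptom sets
#'
#' `|A intersect B| / |A union B|` over canonical term sets: 1 iff the two
#' patients share exactly the same phenotype, 0 iff they share nothing.
#' Both sets empty is an error — similarity is undefined and such patients
#' must be excluded upstream.
#'
#' @param a,b Character vectors (treated as sets).
#' @return A number in \[0, 1\].
#' @examples
#' jaccard(c("a", "b"), c("b", "c"))  # 1/3
#' @export
jaccard <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  if (length(a) == 0 && length(b) == 0) {
    stop_psn("psn_undefined_similarity",
             "Jaccard similarity of two empty sets is undefined")
  }
  length(intersect(a, b)) / length(union(a, b))
}

#' Build a single-field patient similarity network
#'
#' Computes all-pairs Jaccard similarity over one symptom field and keeps
#' edges with `weight >= min_weight` (inclusive threshold). Disjoint pairs
#' never form an edge, even at `min_weight = 0`: a zero-weight edge carries
#' no similarity information. Patients with an empty or missing field are
#' excluded from the node set.
#'
#' @param records Curated cohort data frame; one row per patient.
#' @param field `"main_symptoms"` or `"general_symptoms"`.
#' @param min_weight Similarity threshold in \[0, 1\].
#' @return A `psn_network`. Nodes are `patient_id`s; isolated eligible
#'   patients are kept as nodes here (isolates are only dropped at the
#'   overlap step).
#' @export
build_similarity_network <- function(records,
                                     field = c("main_symptoms",
                                               "general_symptoms"),
                                     min_weight) {
  field <- match.arg(field)
  stopifnot(min_weight >= 0, min_weight <= 1)
  sets <- lapply(records[[field]], as_term_set)
  eligible <- vapply(sets, has_terms, logical(1))
  ids <- records$patient_id[eligible]
  sets <- sets[eligible]
  if (length(ids) < 2) {
    warning("fewer than 2 eligible patients; returning an empty network")
    return(new_psn_network(ids, data.frame()))
  }
  # sparse patient x term incidence; intersections via tcrossprod
  vocab <- sort(unique(unlist(sets)))
  i <- rep(seq_along(sets), lengths(sets))
  j <- match(unlist(sets), vocab)
  x <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(length(sets), length(vocab)))
  inter <- Matrix::tcrossprod(x)
  sizes <- lengths(sets)
  trip <- as(as(inter, "generalMatrix"), "TsparseMatrix")
  keep_tri <- trip@i < trip@j
  ii <- trip@i[keep_tri] + 1L
  jj <- trip@j[keep_tri] + 1L
  ins <- trip@x[keep_tri]
  if (length(ii) > 0) {
    w <- ins / (sizes[ii] + sizes[jj] - ins)
    keep <- w >= min_weight & ins > 0
    edges <- data.frame(u = ids[ii[keep]], v = ids[jj[keep]],
                        weight = w[keep], stringsAsFactors = FALSE)
  } else {
    edges <- data.frame()
  }
  new_psn_network(ids, edges)
}

#' Overlap two similarity networks
#'
#' Keeps the intersection of the two edge sets; each surviving edge carries
#' the weight of the second (general-symptom) network. Nodes left with no
#' edges are dropped.
#'
#' @param main_psn,general_psn `psn_network`s over the same cohort.
#' @return A `psn_network`.
#' @export
overlap_networks <- function(main_psn, general_psn) {
  stopifnot(inherits(main_psn, "psn_network"),
            inherits(general_psn, "psn_network"))
  key_main <- paste(main_psn$edges$u, main_psn$edges$v, sep = "\r")
  key_gen <- paste(general_psn$edges$u, general_psn$edges$v, sep = "\r")
  kept <- general_psn$edges[key_gen %in% key_main, , drop = FALSE]
  if (nrow(kept) == 0) {
    warning("network overlap is empty")
    return(new_psn_network(character(0), data.frame()))
  }
  new_psn_network(unique(c(kept$u, kept$v)), kept)
}

#' Build the shared-symptom patient similarity network
#'
#' The three-step construction: (1) a chief-complaint (main-symptom) network
#' thresholded at `main_threshold`, keeping only pairs with nearly the same
#' predominant symptoms; (2) an unthresholded history-of-present-illness
#' (general-symptom) network; (3) their overlap, with the general-symptom
#' similarity as the edge weight. Patients that end up with no qualifying
#' edge drop out of the final network, so the node count can be well below
#' the cohort size.
#'
#' @param records Curated cohort data frame.
#' @param main_threshold Main-symptom similarity threshold (default 0.8,
#'   inclusive).
#' @return A `psn_network`.
#' @export
build_psn <- function(records, main_threshold = 0.8) {
  main <- build_similarity_network(records, "main_symptoms",
                                   min_weight = main_threshold)
  general <- build_similarity_network(records, "general_symptoms",
                                      min_weight = 0)
  overlap_networks(main, general)
}

#' Export / import a network as an edge list
#'
#' Plain 3-column whitespace-delimited text: `u v weight`, node ids written
#' verbatim, one edge per line (canonical order).
#'
#' @param network A `psn_network`.
#' @param path File path.
#' @return `path` (write) or a `psn_network` (read).
#' @export
write_psn_edgelist <- function(network, path) {
  e <- network$edges
  lines <- sprintf("%s %s %.17g", e$u, e$v, e$weight)
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

#' @rdname write_psn_edgelist
#' @export
read_psn_edgelist <- function(path) {
  if (!file.exists(path)) {
    stop_psn("psn_io_error", "edge list not found: %s", path)
  }
  d <- utils::read.table(path, header = FALSE, colClasses =
                           c("character", "character", "numeric"))
  names(d) <- c("u", "v", "weight")
  new_psn_network(unique(c(d$u, d$v)), d)
}

#' Convert between psn_network and igraph
#'
#' @param network A `psn_network`.
#' @return An undirected weighted [igraph::graph].
#' @export
as_igraph <- function(network) {
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = data.frame(
                                       name = network$nodes))
  g
}

#' @rdname as_igraph
#' @param graph An igraph object with a `weight` edge attribute.
#' @export
from_igraph <- function(graph) {
  e <- igraph::as_data_frame(graph, what = "edges")
  names(e)[1:2] <- c("u", "v")
  if (is.null(e$weight)) e$weight <- rep(1, nrow(e))
  new_psn_network(igraph::V(graph)$name, e[c("u", "v", "weight")])
}

#' Export / import a network as GraphML
#'
#' GraphML with a `weight` edge attribute, via igraph.
#'
#' @param network A `psn_network`.
#' @param path File path.
#' @return `path` (write) or a `psn_network` (read).
#' @export
write_psn_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}

#' @rdname write_psn_graphml
#' @export
read_psn_graphml <- function(path) {
  if (!file.exists(path)) {
    stop_psn("psn_io_error", "GraphML file not found: %s", path)
  }
  from_igraph(igraph::read_graph(path, format = "graphml"))
}
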