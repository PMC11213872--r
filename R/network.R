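#' Build a molecular network from MS2 spectra
#'
#' All spectrum pairs are scored with the modified cosine; an edge is kept
#' only when the score, the matched-fragment count and the fragment-
#' intensity coverage of the smaller spectrum all meet their thresholds.
#' Nodes without a qualifying edge remain in the network as singletons.
#'
#' @param spectra Non-empty list of `ms2_spectrum`.
#' @param min_score Minimum similarity score 0-100 (default 50).
#' @param min_fragments Minimum matched fragments (default 3).
#' @param min_coverage Minimum percent fragment-intensity coverage of the
#'   less intense spectrum (default 70).
#' @param frag_tol Fragment mass tolerance in Da (default 0.0025).
#' @return A `molecular_network`: list with `nodes` (data.frame `id`,
#'   `precursor_mz`, `component`), `edges` (data.frame `from`, `to`,
#'   `score`, `matches`, `coverage`, `mass_shift`), `graph` (igraph object)
#'   and the thresholds used.
#' @export
build_network <- function(spectra, min_score = 50, min_fragments = 3L,
                          min_coverage = 70, frag_tol = 0.0025) {
  stopifnot(length(spectra) > 0L)
  ids <- vapply(spectra, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("spectrum ids must be unique", call. = FALSE)
  prec <- vapply(spectra, `[[`, numeric(1), "precursor_mz")
  # canonical node order: by id, so the edge set is invariant to input order
  o <- order(ids)
  spectra <- spectra[o]; ids <- ids[o]; prec <- prec[o]

  n <- length(spectra)
  edges <- list()
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        sim <- suppressWarnings(
          spectral_similarity(spectra[[i]], spectra[[j]], frag_tol))
        if (sim$score >= min_score && sim$matches >= min_fragments &&
            sim$coverage >= min_coverage) {
          edges[[length(edges) + 1L]] <- data.frame(
            from = ids[i], to = ids[j], score = sim$score,
            matches = sim$matches, coverage = sim$coverage,
            mass_shift = prec[j] - prec[i], stringsAsFactors = FALSE)
        }
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(0), to = character(0), score = numeric(0),
               matches = integer(0), coverage = numeric(0),
               mass_shift = numeric(0), stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = ids, precursor_mz = prec))
  comp <- igraph::components(g)
  nodes <- data.frame(id = ids, precursor_mz = prec,
                      component = comp$membership[ids],
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, graph = g,
                 thresholds = list(min_score = min_score,
                                   min_fragments = min_fragments,
                                   min_coverage = min_coverage,
                                   frag_tol = frag_tol)),
            class = "molecular_network")
}

#' @export
print.molecular_network <- function(x, ...) {
  cat("<molecular_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges, ", length(unique(x$nodes$component)), " components\n",
      sep = "")
  invisible(x)
}

#' Label network nodes and edges with biotransformation candidates
#'
#' Nodes whose precursor m/z matches a candidate expected m/z within
#' `ppm_tol` get the candidate's product formula and chain as labels; edges
#' whose precursor mass shift matches a transformation delta mass (within
#' the absolute tolerance implied at the edge masses) are labelled with the
#' transformation name.
#'
#' @param network A `molecular_network`.
#' @param candidates From [enumerate_biotransformations()]; `NULL` leaves
#'   the network unchanged.
#' @param transformations Transformation set used for edge labels (default
#'   [default_transformations()]).
#' @param ppm_tol Node-matching tolerance in ppm (default 5).
#' @return The network with `annotation`/`chain` columns on nodes and a
#'   `transformation` column on edges.
#' @export
annotate_network_with_candidates <- function(network, candidates,
                                             transformations = default_transformations(),
                                             ppm_tol = 5) {
  network$nodes$annotation <- NA_character_
  network$nodes$chain <- NA_character_
  if (!is.null(candidates) && nrow(candidates) > 0L) {
    mz_cols <- grep("^mz_", names(candidates), value = TRUE)
    for (i in seq_len(nrow(network$nodes))) {
      pmz <- network$nodes$precursor_mz[i]
      for (col in mz_cols) {
        hit <- which(abs(ppm_error(pmz, candidates[[col]])) <= ppm_tol)
        if (length(hit) > 0L) {
          network$nodes$annotation[i] <- candidates$product_formula[hit[1L]]
          network$nodes$chain[i] <- candidates$chain[hit[1L]]
          break
        }
      }
    }
  }
  if (nrow(network$edges) > 0L) {
    dm <- vapply(transformations, function(tr) .delta_mass(tr$delta),
                 numeric(1))
    nm <- vapply(transformations, `[[`, character(1), "name")
    network$edges$transformation <- NA_character_
    for (e in seq_len(nrow(network$edges))) {
      shift <- abs(network$edges$mass_shift[e])
      tol <- 1e-6 * ppm_tol *
        max(abs(network$edges$mass_shift[e]), 200)
      hit <- which(abs(abs(dm) - shift) <= tol)
      if (length(hit) > 0L) network$edges$transformation[e] <- nm[hit[1L]]
    }
  }
  network
}

#' Export a molecular network
#'
#' Writes the edge list as CSV and the graph as GraphML.
#'
#' @param network A `molecular_network`.
#' @param stem Output path stem; writes `stem_edges.csv`, `stem_nodes.csv`
#'   and `stem.graphml`.
#' @return The stem, invisibly.
#' @export
write_network <- function(network, stem) {
  utils::write.csv(network$edges, paste0(stem, "_edges.csv"),
                   row.names = FALSE)
  utils::write.csv(network$nodes, paste0(stem, "_nodes.csv"),
                   row.names = FALSE)
  igraph::write_graph(network$graph, paste0(stem, ".graphml"),
                      format = "graphml")
  invisible(stem)
}
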