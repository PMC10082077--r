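#' Generate a typed metabolite-pathway knowledge graph with planted enrichment
#'
#' Builds a connected, undirected graph with typed nodes (`pathway`,
#' `reaction`, `compound`), structurally mimicking the pathway/reaction/
#' compound levels of a curated metabolic knowledge base. Each pathway owns a
#' block of reactions and compounds; consecutive pathways are connected
#' through dedicated bridge compounds so the graph is connected. The first
#' pathway is the planted enriched pathway: its (>= 3) exclusive compounds
#' are flagged as the input set that a diffusion enrichment should trace back
#' to it. The second pathway is a designated decoy whose compound set is
#' disjoint from the planted one.
#'
#' @param n_pathways number of pathways (>= 2).
#' @param n_compounds total non-bridge compounds distributed over pathways
#'   (>= 3 * n_pathways).
#' @param seed integer seed; fixed seed gives an identical edge list.
#' @return list with `graph` (an [igraph::graph] with vertex attributes
#'   `name` and `type`) and `truth` (a `ground_truth` list with
#'   `enriched_pathways`, `decoy_pathway`, `input_compounds`, and
#'   `pathway_compounds`).
#' @export
make_knowledge_graph <- function(n_pathways = 5, n_compounds = 30, seed = 1) {
  if (n_pathways < 2) stop("n_pathways must be >= 2")
  if (n_compounds < 3 * n_pathways) {
    stop("need at least 3 compounds per pathway")
  }
  g <- with_seed(seed, build_knowledge_graph(n_pathways, n_compounds))
  if (!igraph::is_connected(g$graph)) {
    stop("generated knowledge graph is disconnected")  # construction prevents this
  }
  g
}

build_knowledge_graph <- function(n_pathways, n_compounds) {
  pw <- sprintf("PW%02d", seq_len(n_pathways))
  # distribute compounds: every pathway gets >= 3 exclusive compounds
  extra <- n_compounds - 3 * n_pathways
  sizes <- 3 + as.vector(stats::rmultinom(1, extra, rep(1, n_pathways)))
  cid <- sprintf("C%04d", seq_len(n_compounds))
  owner <- rep(seq_len(n_pathways), sizes)
  pathway_compounds <- split(cid, owner)
  names(pathway_compounds) <- pw

  edges <- character(0)
  types <- c(stats::setNames(rep("pathway", n_pathways), pw),
             stats::setNames(rep("compound", n_compounds), cid))
  rid <- character(0)
  for (p in seq_len(n_pathways)) {
    cps <- pathway_compounds[[p]]
    n_rx <- max(2L, ceiling(length(cps) / 3))
    rx <- sprintf("R%02d_%02d", p, seq_len(n_rx))
    rid <- c(rid, rx)
    types[rx] <- "reaction"
    for (r in rx) edges <- c(edges, pw[p], r)
    # every compound attaches to >= 1 of its pathway's reactions
    assign_rx <- rx[1 + (seq_along(cps) - 1) %% n_rx]
    for (i in seq_along(cps)) edges <- c(edges, assign_rx[i], cps[i])
    # a few extra reaction-compound edges for realistic degree spread
    n_extra <- min(length(cps), n_rx)
    for (i in seq_len(n_extra)) {
      edges <- c(edges, sample(rx, 1), sample(cps, 1))
    }
  }
  # bridge compounds join consecutive pathways' first reactions
  for (p in seq_len(n_pathways - 1)) {
    br <- sprintf("CB%02d", p)
    types[br] <- "compound"
    edges <- c(edges, sprintf("R%02d_01", p), br, br, sprintf("R%02d_01", p + 1))
  }
  g <- igraph::make_graph(edges, directed = FALSE)
  g <- igraph::simplify(g)
  igraph::V(g)$type <- types[igraph::V(g)$name]
  igraph::E(g)$weight <- 1
  truth <- structure(list(enriched_pathways = pw[1],
                          decoy_pathway = pw[2],
                          input_compounds = pathway_compounds[[1]],
                          pathway_compounds = pathway_compounds),
                     class = "ground_truth")
  list(graph = g, truth = truth)
}

#' Write / read a knowledge graph as edge-list and node-type TSV files
#'
#' @param g an igraph knowledge graph with vertex attribute `type`.
#' @param edge_path path of the 3-column edge list
#'   (`source_id`, `target_id`, `edge_type`).
#' @param node_path path of the node-type table (`node_id`, `type`).
#' @return `write_knowledge_graph` returns the paths invisibly;
#'   `read_knowledge_graph` returns the igraph object.
#' @export
write_knowledge_graph <- function(g, edge_path, node_path) {
  el <- igraph::as_edgelist(g)
  ty <- stats::setNames(igraph::V(g)$type, igraph::V(g)$name)
  edge_type <- paste(ty[el[, 1]], ty[el[, 2]], sep = "-")
  utils::write.table(data.frame(source_id = el[, 1], target_id = el[, 2],
                                edge_type = edge_type),
                     edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(node_id = names(ty), type = unname(ty)),
                     node_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(edge_path, node_path))
}

#' @rdname write_knowledge_graph
#' @export
read_knowledge_graph <- function(edge_path, node_path) {
  el <- utils::read.delim(edge_path, stringsAsFactors = FALSE)
  nt <- utils::read.delim(node_path, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(el[, 1:2], directed = FALSE,
                                     vertices = nt)
  igraph::E(g)$weight <- 1
  igraph::V(g)$type <- nt$type[match(igraph::V(g)$name, nt$node_id)]
  g
}
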