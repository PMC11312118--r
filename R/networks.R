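# Typed ortholog/paralog networks, gene-of-interest (GOI) screening and the
# presence/absence matrix. Ortholog edges join genes of different species,
# paralog edges join genes of the same species; the connected components of
# the union graph are the homology networks.

#' Merge ortholog pairs and paralog edges into typed networks
#'
#' Builds the undirected union graph of BBH ortholog pairs and paralog edges
#' and computes its connected components. Components are numbered 1..k in
#' lexicographic order of their smallest member id, so the numbering is
#' reproducible.
#'
#' @param ortholog_pairs Data frame from \code{\link{bbh_orthologs}} /
#'   \code{\link{bbh_all_pairs}} (columns \code{gene_a}, \code{gene_b},
#'   \code{species_a}, \code{species_b}).
#' @param paralog_edges Data frame from \code{\link{paralog_edges}} (columns
#'   \code{gene_a}, \code{gene_b}, \code{species}).
#' @param species_of Optional named vector supplying species for genes (used
#'   to cross-check edge typing); defaults to the species columns carried by
#'   the edges.
#' @return A \code{homology_network}: list with \code{nodes} (data frame
#'   \code{gene_id}, \code{species}, \code{component}, \code{label}) and
#'   \code{edges} (\code{gene_a}, \code{gene_b}, \code{type},
#'   \code{component}).
#' @export
build_networks <- function(ortholog_pairs = NULL, paralog_edges = NULL,
                           species_of = NULL) {
  oe <- if (!is.null(ortholog_pairs) && nrow(ortholog_pairs)) {
    data.frame(gene_a = ortholog_pairs$gene_a, gene_b = ortholog_pairs$gene_b,
               species_a = ortholog_pairs$species_a,
               species_b = ortholog_pairs$species_b,
               type = "ortholog", stringsAsFactors = FALSE)
  }
  pe <- if (!is.null(paralog_edges) && nrow(paralog_edges)) {
    data.frame(gene_a = paralog_edges$gene_a, gene_b = paralog_edges$gene_b,
               species_a = paralog_edges$species, species_b = paralog_edges$species,
               type = "paralog", stringsAsFactors = FALSE)
  }
  edges <- rbind(oe, pe)
  if (is.null(edges) || !nrow(edges)) {
    return(structure(list(
      nodes = data.frame(gene_id = character(), species = character(),
                         component = integer(), label = character(),
                         stringsAsFactors = FALSE),
      edges = data.frame(gene_a = character(), gene_b = character(),
                         type = character(), component = integer(),
                         stringsAsFactors = FALSE)),
      class = "homology_network"))
  }
  if (!is.null(species_of)) {
    edges$species_a <- unname(species_of[edges$gene_a])
    edges$species_b <- unname(species_of[edges$gene_b])
  }
  bad <- (edges$type == "ortholog" & edges$species_a == edges$species_b) |
    (edges$type == "paralog" & edges$species_a != edges$species_b)
  if (any(bad))
    stopf("edge %s--%s violates the species rule for type '%s'",
          edges$gene_a[which(bad)[1]], edges$gene_b[which(bad)[1]],
          edges$type[which(bad)[1]])

  species_map <- stats::setNames(
    c(edges$species_a, edges$species_b), c(edges$gene_a, edges$gene_b))
  genes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  g <- igraph::graph_from_data_frame(edges[, c("gene_a", "gene_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = genes))
  comp <- igraph::components(g)$membership
  # renumber components by their lexicographically smallest member
  smallest <- tapply(names(comp), comp, min)
  new_id <- stats::setNames(rank(smallest), names(smallest))
  comp <- as.integer(new_id[as.character(comp)])
  names(comp) <- genes
  nodes <- data.frame(gene_id = genes,
                      species = unname(species_map[genes]),
                      component = unname(comp),
                      label = NA_character_, stringsAsFactors = FALSE)
  edges_out <- data.frame(gene_a = edges$gene_a, gene_b = edges$gene_b,
                          type = edges$type,
                          component = unname(comp[edges$gene_a]),
                          stringsAsFactors = FALSE)
  edges_out <- edges_out[order(edges_out$component, edges_out$type,
                               edges_out$gene_a, edges_out$gene_b), , drop = FALSE]
  rownames(edges_out) <- NULL
  structure(list(nodes = nodes, edges = edges_out), class = "homology_network")
}

#' @export
print.homology_network <- function(x, ...) {
  cat(sprintf("homology_network: %d genes, %d components, %d ortholog + %d paralog edges\n",
              nrow(x$nodes), length(unique(x$nodes$component)),
              sum(x$edges$type == "ortholog"), sum(x$edges$type == "paralog")))
  invisible(x)
}

#' Attach functional annotation labels to network nodes
#'
#' @param net A \code{homology_network}.
#' @param labels Named character vector, gene id to annotation string; genes
#'   without a label stay unlabeled.
#' @return The network with labels filled in where available.
#' @export
annotate_networks <- function(net, labels) {
  hit <- net$nodes$gene_id %in% names(labels)
  net$nodes$label[hit] <- unname(labels[net$nodes$gene_id[hit]])
  net
}

# parse "AT1G48980.1_ALKBH9B" (optionally followed by extra tokens after a
# space) into its GOI name: token before whitespace, suffix after last "_"
goi_from_query_id <- function(query_ids) {
  tok <- sub("\\s.*$", "", query_ids)
  sub("^.*_", "", tok)
}

#' Screen transcripts for genes of interest
#'
#' Assigns each transcript with at least one qualifying hit to the GOI
#' (writer/eraser) of its minimum-e-value query; ties broken by maximum
#' bitscore, then lexicographically smallest query id. One assignment per
#' transcript.
#'
#' @param query_hits A \code{\link{hit_table}} of query-vs-transcriptome
#'   hits: queries are GOI reference sequences, subjects are transcripts.
#' @param query_to_goi Named character vector mapping query id to GOI name;
#'   by default the name is parsed from the query id (suffix after the last
#'   underscore of its first token, e.g. \code{"AT1G48980.1_ALKBH9B"}).
#' @param evalue_cutoff Screening e-value cutoff (default 1e-5).
#' @return Data frame \code{transcript_id}, \code{species}, \code{goi_name},
#'   \code{best_query_id}, \code{evalue}, sorted by transcript.
#' @export
screen_goi <- function(query_hits, query_to_goi = NULL, evalue_cutoff = 1e-5) {
  h <- query_hits$hits
  if (is.null(query_to_goi)) {
    q <- unique(h$query_id)
    query_to_goi <- stats::setNames(goi_from_query_id(q), q)
  }
  unknown <- setdiff(unique(h$query_id), names(query_to_goi))
  if (length(unknown))
    stopf("query ids without a GOI mapping: %s", toString(unknown))
  bad <- setdiff(unique(query_to_goi), goi_vocabulary())
  if (length(bad))
    stopf("GOI names outside the writer/eraser vocabulary: %s", toString(bad))
  h <- h[h$evalue <= evalue_cutoff, , drop = FALSE]
  if (!nrow(h)) {
    return(data.frame(transcript_id = character(), species = character(),
                      goi_name = character(), best_query_id = character(),
                      evalue = numeric(), stringsAsFactors = FALSE))
  }
  o <- order(h$subject_id, h$evalue, -h$bitscore, h$query_id)
  h <- h[o, , drop = FALSE]
  h <- h[!duplicated(h$subject_id), , drop = FALSE]
  out <- data.frame(transcript_id = h$subject_id,
                    species = unname(query_hits$species_of[h$subject_id]),
                    goi_name = unname(query_to_goi[h$query_id]),
                    best_query_id = h$query_id, evalue = h$evalue,
                    stringsAsFactors = FALSE)
  out <- out[order(out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Networks containing at least one screened GOI
#'
#' Returns every component of the network with at least one assigned
#' transcript, tagged with the union of its members' GOI names; assigned
#' transcripts absent from the network are reported as singletons.
#'
#' @param net A \code{homology_network}.
#' @param assignments Data frame from \code{\link{screen_goi}}.
#' @return List with \code{components} (data frame \code{component},
#'   \code{n_members}, \code{gois}), \code{nodes} (node rows of those
#'   components with a \code{goi_name} column, NA for unassigned members)
#'   and \code{singletons} (assignments outside the network).
#' @export
goi_networks <- function(net, assignments) {
  goi_of <- stats::setNames(assignments$goi_name, assignments$transcript_id)
  in_net <- assignments$transcript_id %in% net$nodes$gene_id
  hit_comps <- sort(unique(
    net$nodes$component[net$nodes$gene_id %in% assignments$transcript_id]))
  nodes <- net$nodes[net$nodes$component %in% hit_comps, , drop = FALSE]
  nodes$goi_name <- unname(goi_of[nodes$gene_id])
  comps <- if (length(hit_comps)) {
    do.call(rbind, lapply(hit_comps, function(cc) {
      members <- nodes[nodes$component == cc, , drop = FALSE]
      data.frame(component = cc, n_members = nrow(members),
                 gois = paste(sort(unique(stats::na.omit(members$goi_name))),
                              collapse = ";"),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(component = integer(), n_members = integer(),
               gois = character(), stringsAsFactors = FALSE)
  }
  rownames(nodes) <- NULL
  list(components = comps, nodes = nodes,
       singletons = assignments[!in_net, , drop = FALSE])
}

#' Transcriptome presence/absence matrix of the GOIs
#'
#' @param assignments Data frame from \code{\link{screen_goi}} (or any data
#'   frame with \code{goi_name}, \code{species}, \code{transcript_id}).
#' @param species_roster Character vector of species (columns).
#' @param vocabulary GOI names (rows); all are emitted even when absent
#'   everywhere.
#' @return A \code{presence_matrix}: character matrix of
#'   \code{"present"}/\code{"absent"} with attribute \code{"evidence"}, a
#'   list of transcript ids per present cell (keyed \code{"goi|species"}).
#' @export
presence_matrix <- function(assignments, species_roster,
                            vocabulary = goi_vocabulary()) {
  if (!length(species_roster)) stopf("species roster must be non-empty")
  bad <- setdiff(unique(assignments$species), species_roster)
  if (length(bad)) stopf("assignments carry species outside the roster: %s",
                         toString(bad))
  m <- matrix("absent", length(vocabulary), length(species_roster),
              dimnames = list(vocabulary, species_roster))
  evidence <- list()
  if (nrow(assignments)) {
    keys <- split(assignments$transcript_id,
                  paste(assignments$goi_name, assignments$species, sep = "|"))
    for (k in names(keys)) {
      gs <- strsplit(k, "|", fixed = TRUE)[[1]]
      if (!gs[1] %in% vocabulary)
        stopf("GOI '%s' outside the vocabulary", gs[1])
      m[gs[1], gs[2]] <- "present"
      evidence[[k]] <- sort(unique(keys[[k]]))
    }
  }
  structure(m, evidence = evidence, class = c("presence_matrix", "matrix"))
}

#' @export
print.presence_matrix <- function(x, ...) {
  print(unclass(structure(x, evidence = NULL)))
  invisible(x)
}

# graph / matrix export -------------------------------------------------------

#' Export a homology network
#'
#' \code{write_network_edges} writes a 4-column edge TSV (gene_a, gene_b,
#' type, component); \code{write_network_graphml} writes GraphML with
#' species, component and label node attributes and an edge type attribute.
#'
#' @param net A \code{homology_network}.
#' @param path Output path.
#' @export
write_network_edges <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_edges
#' @export
write_network_graphml <- function(net, path) {
  v <- data.frame(name = net$nodes$gene_id, species = net$nodes$species,
                  component = net$nodes$component,
                  label = ifelse(is.na(net$nodes$label), "", net$nodes$label),
                  stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(net$edges[, c("gene_a", "gene_b", "type")],
                                     directed = FALSE, vertices = v)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a homology network back from GraphML
#' @param path GraphML path written by \code{\link{write_network_graphml}}.
#' @return A \code{homology_network}.
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  vd <- igraph::as_data_frame(g, what = "vertices")
  ed <- igraph::as_data_frame(g, what = "edges")
  nodes <- data.frame(gene_id = vd$name, species = vd$species,
                      component = as.integer(vd$component),
                      label = ifelse(nzchar(vd$label), vd$label, NA_character_),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$gene_id), , drop = FALSE]
  comp <- stats::setNames(nodes$component, nodes$gene_id)
  edges <- data.frame(gene_a = ed$from, gene_b = ed$to, type = ed$type,
                      component = unname(comp[ed$from]),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$component, edges$type, edges$gene_a, edges$gene_b), ,
                 drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "homology_network")
}

#' Write a presence or reconciled matrix to TSV
#' @param m A \code{presence_matrix} or \code{reconciled_matrix}.
#' @param path Output path.
#' @export
write_presence_matrix <- function(m, path) {
  d <- data.frame(goi = rownames(m), unclass(m), check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
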