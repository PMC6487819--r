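#' Driving-taxa co-occurrence subnetworks
#'
#' For each driving taxon, selects its `top_k` significant partners by
#' absolute co-occurrence score; the node set is the union of the driving
#' taxa and their partners, and edges are drawn among that set wherever
#' the pair is significant (`q < alpha`) and the absolute score reaches
#' `edge_threshold`. The sign of each score is kept as an edge attribute;
#' `positive_only = TRUE` restricts to positive associations (the usual
#' display convention for these community networks).
#'
#' The default `edge_threshold` is the 0.9 quantile of the absolute
#' significant scores — a score-scale-free stand-in for tool-specific
#' absolute cutoffs.
#'
#' @param cooc A [cooccurrence_network()] result.
#' @param driving Driving-taxon labels (must be in the matrix).
#' @param top_k Partners per driving taxon (default 20).
#' @param alpha Significance level on q-values.
#' @param edge_threshold Minimum absolute score for a displayed edge;
#'   `NULL` = 0.9 quantile of absolute significant scores.
#' @param positive_only Keep only positive-score edges.
#' @return An \pkg{igraph} undirected graph with node attribute `role`
#'   (`"driving"`/`"partner"`) and edge attributes `score`, `q`, `sign`.
#' @export
driving_subnetworks <- function(cooc, driving, top_k = 20, alpha = 0.05,
                                edge_threshold = NULL, positive_only = FALSE) {
  taxa <- rownames(cooc$score)
  missing <- setdiff(driving, taxa)
  if (length(missing)) stop("driving taxa absent from matrix: ",
                            paste(missing, collapse = ", "))
  sig <- !is.na(cooc$q) & cooc$q < alpha & !is.na(cooc$score)
  if (is.null(edge_threshold)) {
    vals <- abs(cooc$score[upper.tri(cooc$score)][sig[upper.tri(sig)]])
    edge_threshold <- if (length(vals)) stats::quantile(vals, 0.9, names = FALSE) else 0
  }
  partners <- character(0)
  for (dtx in driving) {
    ok <- sig[dtx, ] & taxa != dtx
    if (!any(ok)) next
    sc <- abs(cooc$score[dtx, ok])
    labs <- taxa[ok]
    ord <- order(-sc, labs)
    partners <- c(partners, labs[ord][seq_len(min(top_k, length(labs)))])
  }
  nodes <- unique(c(driving, partners))
  idx <- match(nodes, taxa)
  edges <- data.frame(from = character(0), to = character(0),
                      score = numeric(0), q = numeric(0))
  if (length(nodes) > 1) {
    comb <- utils::combn(seq_along(nodes), 2)
    i <- idx[comb[1, ]]; j <- idx[comb[2, ]]
    keep <- sig[cbind(i, j)] & abs(cooc$score[cbind(i, j)]) >= edge_threshold
    if (positive_only) keep <- keep & cooc$score[cbind(i, j)] > 0
    edges <- data.frame(from = taxa[i[keep]], to = taxa[j[keep]],
                        score = cooc$score[cbind(i, j)][keep],
                        q = cooc$q[cbind(i, j)][keep],
                        stringsAsFactors = FALSE)
  }
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = nodes,
                          role = ifelse(nodes %in% driving, "driving", "partner"),
                          stringsAsFactors = FALSE))
  if (igraph::ecount(g) > 0)
    igraph::E(g)$sign <- ifelse(igraph::E(g)$score >= 0, "positive", "negative")
  g
}

#' Export a taxa graph
#'
#' Writes the graph as GraphML and/or an edge-list TSV (`from`, `to`,
#' `score`, `q`, `sign`). GraphML round-trips through
#' `igraph::read_graph`.
#'
#' @param g An \pkg{igraph} graph from [driving_subnetworks()].
#' @param path Output path (extension replaced as needed).
#' @param format `"graphml"`, `"edgelist"` or `"both"`.
#' @return Invisibly, the paths written.
#' @export
export_graph <- function(g, path, format = c("graphml", "edgelist", "both")) {
  format <- match.arg(format)
  paths <- character(0)
  base <- sub("\\.(graphml|tsv|txt)$", "", path)
  if (format %in% c("graphml", "both")) {
    p <- paste0(base, ".graphml")
    igraph::write_graph(g, p, format = "graphml")
    paths <- c(paths, p)
  }
  if (format %in% c("edgelist", "both")) {
    p <- paste0(base, "_edges.tsv")
    el <- igraph::as_data_frame(g, what = "edges")
    utils::write.table(el, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
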