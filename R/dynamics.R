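#' Latent-state transition matrix
#'
#' Estimates the row-stochastic transition matrix over latent states from
#' encoded epoch sequences: `T[i,j] = count(i->j) / count(i->.)`, pooled
#' over the requested subjects. Adjacency is broken at subject boundaries
#' and at gaps in the epoch index (artifact exclusions): a transition is
#' only counted between consecutively recorded epochs of one subject. The
#' diagonal is retained — dominant self-loops are the expected structure of
#' 4-s epoch sequences.
#'
#' @param codes a `latent_codes` data frame (`subject_id`, `epoch_index`,
#'   `key`), or a list of integer key vectors (one uninterrupted sequence
#'   each)
#' @param subjects optional subset of subject ids to pool
#' @param states optional fixed state set (defaults to the observed keys)
#' @return a `transition_graph`: list with `T` (row-stochastic where a row
#'   has outgoing transitions), `counts`, `states`, `occupancy` (epoch count
#'   per state) and `layout` (`NULL` until [force_layout()] is run)
#' @export
transition_matrix <- function(codes, subjects = NULL, states = NULL) {
  if (is.data.frame(codes)) {
    df <- codes
    if (!is.null(subjects)) df <- df[df$subject_id %in% subjects, ]
    if (nrow(df) == 0) stop("empty-input: no epochs to pool")
    seqs <- split(df[, c("epoch_index", "key")], df$subject_id, drop = TRUE)
    seqs <- lapply(seqs, function(s) {
      s <- s[order(s$epoch_index), ]
      list(key = s$key, gap = c(TRUE, diff(s$epoch_index) != 1))
    })
  } else if (is.list(codes)) {
    if (length(codes) == 0) stop("empty-input: no sequences")
    seqs <- lapply(codes, function(k)
      list(key = as.integer(k), gap = c(TRUE, rep(FALSE, length(k) - 1))))
  } else {
    seqs <- list(list(key = as.integer(codes),
                      gap = c(TRUE, rep(FALSE, length(codes) - 1))))
  }
  allkeys <- unlist(lapply(seqs, `[[`, "key"))
  if (length(allkeys) == 0) stop("empty-input: no epochs")
  states <- states %||% sort(unique(allkeys))
  K <- length(states)
  counts <- matrix(0, K, K, dimnames = list(states, states))
  occupancy <- as.integer(table(factor(allkeys, levels = states)))
  for (s in seqs) {
    n <- length(s$key)
    if (n < 2) next
    from <- match(s$key[-n], states)
    to <- match(s$key[-1], states)
    ok <- !s$gap[-1] & !is.na(from) & !is.na(to)
    if (!any(ok)) next
    ij <- (from[ok] - 1L) * K + to[ok]
    counts <- counts + matrix(tabulate(ij, nbins = K * K), K, K,
                              byrow = TRUE)
  }
  out <- rowSums(counts)
  Tm <- counts / ifelse(out > 0, out, 1)
  structure(list(T = Tm, counts = counts, states = states,
                 occupancy = occupancy, layout = NULL),
            class = "transition_graph")
}

#' @export
print.transition_graph <- function(x, ...) {
  cat(sprintf("<transition_graph> %d states, %d observed transitions%s\n",
              length(x$states), sum(x$counts),
              if (is.null(x$layout)) "" else ", layout computed"))
  invisible(x)
}

#' Force-directed graph layout
#'
#' Positions the latent states in 2-D by a ForceAtlas2-style iteration:
#' nodes attract along edges proportionally to the transition probability
#' and to their distance, and repel each other with a force weighted by
#' their degrees, so hubs spread out and strongly coupled states cluster.
#' Self-loops exert no force. Deterministic given the seed.
#'
#' @param g a `transition_graph` (or a square weight matrix)
#' @param seed RNG seed for the random initial positions
#' @param iterations number of update sweeps
#' @param repulsion repulsion scaling constant
#' @return the graph with a `layout` matrix (columns `x`, `y`) attached;
#'   for a matrix input, the layout matrix itself
#' @export
force_layout <- function(g, seed = 1, iterations = 300, repulsion = 0.05) {
  W <- if (inherits(g, "transition_graph")) g$T else as.matrix(g)
  n <- nrow(W)
  if (n == 0) stop("empty-input: no states")
  A <- (W + t(W)) / 2
  diag(A) <- 0
  deg <- rowSums(A > 0) + 1
  set.seed(seed)
  pos <- matrix(runif(2 * n, -1, 1), n, 2)
  if (n == 1) pos <- matrix(0, 1, 2)
  for (it in seq_len(iterations)) {
    dx <- outer(pos[, 1], pos[, 1], "-")
    dy <- outer(pos[, 2], pos[, 2], "-")
    d2 <- dx * dx + dy * dy
    d <- sqrt(d2)
    d[d < 1e-6] <- 1e-6
    # attraction ~ w * distance (linear), repulsion ~ k (deg_i deg_j) / d
    fa <- A
    fr <- repulsion * outer(deg, deg) / d
    fx <- rowSums((fr / d - fa) * dx)
    fy <- rowSums((fr / d - fa) * dy)
    step <- 0.05 * (1 - it / iterations) + 0.005
    nrm <- sqrt(fx^2 + fy^2)
    nrm[nrm < 1e-12] <- 1
    sc <- pmin(nrm, step) / nrm
    pos[, 1] <- pos[, 1] + fx * sc
    pos[, 2] <- pos[, 2] + fy * sc
  }
  colnames(pos) <- c("x", "y")
  if (inherits(g, "transition_graph")) {
    rownames(pos) <- g$states
    g$layout <- pos
    g
  } else pos
}

graph_to_igraph <- function(g, roles = NULL, prune = 1e-4) {
  K <- length(g$states)
  idx <- which(g$T > 0, arr.ind = TRUE)
  el <- data.frame(from = as.character(g$states[idx[, 1]]),
                   to = as.character(g$states[idx[, 2]]),
                   weight = g$T[idx], stringsAsFactors = FALSE)
  el <- el[el$weight >= prune, , drop = FALSE]
  role <- if (is.null(roles)) rep(NA_character_, K) else
    roles[as.character(g$states)]
  el$source_role <- role[match(el$from, as.character(g$states))]
  vert <- data.frame(name = as.character(g$states),
                     count = g$occupancy,
                     in_degree = as.numeric(colSums(g$T * g$occupancy)),
                     role = unname(role), stringsAsFactors = FALSE)
  if (!is.null(g$layout)) {
    vert$x <- g$layout[, "x"]
    vert$y <- g$layout[, "y"]
  }
  igraph::graph_from_data_frame(el, directed = TRUE, vertices = vert)
}

#' Export a transition graph
#'
#' Writes the graph with node attributes (stage role, epoch count, weighted
#' in-degree `sum_i T[i,j] count(i)`, layout coordinates) and edge
#' attributes (transition probability, source-node role used as colour key)
#' to GEXF or GraphML. Edges with probability below `prune` are omitted
#' from the display file only, never from the matrix.
#'
#' @param g a `transition_graph`
#' @param path output path
#' @param format `"gexf"` or `"graphml"`
#' @param roles optional named character vector mapping state keys to roles
#'   (from a [build_catalog()] table)
#' @param prune display-only edge probability cutoff
#' @export
export_graph <- function(g, path, format = c("gexf", "graphml"),
                         roles = NULL, prune = 1e-4) {
  format <- match.arg(format)
  ig <- graph_to_igraph(g, roles = roles, prune = prune)
  if (format == "graphml") {
    igraph::write_graph(ig, path, format = "graphml")
    return(invisible(path))
  }
  doc <- xml2::xml_new_root("gexf", version = "1.2")
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "directed")
  atts <- xml2::xml_add_child(graph, "attributes", class = "node")
  for (a in list(c("0", "count", "integer"), c("1", "in_degree", "double"),
                 c("2", "role", "string"), c("3", "x", "double"),
                 c("4", "y", "double")))
    xml2::xml_add_child(atts, "attribute", id = a[1], title = a[2],
                        type = a[3])
  nodes <- xml2::xml_add_child(graph, "nodes")
  vdf <- igraph::as_data_frame(ig, "vertices")
  for (i in seq_len(nrow(vdf))) {
    nd <- xml2::xml_add_child(nodes, "node", id = vdf$name[i],
                              label = vdf$name[i])
    av <- xml2::xml_add_child(nd, "attvalues")
    xml2::xml_add_child(av, "attvalue", `for` = "0",
                        value = as.character(vdf$count[i]))
    xml2::xml_add_child(av, "attvalue", `for` = "1",
                        value = sprintf("%.17g", vdf$in_degree[i]))
    xml2::xml_add_child(av, "attvalue", `for` = "2",
                        value = as.character(vdf$role[i] %||% NA))
    if (!is.null(vdf$x)) {
      xml2::xml_add_child(av, "attvalue", `for` = "3",
                          value = sprintf("%.17g", vdf$x[i]))
      xml2::xml_add_child(av, "attvalue", `for` = "4",
                          value = sprintf("%.17g", vdf$y[i]))
    }
  }
  edges <- xml2::xml_add_child(graph, "edges")
  edf <- igraph::as_data_frame(ig, "edges")
  for (i in seq_len(nrow(edf))) {
    xml2::xml_add_child(edges, "edge", id = as.character(i - 1),
                        source = edf$from[i], target = edf$to[i],
                        weight = sprintf("%.17g", edf$weight[i]),
                        label = as.character(edf$source_role[i] %||% NA))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read back a GEXF transition-graph export
#'
#' Minimal reader for the files written by [export_graph()]; used to verify
#' round trips.
#'
#' @param path path to a GEXF file
#' @return list with `nodes` (data frame) and `edges` (data frame with
#'   `from`, `to`, `weight`)
#' @export
read_gexf <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_find_all(doc, ".//nodes/node")
  nodes <- data.frame(name = xml2::xml_attr(ns, "id"),
                      stringsAsFactors = FALSE)
  es <- xml2::xml_find_all(doc, ".//edges/edge")
  edges <- data.frame(from = xml2::xml_attr(es, "source"),
                      to = xml2::xml_attr(es, "target"),
                      weight = as.numeric(xml2::xml_attr(es, "weight")),
                      stringsAsFactors = FALSE)
  list(nodes = nodes, edges = edges)
}
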