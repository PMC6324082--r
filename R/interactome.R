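# Protein-protein interaction graph ingest and topological features.
#
# The two model features are degree (distinct neighbours) and bridgeness, a
# centrality that is high for nodes whose links span multiple overlapping
# network modules. Bridgeness is computed on the giant component only.

#' Read an interactome edge list
#'
#' Ingests a ComPPI-style TSV edge list: the first two columns are interactor
#' ids; any further columns (localization tags, interaction scores) are
#' carried as edge attributes but unused by the features. A header row is
#' auto-detected. The result is a simple undirected graph: self-loops and
#' duplicate edges are dropped, with counts reported via [message()].
#'
#' @param path Path to a TSV file, or a character vector of its lines.
#' @param quiet Suppress the dropped-row report.
#' @return An undirected simple [igraph::graph] object.
#' @export
read_edge_list <- function(path, quiet = FALSE) {
  lines <- if (length(path) == 1L && !grepl("\n|\t", path) && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else {
    as.character(path)
  }
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(igraph::make_empty_graph(directed = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 2L)
  if (length(short)) {
    stop("edge-list row with fewer than 2 columns at line ", short[1],
         call. = FALSE)
  }
  a <- vapply(parts, `[`, "", 1L)
  b <- vapply(parts, `[`, "", 2L)
  # header heuristic: first row repeated nowhere and labelled like a header
  if (grepl("interactor|protein|^source$", a[1], ignore.case = TRUE)) {
    a <- a[-1]; b <- b[-1]
  }
  if (!length(a)) return(igraph::make_empty_graph(directed = FALSE))
  loops <- a == b
  key <- ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
  dup <- duplicated(key) & !loops
  keep <- !loops & !dup
  if (!quiet && (any(loops) || any(dup))) {
    message(sprintf("read_edge_list: dropped %d self-loop(s) and %d duplicate edge(s)",
                    sum(loops), sum(dup)))
  }
  verts <- sort(unique(c(a, b)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = a[keep], to = b[keep], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = verts, stringsAsFactors = FALSE))
  g
}

#' Giant component of a graph
#'
#' Returns the vertex-induced subgraph of the largest connected component.
#' If several components tie for the largest size, the one containing the
#' lexicographically smallest vertex name wins.
#'
#' @param graph An undirected igraph object.
#' @return The giant-component subgraph.
#' @export
giant_component <- function(graph) {
  if (igraph::vcount(graph) == 0L) {
    stop("giant_component: graph is empty", call. = FALSE)
  }
  comp <- igraph::components(graph)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1L) {
    nm <- igraph::V(graph)$name
    firsts <- vapply(best, function(k) min(nm[comp$membership == k]), "")
    best <- best[order(firsts)[1]]
  }
  igraph::induced_subgraph(graph, which(comp$membership == best))
}

#' Degree of a node
#'
#' The number of distinct interactome neighbours. Self-loops never count
#' (they are removed at ingest).
#'
#' @param graph An igraph object.
#' @param node Vertex name(s); defaults to all vertices.
#' @return Named integer vector of degrees.
#' @export
node_degree <- function(graph, node = NULL) {
  if (is.null(node)) node <- igraph::V(graph)$name
  missing <- setdiff(node, igraph::V(graph)$name)
  if (length(missing)) {
    stop("unknown node(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  d <- igraph::degree(graph, v = node, loops = FALSE)
  stats::setNames(as.integer(d), node)
}

# Deterministic asynchronous label propagation. Nodes are visited in an order
# shuffled once per sweep from the seeded RNG stream; a node adopts the most
# frequent label among its neighbours, ties broken by smallest label.
.label_propagation <- function(graph, seed = 0, max_iter = 100L) {
  n <- igraph::vcount(graph)
  labels <- seq_len(n)
  adj <- igraph::as_adj_list(graph)
  rng <- .lcg_new(seed)
  for (iter in seq_len(max_iter)) {
    ord <- .lcg_shuffle(rng, n)
    changed <- FALSE
    for (v in ord) {
      nb <- as.integer(adj[[v]])
      if (!length(nb)) next
      tab <- table(labels[nb])
      top <- as.integer(names(tab)[tab == max(tab)])
      new <- min(top)
      if (new != labels[v]) { labels[v] <- new; changed <- TRUE }
    }
    if (!changed) break
  }
  match(labels, sort(unique(labels)))
}

#' Bridgeness centrality
#'
#' Quantifies how much a node's links span multiple overlapping network
#' modules: high for inter-module bridges (e.g. proteins connecting protein
#' mega-complexes), near zero for module-internal nodes. Modules are found by
#' seeded label propagation; each node then receives a membership weight
#' vector `p(m|v)` proportional to how many of `{v} U neighbours(v)` carry
#' module label `m`, and
#' \deqn{bridgeness(v) = 1 - \sum_m p(m|v)^2,}
#' the Gini-Simpson diversity of the membership vector, which lies in
#' `[0, 1)`. A single-module graph therefore yields bridgeness 0 everywhere.
#'
#' Absolute values are on this membership-diversity scale, not on the scale
#' of any external module-overlap tool; cutoffs calibrated on externally
#' computed bridgeness columns do not transfer to these values (see the
#' packaged model documentation).
#'
#' @param graph A connected igraph object (apply [giant_component()] first).
#' @param seed Integer seed for the label-propagation visit order.
#' @param membership Optional precomputed integer module assignment (one per
#'   vertex), bypassing label propagation.
#' @return Named numeric vector of bridgeness values in `[0, 1)`.
#' @export
bridgeness <- function(graph, seed = 0, membership = NULL) {
  if (igraph::vcount(graph) == 0L) {
    stop("bridgeness: graph is empty", call. = FALSE)
  }
  if (!igraph::is_connected(graph)) {
    stop("bridgeness requires a connected graph; apply giant_component() first",
         call. = FALSE)
  }
  if (is.null(membership)) {
    membership <- .label_propagation(graph, seed = seed)
  }
  adj <- igraph::as_adj_list(graph)
  n <- igraph::vcount(graph)
  out <- numeric(n)
  for (v in seq_len(n)) {
    labs <- c(membership[v], membership[as.integer(adj[[v]])])
    p <- as.numeric(table(labs)) / length(labs)
    out[v] <- 1 - sum(p^2)
  }
  stats::setNames(out, igraph::V(graph)$name)
}

#' Per-node topology table
#'
#' Degree for every node; bridgeness and giant-component membership flags.
#' Bridgeness is defined only on the giant component and is `NA` elsewhere —
#' downstream, an undefined bridgeness makes every bridgeness-based model
#' indicator evaluate to false.
#'
#' @param graph An igraph object.
#' @param seed Seed passed to [bridgeness()].
#' @return A data.frame with columns `protein_id`, `degree`, `bridgeness`,
#'   `in_giant_component`, one row per node, ordered by `protein_id`.
#' @export
topology_table <- function(graph, seed = 0) {
  nm <- igraph::V(graph)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(graph)))
  out <- data.frame(protein_id = nm,
                    degree = as.integer(igraph::degree(graph, loops = FALSE)),
                    bridgeness = NA_real_,
                    in_giant_component = FALSE,
                    stringsAsFactors = FALSE)
  if (igraph::vcount(graph) > 0L) {
    gc <- giant_component(graph)
    br <- bridgeness(gc, seed = seed)
    idx <- match(names(br), out$protein_id)
    out$bridgeness[idx] <- unname(br)
    out$in_giant_component[idx] <- TRUE
  }
  out[order(out$protein_id), , drop = FALSE]
}

#' Write a topology table
#'
#' @param topology Output of [topology_table()].
#' @param path Output TSV path.
#' @export
write_topology <- function(topology, path) {
  utils::write.table(topology, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a topology table
#'
#' @param path TSV written by [write_topology()] (or with the same columns).
#' @return data.frame with columns `protein_id`, `degree`, `bridgeness`,
#'   `in_giant_component`.
#' @export
read_topology <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "")
  df$degree <- as.integer(df$degree)
  df$bridgeness <- as.numeric(df$bridgeness)
  if (!is.null(df$in_giant_component)) {
    df$in_giant_component <- as.logical(df$in_giant_component)
  }
  df
}
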