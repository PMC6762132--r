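#' Mitochondrial network multigraph
#'
#' Both image-derived and simulated networks share one representation: an
#' undirected igraph multigraph whose edges are the minimal (indivisible)
#' unit segments of the organelle.  Self-loops and parallel edges are
#' permitted; a self-loop contributes 2 to its node's degree.  A graph
#' attribute `provenance` records whether nodes are skeleton pixels
#' (`"image"`), fused tip clusters (`"simulated"`), or synthetic toys.
#'
#' @param g an igraph object (undirected).
#' @param provenance character tag.
#' @return the igraph object with the `provenance` graph attribute set.
#' @export
as_mito_graph <- function(g, provenance = "unknown") {
  stopifnot(igraph::is_igraph(g))
  if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "each")
  g <- igraph::set_graph_attr(g, "provenance", provenance)
  g
}

#' Mean degree of a network
#'
#' The average number of nearest neighbours per node, `sum(degree)/V =
#' 2E/V`, computed over all nodes including any isolated (degree-0) nodes.
#'
#' @param graph a `MitoGraph` (igraph).
#' @return numeric mean degree.
#' @export
mean_degree <- function(graph) {
  if (igraph::vcount(graph) == 0) stop("graph has no nodes")
  mean(igraph::degree(graph, loops = TRUE))
}

#' Per-cluster edge counts
#'
#' Edge count of every connected component holding at least one edge
#' (isolated nodes are not clusters).
#'
#' @param graph a `MitoGraph`.
#' @return integer vector of cluster sizes in edges.
#' @export
cluster_sizes <- function(graph) {
  if (igraph::ecount(graph) == 0) return(integer(0))
  comp <- igraph::components(graph)$membership
  e1 <- igraph::ends(graph, igraph::E(graph), names = FALSE)[, 1]
  as.integer(table(factor(comp[e1], levels = sort(unique(comp[e1])))))
}

#' Giant cluster size and fraction
#'
#' @param graph a `MitoGraph` with at least one edge.
#' @return named numeric vector `c(giant_size, giant_frac)`: the edge count
#'   of the component with the most edges and its fraction of all edges.
#' @export
giant_cluster <- function(graph) {
  n <- igraph::ecount(graph)
  if (n == 0) stop("graph has no edges")
  sz <- cluster_sizes(graph)
  c(giant_size = max(sz), giant_frac = max(sz) / n)
}

#' Cluster size distribution
#'
#' @param graph a `MitoGraph` with at least one edge.
#' @return list with `sizes` (per-cluster edge counts) and `cumulative`, a
#'   data.frame of the cumulative probability `P(size <= s)` over clusters.
#' @export
cluster_size_distribution <- function(graph) {
  sz <- cluster_sizes(graph)
  if (length(sz) == 0) stop("graph has no edges")
  s <- sort(unique(sz))
  list(sizes = sz,
       cumulative = data.frame(size = s,
                               cum_prob = stats::ecdf(sz)(s)))
}

# ---------------------------------------------------------------------------
# chain collapsing: maximal runs of degree-2 nodes -> weighted super-edges

#' Collapse degree-2 chains into weighted super-edges
#'
#' Every maximal chain whose interior nodes have degree 2 becomes a single
#' super-edge weighted by the number of unit edges absorbed.  Components
#' that are pure cycles (every node degree 2) have no anchor to collapse
#' onto and are reported separately by their edge count.
#'
#' @param graph a `MitoGraph`.
#' @return list with `graph` (collapsed igraph; edge attribute `weight`,
#'   vertex attribute `orig_degree`), and `pure_cycles` (integer vector of
#'   edge counts of all-degree-2 cycle components).
#' @keywords internal
collapse_chains <- function(graph) {
  deg <- igraph::degree(graph, loops = TRUE)
  anchors <- which(deg != 2)
  m <- igraph::ecount(graph)
  visited <- logical(m)
  from <- to <- wt <- integer(0)

  ends_of <- igraph::ends(graph, seq_len(m), names = FALSE)
  inc <- igraph::incident_edges(graph, igraph::V(graph))

  other_end <- function(eid, v) {
    e <- ends_of[eid, ]
    if (e[1] == v) e[2] else e[1]
  }

  for (a in anchors) {
    for (e0 in as.integer(inc[[a]])) {
      if (visited[e0]) next
      # a self-loop at an anchor is a chain of length 1 back to itself
      cur <- a
      eid <- e0
      len <- 0L
      repeat {
        visited[eid] <- TRUE
        len <- len + 1L
        nxt <- other_end(eid, cur)
        if (deg[nxt] != 2L || ends_of[eid, 1] == ends_of[eid, 2]) {
          if (ends_of[eid, 1] == ends_of[eid, 2]) nxt <- cur
          from <- c(from, a); to <- c(to, nxt); wt <- c(wt, len)
          break
        }
        nxt_edges <- as.integer(inc[[nxt]])
        eid2 <- nxt_edges[nxt_edges != eid]
        if (length(eid2) == 0) {  # both endpoints of eid are nxt (loop)
          from <- c(from, a); to <- c(to, nxt); wt <- c(wt, len)
          break
        }
        cur <- nxt
        eid <- eid2[1]
      }
    }
  }

  # remaining unvisited edges live in pure-cycle components
  pure <- integer(0)
  if (any(!visited)) {
    comp <- igraph::components(graph)$membership
    left <- which(!visited)
    pure <- as.integer(table(comp[ends_of[left, 1]]))
  }

  ids <- sort(unique(c(anchors, from, to)))
  if (length(ids) == 0) {
    cg <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    el <- cbind(match(from, ids), match(to, ids))
    cg <- igraph::make_empty_graph(length(ids), directed = FALSE)
    if (nrow(el) > 0) cg <- igraph::add_edges(cg, t(el))
    igraph::E(cg)$weight <- wt
    igraph::V(cg)$orig_degree <- deg[ids]
  }
  list(graph = cg, pure_cycles = pure)
}

# ---------------------------------------------------------------------------
# minimum-weight cycle basis (Horton candidates + greedy GF(2) selection)

# XOR-reduce a logical incidence vector against a pivoted basis; returns
# NULL if dependent, else list(vec, pivot)
gf2_reduce <- function(v, basis) {
  for (b in basis) {
    if (v[b$pivot]) v <- xor(v, b$vec)
  }
  p <- which(v)[1]
  if (is.na(p)) NULL else list(vec = v, pivot = p)
}

# minimum-weight cycle basis weights of one connected multigraph component
min_cycle_basis_weights <- function(sg) {
  m <- igraph::ecount(sg)
  n <- igraph::vcount(sg)
  rank <- m - n + 1L
  if (rank <= 0) return(numeric(0))
  w <- igraph::E(sg)$weight
  ends_of <- igraph::ends(sg, seq_len(m), names = FALSE)
  is_loop <- ends_of[, 1] == ends_of[, 2]

  cand_sets <- list()
  cand_w <- numeric(0)
  add_cand <- function(eids) {
    eids <- sort(eids)
    key <- paste(eids, collapse = ",")
    if (is.null(cand_sets[[key]])) {
      cand_sets[[key]] <<- eids
      cand_w[key] <<- sum(w[eids])
    }
  }

  for (e in which(is_loop)) add_cand(e)

  pk <- paste(pmin(ends_of[, 1], ends_of[, 2]),
              pmax(ends_of[, 1], ends_of[, 2]))
  for (grp in split(which(!is_loop), pk[!is_loop])) {
    if (length(grp) >= 2) {
      for (i in seq_len(length(grp) - 1)) {
        for (j in seq(i + 1, length(grp))) add_cand(c(grp[i], grp[j]))
      }
    }
  }

  # Horton cycles: shortest-path trees on the loop-free graph
  igraph::E(sg)$.mcb_id <- seq_len(m)
  sg2 <- igraph::delete_edges(sg, which(is_loop))
  if (igraph::ecount(sg2) > 0) {
    id2 <- igraph::E(sg2)$.mcb_id
    for (v in seq_len(n)) {
      sp <- suppressWarnings(igraph::shortest_paths(
        sg2, from = v, to = igraph::V(sg2),
        weights = igraph::E(sg2)$weight, output = "epath"))
      ep <- lapply(sp$epath, function(p) id2[as.integer(p)])
      for (e in which(!is_loop)) {
        x <- ends_of[e, 1]; y <- ends_of[e, 2]
        px <- ep[[x]]; py <- ep[[y]]
        if (e %in% px || e %in% py) next
        if (length(intersect(px, py)) > 0) next
        add_cand(c(px, py, e))
      }
    }
  }

  ord <- order(cand_w)
  basis <- list()
  out <- numeric(0)
  for (k in ord) {
    eids <- cand_sets[[k]]
    v <- logical(m)
    v[eids] <- TRUE
    red <- gf2_reduce(v, basis)
    if (!is.null(red)) {
      basis[[length(basis) + 1]] <- red
      out <- c(out, unname(cand_w[k]))
      if (length(out) == rank) break
    }
  }
  if (length(out) != rank) {
    stop("internal error: cycle basis incomplete (", length(out),
         " of ", rank, ")")
  }
  out
}

#' Loop (cycle) sizes of a network
#'
#' A loop is a cycle with no open ends, sized in unit edges.  Degree-2
#' chains are collapsed into weighted super-edges and a minimum-weight
#' cycle basis is computed per component of the collapsed multigraph; each
#' basis cycle's total weight is one loop size.  A component that is a pure
#' cycle contributes its full edge count as a single loop.  The number of
#' loops always equals the graph's cycle rank `E - V + C`.
#'
#' @param graph a `MitoGraph`.
#' @return numeric vector of loop sizes (possibly empty), sorted.
#' @export
loop_sizes <- function(graph) {
  col <- collapse_chains(graph)
  out <- as.numeric(col$pure_cycles)
  cg <- col$graph
  if (igraph::ecount(cg) > 0) {
    for (sg in igraph::decompose(cg)) {
      out <- c(out, min_cycle_basis_weights(sg))
    }
  }
  sort(out)
}

#' Branch lengths of a network
#'
#' A branch is a maximal chain whose interior nodes have degree 2,
#' terminating at each end on a node of degree different from 2, with at
#' least one terminal of degree 1 (an open end).  Isolated cycles have no
#' branches; an isolated path is a single branch of its full length.
#'
#' @param graph a `MitoGraph`.
#' @return numeric vector of branch lengths in unit edges, sorted.
#' @export
branch_lengths <- function(graph) {
  col <- collapse_chains(graph)
  cg <- col$graph
  if (igraph::ecount(cg) == 0) return(numeric(0))
  ends_of <- igraph::ends(cg, igraph::E(cg), names = FALSE)
  odeg <- igraph::V(cg)$orig_degree
  open <- odeg[ends_of[, 1]] == 1 | odeg[ends_of[, 2]] == 1
  not_loop <- ends_of[, 1] != ends_of[, 2]
  sort(as.numeric(igraph::E(cg)$weight[open & not_loop]))
}

#' Full network statistics bundle
#'
#' Computes every summary reported for a mitochondrial network: edge count
#' `N`, mean degree, number of clusters (components with at least one edge),
#' average cluster size `N / n_clusters`, giant cluster size `N_g` and
#' fraction `N_g/N`, and the loop-size, branch-length and cluster-size
#' distributions.
#'
#' @param graph a `MitoGraph` with at least one edge.
#' @return an object of class `network_stats`.
#' @examples
#' g <- make_toy_graph(toy_graph_spec(list(
#'   list(kind = "path", size = 3), list(kind = "cycle", size = 4),
#'   list(kind = "isolated-edge", size = 1))))
#' network_stats(g)
#' @export
network_stats <- function(graph) {
  n <- igraph::ecount(graph)
  if (n == 0) stop("graph has no edges")
  sz <- cluster_sizes(graph)
  gc <- giant_cluster(graph)
  structure(
    list(n_edges = n,
         mean_degree = mean_degree(graph),
         n_clusters = length(sz),
         avg_cluster_size = n / length(sz),
         giant_size = unname(gc["giant_size"]),
         giant_frac = unname(gc["giant_frac"]),
         loop_sizes = loop_sizes(graph),
         branch_lengths = branch_lengths(graph),
         cluster_sizes = sz,
         provenance = igraph::graph_attr(graph, "provenance")),
    class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat("network statistics (", x$provenance, ")\n", sep = "")
  cat(sprintf("  N = %d edges   <k> = %.4f\n", x$n_edges, x$mean_degree))
  cat(sprintf("  clusters = %d (avg size %.2f)   N_g = %d   N_g/N = %.4f\n",
              x$n_clusters, x$avg_cluster_size,
              as.integer(x$giant_size), x$giant_frac))
  cat(sprintf("  loops: %d   branches: %d\n",
              length(x$loop_sizes), length(x$branch_lengths)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# skeleton -> pixel graph

#' Convert a labeled skeleton to a pixel graph
#'
#' One node per skeleton pixel; one edge per 8-adjacent pixel pair, after
#' removing redundant diagonal adjacencies: a diagonal edge is dropped when
#' its two pixels already share a 4-connected common neighbour (raw
#' 8-adjacency would otherwise create a spurious 3-cycle at every diagonal
#' step).  The component partition of the graph equals the label partition
#' of the skeleton.
#'
#' @param skeleton a logical matrix (skeleton mask), e.g. from
#'   [skeletonize()].
#' @return a `MitoGraph` with vertex attributes `row` and `col` (pixel
#'   coordinates, 1-based).
#' @export
skeleton_to_graph <- function(skeleton) {
  stopifnot(is.logical(skeleton), is.matrix(skeleton))
  nr <- nrow(skeleton); nc <- ncol(skeleton)
  idx <- which(skeleton)
  n <- length(idx)
  node_id <- integer(nr * nc)
  node_id[idx] <- seq_len(n)

  sh <- function(dr, dc) {
    # for each pixel (r, c) report whether (r+dr, c+dc) is foreground
    out <- matrix(FALSE, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    okr <- rs >= 1 & rs <= nr; okc <- cs >= 1 & cs <= nc
    out[okr, okc] <- skeleton[rs[okr], cs[okc]]
    out
  }

  edges <- matrix(integer(0), 0, 2)
  pair_ids <- function(sel, dr, dc) {
    p <- which(sel & skeleton)
    r <- ((p - 1) %% nr) + 1
    c <- ((p - 1) %/% nr) + 1
    q <- (c + dc - 1) * nr + (r + dr)
    cbind(node_id[p], node_id[q])
  }

  right <- sh(0, 1); down <- sh(1, 0)
  edges <- rbind(edges, pair_ids(right, 0, 1), pair_ids(down, 1, 0))

  # diagonal down-right: redundant if (r, c+1) or (r+1, c) is foreground
  dr_ok <- sh(1, 1) & !(right | down)
  edges <- rbind(edges, pair_ids(dr_ok, 1, 1))
  # diagonal down-left: redundant if (r, c-1) or (r+1, c) is foreground
  left <- sh(0, -1)
  dl_ok <- sh(1, -1) & !(left | down)
  edges <- rbind(edges, pair_ids(dl_ok, 1, -1))

  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  igraph::V(g)$row <- ((idx - 1) %% nr) + 1
  igraph::V(g)$col <- ((idx - 1) %/% nr) + 1
  as_mito_graph(g, provenance = "image")
}

# ---------------------------------------------------------------------------
# graph I/O

#' Write / read a network as GraphML
#'
#' Nodes carry their degree as an attribute; edges carry unit weight.
#'
#' @param graph a `MitoGraph`.
#' @param path file path.
#' @return `write_mito_graph` returns `path` invisibly; `read_mito_graph`
#'   returns the `MitoGraph`.
#' @export
write_mito_graph <- function(graph, path) {
  igraph::V(graph)$degree <- igraph::degree(graph, loops = TRUE)
  if (!"weight" %in% igraph::edge_attr_names(graph)) {
    igraph::E(graph)$weight <- 1
  }
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' @rdname write_mito_graph
#' @export
read_mito_graph <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  as_mito_graph(g, provenance = igraph::graph_attr(g, "provenance") %||%
                  "unknown")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export network statistics
#'
#' Writes scalar metrics as JSON and one-row-per-metric CSV, and the three
#' distributions as `(size, count)` CSVs plus a cumulative CSV for cluster
#' sizes.
#'
#' @param stats a [network_stats()] object.
#' @param dir output directory (created if missing).
#' @param prefix file name prefix.
#' @return invisibly, the vector of files written.
#' @export
write_network_stats <- function(stats, dir, prefix = "network") {
  stopifnot(inherits(stats, "network_stats"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  scalars <- list(n_edges = stats$n_edges, mean_degree = stats$mean_degree,
                  n_clusters = stats$n_clusters,
                  avg_cluster_size = stats$avg_cluster_size,
                  giant_size = stats$giant_size,
                  giant_frac = stats$giant_frac)
  fj <- file.path(dir, paste0(prefix, "_stats.json"))
  jsonlite::write_json(scalars, fj, auto_unbox = TRUE, digits = NA)
  fc <- file.path(dir, paste0(prefix, "_stats.csv"))
  utils::write.csv(data.frame(metric = names(scalars),
                              value = unlist(scalars)),
                   fc, row.names = FALSE)
  files <- c(fj, fc)
  for (nm in c("loop_sizes", "branch_lengths", "cluster_sizes")) {
    v <- stats[[nm]]
    f <- file.path(dir, paste0(prefix, "_", nm, ".csv"))
    tb <- as.data.frame(table(size = v), stringsAsFactors = FALSE)
    names(tb) <- c("size", "count")
    utils::write.csv(tb, f, row.names = FALSE)
    files <- c(files, f)
  }
  cum <- cluster_cumulative(stats$cluster_sizes)
  f <- file.path(dir, paste0(prefix, "_cluster_cumulative.csv"))
  utils::write.csv(cum, f, row.names = FALSE)
  invisible(c(files, f))
}

cluster_cumulative <- function(sizes) {
  s <- sort(unique(sizes))
  data.frame(size = s, cum_prob = stats::ecdf(sizes)(s))
}
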