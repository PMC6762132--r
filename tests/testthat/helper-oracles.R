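# Independent oracles and graph/image builders used across the suite.

cycle_rank <- function(g) {
  igraph::ecount(g) - igraph::vcount(g) + igraph::components(g)$no
}

per_component_ranks <- function(g) {
  sort(vapply(igraph::decompose(g), cycle_rank, numeric(1)))
}

# exhaustive minimum-weight cycle basis for tiny multigraphs: enumerate all
# edge subsets that are non-empty, connected and everywhere even-degree
# (i.e. edge-disjoint unions of cycles), keep the elementary ones, and pick
# a minimum-weight independent set greedily over GF(2)
enumerate_min_basis <- function(g, weights = rep(1, igraph::ecount(g))) {
  m <- igraph::ecount(g)
  rank <- cycle_rank(g)
  if (rank == 0) return(numeric(0))
  ends <- igraph::ends(g, seq_len(m), names = FALSE)
  cycles <- list(); w <- numeric(0)
  for (code in seq_len(2^m - 1)) {
    sel <- as.logical(bitwAnd(code, 2^(seq_len(m) - 1)))
    eids <- which(sel)
    vs <- c(ends[eids, 1], ends[eids, 2])
    degs <- table(vs)
    if (any(degs %% 2 != 0)) next
    sub <- igraph::subgraph_from_edges(g, eids, delete.vertices = TRUE)
    if (igraph::components(sub)$no != 1) next
    # elementary cycle: every vertex degree exactly 2
    if (any(igraph::degree(sub) != 2)) next
    cycles[[length(cycles) + 1]] <- eids
    w <- c(w, sum(weights[eids]))
  }
  ord <- order(w)
  basis <- list(); out <- numeric(0)
  for (k in ord) {
    v <- logical(m); v[cycles[[k]]] <- TRUE
    for (b in basis) if (v[b$pivot]) v <- xor(v, b$vec)
    p <- which(v)[1]
    if (!is.na(p)) {
      basis[[length(basis) + 1]] <- list(vec = v, pivot = p)
      out <- c(out, w[k])
      if (length(out) == rank) break
    }
  }
  sort(out)
}

# exhaustive Otsu: try every histogram cut point, minimize intra-class
# variance directly
brute_otsu <- function(x, levels = 256) {
  x <- as.vector(x)
  breaks <- seq(0, 1, length.out = levels + 1)
  bin <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L),
              levels)
  mids <- (breaks[-1] + breaks[-(levels + 1)]) / 2
  best <- Inf; best_k <- 1L
  for (k in seq_len(levels - 1)) {
    mlo <- mids[bin[bin <= k]]; mhi <- mids[bin[bin > k]]
    if (length(mlo) == 0 || length(mhi) == 0) next
    v <- (sum((mlo - mean(mlo))^2) + sum((mhi - mean(mhi))^2)) / length(x)
    if (v < best) { best <- v; best_k <- k }
  }
  breaks[best_k + 1]
}

# number of topological holes of a binary mask: 4-connected background
# components not touching the border
count_holes <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  bg <- which(!mask)
  if (length(bg) == 0) return(0L)
  id <- integer(nr * nc); id[bg] <- seq_along(bg)
  edges <- matrix(integer(0), 0, 2)
  add <- function(p, q) rbind(edges, cbind(id[p], id[q]))
  p <- bg[(bg - 1) %% nr + 1 < nr & !mask[bg + 1] & bg + 1 <= nr * nc]
  edges <- add(p, p + 1)
  p <- bg[bg + nr <= nr * nc]
  p <- p[!mask[p + nr]]
  edges <- add(p, p + nr)
  g <- igraph::make_empty_graph(length(bg), directed = FALSE)
  if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  r <- (bg - 1) %% nr + 1; c <- (bg - 1) %/% nr + 1
  border_comps <- unique(comp[r == 1 | r == nr | c == 1 | c == nc])
  length(setdiff(unique(comp), border_comps))
}

# 8-connected foreground component count of a mask
count_components_mask <- function(mask) {
  if (!any(mask)) return(0L)
  igraph::components(skeleton_to_graph(mask))$no
}

# expected statistics of a toy spec, in toy-edge units
toy_expected <- function(spec) {
  comps <- spec$components
  ranks <- integer(0); loops <- numeric(0); branches <- numeric(0)
  for (cp in comps) {
    ranks <- c(ranks, switch(cp$kind, cycle = 1L, theta = 2L, 0L))
    if (cp$kind == "cycle") loops <- c(loops, cp$size)
    if (cp$kind == "theta") {
      ch <- sort(mitonet:::theta_chains(cp$size))
      loops <- c(loops, ch[1] + ch[2], ch[1] + ch[3])
    }
    if (cp$kind == "path") branches <- c(branches, cp$size)
    if (cp$kind == "isolated-edge") branches <- c(branches, 1)
    if (cp$kind == "star") branches <- c(branches, rep(1, cp$size))
  }
  list(n_components = length(comps), ranks = sort(ranks),
       loops = sort(loops), branches = sort(branches),
       n_edges = sum(vapply(comps, `[[`, 1, "size")))
}

# seeded toy spec with renderable components
random_toy_spec <- function(seed) {
  set.seed(seed)
  n <- sample(2:4, 1)
  comps <- lapply(seq_len(n), function(i) {
    kind <- sample(c("path", "cycle", "star", "theta", "isolated-edge"), 1)
    size <- switch(kind,
                   path = sample(1:6, 1), cycle = sample(2:6, 1),
                   star = sample(1:8, 1), theta = sample(5:9, 1),
                   `isolated-edge` = 1L)
    list(kind = kind, size = size)
  })
  toy_graph_spec(comps, layout_seed = seed)
}

# lollipop: cycle of `loop` edges with a tail of `tail` edges
make_lollipop <- function(loop = 4, tail = 3) {
  g <- igraph::make_ring(loop)
  g <- igraph::add_vertices(g, tail)
  for (i in seq_len(tail)) {
    from <- if (i == 1) 1 else loop + i - 1
    g <- igraph::add_edges(g, c(from, loop + i))
  }
  as_mito_graph(g, "toy")
}
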