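#' Toy graph specification
#'
#' Describes a disjoint union of parametric components used to exercise the
#' whole pipeline with known ground truth.  Supported kinds: `"path"`
#' (size = edges in the chain), `"cycle"` (edges in the ring), `"star"`
#' (unit-edge arms), `"theta"` (two junctions joined by three chains whose
#' edge counts sum to size), `"isolated-edge"` (size must be 1).
#'
#' @param components list of `list(kind =, size =)` descriptors.
#' @param layout_seed integer seed controlling rendering layout and noise.
#' @return an object of class `toy_graph_spec`.
#' @export
toy_graph_spec <- function(components, layout_seed = 1L) {
  kinds <- c("path", "cycle", "star", "theta", "isolated-edge")
  comps <- lapply(components, function(cp) {
    if (is.null(cp$kind) || !cp$kind %in% kinds) {
      stop("unknown component kind: ", cp$kind %||% "<missing>")
    }
    size <- as.integer(cp$size %||% 1L)
    if (size < 1) stop("component size must be >= 1 edge")
    if (cp$kind == "isolated-edge" && size != 1) {
      stop("isolated-edge components have exactly 1 edge")
    }
    if (cp$kind == "theta" && size < 3) {
      stop("theta components need at least 3 edges")
    }
    list(kind = cp$kind, size = size)
  })
  structure(list(components = comps, layout_seed = as.integer(layout_seed)),
            class = "toy_graph_spec")
}

# split a theta's edge budget over its three chains; chains are made
# unequal whenever possible so the rectangular-arc layout stays collision
# free (see render_graph_to_image)
theta_chains <- function(size) {
  base <- size %/% 3L
  rem <- size %% 3L
  ch <- c(base, base, base)
  if (rem == 1L) {
    ch <- if (base >= 2L) c(base - 1L, base + 1L, base + 1L)
          else c(1L, 1L, 2L)
  }
  if (rem == 2L) ch <- c(base, base + 1L, base + 1L)
  if (rem == 0L && base >= 2L) ch <- c(base - 1L, base, base + 1L)
  sort(ch)
}

#' Build the multigraph described by a toy spec
#'
#' @param spec a [toy_graph_spec()].
#' @return a `MitoGraph`; vertices carry a `comp` attribute giving the
#'   1-based component index, and the graph stores the spec as attribute
#'   `toy_spec`.
#' @examples
#' g <- make_toy_graph(toy_graph_spec(list(list(kind = "path", size = 5))))
#' igraph::vcount(g)  # 6
#' @export
make_toy_graph <- function(spec) {
  stopifnot(inherits(spec, "toy_graph_spec"))
  parts <- lapply(seq_along(spec$components), function(i) {
    cp <- spec$components[[i]]
    g <- switch(cp$kind,
      "path" = igraph::make_ring(cp$size + 1, circular = FALSE),
      "isolated-edge" = igraph::make_ring(2, circular = FALSE),
      "cycle" = if (cp$size == 1) {
        igraph::make_graph(c(1, 1), directed = FALSE)
      } else if (cp$size == 2) {
        igraph::make_graph(c(1, 2, 1, 2), directed = FALSE)
      } else igraph::make_ring(cp$size),
      "star" = igraph::make_star(cp$size + 1, mode = "undirected"),
      "theta" = {
        ch <- theta_chains(cp$size)
        el <- integer(0)
        nxt <- 3L  # vertices 1, 2 are the junctions
        for (s in ch) {
          prev <- 1L
          if (s == 1L) {
            el <- c(el, 1L, 2L)
          } else {
            for (j in seq_len(s - 1L)) {
              el <- c(el, prev, nxt)
              prev <- nxt
              nxt <- nxt + 1L
            }
            el <- c(el, prev, 2L)
          }
        }
        igraph::make_graph(el, directed = FALSE)
      })
    igraph::V(g)$comp <- i
    g
  })
  g <- if (length(parts) == 0) {
    igraph::make_empty_graph(0, directed = FALSE)
  } else Reduce(igraph::disjoint_union, parts)
  g <- as_mito_graph(g, provenance = "toy")
  igraph::set_graph_attr(g, "toy_spec", spec)
}

#' Rendering parameters
#'
#' @param image_shape image size `c(rows, cols)` in pixels, or `NULL` to
#'   size the canvas automatically around the laid-out network.
#' @param stroke_width stroke thickness in pixels, `>= 1`.
#' @param fg,bg foreground and background intensity levels in `[0, 1]`;
#'   `fg` must exceed `bg`.
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @param blur_sigma Gaussian blur sigma in pixels (0 = none).
#' @param edge_px rendered pixel length of one toy edge; loop and branch
#'   sizes measured on the rendering are this multiple of the toy sizes.
#'   Must be even (default 8).
#' @return an object of class `render_params`.
#' @export
render_params <- function(image_shape = NULL, stroke_width = 1, fg = 0.9,
                          bg = 0.05, noise_sd = 0, blur_sigma = 0,
                          edge_px = 8) {
  stopifnot(stroke_width >= 1, fg > bg, fg <= 1, bg >= 0,
            noise_sd >= 0, blur_sigma >= 0, edge_px >= 2,
            edge_px %% 2 == 0)
  structure(list(image_shape = image_shape,
                 stroke_width = as.integer(stroke_width),
                 fg = fg, bg = bg, noise_sd = noise_sd,
                 blur_sigma = blur_sigma, edge_px = as.integer(edge_px)),
            class = "render_params")
}

# run code under a temporary RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# ---------------------------------------------------------------------------
# pixel-path routers: each returns a list of integer (x, y) step matrices;
# consecutive points are 8-adjacent.  x = column, y = row (up positive);
# converted to matrix indices at rasterization.

moves_to_path <- function(start, moves) {
  # moves: two-column matrix of unit steps, each row repeated `times`
  pts <- matrix(0L, nrow = sum(moves[, 3]) + 1L, ncol = 2)
  pts[1, ] <- start
  k <- 1L
  for (i in seq_len(nrow(moves))) {
    for (j in seq_len(moves[i, 3])) {
      pts[k + 1L, ] <- pts[k, ] + moves[i, 1:2]
      k <- k + 1L
    }
  }
  pts
}

mv <- function(dx, dy, times) c(dx, dy, times)

route_path <- function(size, e) {
  list(moves_to_path(c(0L, 0L), rbind(mv(1, 0, size * e))))
}

route_cycle <- function(size, e, sw = 1L) {
  per <- size * e
  # the dilated stroke must not fill the hole: both sides >= sw + 1
  if (per < 4L * (sw + 1L)) {
    stop("layout failure: cycle component of ", size, " edge(s) is too ",
         "small to keep its hole at stroke width ", sw)
  }
  w <- max(sw + 1L, per %/% 4L)
  h <- per %/% 2L - w
  if (h < sw + 1L) { h <- sw + 1L; w <- per %/% 2L - h }
  list(moves_to_path(c(0L, 0L),
                     rbind(mv(1, 0, w), mv(0, 1, h), mv(-1, 0, w),
                           mv(0, -1, h))))
}

route_star <- function(size, e, sw = 1L) {
  if (size > 8) {
    stop("layout failure: star component with more than 8 arms ",
         "cannot be rendered without merging")
  }
  arm <- function(x0, dx, dy) {
    moves_to_path(c(x0, 0L), rbind(mv(dx, dy, e)))
  }
  if (size <= 4) {
    dirs <- list(c(1, 0), c(0, 1), c(-1, 0), c(0, -1))
    return(lapply(seq_len(size),
                  function(i) arm(0L, dirs[[i]][1], dirs[[i]][2])))
  }
  # 5-8 arms: a short horizontal junction bar hosts the extra arms; this
  # preserves branch and loop statistics (the bar is a closed chain).
  # parallel arms sit 2*sw apart so dilated strokes stay separated
  gap <- 2L * sw
  far <- if (size <= 6) gap else 2L * gap
  bar <- list(moves_to_path(c(0L, 0L), rbind(mv(1, 0, far))))
  slots <- list(c(0L, -1L, 0L), c(far, 1L, 0L), c(0L, 0L, 1L),
                c(far, 0L, 1L), c(0L, 0L, -1L), c(far, 0L, -1L),
                c(gap, 0L, 1L), c(gap, 0L, -1L))
  arms <- lapply(seq_len(size), function(i) {
    s <- slots[[i]]
    arm(s[1], s[2], s[3])
  })
  c(bar, arms)
}

route_theta <- function(size, e, sw = 1L) {
  ch <- theta_chains(size)
  if (ch[1] == ch[2]) {
    stop("layout failure: theta component of size ", size,
         " has two equal shortest chains and cannot be drawn with ",
         "disjoint rectangular arcs")
  }
  D <- ch[1] * e
  arc <- function(s, sign) {
    v <- (s * e - D) %/% 2L
    if (v - (sw - 1L) < 2L) {
      stop("layout failure: theta component of size ", size,
           " has chains too close for stroke width ", sw)
    }
    moves_to_path(c(0L, 0L),
                  rbind(mv(0, sign, v), mv(1, 0, D), mv(0, -sign, v)))
  }
  list(moves_to_path(c(0L, 0L), rbind(mv(1, 0, D))),  # straight chain
       arc(ch[2], -1L), arc(ch[3], 1L))
}

route_component <- function(kind, size, e, sw = 1L) {
  switch(kind,
         "path" = route_path(size, e),
         "isolated-edge" = route_path(1L, e),
         "cycle" = route_cycle(size, e, sw),
         "star" = route_star(size, e, sw),
         "theta" = route_theta(size, e, sw),
         stop("unknown component kind: ", kind))
}

# generic router for arbitrary components (e.g. simulated networks):
# seeded planar-ish layout, straight strokes, verified by re-extraction
route_generic <- function(sg, e, tries = 8) {
  n <- igraph::vcount(sg)
  target_rank <- igraph::ecount(sg) - n + 1L
  for (t in seq_len(tries)) {
    xy <- igraph::layout_with_fr(sg, niter = 200 + 50 * t)
    xy <- xy - matrix(apply(xy, 2, min), n, 2, byrow = TRUE)
    span <- max(apply(xy, 2, max), 1e-6)
    xy <- round(xy / span * max(e * sqrt(n) * 1.5, 3 * e))
    paths <- list()
    seen <- character(0)
    ok <- TRUE
    es <- igraph::ends(sg, igraph::E(sg), names = FALSE)
    for (i in seq_len(nrow(es))) {
      a <- es[i, 1]; b <- es[i, 2]
      if (a == b) {  # self-loop: small square hung on the node
        p <- moves_to_path(c(xy[a, 1], xy[a, 2]),
                           rbind(mv(1, 0, 3), mv(0, 1, 3), mv(-1, 0, 3),
                                 mv(0, -1, 3)))
      } else {
        key <- paste(min(a, b), max(a, b))
        bend <- sum(seen == key)  # parallel edges get bent midpoints
        seen <- c(seen, key)
        p <- bresenham_poly(xy[a, ], xy[b, ], bend)
      }
      paths[[length(paths) + 1]] <- p
    }
    mask <- rasterize_paths(paths)
    g2 <- skeleton_to_graph(mask)
    comp2 <- igraph::components(g2)
    rank2 <- igraph::ecount(g2) - igraph::vcount(g2) + comp2$no
    if (comp2$no == 1 && rank2 == target_rank) return(paths)
  }
  stop("layout failure: could not place a simulated component of ",
       n, " nodes without changing its topology")
}

# 8-connected line, optionally bent through a perpendicular midpoint offset
bresenham_poly <- function(p0, p1, bend = 0) {
  if (bend == 0) return(bresenham(p0, p1))
  mid <- round((p0 + p1) / 2)
  d <- p1 - p0
  perp <- c(-sign(d[2]), sign(d[1]))
  if (all(perp == 0)) perp <- c(0, 1)
  off <- mid + perp * (2 + 2 * bend)
  rbind(bresenham(p0, off), bresenham(off, p1)[-1, , drop = FALSE])
}

bresenham <- function(p0, p1) {
  dx <- abs(p1[1] - p0[1]); dy <- abs(p1[2] - p0[2])
  n <- max(dx, dy)
  if (n == 0) return(matrix(p0, 1, 2))
  xs <- round(seq(p0[1], p1[1], length.out = n + 1))
  ys <- round(seq(p0[2], p1[2], length.out = n + 1))
  cbind(as.integer(xs), as.integer(ys))
}

rasterize_paths <- function(paths, pad = 1L) {
  pts <- do.call(rbind, paths)
  xr <- range(pts[, 1]); yr <- range(pts[, 2])
  nr <- diff(yr) + 1L + 2L * pad
  nc <- diff(xr) + 1L + 2L * pad
  m <- matrix(FALSE, nr, nc)
  r <- nr - (pts[, 2] - yr[1] + pad)       # flip y so "up" is up
  c <- pts[, 1] - xr[1] + 1L + pad
  m[cbind(r, c)] <- TRUE
  m
}

#' Render a graph into a synthetic micrograph
#'
#' Lays each connected component out on a collision-free grid (with
#' seeded jitter), draws every edge chain as an 8-connected one-pixel
#' stroke, dilates to `stroke_width`, and applies noise and blur last.
#' Toy components (from [make_toy_graph()]) use exact routers so that one
#' toy edge maps to `edge_px` pixel steps; other graphs (e.g. simulated
#' networks) are laid out with a seeded force-directed embedding and
#' verified by re-extraction, with retries.  Component topology (component
#' count and per-component cycle rank) is preserved in the clean rendering.
#'
#' @param graph a `MitoGraph`; if built by [make_toy_graph()] the exact
#'   per-kind routers are used.
#' @param params a [render_params()] object.
#' @param layout_seed integer; the rendering (layout jitter and noise) is
#'   deterministic given this seed.
#' @return numeric intensity matrix in `[0, 1]` with attributes
#'   `stroke_mask` (logical, the dilated clean stroke mask),
#'   `thin_mask` (the pre-dilation centrelines) and `edge_px`.
#' @export
render_graph_to_image <- function(graph, params = render_params(),
                                  layout_seed = 1L) {
  stopifnot(inherits(params, "render_params"))
  e <- params$edge_px
  spec <- igraph::graph_attr(graph, "toy_spec")

  with_seed(layout_seed, {
    comp_paths <- list()
    if (!is.null(spec)) {
      for (cp in spec$components) {
        comp_paths[[length(comp_paths) + 1]] <-
          route_component(cp$kind, cp$size, e, params$stroke_width)
      }
    } else {
      if (igraph::vcount(graph) > 0) {
        for (sg in igraph::decompose(graph)) {
          if (igraph::ecount(sg) == 0) next  # isolated nodes: not drawn
          comp_paths[[length(comp_paths) + 1]] <- route_generic(sg, e)
        }
      }
    }

    sep <- params$stroke_width + 4L
    placed <- place_components(comp_paths, sep, jitter = 2L)
    mask <- if (length(placed) == 0) {
      shp <- params$image_shape %||% c(64L, 64L)
      matrix(FALSE, shp[1], shp[2])
    } else {
      rasterize_paths(placed, pad = sep)
    }

    if (!is.null(params$image_shape)) {
      shp <- params$image_shape
      if (nrow(mask) > shp[1] || ncol(mask) > shp[2]) {
        stop("layout failure: network does not fit the requested ",
             shp[1], "x", shp[2], " image")
      }
      big <- matrix(FALSE, shp[1], shp[2])
      r0 <- (shp[1] - nrow(mask)) %/% 2
      c0 <- (shp[2] - ncol(mask)) %/% 2
      big[r0 + seq_len(nrow(mask)), c0 + seq_len(ncol(mask))] <- mask
      mask <- big
    }

    thin <- mask
    if (params$stroke_width > 1) mask <- dilate_square(mask,
                                                       params$stroke_width)
    img <- matrix(params$bg, nrow(mask), ncol(mask))
    img[mask] <- params$fg
    if (params$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(length(img), 0, params$noise_sd),
                          nrow(img))
    }
    if (params$blur_sigma > 0) img <- gaussian_blur(img, params$blur_sigma)
    img <- pmin(pmax(img, 0), 1)
    attr(img, "stroke_mask") <- mask
    attr(img, "thin_mask") <- thin
    attr(img, "edge_px") <- e
    img
  })
}

# shelf-pack component paths left to right with jittered offsets
place_components <- function(comp_paths, sep, jitter = 0L) {
  out <- list()
  x_cursor <- 0L
  y_cursor <- 0L
  row_h <- 0L
  row_w_max <- 0L
  total <- length(comp_paths)
  per_row <- max(1L, ceiling(sqrt(total)))
  for (i in seq_along(comp_paths)) {
    paths <- comp_paths[[i]]
    pts <- do.call(rbind, paths)
    xr <- range(pts[, 1]); yr <- range(pts[, 2])
    w <- diff(xr) + 1L; h <- diff(yr) + 1L
    jx <- if (jitter > 0) sample.int(2L * jitter + 1L, 1L) - jitter - 1L
          else 0L
    jy <- if (jitter > 0) sample.int(2L * jitter + 1L, 1L) - jitter - 1L
          else 0L
    dx <- x_cursor - xr[1] + abs(jx)
    dy <- y_cursor - yr[1] + abs(jy)
    for (p in paths) {
      p[, 1] <- p[, 1] + dx
      p[, 2] <- p[, 2] + dy
      out[[length(out) + 1]] <- p
    }
    x_cursor <- x_cursor + w + sep + 2L * jitter
    row_h <- max(row_h, h + 2L * jitter)
    if (i %% per_row == 0) {
      row_w_max <- max(row_w_max, x_cursor)
      x_cursor <- 0L
      y_cursor <- y_cursor + row_h + sep
      row_h <- 0L
    }
  }
  out
}

dilate_square <- function(mask, w) {
  lo <- -((w - 1L) %/% 2L); hi <- w %/% 2L
  out <- mask
  nr <- nrow(mask); nc <- ncol(mask)
  for (dr in lo:hi) for (dc in lo:hi) {
    if (dr == 0 && dc == 0) next
    rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
    okr <- rs >= 1 & rs <= nr; okc <- cs >= 1 & cs <= nc
    out[okr, okc] <- out[okr, okc] | mask[rs[okr], cs[okc]]
  }
  out
}

gaussian_blur <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  conv1 <- function(m, k) {
    # replicate-padded 1-D convolution along rows
    r <- (length(k) - 1L) %/% 2L
    pad <- m[c(rep(1, r), seq_len(nrow(m)), rep(nrow(m), r)), , drop = FALSE]
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k)) {
      out <- out + k[i] * pad[i:(i + nrow(m) - 1L), , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(img, k)), k))
}

#' Overlay legend boxes and extra fluorescence channels
#'
#' Emulates the artifacts that published micrographs carry: a bright
#' legend/scale-bar box, and a distinctly coloured non-mitochondrial
#' structure (e.g. a nuclear stain) on a separate channel.  Pixels outside
#' the requested artifacts are unchanged.
#'
#' @param image grayscale matrix (treated as the mitochondrial channel).
#' @param legend optional `list(row, col, height, width, intensity = 1)`.
#' @param extra_channel optional `list(row, col, radius, intensity = 1)`:
#'   a bright disc added on the red channel; the output becomes an RGB
#'   array with the mitochondrial signal on the green (and gray) channels.
#' @return matrix (legend only) or RGB array (when `extra_channel` given).
#' @export
add_artifacts <- function(image, legend = NULL, extra_channel = NULL) {
  if (!is.null(legend)) {
    inten <- legend$intensity %||% 1
    image <- apply_region(image, legend, value = inten)
  }
  if (is.null(extra_channel)) return(image)
  nr <- nrow(image); nc <- ncol(image)
  blob <- matrix(0, nr, nc)
  rr <- outer(seq_len(nr) - extra_channel$row, rep(1, nc))
  cc <- outer(rep(1, nr), seq_len(nc) - extra_channel$col)
  blob[rr^2 + cc^2 <= extra_channel$radius^2] <-
    extra_channel$intensity %||% 1
  out <- array(0, dim = c(nr, nc, 3))
  out[, , 1] <- pmax(image, blob)   # red: blob over background
  out[, , 2] <- image               # green: mitochondria, untouched
  out[, , 3] <- image * 0
  out
}

#' Write a synthetic micrograph with its ground truth
#'
#' Renders the toy graph, writes the image (PNG and TIFF), the ground-truth
#' graph as GraphML, and a JSON sidecar with the spec and seeds.
#'
#' @param spec a [toy_graph_spec()].
#' @param dir output directory.
#' @param params a [render_params()].
#' @param name file name stem.
#' @return invisibly, the list of files written.
#' @export
write_synthetic <- function(spec, dir, params = render_params(),
                            name = "synthetic") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  g <- make_toy_graph(spec)
  img <- render_graph_to_image(g, params, layout_seed = spec$layout_seed)
  fp <- file.path(dir, paste0(name, ".png"))
  ft <- file.path(dir, paste0(name, ".tiff"))
  write_micrograph(unclass_img(img), fp)
  write_micrograph(unclass_img(img), ft)
  fg <- file.path(dir, paste0(name, ".graphml"))
  write_mito_graph(g, fg)
  fj <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(
    list(components = spec$components, layout_seed = spec$layout_seed,
         edge_px = params$edge_px, stroke_width = params$stroke_width),
    fj, auto_unbox = TRUE)
  invisible(c(fp, ft, fg, fj))
}

unclass_img <- function(img) {
  attributes(img) <- attributes(img)["dim"]
  img
}

#' Convert pixel-measured sizes back to toy edge units
#'
#' A rendered toy edge spans `edge_px` pixel steps, so loop sizes and
#' branch lengths measured on the pixel graph are divided by `edge_px` and
#' rounded (minimum 1) to recover the toy-graph sizes.
#'
#' @param px numeric vector of sizes in pixel-graph edges.
#' @param edge_px pixels per toy edge (see [render_params()]).
#' @return numeric vector in toy-edge units.
#' @export
pixels_to_edges <- function(px, edge_px) {
  if (length(px) == 0) return(numeric(0))
  pmax(1, round(px / edge_px))
}
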