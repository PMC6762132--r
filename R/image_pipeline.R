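#' Read a micrograph from PNG or TIFF
#'
#' Intensities are normalized to `[0, 1]` regardless of bit depth; a
#' multi-channel image is returned as a 3-D array (rows, cols, channels).
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return numeric matrix (grayscale) or 3-D array (multi-channel).
#' @export
read_micrograph <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext))
  img <- pmin(pmax(img, 0), 1)
  if (length(dim(img)) == 3 && dim(img)[3] == 1) img <- img[, , 1]
  img
}

#' Write a micrograph to PNG or TIFF
#' @param image numeric matrix or array with intensities in `[0, 1]`.
#' @param path output path; the extension selects the format.
#' @param bits bit depth (8 or 16).
#' @return `path`, invisibly.
#' @export
write_micrograph <- function(image, path, bits = 8) {
  image <- pmin(pmax(image, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(image, path),
    tif = ,
    tiff = tiff::writeTIFF(image, path, bits.per.sample = bits),
    stop("unsupported image format: .", ext))
  invisible(path)
}

#' Mask artifacts and select the mitochondrial channel
#'
#' Published micrographs often carry legends, scale bars, or labels from
#' other stains; these are removed explicitly (which regions to mask is
#' user input, not guessed).  Exclusion regions are set to background (0)
#' and non-mitochondrial channels dropped.
#'
#' @param image numeric matrix or 3-D array in `[0, 1]`.
#' @param exclusion_regions list of regions; each either
#'   `list(row, col, height, width)` (a rectangle, 1-based pixel
#'   coordinates) or `list(poly = cbind(row, col))` (a polygon).
#' @param channel for multi-channel input: channel index, or one of
#'   `"red"`, `"green"`, `"blue"`, or `"luminance"` (the default mix, see
#'   [to_grayscale()]).
#' @return single-channel numeric matrix.
#' @export
preprocess <- function(image, exclusion_regions = NULL, channel = NULL) {
  if (length(dim(image)) == 3) {
    nch <- dim(image)[3]
    if (is.null(channel) || identical(channel, "luminance")) {
      image <- to_grayscale(image)
    } else {
      ci <- if (is.character(channel)) {
        match(channel, c("red", "green", "blue"))
      } else as.integer(channel)
      if (is.na(ci) || ci < 1 || ci > nch) {
        stop("channel specification refers to an absent channel")
      }
      image <- image[, , ci]
    }
  } else if (!is.null(channel) && !identical(channel, "luminance") &&
             !identical(channel, 1L) && !identical(channel, 1)) {
    stop("channel specification refers to an absent channel")
  }
  for (reg in exclusion_regions) {
    image <- apply_region(image, reg, value = 0)
  }
  image
}

apply_region <- function(image, reg, value) {
  nr <- nrow(image); nc <- ncol(image)
  if (!is.null(reg$poly)) {
    rc <- expand.grid(row = seq_len(nr), col = seq_len(nc))
    inside <- point_in_polygon(rc$row, rc$col, reg$poly[, 1], reg$poly[, 2])
    image[matrix(inside, nr, nc)] <- value
  } else {
    rows <- reg$row:(reg$row + reg$height - 1)
    cols <- reg$col:(reg$col + reg$width - 1)
    rows <- rows[rows >= 1 & rows <= nr]
    cols <- cols[cols >= 1 & cols <= nc]
    image[rows, cols] <- value
  }
  image
}

# even-odd ray casting
point_in_polygon <- function(pr, pc, vr, vc) {
  n <- length(vr)
  inside <- logical(length(pr))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((vc[i] > pc) != (vc[j] > pc)) &
      (pr < (vr[j] - vr[i]) * (pc - vc[i]) / (vc[j] - vc[i]) + vr[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Convert to grayscale
#'
#' Luminance mix `0.2126 R + 0.7152 G + 0.0722 B` (weights renormalized for
#' 2- or 4-channel input, alpha ignored).  Monotone in each channel;
#' constant input maps to the same constant.
#'
#' @param image numeric matrix or array with 1-4 channels.
#' @return numeric matrix.
#' @export
to_grayscale <- function(image) {
  if (length(dim(image)) == 2) return(image)
  nch <- dim(image)[3]
  stopifnot(nch >= 1, nch <= 4)
  if (nch == 1) return(image[, , 1])
  if (nch == 2) return(image[, , 1])          # gray + alpha
  w <- c(0.2126, 0.7152, 0.0722)  # sums to 1, so constants are preserved
  image[, , 1] * w[1] + image[, , 2] * w[2] + image[, , 3] * w[3]
}

#' Otsu threshold
#'
#' The global threshold minimizing the intra-class intensity variance
#' (equivalently maximizing the between-class variance) over a 256-bin
#' histogram of the `[0, 1]` intensity range.
#'
#' @param image numeric matrix in `[0, 1]` with at least two distinct
#'   values.
#' @param levels number of histogram bins.
#' @return the threshold level; pixels strictly above it are foreground.
#' @export
otsu_threshold <- function(image, levels = 256) {
  x <- as.vector(image)
  if (length(unique(x)) < 2) stop("degenerate histogram: constant image")
  breaks <- seq(0, 1, length.out = levels + 1)
  h <- tabulate(pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE),
                          1L), levels), nbins = levels)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(levels + 1)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_total <- mu0[levels]
  w1 <- 1 - w0
  between <- (mu_total * w0 - mu0)^2 / (w0 * w1)
  between[!is.finite(between)] <- -Inf
  k <- which.max(between[-levels])   # cut after bin k
  breaks[k + 1]
}

#' Binarize an image at a threshold
#'
#' @param image numeric matrix.
#' @param level threshold; a pixel is foreground iff its intensity is
#'   strictly greater than `level`.
#' @return logical matrix (a `BinaryMask`).
#' @export
binarize <- function(image, level = otsu_threshold(image)) {
  stopifnot(is.matrix(image))
  image > level
}

# ---------------------------------------------------------------------------
# topology-preserving thinning

# number of 0->1 transitions around the 8-neighbourhood ring of (r, c),
# and the foreground neighbour count, on the padded mask
ring_order <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                    c(1, 0), c(1, -1), c(0, -1), c(-1, -1))

#' Skeletonize a binary mask
#'
#' Reduces the mask to one-pixel-thick, 8-connected lines by sequential
#' removal of simple points: a border pixel is deleted only when (i) the
#' 0-to-1 transition count around its 8-neighbourhood ring is exactly 1,
#' (ii) it has 2-7 foreground neighbours (so end points of lines survive),
#' and (iii) it has a 4-connected background neighbour.  Deletions are
#' applied one pixel at a time against the current mask, which guarantees
#' that the number of connected components and the cycle rank of each
#' component are preserved exactly; directional sub-passes (north, south,
#' east, west borders) keep the skeleton centred.  The operation is
#' idempotent: a converged skeleton passes through unchanged.
#'
#' @param mask logical matrix (a `BinaryMask`).
#' @return logical matrix of the same shape (a `SkeletonMask`).
#' @export
skeletonize <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  # pad by one background pixel so neighbourhoods never leave the matrix
  m <- matrix(FALSE, nr + 2, nc + 2)
  m[2:(nr + 1), 2:(nc + 1)] <- mask

  removable <- function(r, c) {
    ring <- m[cbind(r + ring_order[, 1], c + ring_order[, 2])]
    b <- sum(ring)
    if (b < 2 || b > 7) return(FALSE)
    a <- sum(!ring & c(ring[-1], ring[1]))   # 0 -> 1 transitions
    if (a != 1) return(FALSE)
    # 4-connected background neighbour (border condition)
    !(m[r - 1, c] && m[r + 1, c] && m[r, c - 1] && m[r, c + 1])
  }

  dirs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  repeat {
    changed <- FALSE
    for (d in dirs) {
      fg <- which(m)
      if (length(fg) == 0) break
      r <- ((fg - 1) %% (nr + 2)) + 1
      c <- ((fg - 1) %/% (nr + 2)) + 1
      # candidates: pixels whose d-side 4-neighbour is background
      side_bg <- !m[cbind(r + d[1], c + d[2])]
      cand <- which(side_bg)
      for (i in cand) {
        if (removable(r[i], c[i])) {
          m[r[i], c[i]] <- FALSE
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  m[2:(nr + 1), 2:(nc + 1)]
}

#' Label connected skeleton components
#'
#' Two foreground pixels share a label iff they are connected by an
#' 8-adjacent foreground path; labels are contiguous `1..C`, background 0.
#'
#' @param skeleton logical matrix.
#' @return integer matrix of component labels.
#' @export
label_components <- function(skeleton) {
  stopifnot(is.logical(skeleton), is.matrix(skeleton))
  lab <- matrix(0L, nrow(skeleton), ncol(skeleton))
  idx <- which(skeleton)
  if (length(idx) == 0) return(lab)
  g <- skeleton_to_graph(skeleton)
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

#' Run the full extraction pipeline on a micrograph
#'
#' Convenience wrapper: preprocess, grayscale, Otsu binarization,
#' skeletonization, labeling and conversion to the pixel graph.
#'
#' @inheritParams preprocess
#' @param level optional fixed threshold; default Otsu.
#' @return list with `binary`, `skeleton`, `labels`, `graph`, and `stats`
#'   (a [network_stats()] bundle).
#' @export
extract_network <- function(image, exclusion_regions = NULL, channel = NULL,
                            level = NULL) {
  gray <- preprocess(image, exclusion_regions, channel)
  if (is.null(level)) level <- otsu_threshold(gray)
  bin <- binarize(gray, level)
  skel <- skeletonize(bin)
  labels <- label_components(skel)
  g <- skeleton_to_graph(skel)
  list(binary = bin, skeleton = skel, labels = labels, graph = g,
       stats = if (igraph::ecount(g) > 0) network_stats(g) else NULL,
       level = level)
}

#' Read exclusion regions from JSON
#'
#' The JSON is a list of objects, either rectangles
#' `{"row":, "col":, "height":, "width":}` in 0-based pixel coordinates, or
#' polygons `{"poly": [[row, col], ...]}`.  Coordinates are converted to
#' the 1-based convention used by [preprocess()].
#'
#' @param path JSON file path.
#' @return a list of region specifications.
#' @export
read_exclusion_regions <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(spec)) spec <- split(spec, seq_len(nrow(spec)))
  lapply(spec, function(r) {
    if (!is.null(r$poly)) {
      list(poly = matrix(unlist(r$poly), ncol = 2, byrow = TRUE) + 1)
    } else {
      list(row = r$row + 1, col = r$col + 1,
           height = r$height, width = r$width)
    }
  })
}
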