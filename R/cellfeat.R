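#' Per-nucleus shape and colour features
#'
#' Measures, for every labelled region in a segmentation mask, the seven
#' intrinsic cell-level features: `area` (pixel count), `major` and `minor`
#' (full axis lengths of the ellipse with the same second central moments
#' as the region), `ratio` (major/minor), and the mean pixel value of the
#' region in each RGB channel (`rMean`, `gMean`, `bMean`, on the 0-255
#' scale). Degenerate regions (single pixels or perfectly collinear pixel
#' sets, where the minor axis vanishes) have `minor` clamped to 1 px and
#' are flagged in the `degenerate` column.
#'
#' @param mask Integer label matrix (0 = background), e.g. from
#'   [segment_nuclei()].
#' @param image Height x width x 3 RGB array in \[0, 255\], same size as
#'   `mask`.
#' @return data.frame with one row per label: id, row, col (centroid,
#'   1-based), area, major, minor, ratio, rMean, gMean, bMean, degenerate.
#' @export
compute_nucleus_features <- function(mask, image) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L,
            all(dim(mask) == dim(image)[1:2]))
  idx <- which(mask > 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(id = integer(), row = numeric(), col = numeric(),
                      area = numeric(), major = numeric(), minor = numeric(),
                      ratio = numeric(), rMean = numeric(), gMean = numeric(),
                      bMean = numeric(), degenerate = logical()))
  lab <- mask[mask > 0L]
  ids <- sort(unique(lab))
  g <- match(lab, ids)
  n <- as.numeric(tabulate(g, nbins = length(ids)))
  r <- idx[, 1]; cc <- idx[, 2]
  sums <- rowsum(cbind(r, cc, r * r, cc * cc, r * cc), g)
  mr <- sums[, 1] / n
  mc <- sums[, 2] / n
  # second central moments of the pixel set
  vrr <- sums[, 3] / n - mr^2
  vcc <- sums[, 4] / n - mc^2
  vrc <- sums[, 5] / n - mr * mc
  tr2 <- (vrr + vcc) / 2
  det_root <- sqrt(pmax(((vrr - vcc) / 2)^2 + vrc^2, 0))
  l1 <- pmax(tr2 + det_root, 0)
  l2 <- pmax(tr2 - det_root, 0)
  major <- 4 * sqrt(l1)
  minor <- 4 * sqrt(l2)
  degenerate <- minor < 1
  minor[degenerate] <- 1
  major <- pmax(major, minor)
  pix <- (idx[, 2] - 1) * dim(image)[1] + idx[, 1]
  npix <- prod(dim(image)[1:2])
  ch_mean <- function(k)
    as.numeric(rowsum(image[pix + (k - 1) * npix], g)) / n
  data.frame(id = ids, row = mr, col = mc, area = n,
             major = major, minor = minor, ratio = major / minor,
             rMean = ch_mean(1), gMean = ch_mean(2),
             bMean = ch_mean(3), degenerate = degenerate)
}

#' Delaunay neighbour graph of nucleus centroids
#'
#' Builds the undirected neighbour graph from the Delaunay triangulation of
#' the centroids. Exactly two points form a single edge; collinear point
#' sets are connected as a path in coordinate order (the triangulation is
#' degenerate there). If the triangulation fails numerically, a
#' deterministic seedless jitter of 1e-6 px is applied and the
#' triangulation retried.
#'
#' @param centroids Two-column matrix or data.frame of (row, col)
#'   coordinates.
#' @return List of class `neighbor_graph` with `n` (node count) and
#'   `edges` (two-column integer matrix, each undirected edge once with
#'   `edges[,1] < edges[,2]`). Fewer than 2 centroids give an empty edge
#'   set with a warning.
#' @export
build_neighbor_graph <- function(centroids) {
  if (is.data.frame(centroids))
    centroids <- as.matrix(centroids[, c("row", "col")])
  n <- nrow(centroids)
  if (is.null(n) || n < 2L) {
    warning("fewer than 2 centroids: neighbour distances undefined")
    return(structure(list(n = if (is.null(n)) 0L else n,
                          edges = matrix(integer(), 0, 2)),
                     class = "neighbor_graph"))
  }
  if (n == 2L)
    return(structure(list(n = 2L, edges = matrix(c(1L, 2L), 1)),
                     class = "neighbor_graph"))
  tri <- function(y, x) {
    d <- deldir::deldir(x = x, y = y, suppressMsge = TRUE)
    cbind(d$delsgs$ind1, d$delsgs$ind2)
  }
  e <- tryCatch(tri(centroids[, 1], centroids[, 2]), error = function(err) NULL)
  if (is.null(e) || nrow(e) == 0L) {
    e <- tryCatch(tri(centroids[, 1] + 1e-6 * sin(seq_len(n)),
                      centroids[, 2] + 1e-6 * cos(seq_len(n) * 2)),
                  error = function(err) NULL)
  }
  if (is.null(e)) stop("Delaunay triangulation failed")
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  structure(list(n = n, edges = e), class = "neighbor_graph")
}

#' Neighbour-distance features per nucleus
#'
#' Euclidean centroid distances to Delaunay neighbours, summarized per node
#' as mean, maximum, and minimum. The neighbour relation is symmetric: the
#' distance between i and j contributes to both nodes. Isolated nodes
#' (possible after centroid deduplication or for tiny inputs) get `NA`
#' distances and are flagged; such nuclei are excluded from distance-feature
#' aggregation downstream.
#'
#' @param graph A `neighbor_graph` from [build_neighbor_graph()].
#' @param centroids The same coordinates the graph was built on.
#' @return data.frame with columns distMean, distMax, distMin (px) and
#'   `isolated` (logical), one row per node.
#' @export
compute_distance_features <- function(graph, centroids) {
  stopifnot(inherits(graph, "neighbor_graph"))
  if (is.data.frame(centroids))
    centroids <- as.matrix(centroids[, c("row", "col")])
  n <- graph$n
  out <- data.frame(distMean = rep(NA_real_, n), distMax = NA_real_,
                    distMin = NA_real_, isolated = TRUE)
  if (nrow(graph$edges) == 0L) return(out)
  e <- graph$edges
  d <- sqrt((centroids[e[, 1], 1] - centroids[e[, 2], 1])^2 +
            (centroids[e[, 1], 2] - centroids[e[, 2], 2])^2)
  nodes <- c(e[, 1], e[, 2])
  dd <- c(d, d)
  by_node <- split(dd, nodes)
  present <- as.integer(names(by_node))
  out$distMean[present] <- vapply(by_node, mean, numeric(1))
  out$distMax[present] <- vapply(by_node, max, numeric(1))
  out$distMin[present] <- vapply(by_node, min, numeric(1))
  out$isolated[present] <- FALSE
  out
}

#' Full 10-feature cell table for one tile
#'
#' Convenience wrapper: region morphometry and colour via
#' [compute_nucleus_features()], then the Delaunay graph and neighbour
#' distances over the tile's centroids.
#'
#' @param image RGB array in \[0, 255\].
#' @param segmentation A `segmentation_result` (or a plain integer label
#'   matrix).
#' @return data.frame with columns id, row, col, the ten
#'   [cell_feature_names()], and `degenerate`/`isolated` flags.
#' @export
extract_cell_features <- function(image, segmentation) {
  mask <- if (inherits(segmentation, "segmentation_result"))
    segmentation$mask else segmentation
  cells <- compute_nucleus_features(mask, image)
  if (nrow(cells) >= 2L) {
    g <- build_neighbor_graph(cells[, c("row", "col")])
    dist_f <- compute_distance_features(g, cells[, c("row", "col")])
  } else {
    if (nrow(cells) == 1L)
      warning("single nucleus: neighbour distances undefined")
    k <- nrow(cells)
    dist_f <- data.frame(distMean = rep(NA_real_, k),
                         distMax = rep(NA_real_, k),
                         distMin = rep(NA_real_, k),
                         isolated = rep(TRUE, k))
  }
  cbind(cells[, c("id", "row", "col", "area", "major", "minor", "ratio",
                  "rMean", "gMean", "bMean")],
        dist_f[, c("distMean", "distMax", "distMin")],
        degenerate = cells$degenerate, isolated = dist_f$isolated)
}
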