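#' Reference H&E stain profile
#'
#' The target stain basis used by [normalize_stain()]: unit optical-density
#' (OD) vectors for hematoxylin and eosin (Ruifrok-Johnston values) plus
#' reference maximum stain concentrations (the scale the 99th-percentile
#' source concentrations are mapped onto).
#'
#' @return List with `stains` (3 x 2 matrix, columns = hematoxylin, eosin,
#'   unit columns) and `max_c` (length-2 numeric).
#' @export
stain_reference <- function() {
  s <- cbind(h = c(0.650, 0.704, 0.286), e = c(0.072, 0.990, 0.105))
  s <- sweep(s, 2, sqrt(colSums(s^2)), "/")
  list(stains = s, max_c = c(1.9705, 1.0308))
}

# optical density of an RGB image (values 0..255); I0 = 255
.optical_density <- function(image) {
  -log(pmax(image, 1) / 255)
}

# Otsu threshold on a numeric vector with a bimodality score: the maximized
# between-class variance as a fraction of total variance. Unimodal (e.g.
# Gaussian noise) data score around 0.64; well-separated modes approach 1.
.otsu <- function(x, n_bins = 256L) {
  r <- range(x)
  if (!is.finite(diff(r)) || diff(r) < 1e-10)
    return(list(threshold = r[1], score = 0))
  mids <- seq(r[1], r[2], length.out = n_bins)
  counts <- tabulate(findInterval(x, mids, all.inside = TRUE), nbins = n_bins)
  w <- counts / sum(counts)
  mu <- cumsum(w * mids)
  omega <- cumsum(w)
  mu_t <- mu[n_bins]
  sigma_b2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b2[!is.finite(sigma_b2)] <- 0
  k <- which.max(sigma_b2)
  total_var <- sum(w * (mids - mu_t)^2)
  list(threshold = mids[k],
       score = if (total_var > 0) sigma_b2[k] / total_var else 0)
}

# Dominant stain OD channel: projection of per-pixel OD onto the first
# principal direction of the tissue pixels' OD (sign-fixed positive).
.dominant_od_channel <- function(image, od_threshold = 0.15) {
  od <- .optical_density(image)
  odm <- matrix(od, ncol = 3)
  tissue <- rowSums(odm) > od_threshold
  if (sum(tissue) < 2) return(NULL)
  v <- eigen(crossprod(odm[tissue, , drop = FALSE]),
             symmetric = TRUE)$vectors[, 1]
  if (sum(v) < 0) v <- -v
  matrix(odm %*% v, nrow = dim(image)[1])
}

#' Normalize the stain appearance of an RGB tile
#'
#' Decomposes the tile into two stain components in optical-density space
#' (plane spanned by the top two principal directions of the tissue pixels'
#' OD; stain vectors at the 1st/99th percentile of the angular
#' distribution), then rescales each stain's concentration so its 99th
#' percentile matches the reference maximum and reconstructs the image in
#' the reference stain basis. Stain-density ranks are preserved per
#' channel. Tiles with (almost) no tissue under the OD threshold are
#' returned unchanged with attribute `no_tissue = TRUE` and a warning.
#'
#' @param image Height x width x 3 array, values in \[0, 255\].
#' @param reference Target profile, see [stain_reference()].
#' @param od_threshold Minimum summed OD for a pixel to count as tissue.
#' @param min_tissue Minimum number of tissue pixels required.
#' @return Normalized image array (same dimensions, values in \[0, 255\]).
#' @export
normalize_stain <- function(image, reference = stain_reference(),
                            od_threshold = 0.15, min_tissue = 50L) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("input must be a 3-channel RGB image array")
  odm <- matrix(.optical_density(image), ncol = 3)
  tissue <- rowSums(odm) > od_threshold
  if (sum(tissue) < min_tissue) {
    warning("no tissue pixels under the OD threshold; image returned unchanged")
    attr(image, "no_tissue") <- TRUE
    return(image)
  }
  odt <- odm[tissue, , drop = FALSE]
  # uncentered second moment: stain mixtures live in a plane through the
  # origin, and the first eigenvector then points along the mean OD
  # direction so stain angles do not wrap around +/-pi
  ev <- eigen(crossprod(odt) / nrow(odt), symmetric = TRUE)
  V <- ev$vectors[, 1:2, drop = FALSE]
  if (sum(V[, 1]) < 0) V[, 1] <- -V[, 1]
  proj <- odt %*% V
  single_stain <- ev$values[2] < 1e-8 * max(ev$values[1], 1e-12)
  if (!single_stain) {
    ang <- atan2(proj[, 2], proj[, 1])
    a_lo <- stats::quantile(ang, 0.01, names = FALSE)
    a_hi <- stats::quantile(ang, 0.99, names = FALSE)
    single_stain <- (a_hi - a_lo) < 1e-3
  }
  if (single_stain) {
    v1 <- V[, 1]
    if (sum(v1) < 0) v1 <- -v1
    conc <- pmax(odm %*% v1, 0)
    sf <- reference$max_c[1] /
      max(stats::quantile(conc[tissue], 0.99, names = FALSE), 1e-12)
    od_new <- (conc * sf) %*% t(reference$stains[, 1, drop = FALSE])
  } else {
    mk <- function(a) {
      v <- V %*% c(cos(a), sin(a))
      if (sum(v) < 0) v <- -v
      v / sqrt(sum(v^2))
    }
    s1 <- mk(a_lo); s2 <- mk(a_hi)
    # hematoxylin absorbs red light most strongly: larger red-channel OD
    S <- if (s1[1] >= s2[1]) cbind(s1, s2) else cbind(s2, s1)
    conc <- t(pmax(solve(crossprod(S), t(S) %*% t(odm)), 0))
    sf <- reference$max_c /
      pmax(apply(conc[tissue, , drop = FALSE], 2, stats::quantile,
                 probs = 0.99, names = FALSE), 1e-12)
    od_new <- sweep(conc, 2, sf, "*") %*% t(reference$stains)
  }
  out <- array(pmin(pmax(255 * exp(-od_new), 0), 255), dim = dim(image))
  out
}

#' Segmentation configuration
#'
#' @param min_area Minimum region area in px^2 (smaller regions dropped;
#'   default 30 px^2, appropriate near 0.5 um/px).
#' @param od_threshold Summed-OD threshold separating tissue from glass.
#' @param second_level_score Bimodality score above which the second-level
#'   Otsu split (dark nuclei vs dim cytoplasm inside the foreground) is
#'   applied; foregrounds that are effectively unimodal keep the
#'   first-level threshold.
#' @param watershed_tolerance Minimum depth for watershed object splitting.
#' @return List of class `seg_params`.
#' @export
seg_params <- function(min_area = 30L, od_threshold = 0.15,
                       second_level_score = 0.75, watershed_tolerance = 1) {
  structure(list(min_area = min_area, od_threshold = od_threshold,
                 second_level_score = second_level_score,
                 watershed_tolerance = watershed_tolerance),
            class = "seg_params")
}

# label-mask summary table; relabels to consecutive positive integers
.label_table <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0L)
    return(list(mask = matrix(0L, nrow(labels), ncol(labels)),
                table = data.frame(label = integer(), area = numeric(),
                                   row = numeric(), col = numeric())))
  relab <- matrix(0L, nrow(labels), ncol(labels))
  tab <- data.frame(label = seq_along(ids), area = NA_real_,
                    row = NA_real_, col = NA_real_)
  idx <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[labels > 0]
  new <- match(lab, ids)
  relab[idx] <- new
  tab$area <- as.numeric(tabulate(new, nbins = length(ids)))
  tab$row <- as.numeric(rowsum(idx[, 1], new)) / tab$area
  tab$col <- as.numeric(rowsum(idx[, 2], new)) / tab$area
  list(mask = relab, table = tab)
}

#' Segment cell nuclei in an RGB tile
#'
#' Hierarchical multilevel thresholding on the dominant-stain
#' (hematoxylin-like) optical-density channel: a first Otsu threshold
#' isolates stained foreground from background; a second Otsu within the
#' foreground separates dark nuclei from dimmer stained tissue when the
#' foreground is genuinely bimodal (see `second_level_score` in
#' [seg_params()]). Binary regions are hole-filled, touching nuclei are
#' split by watershed on the distance transform, and regions below
#' `min_area` are discarded. Deterministic: identical inputs give identical
#' masks.
#'
#' @param image Height x width x 3 RGB array, values in \[0, 255\]
#'   (normally the output of [normalize_stain()]).
#' @param params A [seg_params()] configuration.
#' @return An object of class `segmentation_result`: list with `mask`
#'   (integer label matrix, labels consecutive from 1, 0 = background) and
#'   `table` (data.frame: label, area (px^2), row, col centroid in 1-based
#'   pixel coordinates).
#' @export
segment_nuclei <- function(image, params = seg_params()) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("input must be a 3-channel RGB image array")
  chan <- .dominant_od_channel(image, params$od_threshold)
  empty <- .label_table(matrix(0L, dim(image)[1], dim(image)[2]))
  if (is.null(chan)) return(structure(empty, class = "segmentation_result"))
  o1 <- .otsu(as.numeric(chan))
  # a unimodal channel (blank or noise-only tile) has a weak Otsu
  # separation; treat it as containing no nuclei
  if (o1$score <= params$second_level_score)
    return(structure(empty, class = "segmentation_result"))
  fg <- chan > o1$threshold
  if (!any(fg)) return(structure(empty, class = "segmentation_result"))
  o2 <- .otsu(chan[fg])
  nuclei <- if (o2$score > params$second_level_score)
    fg & (chan > o2$threshold) else fg
  if (!any(nuclei)) return(structure(empty, class = "segmentation_result"))
  bin <- EBImage::fillHull(EBImage::Image(nuclei * 1))
  dm <- EBImage::distmap(bin)
  ws <- EBImage::watershed(dm, tolerance = params$watershed_tolerance, ext = 1)
  labels <- matrix(as.integer(EBImage::imageData(ws)),
                   nrow(nuclei), ncol(nuclei))
  areas <- tabulate(labels[labels > 0])
  small <- which(areas < params$min_area)
  if (length(small)) labels[labels %in% small] <- 0L
  structure(.label_table(labels), class = "segmentation_result")
}

#' Remove implausibly large detections
#'
#' Detections with area strictly above the given nearest-rank percentile of
#' the areas in the same image are treated as false detections (typically
#' tissue folds or merged clumps) and removed; remaining labels are
#' relabelled consecutively. With all areas equal nothing is strictly above
#' the percentile, so nothing is removed.
#'
#' @param result A `segmentation_result`.
#' @param percentile Percentile of the per-image area distribution
#'   (default 95).
#' @return A filtered `segmentation_result`.
#' @export
filter_large_nuclei <- function(result, percentile = 95) {
  stopifnot(inherits(result, "segmentation_result"))
  if (nrow(result$table) == 0L) return(result)
  thr <- nearest_rank_percentile(result$table$area, percentile)
  drop <- result$table$label[result$table$area > thr]
  if (length(drop) == 0L) return(result)
  mask <- result$mask
  mask[mask %in% drop] <- 0L
  structure(.label_table(mask), class = "segmentation_result")
}

#' Match detections against ground truth
#'
#' Greedy nearest-centroid matching between detected nuclei and a
#' ground-truth table (closest pairs first, each nucleus used once, pairs
#' beyond `max_dist` unmatched). Used to score segmentation recall and
#' area accuracy on synthetic tiles.
#'
#' @param result A `segmentation_result`.
#' @param truth Ground-truth table with columns row, col, area
#'   (e.g. from [generate_tile()]).
#' @param max_dist Maximum centroid distance (px) for a valid match.
#' @return List with `n_truth`, `n_detected`, `n_matched`, `recall`,
#'   `n_spurious` (detections left unmatched), and `area_ratio` (matched
#'   detected/truth areas).
#' @export
evaluate_segmentation <- function(result, truth, max_dist = 5) {
  stopifnot(inherits(result, "segmentation_result"))
  det <- result$table
  if (nrow(det) == 0L || nrow(truth) == 0L)
    return(list(n_truth = nrow(truth), n_detected = nrow(det),
                n_matched = 0L, recall = 0, n_spurious = nrow(det),
                area_ratio = numeric(0)))
  d <- sqrt(outer(det$row, truth$row, "-")^2 + outer(det$col, truth$col, "-")^2)
  matched_det <- integer(0); matched_tr <- integer(0)
  repeat {
    k <- which.min(d)
    if (!length(k) || d[k] > max_dist) break
    i <- (k - 1) %% nrow(d) + 1
    j <- (k - 1) %/% nrow(d) + 1
    matched_det <- c(matched_det, i); matched_tr <- c(matched_tr, j)
    d[i, ] <- Inf; d[, j] <- Inf
  }
  list(n_truth = nrow(truth), n_detected = nrow(det),
       n_matched = length(matched_det),
       recall = length(matched_det) / nrow(truth),
       n_spurious = nrow(det) - length(matched_det),
       area_ratio = det$area[matched_det] / truth$area[matched_tr])
}
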