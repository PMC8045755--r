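#' Specification for a synthetic histology tile
#'
#' Describes a tile of elliptical "nuclei" on a uniform background, used to
#' validate segmentation and morphometry with known ground truth. Nucleus
#' areas are lognormal with the given mean and standard deviation (in px^2,
#' on the natural scale); elongation ratios are lognormal clipped to >= 1;
#' orientations are uniform. Centres are placed by hard-core rejection
#' sampling so that no two centroids are closer than `min_separation` and no
#' two rendered ellipses touch.
#'
#' @param width,height Tile dimensions in pixels.
#' @param n_nuclei Number of nuclei to place.
#' @param area_mean,area_sd Mean and SD of nucleus area (px^2).
#' @param ratio_mean,ratio_sd Mean and SD of the major/minor axis ratio.
#' @param nucleus_color,background_color RGB triples in \[0, 255\].
#' @param min_separation Hard-core distance between centroids (px).
#' @param noise_sd SD of i.i.d. Gaussian pixel noise added per channel.
#' @param seed Integer seed; identical specs give bit-identical tiles.
#' @return An object of class `tile_spec`.
#' @export
tile_spec <- function(width = 512L, height = 512L, n_nuclei = 50L,
                      area_mean = 300, area_sd = 100,
                      ratio_mean = 1.6, ratio_sd = 0.4,
                      nucleus_color = c(80, 50, 130),
                      background_color = c(243, 242, 247),
                      min_separation = 25, noise_sd = 3, seed = 1L) {
  width <- stopifnot_scalar_count(width, "width", 1L)
  height <- stopifnot_scalar_count(height, "height", 1L)
  n_nuclei <- stopifnot_scalar_count(n_nuclei, "n_nuclei", 0L)
  if (area_mean <= 0) stop("area_mean must be > 0")
  if (min_separation < 0) stop("min_separation must be >= 0")
  if (length(nucleus_color) != 3L || length(background_color) != 3L ||
      any(c(nucleus_color, background_color) < 0) ||
      any(c(nucleus_color, background_color) > 255))
    stop("colors must be RGB triples in [0, 255]")
  structure(list(width = width, height = height, n_nuclei = n_nuclei,
                 area_mean = area_mean, area_sd = area_sd,
                 ratio_mean = ratio_mean, ratio_sd = ratio_sd,
                 nucleus_color = as.numeric(nucleus_color),
                 background_color = as.numeric(background_color),
                 min_separation = min_separation, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "tile_spec")
}

# lognormal parameters on the log scale from a natural-scale mean and sd
.lognormal_pars <- function(mean, sd) {
  sdlog2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

# integer pixel coordinates (1-based rows/cols) covered by an ellipse
.ellipse_pixels <- function(cy, cx, a, b, theta, height, width) {
  ext <- ceiling(max(a, b)) + 1L
  rows <- max(1L, floor(cy - ext)):min(height, ceiling(cy + ext))
  cols <- max(1L, floor(cx - ext)):min(width, ceiling(cx + ext))
  rr <- rep(rows, times = length(cols))
  cc <- rep(cols, each = length(rows))
  dy <- rr - cy
  dx <- cc - cx
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  keep <- (u / a)^2 + (v / b)^2 <= 1
  cbind(row = rr[keep], col = cc[keep])
}

#' Generate a synthetic tile with ground truth
#'
#' Renders the tile described by a [tile_spec()]: an RGB image, an integer
#' label mask (0 = background) and a ground-truth nucleus table. Placement
#' uses rejection sampling with a cap of 10,000 attempts per nucleus;
#' if a nucleus cannot be placed the function stops with an
#' "overcrowded tile" error. Rendered ellipses never touch, so the mask is
#' guaranteed to contain exactly `n_nuclei` connected components.
#'
#' @param spec A [tile_spec()].
#' @return A list of class `synthetic_tile` with elements `image`
#'   (height x width x 3 array, values in \[0, 255\]), `mask` (integer
#'   height x width matrix with labels 1..n), and `truth` (data.frame with
#'   columns id, row, col, area, major, minor, ratio; centroids are 1-based
#'   pixel coordinates, area is the rendered pixel count, major/minor are
#'   the generating full axis lengths in px).
#' @export
generate_tile <- function(spec) {
  stopifnot(inherits(spec, "tile_spec"))
  with_seed(spec$seed, {
    h <- spec$height; w <- spec$width; n <- spec$n_nuclei
    mask <- matrix(0L, h, w)
    truth <- data.frame(id = integer(), row = numeric(), col = numeric(),
                        area = numeric(), major = numeric(),
                        minor = numeric(), ratio = numeric())
    if (n > 0) {
      ap <- .lognormal_pars(spec$area_mean, max(spec$area_sd, 1e-8))
      rp <- .lognormal_pars(spec$ratio_mean, max(spec$ratio_sd, 1e-8))
      areas <- stats::rlnorm(n, ap$meanlog, ap$sdlog)
      ratios <- pmax(1, stats::rlnorm(n, rp$meanlog, rp$sdlog))
      thetas <- stats::runif(n, 0, pi)
      centers <- matrix(NA_real_, n, 2)
      for (i in seq_len(n)) {
        a <- sqrt(areas[i] * ratios[i] / pi)   # semi-major
        b <- sqrt(areas[i] / (ratios[i] * pi)) # semi-minor
        ext <- ceiling(a) + 2
        if (2 * ext >= min(h, w)) stop("overcrowded tile: nucleus larger than tile")
        placed <- FALSE
        for (attempt in seq_len(10000L)) {
          cy <- stats::runif(1, 1 + ext, h - ext)
          cx <- stats::runif(1, 1 + ext, w - ext)
          if (i > 1) {
            d2 <- (centers[seq_len(i - 1), 1] - cy)^2 +
                  (centers[seq_len(i - 1), 2] - cx)^2
            if (min(d2) < spec$min_separation^2) next
          }
          px <- .ellipse_pixels(cy, cx, a, b, thetas[i], h, w)
          if (nrow(px) == 0L) next
          # forbid touching: check a 1-pixel neighbourhood around the ellipse
          nb <- rbind(px, px + rep(c(1, 0), each = nrow(px)),
                      px + rep(c(-1, 0), each = nrow(px)),
                      px + rep(c(0, 1), each = nrow(px)),
                      px + rep(c(0, -1), each = nrow(px)))
          nb <- nb[nb[, 1] >= 1 & nb[, 1] <= h & nb[, 2] >= 1 & nb[, 2] <= w, , drop = FALSE]
          if (any(mask[nb] != 0L)) next
          mask[px] <- i
          truth[i, ] <- list(i, mean(px[, 1]), mean(px[, 2]),
                             nrow(px), 2 * a, 2 * b, ratios[i])
          centers[i, ] <- c(cy, cx)
          placed <- TRUE
          break
        }
        if (!placed) stop("overcrowded tile: could not place nucleus ", i,
                          " after 10000 attempts")
      }
    }
    img <- array(rep(spec$background_color, each = h * w), dim = c(h, w, 3))
    idx <- which(mask != 0L)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[idx] <- spec$nucleus_color[ch]
      img[, , ch] <- plane
    }
    if (spec$noise_sd > 0)
      img <- img + array(stats::rnorm(h * w * 3, 0, spec$noise_sd), dim = c(h, w, 3))
    img <- pmin(pmax(img, 0), 255)
    structure(list(image = img, mask = mask, truth = truth, spec = spec),
              class = "synthetic_tile")
  })
}

#' Read and write tiles and label masks
#'
#' Tiles are stored as 8-bit RGB PNG. Label masks are stored as 16-bit
#' single-channel TIFF so that up to 65,535 nucleus labels round-trip
#' exactly.
#'
#' @param image Height x width x 3 array with values in \[0, 255\].
#' @param mask Integer label matrix (0 = background).
#' @param path Output/input file path.
#' @return `read_tile` returns the image array in \[0, 255\];
#'   `read_mask` returns an integer label matrix. Writers return `path`
#'   invisibly.
#' @name tile_io
NULL

#' @rdname tile_io
#' @export
write_tile <- function(image, path) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  png::writePNG(image / 255, path)
  invisible(path)
}

#' @rdname tile_io
#' @export
read_tile <- function(path) {
  img <- if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    tiff::readTIFF(path) else png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] > 3L) img <- img[, , 1:3]
  img * 255
}

#' @rdname tile_io
#' @export
write_mask <- function(mask, path) {
  if (max(mask) > 65535L) stop("more than 65535 labels cannot be stored")
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname tile_io
#' @export
read_mask <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}
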