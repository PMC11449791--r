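#' Grayscale puncta image container
#'
#' @param pixels numeric matrix of grey levels (rows = y, columns = x),
#'   in `[0, 2^bit_depth - 1]`.
#' @param px_um pixel size, micrometers per pixel.
#' @param bit_depth 8 or 16.
#' @param roi optional polygon (data.frame with `x`, `y` in um) limiting
#'   the analysis region; `NULL` means the full field.
#' @return object of class `puncta_image`.
#' @export
puncta_image <- function(pixels, px_um, bit_depth = 8, roi = NULL) {
  stopifnot(is.matrix(pixels), px_um > 0, bit_depth %in% c(8, 16))
  structure(list(pixels = pixels, px_um = px_um, bit_depth = bit_depth,
                 roi = roi),
            class = "puncta_image")
}

#' Write / read a puncta image as TIFF with a JSON sidecar
#'
#' Single-channel TIFF (8- or 16-bit); pixel size and bit depth go into
#' `<path>.json`.
#'
#' @param img a [puncta_image()].
#' @param path TIFF file path.
#' @return `write_puncta_tiff` returns `path` invisibly;
#'   `read_puncta_tiff` a `puncta_image`.
#' @export
write_puncta_tiff <- function(img, path) {
  stopifnot(inherits(img, "puncta_image"))
  maxv <- 2^img$bit_depth - 1
  tiff::writeTIFF(img$pixels / maxv, path,
                  bits.per.sample = img$bit_depth)
  jsonlite::write_json(list(px_um = img$px_um, bit_depth = img$bit_depth),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_puncta_tiff
#' @export
read_puncta_tiff <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"))
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  maxv <- 2^side$bit_depth - 1
  puncta_image(round(px * maxv), side$px_um, side$bit_depth)
}

#' Generate a synthetic puncta image with known ground truth
#'
#' Places `n_puncta` non-overlapping bright disks (areas drawn uniformly
#' within `area_range_um2`) on a uniform background, adds Gaussian pixel
#' noise, and returns the image together with the truth table of centers
#' and areas. Placement uses rejection sampling; an error is raised when
#' the requested number of non-overlapping disks cannot be placed within
#' a bounded number of retries.
#'
#' @param field_um field width and height in micrometers.
#' @param px_um pixel size (um/pixel).
#' @param n_puncta number of puncta (>= 0).
#' @param area_range_um2 two-element range of disk areas.
#' @param noise_sd Gaussian noise SD in grey levels (8-bit scale).
#' @param seed integer seed.
#' @param intensity disk grey level; `background` the field grey level.
#' @param background background grey level.
#' @return list with `img` (a [puncta_image()]) and `truth`
#'   (data.frame: `x_um`, `y_um`, `radius_um`, `area_um2`).
#' @export
generate_puncta_image <- function(field_um = c(18.3, 18.3), px_um = 0.1,
                                  n_puncta = 10,
                                  area_range_um2 = c(0.3, 0.8),
                                  noise_sd = 0, seed = 1L,
                                  intensity = 200, background = 20) {
  stopifnot(n_puncta >= 0, all(field_um > 0), px_um > 0)
  w <- round(field_um[1] / px_um)
  h <- round(field_um[2] / px_um)
  with_seed(seed, {
    centers <- matrix(numeric(0), ncol = 3)   # x_um, y_um, r_um
    tries <- 0L
    max_tries <- 500L * max(n_puncta, 1L)
    while (nrow(centers) < n_puncta) {
      if (tries >= max_tries) {
        stop("could not place the requested non-overlapping puncta")
      }
      tries <- tries + 1L
      a <- stats::runif(1, area_range_um2[1], area_range_um2[2])
      r <- sqrt(a / pi)
      cx <- stats::runif(1, r + 2 * px_um, field_um[1] - r - 2 * px_um)
      cy <- stats::runif(1, r + 2 * px_um, field_um[2] - r - 2 * px_um)
      if (nrow(centers) > 0) {
        d <- sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2)
        if (any(d < centers[, 3] + r + 3 * px_um)) next
      }
      centers <- rbind(centers, c(cx, cy, r))
    }
    px <- matrix(background, nrow = h, ncol = w)
    xg <- (col(px) - 0.5) * px_um
    yg <- (row(px) - 0.5) * px_um
    if (n_puncta > 0) {
      for (i in seq_len(nrow(centers))) {
        inside <- (xg - centers[i, 1])^2 + (yg - centers[i, 2])^2 <=
          centers[i, 3]^2
        px[inside] <- intensity
      }
    }
    if (noise_sd > 0) px <- px + stats::rnorm(length(px), 0, noise_sd)
    px <- round(pmin(pmax(px, 0), 255))
    truth <- if (n_puncta > 0) {
      data.frame(x_um = centers[, 1], y_um = centers[, 2],
                 radius_um = centers[, 3],
                 area_um2 = pi * centers[, 3]^2)
    } else {
      data.frame(x_um = numeric(0), y_um = numeric(0),
                 radius_um = numeric(0), area_um2 = numeric(0))
    }
    list(img = puncta_image(px, px_um, 8), truth = truth)
  })
}

# shared binarization: rolling-ball-style background subtraction
# (grayscale opening with a disc), 8-bit conversion, fixed threshold,
# Gaussian blur + re-threshold to split touching puncta
binarize_puncta <- function(img, threshold, rolling_radius_px = 50,
                            blur_sigma_px = 1) {
  maxv <- 2^img$bit_depth - 1
  if (threshold < 0 || threshold > 255) stop("threshold outside 8-bit range")
  x <- img$pixels / maxv
  rad <- min(rolling_radius_px, floor(min(dim(x)) / 2) - 1L)
  if (rad >= 1) {
    bg <- EBImage::opening(x, EBImage::makeBrush(2L * rad + 1L, "disc"))
    x <- pmax(x - bg, 0)
  }
  x8 <- x * 255
  bin <- x8 > threshold
  if (blur_sigma_px > 0) {
    sm <- EBImage::gblur(bin * 1, sigma = blur_sigma_px)
    bin <- sm > 0.5
  }
  bin
}

#' Count synaptic puncta in a grayscale image
#'
#' Background subtraction (grayscale opening with a disc of
#' `rolling_radius_px`), conversion to 8-bit, fixed-threshold
#' binarization, a Gaussian blur + re-threshold pass to separate closely
#' apposed puncta, and connected-component counting within the image ROI.
#' An optional area filter restricts the accepted component areas.
#'
#' @param img a [puncta_image()].
#' @param threshold binarization threshold on the 8-bit scale.
#' @param rolling_radius_px background-subtraction radius in pixels.
#' @param min_area_um2,max_area_um2 optional area filter (um^2).
#' @param blur_sigma_px Gaussian blur sigma in pixels.
#' @return list with `count`, `density_per_um2` (count / ROI area),
#'   `areas_um2`, `centroids_um` (data.frame `x_um`, `y_um`),
#'   `roi_area_um2`.
#' @export
puncta_count <- function(img, threshold, rolling_radius_px = 50,
                         min_area_um2 = NULL, max_area_um2 = NULL,
                         blur_sigma_px = 1) {
  stopifnot(inherits(img, "puncta_image"))
  bin <- binarize_puncta(img, threshold, rolling_radius_px, blur_sigma_px)
  lab <- EBImage::bwlabel(bin)
  nlab <- max(lab)
  roi_area <- if (is.null(img$roi)) {
    prod(dim(img$pixels)) * img$px_um^2
  } else {
    polygon_area(img$roi)
  }
  if (roi_area <= 0) stop("empty ROI")
  if (nlab == 0L) {
    return(list(count = 0L, density_per_um2 = 0, areas_um2 = numeric(0),
                centroids_um = data.frame(x_um = numeric(0),
                                          y_um = numeric(0)),
                roi_area_um2 = roi_area))
  }
  px_area <- tabulate(lab[lab > 0], nbins = nlab)
  cx <- vapply(seq_len(nlab), function(k) mean(col(lab)[lab == k]),
               numeric(1)) * img$px_um
  cy <- vapply(seq_len(nlab), function(k) mean(row(lab)[lab == k]),
               numeric(1)) * img$px_um
  areas <- px_area * img$px_um^2
  keep <- rep(TRUE, nlab)
  if (!is.null(min_area_um2)) keep <- keep & areas >= min_area_um2
  if (!is.null(max_area_um2)) keep <- keep & areas <= max_area_um2
  if (!is.null(img$roi)) {
    keep <- keep & pracma::inpolygon(cx, cy, img$roi$x, img$roi$y,
                                     boundary = TRUE)
  }
  list(count = sum(keep), density_per_um2 = sum(keep) / roi_area,
       areas_um2 = areas[keep],
       centroids_um = data.frame(x_um = cx[keep], y_um = cy[keep]),
       roi_area_um2 = roi_area)
}

#' Excitation/inhibition ratio from puncta densities
#'
#' Quotient of the excitatory (VGLUT1+) over the inhibitory (VGAT+)
#' puncta density.
#'
#' @param vglut1_density,vgat_density puncta densities per um^2.
#' @return the E/I ratio.
#' @export
ei_ratio <- function(vglut1_density, vgat_density) {
  stopifnot(vglut1_density >= 0)
  if (vgat_density <= 0) stop("VGAT density must be positive")
  vglut1_density / vgat_density
}

#' Perisomatic puncta density around a soma
#'
#' The soma polygon is dilated by `ring_um` and the soma removed, giving
#' a perisomatic ring. The image is binarized as in [puncta_count()];
#' connected components within the ring whose areas fall in
#' `area_bounds_um2` count as puncta. Density is puncta per micrometer of
#' soma perimeter; `area_fraction` is the puncta area inside the ring
#' divided by the ring area.
#'
#' @param img a [puncta_image()].
#' @param soma_polygon data.frame with `x`, `y` vertices in um (closed,
#'   non-self-intersecting).
#' @param threshold binarization threshold (8-bit scale).
#' @param ring_um ring width in um (default 1.25).
#' @param area_bounds_um2 accepted puncta area range (default
#'   0.15-2.5 um^2).
#' @inheritParams puncta_count
#' @return list with `count`, `density_per_um` (per um of perimeter),
#'   `area_fraction`, `perimeter_um`, `ring_area_um2`.
#' @export
perisomatic_density <- function(img, soma_polygon, threshold,
                                ring_um = 1.25,
                                area_bounds_um2 = c(0.15, 2.5),
                                rolling_radius_px = 50,
                                blur_sigma_px = 1) {
  stopifnot(inherits(img, "puncta_image"))
  d <- dim(img$pixels)
  xg <- (col(img$pixels) - 0.5) * img$px_um
  yg <- (row(img$pixels) - 0.5) * img$px_um
  soma <- matrix(pracma::inpolygon(as.numeric(xg), as.numeric(yg),
                                   soma_polygon$x, soma_polygon$y,
                                   boundary = TRUE), d[1], d[2])
  rpx <- max(1L, round(ring_um / img$px_um))
  dil <- EBImage::dilate(soma * 1, EBImage::makeBrush(2L * rpx + 1L, "disc")) > 0
  if (any(dil[1, ]) || any(dil[d[1], ]) || any(dil[, 1]) || any(dil[, d[2]])) {
    stop("perisomatic ring exits the image bounds")
  }
  ring <- dil & !soma
  bin <- binarize_puncta(img, threshold, rolling_radius_px, blur_sigma_px)
  lab <- EBImage::bwlabel(bin & ring)
  nlab <- max(lab)
  peri <- polygon_perimeter(soma_polygon)
  ring_area <- sum(ring) * img$px_um^2
  if (nlab == 0L) {
    return(list(count = 0L, density_per_um = 0, area_fraction = 0,
                perimeter_um = peri, ring_area_um2 = ring_area))
  }
  areas <- tabulate(lab[lab > 0], nbins = nlab) * img$px_um^2
  keep <- areas >= area_bounds_um2[1] & areas <= area_bounds_um2[2]
  list(count = sum(keep), density_per_um = sum(keep) / peri,
       area_fraction = sum(areas[keep]) / ring_area,
       perimeter_um = peri, ring_area_um2 = ring_area)
}

polygon_area <- function(poly) {
  x <- poly$x; y <- poly$y
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

polygon_perimeter <- function(poly) {
  x <- poly$x; y <- poly$y
  n <- length(x)
  j <- c(seq_len(n)[-1], 1L)
  sum(sqrt((x[j] - x)^2 + (y[j] - y)^2))
}
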