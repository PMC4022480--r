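#' Synthetic microscopy scene
#'
#' Describes a field of roughly circular cells to be rendered as a
#' phase-contrast / fluorescence image pair: the phase channel shows dark
#' cell bodies with a bright rim on a mid-grey background (the appearance a
#' trapped yeast monolayer has in phase contrast), the fluorescence channel
#' shows each cell's intensity on a dark background. Both channels get
#' additive Gaussian optics noise.
#'
#' @param size image size in pixels (square), default 256.
#' @param centers n x 2 matrix of cell centers (x, y in pixels).
#' @param radii cell radii (px).
#' @param intensities per-cell fluorescence intensities (arbitrary units,
#'   mapped 1:1 to fluorescence-channel pixel values).
#' @param background phase-channel background grey level (default 0.55).
#' @param noise_sd optics noise SD (default 0.02).
#' @param seed RNG seed used at render time.
#' @return an object of class \code{"synthetic_scene"}.
#' @export
synthetic_scene <- function(size = 256, centers, radii, intensities,
                            background = 0.55, noise_sd = 0.02, seed = 1) {
  centers <- matrix(centers, ncol = 2L)
  n <- nrow(centers)
  if (length(radii) == 1L) radii <- rep(radii, n)
  if (length(intensities) == 1L) intensities <- rep(intensities, n)
  if (length(radii) != n || length(intensities) != n)
    stop("radii and intensities must match the number of centers")
  if (n > 0) {
    if (any(radii <= 0)) stop("radii must be positive")
    if (any(intensities < 0)) stop("intensities must be >= 0")
    if (any(centers < 1) || any(centers > size))
      stop("cell centers must lie inside the frame")
  }
  structure(list(size = as.integer(size), centers = centers, radii = radii,
                 intensities = intensities, background = background,
                 noise_sd = noise_sd, seed = seed),
            class = "synthetic_scene")
}

#' Random non-overlapping scene
#'
#' Places cells by seeded rejection sampling with a minimum center
#' separation, emulating a crowded but mostly non-fused monolayer.
#'
#' @param n_cells number of cells to place.
#' @param size frame size (px).
#' @param r_range radius range (px), default c(5, 8).
#' @param intensity_range per-cell fluorescence range.
#' @param min_sep_frac minimum center separation as a fraction of the radius
#'   sum (default 0.95, allowing slight boundary contact).
#' @param seed RNG seed.
#' @inheritParams synthetic_scene
#' @return a \code{"synthetic_scene"}.
#' @export
random_scene <- function(n_cells = 100, size = 256, r_range = c(5, 8),
                         intensity_range = c(0.4, 0.9), min_sep_frac = 0.95,
                         noise_sd = 0.02, seed = 1) {
  set.seed(as.integer(seed))
  margin <- r_range[2L] + 2
  centers <- matrix(NA_real_, n_cells, 2L)
  radii <- stats::runif(n_cells, r_range[1L], r_range[2L])
  placed <- 0L; tries <- 0L
  while (placed < n_cells && tries < 50000L) {
    tries <- tries + 1L
    cand <- stats::runif(2, margin, size - margin)
    if (placed > 0L) {
      dd <- sqrt(colSums((t(centers[seq_len(placed), , drop = FALSE]) - cand)^2))
      if (any(dd < min_sep_frac * (radii[seq_len(placed)] + radii[placed + 1L])))
        next
    }
    placed <- placed + 1L
    centers[placed, ] <- cand
  }
  if (placed < n_cells)
    stop("could not place ", n_cells, " cells; reduce density")
  synthetic_scene(size = size, centers = centers, radii = radii,
                  intensities = stats::runif(n_cells, intensity_range[1L],
                                             intensity_range[2L]),
                  noise_sd = noise_sd, seed = seed + 1L)
}

#' Render a scene into a phase-contrast / fluorescence image pair
#'
#' Deterministic under the scene's seed. Pixel values are clamped to [0, 1]
#' in the phase channel; the fluorescence channel keeps intensity units.
#'
#' @param scene a \code{"synthetic_scene"}.
#' @return an object of class \code{"image_pair"}: list(phase, fluo), both
#'   size x size matrices (row = y, column = x).
#' @export
render_scene <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  set.seed(as.integer(scene$seed))
  sz <- scene$size
  phase <- matrix(scene$background, sz, sz)
  fluo <- matrix(0.02, sz, sz)
  n <- nrow(scene$centers)
  if (n > 0) for (i in seq_len(n)) {
    cx <- scene$centers[i, 1L]; cy <- scene$centers[i, 2L]; r <- scene$radii[i]
    xr <- max(1L, floor(cx - r - 2)):min(sz, ceiling(cx + r + 2))
    yr <- max(1L, floor(cy - r - 2)):min(sz, ceiling(cy + r + 2))
    d <- sqrt(outer((yr - cy)^2, (xr - cx)^2, `+`))
    body <- d <= r - 1
    rim <- d > r - 1 & d <= r + 1
    sub_p <- phase[yr, xr]
    sub_p[body] <- 0.25
    sub_p[rim] <- 0.9
    phase[yr, xr] <- sub_p
    sub_f <- fluo[yr, xr]
    sub_f[d <= r] <- pmax(sub_f[d <= r], scene$intensities[i])
    fluo[yr, xr] <- sub_f
  }
  if (scene$noise_sd > 0) {
    phase <- phase + matrix(stats::rnorm(sz * sz, 0, scene$noise_sd), sz, sz)
    fluo <- fluo + matrix(stats::rnorm(sz * sz, 0, scene$noise_sd), sz, sz)
  }
  structure(list(phase = pmin(pmax(phase, 0), 1), fluo = pmax(fluo, 0)),
            class = "image_pair")
}

#' Otsu threshold of a grayscale image
#'
#' Returns the threshold maximizing the between-class variance of the image
#' histogram (256 bins over the value range). Pixels strictly above the
#' threshold form one class.
#'
#' @param image numeric matrix (any value range).
#' @param n_bins histogram resolution (default 256).
#' @return the threshold value.
#' @export
otsu_threshold <- function(image, n_bins = 256L) {
  v <- as.vector(image)
  if (diff(range(v)) == 0) stop("constant image: threshold undefined")
  lo <- min(v); hi <- max(v)
  br <- seq(lo, hi, length.out = n_bins + 1L)
  h <- tabulate(pmin(findInterval(v, br, rightmost.closed = TRUE), n_bins),
                nbins = n_bins)
  w <- h / sum(h)
  mids <- (br[-1L] + br[-(n_bins + 1L)]) / 2
  w0 <- cumsum(w); mu <- cumsum(w * mids); mut <- mu[n_bins]
  # between-class variance at each candidate cut (class 0 = bins 1..k)
  valid <- w0 > 0 & w0 < 1
  bcv <- (mut * w0 - mu)^2 / (w0 * (1 - w0))
  bcv[!valid] <- -Inf
  k <- which.max(bcv)
  br[k + 1L]
}

#' Convex hulls of the connected components of a binary mask
#'
#' Components are labelled with \code{EBImage::bwlabel}; each component is
#' replaced by the convex hull of its pixel coordinates.
#'
#' @param mask logical or 0/1 matrix.
#' @param min_pixels drop components smaller than this (default 9).
#' @return list of hulls; each a list(vertices = k x 2 matrix of (x, y)
#'   pixel coordinates in hull order, bbox = c(x0, x1, y0, y1)).
#' @export
convex_hull_regions <- function(mask, min_pixels = 9L) {
  m <- matrix(as.numeric(mask > 0), nrow(mask), ncol(mask))
  if (!any(m > 0)) return(list())
  if (!requireNamespace("EBImage", quietly = TRUE))
    stop("convex_hull_regions requires the EBImage package")
  lab <- EBImage::bwlabel(m)
  labs <- sort(unique(as.vector(lab))); labs <- labs[labs > 0]
  out <- list()
  for (l in labs) {
    idx <- which(lab == l, arr.ind = TRUE)   # (row = y, col = x)
    if (nrow(idx) < min_pixels) next
    x <- idx[, 2L]; y <- idx[, 1L]
    h <- grDevices::chull(x, y)
    out[[length(out) + 1L]] <- list(
      vertices = cbind(x = x[h], y = y[h]),
      bbox = c(x0 = min(x), x1 = max(x), y0 = min(y), y1 = max(y)))
  }
  out
}

#' Circular Hough transform cell detection
#'
#' Gradient-direction voting: every edge pixel casts votes at the two points
#' a distance r away along its gradient direction (cell rims have radial
#' gradients, so a circle of radius r concentrates its rim votes at its
#' center). The per-radius accumulator is smoothed with a 3 x 3 box sum to
#' absorb rounding spread and normalized by circle circumference so scores
#' are comparable across radii. Candidate peaks above \code{score_min} are
#' accepted greedily by score with non-maximum suppression (no two accepted
#' centers closer than \code{min_dist}). When hull regions are supplied,
#' voting is restricted to their (slightly padded) bounding boxes.
#'
#' @param image grayscale matrix (phase contrast).
#' @param hulls optional output of [convex_hull_regions()].
#' @param r_min,r_max radius search range (px), defaults 4 and 12.
#' @param score_min minimum normalized vote score (default 0.65; a clean rim
#'   contributes about 2 circumferences of votes after smoothing).
#' @param min_dist non-maximum suppression distance (px, default 2 * r_min).
#' @param edge_quantile quantile of gradient magnitude above which a pixel
#'   counts as an edge (default 0.9).
#' @return data frame cx, cy, r, score (one row per detected circle).
#' @export
hough_circles <- function(image, hulls = NULL, r_min = 4, r_max = 12,
                          score_min = 0.65, min_dist = 2 * r_min,
                          edge_quantile = 0.9) {
  if (r_min >= r_max) stop("need r_min < r_max")
  empty <- data.frame(cx = numeric(0), cy = numeric(0),
                      r = numeric(0), score = numeric(0))
  ny <- nrow(image); nx <- ncol(image)
  gx <- matrix(0, ny, nx); gy <- matrix(0, ny, nx)
  gx[, 2:(nx - 1)] <- (image[, 3:nx] - image[, 1:(nx - 2)]) / 2
  gy[2:(ny - 1), ] <- (image[3:ny, ] - image[1:(ny - 2), ]) / 2
  gmag <- sqrt(gx^2 + gy^2)
  thr <- stats::quantile(gmag, edge_quantile)
  sel <- gmag > pmax(thr, 1e-8)
  if (!is.null(hulls)) {
    inhull <- matrix(FALSE, ny, nx)
    for (h in hulls) {
      b <- h$bbox
      inhull[max(1, b["y0"] - 2):min(ny, b["y1"] + 2),
             max(1, b["x0"] - 2):min(nx, b["x1"] + 2)] <- TRUE
    }
    sel <- sel & inhull
  }
  edge <- which(sel, arr.ind = TRUE)
  if (nrow(edge) == 0L) return(empty)
  ex <- edge[, 2L]; ey <- edge[, 1L]
  g <- gmag[sel]
  ux <- gx[sel] / g; uy <- gy[sel] / g

  radii <- seq(ceiling(r_min), floor(r_max))
  box3 <- function(a) {   # 3x3 box sum via shifted additions
    pad <- matrix(0, nrow(a) + 2L, ncol(a) + 2L)
    pad[2:(nrow(a) + 1L), 2:(ncol(a) + 1L)] <- a
    out <- matrix(0, nrow(a), ncol(a))
    for (dy in 0:2) for (dx in 0:2)
      out <- out + pad[(1 + dy):(nrow(a) + dy), (1 + dx):(ncol(a) + dx)]
    out
  }
  cand <- list()
  for (r in radii) {
    cx <- c(round(ex + r * ux), round(ex - r * ux))
    cy <- c(round(ey + r * uy), round(ey - r * uy))
    ok <- cx >= 1 & cx <= nx & cy >= 1 & cy <= ny
    votes <- tabulate((cx[ok] - 1L) * ny + cy[ok], nbins = nx * ny)
    acc <- box3(matrix(votes, ny, nx)) / (2 * pi * r)
    pk <- which(acc >= score_min)
    if (length(pk))
      cand[[length(cand) + 1L]] <- data.frame(
        cx = (pk - 1L) %/% ny + 1L, cy = (pk - 1L) %% ny + 1L,
        r = r, score = acc[pk])
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$score), , drop = FALSE]
  if (nrow(cand) > 5000L) cand <- cand[seq_len(5000L), ]
  keep_x <- numeric(0); keep_y <- numeric(0); keep_i <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (length(keep_x) &&
        any((keep_x - cand$cx[i])^2 + (keep_y - cand$cy[i])^2 < min_dist^2))
      next
    keep_x <- c(keep_x, cand$cx[i]); keep_y <- c(keep_y, cand$cy[i])
    keep_i <- c(keep_i, i)
  }
  out <- cand[keep_i, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full segmentation and quantification chain
#'
#' The measurement chain applied to every frame: Otsu binarization of the
#' phase-contrast image (the cell class is the one whose mean differs from
#' the image-border background), convex hulls of the connected components,
#' circular Hough transform restricted to the hull regions, and masked
#' fluorescence quantification over the union of detected cell disks. If no
#' cell is detected the frame is flagged and \code{prev_value} is carried
#' over so a control loop never crashes on a bad frame.
#'
#' @param pair an \code{"image_pair"} (or list with phase and fluo matrices).
#' @param r_min,r_max Hough radius range (px).
#' @param score_min Hough evidence threshold.
#' @param shrink disk erosion (px) applied when building the quantification
#'   mask, keeping it inside the cell body (default 1).
#' @param prev_value measurement to report for a flagged frame.
#' @return an object of class \code{"segmentation_result"}: list(mask,
#'   circles, mean_fluo, flagged, n_cells).
#' @export
segment_and_quantify <- function(pair, r_min = 4, r_max = 12,
                                 score_min = 0.65, shrink = 1,
                                 prev_value = NA_real_) {
  phase <- pair$phase; fluo <- pair$fluo
  if (!identical(dim(phase), dim(fluo))) stop("phase and fluo shapes differ")
  thr <- otsu_threshold(phase)
  # the cell class is the one less like the border (background) pixels
  border <- c(phase[1L, ], phase[nrow(phase), ], phase[, 1L], phase[, ncol(phase)])
  fg_is_low <- mean(border) > thr
  mask0 <- if (fg_is_low) phase <= thr else phase > thr
  hulls <- convex_hull_regions(mask0)
  circles <- hough_circles(phase, hulls, r_min = r_min, r_max = r_max,
                           score_min = score_min)
  ny <- nrow(phase); nx <- ncol(phase)
  mask <- matrix(FALSE, ny, nx)
  if (nrow(circles)) {
    for (i in seq_len(nrow(circles))) {
      r <- circles$r[i] - shrink
      if (r <= 0) next
      xr <- max(1L, floor(circles$cx[i] - r)):min(nx, ceiling(circles$cx[i] + r))
      yr <- max(1L, floor(circles$cy[i] - r)):min(ny, ceiling(circles$cy[i] + r))
      d <- sqrt(outer((yr - circles$cy[i])^2, (xr - circles$cx[i])^2, `+`))
      mask[yr, xr] <- mask[yr, xr] | (d <= r)
    }
  }
  flagged <- !any(mask)
  mean_fluo <- if (flagged) prev_value else mean(fluo[mask])
  structure(list(mask = mask, circles = circles, mean_fluo = mean_fluo,
                 flagged = flagged, n_cells = nrow(circles)),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  if (x$flagged) cat("Segmentation: FLAGGED frame (no cells detected)\n")
  else cat(sprintf("Segmentation: %d cells detected, masked mean fluorescence = %.4f\n",
                   x$n_cells, x$mean_fluo))
  invisible(x)
}

#' Match detections against ground truth
#'
#' Greedy nearest matching of detected circles to true centers within a
#' tolerance radius; used to score detection recall and precision on
#' rendered scenes.
#'
#' @param circles detection data frame (cx, cy, r).
#' @param scene the \code{"synthetic_scene"} ground truth.
#' @param tol_px matching tolerance (px, default 3).
#' @return list(recall, precision, matched, center_errors).
#' @export
score_detections <- function(circles, scene, tol_px = 3) {
  n_true <- nrow(scene$centers)
  if (!nrow(circles))
    return(list(recall = 0, precision = NA_real_, matched = 0L,
                center_errors = numeric(0)))
  used <- rep(FALSE, nrow(circles))
  errs <- numeric(0); matched <- 0L
  for (i in seq_len(n_true)) {
    d <- sqrt((circles$cx - scene$centers[i, 1L])^2 +
              (circles$cy - scene$centers[i, 2L])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (d[j] <= tol_px) {
      used[j] <- TRUE; matched <- matched + 1L
      errs <- c(errs, d[j])
    }
  }
  list(recall = matched / n_true, precision = matched / nrow(circles),
       matched = matched, center_errors = errs)
}

#' Read / write grayscale images
#'
#' Thin wrappers over the png package; matrices are stored as 16-bit
#' grayscale PNG with values clipped to [0, 1].
#'
#' @param path file path.
#' @param image numeric matrix in [0, 1].
#' @name image_io
#' @export
read_gray_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  a
}

#' @rdname image_io
#' @export
write_gray_png <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}
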