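test_that("scene rendering is deterministic and structurally correct", {
  skip_if_not_installed("EBImage")
  # zero cells: background plus noise only
  sc0 <- synthetic_scene(size = 64, centers = matrix(numeric(0), 0, 2),
                         radii = numeric(0), intensities = numeric(0),
                         noise_sd = 0.01, seed = 2)
  pr0 <- render_scene(sc0)
  expect_lt(diff(range(pr0$phase)), 0.12)
  # one cell, zero noise: exactly one connected non-background component
  sc1 <- synthetic_scene(size = 64, centers = c(32, 32), radii = 8,
                         intensities = 0.5, noise_sd = 0, seed = 1)
  pr1 <- render_scene(sc1)
  mask <- pr1$phase != sc1$background
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), 64, 64))
  expect_equal(max(lab), 1)
  # same seed, identical rasters
  expect_identical(render_scene(sc1), render_scene(sc1))
})

test_that("Otsu threshold maximizes between-class variance (exhaustive oracle)", {
  set.seed(8)
  v <- c(rnorm(600, 10, 0.5), rnorm(400, 200, 3))
  img <- matrix(v, 40, 25)
  thr <- otsu_threshold(img)
  expect_gt(thr, min(v)); expect_lt(thr, max(v))
  # separates the two modes perfectly
  expect_true(all(v[v <= thr] < 100) && all(v[v > thr] > 100))
  # exhaustive search over every candidate cut point
  cuts <- sort(unique(v))
  bcv <- vapply(cuts[-length(cuts)], function(cut) {
    w0 <- mean(v <= cut)
    if (w0 == 0 || w0 == 1) return(-Inf)
    w0 * (1 - w0) * (mean(v[v <= cut]) - mean(v[v > cut]))^2
  }, numeric(1))
  best_cut <- cuts[which.max(bcv)]
  # identical classification as the exhaustive oracle
  expect_equal(img > thr, img > best_cut)
  # shift invariance: adding a constant shifts the threshold by that constant
  expect_equal(otsu_threshold(img + 50), thr + 50, tolerance = 1e-9)
  expect_error(otsu_threshold(matrix(1, 5, 5)), "constant")
})

test_that("Otsu agrees with the EBImage reference implementation", {
  skip_if_not_installed("EBImage")
  sc <- random_scene(n_cells = 40, size = 128, seed = 6)
  img <- render_scene(sc)$phase
  thr <- otsu_threshold(img, n_bins = 256L)
  ref <- EBImage::otsu(EBImage::Image(t(img)), range = c(0, 1), levels = 256)
  # thresholds may sit anywhere on the same between-class-variance plateau;
  # the classifications they induce must agree almost everywhere
  expect_lt(mean((img > thr) != (img > ref)), 0.02)
})

test_that("convex hulls of mask components match a gift-wrapping oracle", {
  skip_if_not_installed("EBImage")
  m <- matrix(FALSE, 40, 40)
  m[10:20, 10:20] <- TRUE                           # filled square
  hulls <- convex_hull_regions(m)
  expect_length(hulls, 1)
  v <- hulls[[1]]$vertices
  expect_setequal(paste(v[, 1], v[, 2]),
                  c("10 10", "20 10", "20 20", "10 20"))
  # L-shaped component: hull area exceeds component area
  m2 <- matrix(FALSE, 40, 40)
  m2[5:25, 5:10] <- TRUE; m2[20:25, 5:25] <- TRUE
  h2 <- convex_hull_regions(m2)
  shoelace <- function(v) {
    x <- v[, 1]; y <- v[, 2]
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }
  expect_gt(shoelace(h2[[1]]$vertices), sum(m2))
  # gift-wrapping oracle on a random blob (union of overlapping discs)
  m3 <- matrix(FALSE, 60, 60)
  cx <- c(22, 30, 38, 30); cy <- c(25, 30, 26, 38); cr <- c(8, 8, 7, 7)
  for (i in 1:4) {
    d <- sqrt(outer((1:60 - cy[i])^2, (1:60 - cx[i])^2, `+`))
    m3 <- m3 | (d <= cr[i])
  }
  h3 <- convex_hull_regions(m3)
  expect_length(h3, 1)
  idx <- which(m3, arr.ind = TRUE)
  gift_wrap <- function(x, y) {
    n <- length(x)
    start <- which.min(x + y / 1e9)
    hull <- integer(0); cur <- start
    repeat {
      hull <- c(hull, cur)
      cand <- setdiff(seq_len(n), cur)
      nxt <- cand[1]
      for (j in cand[-1]) {
        cr <- (x[nxt] - x[cur]) * (y[j] - y[cur]) -
              (y[nxt] - y[cur]) * (x[j] - x[cur])
        d_nxt <- (x[nxt] - x[cur])^2 + (y[nxt] - y[cur])^2
        d_j <- (x[j] - x[cur])^2 + (y[j] - y[cur])^2
        if (cr < 0 || (cr == 0 && d_j > d_nxt)) nxt <- j
      }
      cur <- nxt
      if (cur == start) break
    }
    hull
  }
  hw <- gift_wrap(idx[, 2], idx[, 1])
  oracle_set <- paste(idx[hw, 2], idx[hw, 1])
  ours_set <- paste(h3[[1]]$vertices[, 1], h3[[1]]$vertices[, 2])
  expect_true(all(ours_set %in% oracle_set))
  expect_true(all(oracle_set %in% ours_set))
  expect_identical(convex_hull_regions(matrix(FALSE, 5, 5)), list())
})

test_that("Hough transform localizes rendered rings to pixel accuracy", {
  sc <- synthetic_scene(size = 64, centers = c(32, 32), radii = 8,
                        intensities = 0.5, noise_sd = 0, seed = 1)
  img <- render_scene(sc)$phase
  circ <- hough_circles(img, r_min = 4, r_max = 12)
  expect_equal(nrow(circ), 1)
  expect_lt(abs(circ$cx - 32), 1 + 1e-9)
  expect_lt(abs(circ$cy - 32), 1 + 1e-9)
  expect_lt(abs(circ$r - 8), 1 + 1e-9)
  # blank image: no detections
  expect_equal(nrow(hough_circles(matrix(0.5, 64, 64), r_min = 4, r_max = 12)), 0)
  # two well-separated rings: exactly two detections
  sc2 <- synthetic_scene(size = 96, centers = rbind(c(25, 30), c(70, 65)),
                         radii = c(7, 9), intensities = 0.5, noise_sd = 0, seed = 1)
  circ2 <- hough_circles(render_scene(sc2)$phase, r_min = 4, r_max = 12)
  expect_equal(nrow(circ2), 2)
  expect_error(hough_circles(matrix(0.5, 8, 8), r_min = 5, r_max = 5), "r_min")
})

test_that("full chain detects and quantifies a crowded frame", {
  skip_if_not_installed("EBImage")
  sc <- random_scene(n_cells = 100, size = 256, seed = 314)
  res <- segment_and_quantify(render_scene(sc))
  sco <- score_detections(res$circles, sc, tol_px = 3)
  expect_gte(sco$recall, 0.95)
  expect_gte(sco$precision, 0.95)
  expect_lte(max(sco$center_errors), 2)
  truem <- mean(sc$intensities)
  expect_lt(abs(res$mean_fluo - truem) / truem, 0.05)
  # uniform intensity: masked mean recovers it within the optics noise
  scu <- random_scene(n_cells = 50, size = 192, intensity_range = c(0.6, 0.6),
                      noise_sd = 0.02, seed = 7)
  resu <- segment_and_quantify(render_scene(scu))
  expect_lt(abs(resu$mean_fluo - 0.6), 3 * 0.02)
  # determinism of the whole chain
  r2 <- segment_and_quantify(render_scene(sc))
  expect_identical(res$circles, r2$circles)
  expect_identical(res$mean_fluo, r2$mean_fluo)
})

test_that("an empty frame is flagged and the previous measurement is carried over", {
  skip_if_not_installed("EBImage")
  blank <- list(phase = matrix(0.5, 64, 64) +
                  matrix(rnorm(64 * 64, 0, 0.005), 64, 64),
                fluo = matrix(0.02, 64, 64))
  res <- segment_and_quantify(blank, prev_value = 1.23)
  expect_true(res$flagged)
  expect_equal(res$mean_fluo, 1.23)
  expect_error(segment_and_quantify(list(phase = matrix(0.5, 4, 4),
                                         fluo = matrix(0.5, 5, 5))), "shapes")
})

test_that("grayscale PNG round trip preserves images", {
  img <- matrix(runif(64 * 48), 48, 64)
  f <- tempfile(fileext = ".png")
  write_gray_png(img, f)
  back <- read_gray_png(f)
  expect_equal(dim(back), dim(img))
  expect_lt(max(abs(back - img)), 1 / 255)
})
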