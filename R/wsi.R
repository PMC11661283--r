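#' Segment tissue from an RGB slide image
#'
#' Classic saturation-threshold tissue masking: downsample, convert RGB to
#' HSV, threshold the saturation channel (background and holes are near-white
#' hence low-saturation), median-blur to remove speckle, then morphological
#' closing to smooth tissue contours. Holes larger than the closing kernel
#' remain background.
#'
#' @param image `H x W x 3` numeric array in `[0, 1]` (values in 0..255 are
#'   rescaled), or a path readable by `EBImage::readImage()` (PNG/TIFF).
#' @param downsample Integer downsample factor for masking, default 32.
#' @param sat_threshold `"auto"` (Otsu's method on the saturation channel) or
#'   a fixed value in (0, 1).
#' @param blur_kernel Median blur kernel width at mask scale, default 7.
#' @param close_kernel Morphological closing brush width at mask scale,
#'   default 9 (odd).
#' @return Object of class `tissue_mask`: logical `mask` (rows = y at mask
#'   scale), `downsample`, `threshold`, `level0_dim` (H, W).
#' @export
segment_tissue <- function(image, downsample = 32, sat_threshold = "auto",
                           blur_kernel = 7, close_kernel = 9) {
  if (is.character(image)) {
    img <- EBImage::imageData(EBImage::readImage(image))
    # EBImage reads as width x height (x channels); convert to H x W x 3
    img <- if (length(dim(img)) == 2L) {
      array(rep(t(img), 3), c(ncol(img), nrow(img), 3))
    } else {
      aperm(img[, , 1:3], c(2, 1, 3))
    }
  } else {
    img <- image
  }
  if (length(dim(img)) != 3L || dim(img)[3] < 3L) stop("need an RGB image")
  if (max(img) > 1) img <- img / 255
  h0 <- dim(img)[1]; w0 <- dim(img)[2]
  hm <- max(1L, floor(h0 / downsample)); wm <- max(1L, floor(w0 / downsample))
  ch <- lapply(1:3, function(k)
    EBImage::imageData(EBImage::resize(EBImage::Image(img[, , k]), hm, wm)))
  mx <- pmax(ch[[1]], ch[[2]], ch[[3]])
  mn <- pmin(ch[[1]], ch[[2]], ch[[3]])
  sat <- ifelse(mx > 0, (mx - mn) / mx, 0)
  thr <- if (identical(sat_threshold, "auto")) {
    EBImage::otsu(EBImage::Image(sat), range = c(0, 1))
  } else {
    as.numeric(sat_threshold)
  }
  mask <- (sat > thr) * 1
  if (blur_kernel >= 3) {
    mask <- EBImage::imageData(
      EBImage::medianFilter(EBImage::Image(mask), max(1L, blur_kernel %/% 2L)))
    mask <- (mask > 0.5) * 1
  }
  if (close_kernel >= 3) {
    brush <- EBImage::makeBrush(close_kernel - (1 - close_kernel %% 2),
                                shape = "disc")
    mask <- EBImage::imageData(EBImage::closing(EBImage::Image(mask), brush))
  }
  mask <- mask > 0.5
  if (!any(mask)) warning("empty tissue mask")
  structure(list(mask = mask, downsample = as.integer(downsample),
                 threshold = thr, level0_dim = c(h0, w0)),
            class = "tissue_mask")
}

#' Extract a grid of tissue patches from a mask
#'
#' Divides the level-0 plane into contiguous non-overlapping grid-aligned
#' `patch_size x patch_size` tiles and keeps every tile whose mask coverage
#' is at least `min_tissue_frac`. Coordinates are 0-based (x, y) level-0
#' pixel origins of half-open tiles; partial tiles at the right/bottom edge
#' are not generated.
#'
#' @param mask A [segment_tissue()] result.
#' @param patch_size Tile side in level-0 pixels, default 512.
#' @param min_tissue_frac Minimum tissue coverage to keep a tile, default
#'   0.5.
#' @return Object of class `patch_grid`: integer `coords` (n x 2, columns x
#'   and y), `tissue_frac`, `patch_size`.
#' @export
extract_patches <- function(mask, patch_size = 512, min_tissue_frac = 0.5) {
  h0 <- mask$level0_dim[1]; w0 <- mask$level0_dim[2]
  ds <- mask$downsample
  mp <- patch_size / ds  # tile side at mask scale
  xs <- seq(0, w0 - patch_size, by = patch_size)
  ys <- seq(0, h0 - patch_size, by = patch_size)
  coords <- NULL
  fracs <- c()
  if (length(xs) && length(ys)) {
    for (y in ys) {
      rows <- floor(y / ds) + seq_len(max(1, round(mp)))
      rows <- rows[rows <= nrow(mask$mask)]
      for (x in xs) {
        cols <- floor(x / ds) + seq_len(max(1, round(mp)))
        cols <- cols[cols <= ncol(mask$mask)]
        f <- mean(mask$mask[rows, cols])
        if (f >= min_tissue_frac) {
          coords <- rbind(coords, c(x, y))
          fracs <- c(fracs, f)
        }
      }
    }
  }
  if (is.null(coords)) coords <- matrix(integer(), 0, 2)
  storage.mode(coords) <- "integer"
  colnames(coords) <- c("x", "y")
  structure(list(coords = coords, tissue_frac = fracs,
                 patch_size = as.integer(patch_size)),
            class = "patch_grid")
}

#' Deterministic toy patch encoder
#'
#' A stand-in for pretrained patch encoders with the same calling contract:
#' a deterministic map from a `224 x 224 x 3` patch to a `d`-vector. It
#' computes per-channel summary statistics (mean, sd, 8-bin histogram) and
#' applies a fixed seeded random projection. Identical patches always map to
#' identical vectors; any user-supplied encoder function with the same
#' signature can be used instead.
#'
#' @param d Output dimension, default 32.
#' @param seed Seed fixing the projection, default 1.
#' @return Function `patch -> numeric(d)` with attribute `"out_dim" = d`.
#' @export
toy_encoder <- function(d = 32, seed = 1) {
  n_stats <- 3 * (2 + 8)
  set.seed(seed)
  W <- matrix(stats::rnorm(d * n_stats), d, n_stats) / sqrt(n_stats)
  f <- function(patch) {
    stats_vec <- unlist(lapply(1:3, function(k) {
      ch <- patch[, , k]
      c(mean(ch), stats::sd(ch),
        as.numeric(graphics::hist(ch, breaks = seq(0, 1, length.out = 9),
                                  plot = FALSE)$counts) / length(ch))
    }))
    as.numeric(W %*% stats_vec)
  }
  attr(f, "out_dim") <- d
  f
}

#' Encode the patches of a grid into an embedding bag
#'
#' Crops each `patch_size` tile from the level-0 image, downsamples it to
#' `224 x 224`, and applies the encoder; bag rows follow grid order and the
#' grid coordinates are stored in the bag.
#'
#' @param grid A [extract_patches()] result.
#' @param image Level-0 `H x W x 3` array in `[0, 1]`.
#' @param encoder Encoder function (e.g. [toy_encoder()]).
#' @param patient_id Id for the resulting bag.
#' @return An [embedding_bag()] with `coords`.
#' @export
encode_patches <- function(grid, image, encoder, patient_id = "patient") {
  if (max(image) > 1) image <- image / 255
  n <- nrow(grid$coords)
  if (n == 0L) stop("patch grid is empty")
  ps <- grid$patch_size
  vecs <- NULL
  for (i in seq_len(n)) {
    x <- grid$coords[i, 1]; y <- grid$coords[i, 2]
    patch <- image[(y + 1):(y + ps), (x + 1):(x + ps), 1:3, drop = FALSE]
    small <- array(0, c(224, 224, 3))
    for (k in 1:3) {
      small[, , k] <- EBImage::imageData(
        EBImage::resize(EBImage::Image(patch[, , k]), 224, 224))
    }
    v <- encoder(small)
    if (i == 1L) {
      vecs <- matrix(0, n, length(v))
    } else if (length(v) != ncol(vecs)) {
      stop("encoder output dimension is inconsistent")
    }
    vecs[i, ] <- v
  }
  enc_d <- attr(encoder, "out_dim")
  if (!is.null(enc_d) && ncol(vecs) != enc_d) {
    stop("encoder returned wrong output dimension")
  }
  embedding_bag(patient_id, vecs, coords = grid$coords)
}

#' Run the full image-to-bag pipeline on one slide image
#'
#' [segment_tissue()] then [extract_patches()] then [encode_patches()].
#'
#' @inheritParams segment_tissue
#' @inheritParams extract_patches
#' @param encoder Encoder function.
#' @param patient_id Id for the bag.
#' @param ... Passed to [segment_tissue()].
#' @return An [embedding_bag()].
#' @export
wsi_to_bag <- function(image, encoder, patient_id = "patient",
                       patch_size = 512, min_tissue_frac = 0.5, ...) {
  mask <- segment_tissue(image, ...)
  grid <- extract_patches(mask, patch_size = patch_size,
                          min_tissue_frac = min_tissue_frac)
  encode_patches(grid, image, encoder, patient_id = patient_id)
}
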