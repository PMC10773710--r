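#' In-memory 5-band reflectance raster
#'
#' A reflectance scene is represented as a named list of five numeric
#' matrices (`blue`, `green`, `red`, `red_edge`, `nir`) of identical
#' dimensions, fractional reflectance in `[0, 1]`, with `NA` marking nodata
#' pixels. Pixel coordinates are 0-based, row-major, top-left origin.
#'
#' @param blue,green,red,red_edge,nir numeric matrices of equal dimensions.
#' @return A list of class `reflectance_raster`.
#' @export
reflectance_raster <- function(blue, green, red, red_edge, nir) {
  bands <- list(blue = blue, green = green, red = red,
                red_edge = red_edge, nir = nir)
  dims <- vapply(bands, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("format error: all five bands must have identical dimensions")
  }
  structure(bands, class = "reflectance_raster")
}

band_names <- c("blue", "green", "red", "red_edge", "nir")

#' Read / write a 5-band reflectance TIFF
#'
#' `write_raster()` stores the five bands as a multi-directory 32-bit float
#' TIFF in the fixed order blue, green, red, red-edge, NIR. Reflectance is
#' constrained to `[0, 1]`, which is also the storable range of the float
#' TIFF writer, so `NA` (nodata) pixels are carried in a sixth directory
#' holding a validity mask (1 = valid, 0 = nodata); the mask directory is
#' written only when nodata pixels exist. The mask is shared across bands —
#' a pixel missing in any band (e.g. an orthomosaic edge) is treated as
#' missing in all five. `read_raster()` accepts both the 5- and 6-directory
#' layout and restores `NA` pixels from the mask.
#'
#' @param raster a [reflectance_raster()].
#' @param file path to the TIFF file.
#' @return `write_raster()` the file path invisibly; `read_raster()` a
#'   [reflectance_raster()].
#' @export
write_raster <- function(raster, file) {
  imgs <- lapply(band_names, function(b) {
    m <- raster[[b]]
    m[is.na(m)] <- 0
    m
  })
  any_na <- Reduce(`|`, lapply(band_names, function(b) is.na(raster[[b]])))
  if (any(any_na)) {
    mask <- matrix(1, nrow(any_na), ncol(any_na))
    mask[any_na] <- 0
    imgs <- c(imgs, list(mask))
  }
  tiff::writeTIFF(imgs, file, bits.per.sample = 32L)
  invisible(file)
}

#' @rdname write_raster
#' @export
read_raster <- function(file) {
  imgs <- tiff::readTIFF(file, all = TRUE)
  if (!length(imgs) %in% c(5L, 6L)) {
    stop("format error: expected a 5-band TIFF (plus optional validity mask), found ",
         length(imgs), " directories")
  }
  mask <- if (length(imgs) == 6L) imgs[[6]] < 0.5 else NULL
  imgs <- lapply(imgs[1:5], function(m) {
    if (!is.null(mask)) m[mask] <- NA_real_
    m
  })
  names(imgs) <- band_names
  do.call(reflectance_raster, imgs)
}

#' Read a ROI table
#'
#' Reads rectangular region-of-interest definitions from a CSV with columns
#' `plot_id,row,col,height,width`; `row`/`col` are the 0-based top-left
#' pixel of the rectangle, which covers the half-open window
#' `[row, row+height) x [col, col+width)`.
#'
#' @param file CSV path.
#' @return data.frame of ROI specs.
#' @export
read_rois <- function(file) {
  read_checked_csv(file, c("plot_id", "row", "col", "height", "width"),
                   numeric_cols = c("row", "col", "height", "width"))
}

#' Extract per-plot mean reflectance from ROIs
#'
#' For each rectangular ROI, computes the arithmetic mean of each band over
#' the ROI's non-nodata pixels, yielding one 5-band plot reflectance per
#' ROI — the plot-level summary normally taken over a fixed window (e.g.
#' 100 x 100 pixels) inside each plot of an orthomosaic. A plot whose ROI is
#' entirely nodata in some band gets `NA` for that band and is listed in the
#' `"flagged_missing"` attribute.
#'
#' @param raster a [reflectance_raster()].
#' @param rois data.frame with columns `plot_id`, `row`, `col`, `height`,
#'   `width` (0-based top-left origin, half-open extents).
#' @param stage stage label copied into the output (default `NA`).
#' @return data.frame `plot_id`, `stage`, `blue`, `green`, `red`,
#'   `red_edge`, `nir`.
#' @export
extract_roi_means <- function(raster, rois, stage = NA_character_) {
  nr <- nrow(raster$blue)
  nc <- ncol(raster$blue)
  flagged <- character(0)
  rows <- lapply(seq_len(nrow(rois)), function(i) {
    r0 <- rois$row[i]
    c0 <- rois$col[i]
    h <- rois$height[i]
    w <- rois$width[i]
    if (h < 1 || w < 1 || r0 < 0 || c0 < 0 || r0 + h > nr || c0 + w > nc) {
      stop("ROI for plot '", rois$plot_id[i], "' is out of raster bounds (",
           nr, "x", nc, ")")
    }
    vals <- vapply(band_names, function(b) {
      px <- raster[[b]][(r0 + 1):(r0 + h), (c0 + 1):(c0 + w)]
      if (all(is.na(px))) NA_real_ else mean(px, na.rm = TRUE)
    }, numeric(1))
    if (anyNA(vals)) flagged <<- c(flagged, rois$plot_id[i])
    data.frame(plot_id = rois$plot_id[i], stage = stage,
               blue = vals[["blue"]], green = vals[["green"]],
               red = vals[["red"]], red_edge = vals[["red_edge"]],
               nir = vals[["nir"]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "flagged_missing") <- flagged
  out
}

#' Build a fixture raster with known block-mean reflectance
#'
#' Tiles one constant (optionally noisy) block per plot into a 5-band
#' raster and returns matching ROI specs, so that
#' `extract_roi_means(make_fixture_raster(x)$raster, ...)` reproduces `x`
#' exactly in the noiseless case (and within sampling error of the block
#' mean when `pixel_noise_sd > 0`). Deterministic for a given seed.
#'
#' @param reflectance data.frame of target plot reflectance (columns
#'   `plot_id`, `blue`, `green`, `red`, `red_edge`, `nir`).
#' @param block_size ROI block edge in pixels, `c(height, width)`
#'   (default 100 x 100).
#' @param gap pixels of zero-reflectance background between blocks.
#' @param pixel_noise_sd per-pixel additive Gaussian noise sd (default 0).
#' @param seed integer seed for the pixel noise.
#' @param max_dim maximum allowed raster edge (default 2000 pixels).
#' @return list with `raster` (a [reflectance_raster()]) and `rois` (a ROI
#'   data.frame usable with [extract_roi_means()]).
#' @export
make_fixture_raster <- function(reflectance, block_size = c(100L, 100L),
                                gap = 10L, pixel_noise_sd = 0, seed = 1L,
                                max_dim = 2000L) {
  n <- nrow(reflectance)
  bh <- block_size[1]
  bw <- block_size[2]
  ncols <- max(1L, ceiling(sqrt(n)))
  nrows <- ceiling(n / ncols)
  H <- nrows * (bh + gap) + gap
  W <- ncols * (bw + gap) + gap
  if (H > max_dim || W > max_dim) {
    stop("layout of ", n, " blocks exceeds the maximum raster size (",
         max_dim, "x", max_dim, ")")
  }
  bands <- lapply(band_names, function(b) matrix(0, H, W))
  names(bands) <- band_names

  set.seed(seed)
  rois <- vector("list", n)
  for (i in seq_len(n)) {
    gr <- (i - 1) %/% ncols
    gc <- (i - 1) %% ncols
    r0 <- gap + gr * (bh + gap)
    c0 <- gap + gc * (bw + gap)
    for (b in band_names) {
      block <- matrix(reflectance[[b]][i], bh, bw)
      if (pixel_noise_sd > 0) {
        block <- block + matrix(stats::rnorm(bh * bw, 0, pixel_noise_sd), bh, bw)
      }
      bands[[b]][(r0 + 1):(r0 + bh), (c0 + 1):(c0 + bw)] <- block
    }
    rois[[i]] <- data.frame(plot_id = reflectance$plot_id[i], row = r0,
                            col = c0, height = bh, width = bw,
                            stringsAsFactors = FALSE)
  }
  list(raster = do.call(reflectance_raster, bands),
       rois = do.call(rbind, rois))
}
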