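#' Names of the supported vegetation indices
#'
#' The 17 chlorophyll-related broadband indices computable from 5-band
#' (blue / green / red / red-edge / NIR) reflectance, with band centers at
#' 475 / 560 / 668 / 717 / 842 nm. All but CCCI are per-plot functions of
#' the plot's band reflectances; CCCI is NDRE min–max rescaled over all
#' plots of one stage/date (see [compute_ccci()]).
#'
#' @return Character vector of length 17.
#' @export
vi_names <- function() {
  c("NDVI", "NDCI", "NDRE", "GNDVI", "PPR", "CCCI", "MTCI", "SR",
    "CIred_edge", "CIgreen", "TCARI", "TVI", "mTVI", "MCARI",
    "mNDblue", "EVI", "DVI")
}

#' Compute one vegetation index from band reflectance
#'
#' Evaluates a single index by its published broadband formula on
#' fractional reflectance, e.g. NDVI = (NIR - red)/(NIR + red),
#' MTCI = (NIR - re)/(re - red), EVI = 2.5 (NIR - red)/(NIR + 6 red -
#' 7.5 blue + 1). Formulas are applied to fractional reflectance exactly as
#' written (no percent rescaling of the triangular/absorption indices).
#' A zero ratio denominator yields `NA`, never infinity. `mNDblue` here is
#' (blue - re)/(blue + NIR), the red-edge variant; note that other
#' definitions of mNDblue circulate in the literature.
#'
#' CCCI is a campaign-normalized index and cannot be computed from a single
#' plot; request it through [compute_ccci()] or [build_vi_table()].
#'
#' @param index one of [vi_names()] except `"CCCI"`.
#' @param blue,green,red,red_edge,nir fractional reflectance in (0, 1);
#'   vectorized over plots.
#' @return Numeric vector of index values (`NA` where undefined).
#' @examples
#' compute_vi("NDVI", nir = 0.5, red = 0.1)        # 0.6667
#' compute_vi("MTCI", nir = 0.45, red_edge = 0.30, red = 0.10)  # 0.75
#' @export
compute_vi <- function(index, blue = NULL, green = NULL, red = NULL,
                       red_edge = NULL, nir = NULL) {
  if (!index %in% vi_names()) {
    stop("unknown vegetation index '", index, "'; supported: ",
         paste(vi_names(), collapse = ", "))
  }
  if (index == "CCCI") {
    stop("CCCI is normalized over a campaign; use compute_ccci() or build_vi_table()")
  }
  safe_div <- function(num, den) ifelse(den == 0, NA_real_, num / den)
  switch(index,
    NDVI = safe_div(nir - red, nir + red),
    NDCI = safe_div(red_edge - red, red_edge + red),
    NDRE = safe_div(nir - red_edge, nir + red_edge),
    GNDVI = safe_div(nir - green, nir + green),
    PPR = safe_div(green - blue, green + blue),
    MTCI = safe_div(nir - red_edge, red_edge - red),
    SR = safe_div(nir, red),
    CIred_edge = safe_div(nir, red_edge) - 1,
    CIgreen = safe_div(nir, green) - 1,
    TCARI = 3 * ((red_edge - red) - 0.2 * (red_edge - green) *
                   safe_div(red_edge, red)),
    TVI = 60 * (nir - green) - 100 * (red - green),
    mTVI = 60 * (nir - green) - 100 * (red_edge - green),
    MCARI = (red_edge - red) - 0.2 * (red_edge - green) *
      safe_div(red_edge, red),
    mNDblue = safe_div(blue - red_edge, blue + nir),
    EVI = 2.5 * safe_div(nir - red, nir + 6 * red - 7.5 * blue + 1),
    DVI = nir - red
  )
}

#' Canopy chlorophyll content index (CCCI)
#'
#' Min–max rescaling of NDRE over the plots of one campaign/date:
#' `CCCI = (NDRE - NDRE_min) / (NDRE_max - NDRE_min)`. The plot at the
#' campaign minimum maps to 0, the maximum to 1, and CCCI is invariant to
#' any increasing affine transform applied to all NDRE values. The
#' normalization population should be all plot ROIs of the same flight
#' date/stage.
#'
#' @param ndre numeric vector of NDRE values for the normalization set
#'   (at least 2 distinct values).
#' @return CCCI values in `[0, 1]`, same length as `ndre`.
#' @export
compute_ccci <- function(ndre) {
  ndre_ok <- ndre[!is.na(ndre)]
  if (length(unique(ndre_ok)) < 2) {
    stop("CCCI normalization undefined: need >= 2 distinct NDRE values")
  }
  (ndre - min(ndre_ok)) / (max(ndre_ok) - min(ndre_ok))
}

#' Build the full 17-index table for one stage
#'
#' Computes every supported index for each plot of one stage, normalizing
#' CCCI within the supplied plot set. Undefined values (zero denominators;
#' CCCI with a degenerate normalization set) are carried as `NA`, and
#' per-index `NA` counts are attached as the `"n_missing"` attribute.
#'
#' @param reflectance data.frame with columns `plot_id`, `stage`, `blue`,
#'   `green`, `red`, `red_edge`, `nir`; all rows must share one stage label.
#' @return data.frame: `plot_id`, `stage`, then one column per index in
#'   [vi_names()] order.
#' @export
build_vi_table <- function(reflectance) {
  if (nrow(reflectance) == 0) stop("empty reflectance collection")
  if (length(unique(reflectance$stage)) != 1) {
    stop("all plots must share one stage label; got: ",
         paste(unique(reflectance$stage), collapse = ", "))
  }
  out <- reflectance[, c("plot_id", "stage")]
  for (idx in setdiff(vi_names(), "CCCI")) {
    out[[idx]] <- compute_vi(
      idx,
      blue = reflectance$blue, green = reflectance$green,
      red = reflectance$red, red_edge = reflectance$red_edge,
      nir = reflectance$nir
    )
  }
  out$CCCI <- tryCatch(compute_ccci(out$NDRE), error = function(e) {
    rep(NA_real_, nrow(out))
  })
  out <- out[, c("plot_id", "stage", vi_names())]
  counts <- vapply(vi_names(), function(v) sum(is.na(out[[v]])), integer(1))
  attr(out, "n_missing") <- counts
  out
}
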