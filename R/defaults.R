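# Reference parameter set for the synthetic generator: Lorentz triples per
# nitrogen treatment (N0-N6, 0-400 kg N/ha) and growth stage, from a
# two-season split-plot maize trial. Vegetative stages peak around leaf 4-5,
# reproductive stages around the ear leaves (12-14), and both the peak SPAD
# and the width grow with nitrogen rate and stage.

#' Default Lorentz ground-truth parameters
#'
#' Returns the built-in table of Lorentz peak parameters (`spad_m`, `n_m`,
#' `b`) for seven nitrogen treatments (N0–N6) at four growth stages (V6, V9,
#' R1, R2). These are the default generating parameters of the synthetic
#' campaign generator and the reference triples for round-trip fitting
#' checks.
#'
#' @return data.frame with columns `n_treatment`, `stage`, `spad_m`, `n_m`, `b`.
#' @export
default_lorentz_params <- function() {
  tab <- rbind(
    # treatment, spad_m, n_m, b for V6 | V9 | R1 | R2
    c("N0", 39.16, 4, 6.51,  41.80, 4, 7.01,   48.69, 12, 8.24,  47.62, 14, 10.58),
    c("N1", 42.12, 4, 6.99,  47.94, 4, 8.92,   56.58, 13, 10.56, 57.12, 13, 9.83),
    c("N2", 40.48, 4, 6.83,  49.55, 4, 8.87,   58.37, 13, 10.26, 57.92, 12, 12.27),
    c("N3", 41.75, 4, 6.18,  51.92, 5, 8.17,   57.06, 13, 11.49, 55.28, 12, 13.40),
    c("N4", 46.00, 5, 8.32,  54.40, 5, 8.55,   59.33, 13, 11.09, 59.20, 14, 13.02),
    c("N5", 47.40, 4, 6.90,  53.89, 4, 8.77,   58.29, 12, 12.87, 58.86, 12, 12.08),
    c("N6", 47.22, 4, 7.42,  54.40, 4, 10.03,  57.77, 13, 10.94, 58.11, 14, 14.56)
  )
  stages <- c("V6", "V9", "R1", "R2")
  out <- do.call(rbind, lapply(seq_along(stages), function(k) {
    data.frame(
      n_treatment = tab[, 1],
      stage = stages[k],
      spad_m = as.numeric(tab[, 3 * k - 1]),
      n_m = as.numeric(tab[, 3 * k]),
      b = as.numeric(tab[, 3 * k + 1]),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Default stage leaf-position ranges
#'
#' Inclusive leaf-position ranges measured at each growth stage. Early
#' stages start at the first leaf; at silking (R1) and blister (R2) the
#' lowest leaves have senesced, so counting starts at leaf 6, and top-leaf
#' shedding shortens R2 by one position.
#'
#' @return Named list of integer vectors `c(first, last)`.
#' @export
default_leaf_ranges <- function() {
  list(V6 = c(1L, 6L), V9 = c(1L, 9L), R1 = c(6L, 20L), R2 = c(6L, 19L))
}

#' Default sensitive leaf positions per stage
#'
#' The leaf position whose SPAD is most strongly coupled to canopy-level
#' reflectance at each stage; used by the synthetic generator as the leaf
#' that drives the red-edge/NIR contrast.
#'
#' @return Named integer vector over stages V6, V9, R1, R2.
#' @export
default_sensitive_positions <- function() {
  c(V6 = 6L, V9 = 4L, R1 = 12L, R2 = 12L)
}
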