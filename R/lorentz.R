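#' Lorentz peak distribution function
#'
#' Evaluates the three-parameter Lorentz (Cauchy-type) peak function used to
#' describe the bell-shaped vertical distribution of SPAD values in a maize
#' canopy:
#' \deqn{SPAD(n) = SPAD_m / (1 + ((n - n_m)/b)^2)}
#' where `spad_m` is the peak SPAD value, `n_m` the leaf position at which
#' the peak occurs (counted from the bottom of the canopy) and `b` a width /
#' slope coefficient in leaf-position units. The curve is symmetric about
#' `n_m`, equals `spad_m / 2` at `n = n_m +- b`, and decays monotonically as
#' `|n - n_m|` grows. The function is even in `b`; the positive
#' representative is the canonical sign.
#'
#' @param n leaf position(s), real-valued; vectorized.
#' @param spad_m peak SPAD value (> 0).
#' @param n_m leaf position of the peak.
#' @param b width coefficient in leaf positions; must be non-zero.
#' @return SPAD value(s) at `n`.
#' @examples
#' lorentz_evaluate(4, spad_m = 39.16, n_m = 4, b = 6.51)   # 39.16 (peak)
#' lorentz_evaluate(15, spad_m = 50, n_m = 10, b = 5)       # 25 (half peak)
#' @export
lorentz_evaluate <- function(n, spad_m, n_m, b) {
  if (any(b == 0)) stop("Lorentz width parameter b must be non-zero")
  spad_m / (1 + ((n - n_m) / b)^2)
}

#' Fit the Lorentz peak function to one vertical SPAD profile
#'
#' Least-squares estimation of `(spad_m, n_m, b)` from paired (leaf
#' position, SPAD) observations, minimizing
#' \eqn{\sum_i (SPAD_i - Lorentz(n_i))^2} with a Levenberg-Marquardt
#' optimizer. Initial values are taken from the data (peak at the observed
#' maximum, width at half the observed position range) and box constraints
#' keep the parameters in the physically meaningful region; `b` is always
#' reported with positive sign. `n_m` is estimated as a continuous quantity
#' even though observed leaf positions are integers.
#'
#' @param leaf_position integer-valued vector of leaf positions; at least 3
#'   distinct positions are required to identify the 3 parameters.
#' @param spad SPAD values (>= 0) paired with `leaf_position`.
#' @return A list of class `lorentz_fit` with elements `spad_m`, `n_m`, `b`,
#'   `r2`, `rmse`, `n_obs`, `converged` and `fitted`. When the optimizer
#'   fails to converge, `converged` is `FALSE` and the parameters are the
#'   last iterate (flagged unusable rather than raising an error).
#' @examples
#' n <- 1:6
#' s <- lorentz_evaluate(n, 39.16, 4, 6.51)
#' fit_lorentz(n, s)$spad_m  # 39.16 recovered
#' @export
fit_lorentz <- function(leaf_position, spad) {
  if (length(leaf_position) != length(spad)) {
    stop("leaf_position and spad must have equal length")
  }
  keep <- !(is.na(leaf_position) | is.na(spad))
  leaf_position <- leaf_position[keep]
  spad <- spad[keep]
  if (length(unique(leaf_position)) < 3) {
    stop("insufficient data: need >= 3 distinct leaf positions to fit 3 parameters")
  }
  if (max(spad) == min(spad)) {
    stop("degenerate profile: all SPAD values are equal")
  }

  rng <- max(leaf_position) - min(leaf_position)
  start <- list(
    spad_m = max(spad),
    n_m = leaf_position[which.max(spad)],
    b = rng / 2
  )
  lower <- c(spad_m = 1e-6, n_m = min(leaf_position) - 2, b = 0.1)
  upper <- c(spad_m = 2 * max(spad), n_m = max(leaf_position) + 2, b = 3 * rng)

  dat <- data.frame(n = leaf_position, s = spad)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      s ~ spad_m / (1 + ((n - n_m) / b)^2),
      data = dat, start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(
        ftol = 1e-15, ptol = 1e-15, maxiter = 500, maxfev = 2000
      )
    ),
    error = function(e) e
  )

  if (inherits(fit, "error")) {
    out <- list(
      spad_m = NA_real_, n_m = NA_real_, b = NA_real_,
      r2 = NA_real_, rmse = NA_real_,
      n_obs = length(spad), converged = FALSE, fitted = rep(NA_real_, length(spad))
    )
    class(out) <- "lorentz_fit"
    return(out)
  }

  cf <- stats::coef(fit)
  pred <- lorentz_evaluate(leaf_position, cf[["spad_m"]], cf[["n_m"]], abs(cf[["b"]]))
  out <- list(
    spad_m = unname(cf[["spad_m"]]),
    n_m = unname(cf[["n_m"]]),
    b = abs(unname(cf[["b"]])),
    r2 = r_squared(spad, pred),
    rmse = rmse(spad, pred),
    n_obs = length(spad),
    converged = isTRUE(fit$convInfo$isConv),
    fitted = pred
  )
  class(out) <- "lorentz_fit"
  out
}

#' @export
print.lorentz_fit <- function(x, ...) {
  cat(sprintf(
    "Lorentz peak fit: SPAD_m = %.4f at n_m = %.4f, b = %.4f  (R2 = %.4f, RMSE = %.4f, n = %d%s)\n",
    x$spad_m, x$n_m, x$b, x$r2, x$rmse, x$n_obs,
    if (x$converged) "" else ", NOT CONVERGED"
  ))
  invisible(x)
}

#' Fit Lorentz parameters per nitrogen treatment and growth stage
#'
#' Groups a long-format profile table by `(n_treatment, stage)` and fits the
#' Lorentz peak function to each group, producing the per-treatment /
#' per-stage parameter table. Two aggregation modes are available:
#'
#' * `"mean"` (default): the leaf-position-wise mean SPAD across the group's
#'   plots is computed first and a single fit is performed on that mean
#'   profile. This matches the usual presentation of one fitted curve
#'   through per-position means with error bars.
#' * `"pooled"`: all (position, SPAD) observations of the group enter one
#'   least-squares fit without averaging.
#'
#' @param profiles data.frame with columns `plot_id`, `n_treatment`,
#'   `stage`, `leaf_position`, `spad` (extra columns ignored).
#' @param aggregation `"mean"` or `"pooled"`.
#' @return data.frame with one row per group: `n_treatment`, `stage`,
#'   `spad_m`, `n_m`, `n_m_rounded`, `b`, `r2`, `rmse`, `n_obs`,
#'   `converged`, `error` (NA or the failure message; a failed group is
#'   reported, never a crash). Groups with no rows are listed in the
#'   `"skipped"` attribute.
#' @export
fit_campaign <- function(profiles, aggregation = c("mean", "pooled")) {
  aggregation <- match.arg(aggregation)
  need <- c("n_treatment", "stage", "leaf_position", "spad")
  miss <- setdiff(need, names(profiles))
  if (length(miss)) stop("profiles is missing columns: ", paste(miss, collapse = ", "))

  groups <- unique(profiles[, c("n_treatment", "stage")])
  groups <- groups[order(groups$n_treatment, groups$stage), , drop = FALSE]

  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- profiles[profiles$n_treatment == groups$n_treatment[i] &
                    profiles$stage == groups$stage[i], ]
    if (aggregation == "mean") {
      m <- stats::aggregate(spad ~ leaf_position, data = g, FUN = mean)
      pos <- m$leaf_position
      val <- m$spad
    } else {
      pos <- g$leaf_position
      val <- g$spad
    }
    res <- tryCatch(fit_lorentz(pos, val), error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(
        n_treatment = groups$n_treatment[i], stage = groups$stage[i],
        spad_m = NA_real_, n_m = NA_real_, n_m_rounded = NA_integer_,
        b = NA_real_, r2 = NA_real_, rmse = NA_real_,
        n_obs = length(val), converged = FALSE,
        error = conditionMessage(res), stringsAsFactors = FALSE
      )
    } else {
      data.frame(
        n_treatment = groups$n_treatment[i], stage = groups$stage[i],
        spad_m = res$spad_m, n_m = res$n_m,
        n_m_rounded = as.integer(round(res$n_m)),
        b = res$b, r2 = res$r2, rmse = res$rmse,
        n_obs = res$n_obs, converged = res$converged,
        error = NA_character_, stringsAsFactors = FALSE
      )
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "skipped") <- character(0)
  out
}

#' Validate a fitted parameter table against independent profiles
#'
#' For every observation in a validation profile set, predicts SPAD from the
#' Lorentz parameters of the observation's `(n_treatment, stage)` group and
#' pools predicted vs observed values per stage. Typical use is cross-season
#' validation: parameters fitted on one season's campaign, profiles from
#' another.
#'
#' @param params parameter table as returned by [fit_campaign()] (columns
#'   `n_treatment`, `stage`, `spad_m`, `n_m`, `b`).
#' @param profiles validation profiles, same layout as in [fit_campaign()].
#' @return data.frame with one row per stage: `stage`, `r2`, `rmse`, `n`.
#'   Treatments absent from `params` are excluded and listed in the
#'   `"excluded_treatments"` attribute.
#' @export
validate_fit <- function(params, profiles) {
  key_p <- paste(params$n_treatment, params$stage, sep = "\r")
  key_o <- paste(profiles$n_treatment, profiles$stage, sep = "\r")
  ok <- key_o %in% key_p[!is.na(params$spad_m)]
  excluded <- sort(unique(profiles$n_treatment[!ok]))
  obs <- profiles[ok, ]
  if (nrow(obs) == 0) stop("no validation observations have matching parameters")

  idx <- match(paste(obs$n_treatment, obs$stage, sep = "\r"), key_p)
  pred <- lorentz_evaluate(obs$leaf_position,
                           params$spad_m[idx], params$n_m[idx], params$b[idx])

  stages <- unique(obs$stage)
  out <- do.call(rbind, lapply(stages, function(st) {
    sel <- obs$stage == st
    data.frame(
      stage = st,
      r2 = r_squared(obs$spad[sel], pred[sel]),
      rmse = rmse(obs$spad[sel], pred[sel]),
      n = sum(sel), stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  attr(out, "excluded_treatments") <- excluded
  out
}
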