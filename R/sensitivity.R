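#' Descriptive summary of vertical SPAD profiles
#'
#' Summarizes the vertical distribution per (stage, nitrogen treatment):
#' the leaf position at which the position-wise mean profile peaks, the
#' mean canopy SPAD (mean of per-plot canopy means), and a bell-shape flag
#' that is `TRUE` when the peak sits strictly inside the measured leaf
#' range — the rise-then-fall signature typical of maize canopies.
#'
#' @param profiles long-format profile table (see [generate_profiles()]).
#' @return data.frame: `stage`, `n_treatment`, `peak_position`,
#'   `mean_canopy_spad`, `bell_shaped`, `n_plots`.
#' @export
describe_profiles <- function(profiles) {
  groups <- unique(profiles[, c("stage", "n_treatment")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- profiles[profiles$stage == groups$stage[i] &
                    profiles$n_treatment == groups$n_treatment[i], ]
    m <- stats::aggregate(spad ~ leaf_position, data = g, FUN = mean)
    m <- m[order(m$leaf_position), ]
    peak_idx <- which.max(m$spad)
    canopy <- stats::aggregate(spad ~ plot_id, data = g, FUN = mean)
    data.frame(
      stage = groups$stage[i], n_treatment = groups$n_treatment[i],
      peak_position = m$leaf_position[peak_idx],
      mean_canopy_spad = mean(canopy$spad),
      bell_shaped = peak_idx > 1 && peak_idx < nrow(m),
      n_plots = length(unique(g$plot_id)), stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble the per-stage dataset for sensitivity and inversion analysis
#'
#' Aligns, for one growth stage, the per-plot canopy-mean SPAD, the
#' per-leaf-position SPAD matrix, and the vegetation-index table by
#' `plot_id`. Plots present in only one of the two sources are dropped.
#'
#' @param profiles long-format SPAD profiles.
#' @param vi_table index table from [build_vi_table()] for the same stage.
#' @param stage stage label to subset `profiles` on.
#' @return A list of class `stage_dataset` with elements `stage`,
#'   `plot_id`, `canopy_spad` (vector), `leaf_spad` (plots x positions
#'   matrix, columns named by position), and `vi` (data.frame of the 17
#'   index columns).
#' @export
stage_dataset <- function(profiles, vi_table, stage) {
  p <- profiles[profiles$stage == stage, ]
  if (nrow(p) == 0) stop("no profiles for stage ", stage)
  ids <- intersect(unique(p$plot_id), vi_table$plot_id)
  if (length(ids) == 0) stop("no plot ids shared between profiles and VI table")
  p <- p[p$plot_id %in% ids, ]

  positions <- sort(unique(p$leaf_position))
  leaf <- matrix(NA_real_, length(ids), length(positions),
                 dimnames = list(ids, as.character(positions)))
  for (k in seq_len(nrow(p))) {
    leaf[p$plot_id[k], as.character(p$leaf_position[k])] <- p$spad[k]
  }
  canopy <- rowMeans(leaf, na.rm = TRUE)

  vi <- vi_table[match(ids, vi_table$plot_id), vi_names(), drop = FALSE]
  structure(
    list(stage = stage, plot_id = ids, canopy_spad = unname(canopy),
         leaf_spad = leaf, vi = vi),
    class = "stage_dataset"
  )
}

# pairwise-complete Pearson r between two vectors; NULL when not computable
pairwise_r <- function(x, y) {
  ok <- !(is.na(x) | is.na(y))
  if (sum(ok) < 3) return(NULL)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NULL)
  pearson_r(x[ok], y[ok])
}

#' Rank vegetation indices by correlation with canopy SPAD
#'
#' Computes the Pearson correlation of every index with the canopy-mean
#' SPAD over the stage's plots and orders indices by descending r (signed,
#' not absolute), ties broken alphabetically by index name. Constant or
#' incomputable index columns are excluded and reported in the
#' `"excluded"` attribute.
#'
#' @param dataset a [stage_dataset()]; needs at least 3 plots.
#' @return data.frame: `stage`, `rank`, `vi`, `r`, `p`, `n`.
#' @export
rank_vis <- function(dataset) {
  if (length(dataset$plot_id) < 3) {
    stop("need at least 3 plots to correlate indices with canopy SPAD")
  }
  excluded <- character(0)
  rows <- lapply(vi_names(), function(v) {
    res <- pairwise_r(dataset$vi[[v]], dataset$canopy_spad)
    if (is.null(res)) {
      excluded <<- c(excluded, v)
      return(NULL)
    }
    data.frame(stage = dataset$stage, vi = v, r = res$r, p = res$p,
               n = res$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) stop("no usable vegetation index columns")
  out <- out[order(-out$r, out$vi), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out <- out[, c("stage", "rank", "vi", "r", "p", "n")]
  attr(out, "excluded") <- excluded
  out
}

#' Locate the leaf position most sensitive to a vegetation index
#'
#' Correlates the chosen index with SPAD at every leaf position across the
#' stage's plots (pairwise-complete per position) and returns the position
#' with the largest correlation. By default the signed maximum is taken
#' (canopy reflectance contrasts increase with chlorophyll, so sensitivity
#' profiles are positive); set `use_abs = TRUE` to maximize |r| instead.
#' Ties go to the lower position; positions with constant or insufficient
#' SPAD are excluded and reported.
#'
#' @param dataset a [stage_dataset()].
#' @param vi_name one of [vi_names()].
#' @param use_abs maximize |r| instead of signed r (default `FALSE`).
#' @return list with `position`, `r`, and `profile` (data.frame
#'   `leaf_position`, `r`, `p`, `n`); excluded positions in the
#'   `"excluded_positions"` attribute of `profile`.
#' @export
find_sensitive_leaf <- function(dataset, vi_name, use_abs = FALSE) {
  if (!vi_name %in% vi_names()) stop("unknown vegetation index '", vi_name, "'")
  vi <- dataset$vi[[vi_name]]
  positions <- as.integer(colnames(dataset$leaf_spad))
  excluded <- integer(0)
  rows <- lapply(seq_along(positions), function(j) {
    res <- pairwise_r(vi, dataset$leaf_spad[, j])
    if (is.null(res)) {
      excluded <<- c(excluded, positions[j])
      return(NULL)
    }
    data.frame(leaf_position = positions[j], r = res$r, p = res$p,
               n = res$n)
  })
  profile <- do.call(rbind, rows)
  if (is.null(profile) || nrow(profile) == 0) {
    stop("no leaf position has enough non-constant SPAD data")
  }
  score <- if (use_abs) abs(profile$r) else profile$r
  best <- which(score == max(score))[1]  # profile is position-ordered: ties -> lower
  attr(profile, "excluded_positions") <- excluded
  list(position = profile$leaf_position[best], r = profile$r[best],
       profile = profile)
}

#' Fit a simple linear SPAD inversion model from one vegetation index
#'
#' Ordinary least squares of SPAD on one index, `SPAD = intercept +
#' slope * VI`, on a training subset of plots; evaluated (R2, RMSE, nRMSE)
#' on both the training plots and an optional disjoint test set. The SPAD
#' target is either the canopy mean or the SPAD at one leaf position (the
#' sensitive-leaf model). Without a test set the model is flagged
#' `resubstitution` and test metrics repeat the training plots.
#'
#' @param dataset a [stage_dataset()].
#' @param vi_name one of [vi_names()].
#' @param target `"canopy_mean"` or `"sensitive_leaf"`.
#' @param position leaf position for `target = "sensitive_leaf"`.
#' @param train_ids plot ids used for fitting (>= 3).
#' @param test_ids plot ids for evaluation, disjoint from `train_ids`;
#'   `NULL` for resubstitution.
#' @return list of class `stage_inversion_model`: `stage`, `vi_name`,
#'   `target`, `position`, `intercept`, `slope`, `train`, `test`
#'   (metric blocks), `resubstitution`, `train_ids`, `test_ids`.
#' @export
fit_inversion <- function(dataset, vi_name,
                          target = c("canopy_mean", "sensitive_leaf"),
                          position = NULL, train_ids = dataset$plot_id,
                          test_ids = NULL) {
  target <- match.arg(target)
  if (!vi_name %in% vi_names()) stop("unknown vegetation index '", vi_name, "'")
  resub <- is.null(test_ids) || length(test_ids) == 0
  if (!resub && length(intersect(train_ids, test_ids))) {
    stop("train and test plot ids must be disjoint")
  }

  y_all <- if (target == "canopy_mean") {
    dataset$canopy_spad
  } else {
    if (is.null(position)) stop("target 'sensitive_leaf' requires a position")
    dataset$leaf_spad[, as.character(position)]
  }
  x_all <- dataset$vi[[vi_name]]

  tr <- match(train_ids, dataset$plot_id)
  te <- if (resub) tr else match(test_ids, dataset$plot_id)
  if (anyNA(tr) || anyNA(te)) stop("unknown plot ids in train/test split")
  ok_tr <- tr[!(is.na(x_all[tr]) | is.na(y_all[tr]))]
  if (length(ok_tr) < 3) stop("need at least 3 training plots with data")
  if (stats::sd(x_all[ok_tr]) == 0) {
    stop("vegetation index is constant on the training set")
  }

  fit <- stats::lm(y ~ x, data = data.frame(x = x_all[ok_tr], y = y_all[ok_tr]))
  cf <- stats::coef(fit)
  pred <- function(idx) cf[[1]] + cf[[2]] * x_all[idx]
  ok_te <- te[!(is.na(x_all[te]) | is.na(y_all[te]))]

  structure(
    list(
      stage = dataset$stage, vi_name = vi_name, target = target,
      position = if (target == "sensitive_leaf") position else NA_integer_,
      intercept = unname(cf[[1]]), slope = unname(cf[[2]]),
      train = metric_block(y_all[ok_tr], pred(ok_tr)),
      test = metric_block(y_all[ok_te], pred(ok_te)),
      resubstitution = resub,
      train_ids = dataset$plot_id[ok_tr],
      test_ids = dataset$plot_id[ok_te]
    ),
    class = "stage_inversion_model"
  )
}

#' Compare a sensitive-leaf model against a canopy-mean model
#'
#' Reports the relative improvement in test R-squared of the sensitive-leaf
#' model over the canopy-mean model,
#' `100 * (r2_sensitive - r2_canopy) / r2_canopy`, rounded to the nearest
#' integer percent, along with the absolute R2 and RMSE deltas. Both models
#' must come from the same stage and index and share the same test plots.
#'
#' @param model_sensitive,model_canopy [fit_inversion()] results with
#'   targets `sensitive_leaf` and `canopy_mean`.
#' @return list: `stage`, `vi_name`, `r2_sensitive`, `r2_canopy`,
#'   `improvement_pct`, `delta_r2`, `delta_rmse`.
#' @export
compare_models <- function(model_sensitive, model_canopy) {
  if (model_sensitive$stage != model_canopy$stage ||
      model_sensitive$vi_name != model_canopy$vi_name) {
    stop("models must share stage and vegetation index")
  }
  if (!identical(sort(model_sensitive$test_ids), sort(model_canopy$test_ids))) {
    stop("models must be evaluated on the same test plots")
  }
  r2_s <- model_sensitive$test$r2
  r2_c <- model_canopy$test$r2
  list(
    stage = model_sensitive$stage, vi_name = model_sensitive$vi_name,
    r2_sensitive = r2_s, r2_canopy = r2_c,
    improvement_pct = round(100 * (r2_s - r2_c) / r2_c),
    delta_r2 = r2_s - r2_c,
    delta_rmse = model_sensitive$test$rmse - model_canopy$test$rmse
  )
}

#' Predict per-plot SPAD from a fitted inversion model
#'
#' Applies `intercept + slope * VI` to every plot of an index table — the
#' tabular counterpart of a plot-level predicted-SPAD map. Missing index
#' values propagate to missing predictions, counted in the `"n_missing"`
#' attribute.
#'
#' @param model a [fit_inversion()] result.
#' @param vi_table index table from [build_vi_table()].
#' @return data.frame `plot_id`, `stage`, `predicted_spad`.
#' @export
predict_spad_map <- function(model, vi_table) {
  x <- vi_table[[model$vi_name]]
  out <- data.frame(
    plot_id = vi_table$plot_id, stage = vi_table$stage,
    predicted_spad = model$intercept + model$slope * x,
    stringsAsFactors = FALSE
  )
  attr(out, "n_missing") <- sum(is.na(out$predicted_spad))
  out
}
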