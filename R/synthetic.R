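#' Configuration for a synthetic SPAD / reflectance campaign
#'
#' Describes one simulated field campaign mimicking a split-plot maize
#' nitrogen trial: nitrogen treatments are the main plots, varieties are
#' randomized within treatment, and the whole layout is replicated. Each
#' plot is visited at each growth stage, yielding one vertical SPAD profile
#' and one 5-band plot reflectance per visit.
#'
#' @param n_treatments character vector of nitrogen-level labels (main-plot
#'   factor), default `N0`–`N6` (0–400 kg N/ha).
#' @param varieties number of varieties per treatment (default 10).
#' @param reps number of replicates (default 3).
#' @param stages ordered subset of `c("V6","V9","R1","R2")`.
#' @param leaf_ranges named list `stage -> c(first, last)` inclusive leaf
#'   positions; each range must span at least 3 positions so the
#'   3-parameter Lorentz fit stays identifiable.
#' @param spad_noise_sd standard deviation of additive Gaussian measurement
#'   noise on SPAD values (SPAD units, >= 0). Default 1.5, a typical
#'   repeatability figure for plot-averaged handheld SPAD readings.
#' @param reflectance_noise_sd standard deviation of additive Gaussian noise
#'   on the latent NDRE contrast (reflectance units, >= 0). Default 0.02.
#' @param seed integer seed; all draws are derived from it by per-plot
#'   counter offsets, so each plot consumes its own RNG stream and plots
#'   appended at the end of the layout leave earlier plots' draws unchanged.
#' @return A list of class `campaign_config`.
#' @export
campaign_config <- function(n_treatments = paste0("N", 0:6),
                            varieties = 10L,
                            reps = 3L,
                            stages = c("V6", "V9", "R1", "R2"),
                            leaf_ranges = default_leaf_ranges(),
                            spad_noise_sd = 1.5,
                            reflectance_noise_sd = 0.02,
                            seed = 1L) {
  stages <- match.arg(stages, c("V6", "V9", "R1", "R2"), several.ok = TRUE)
  if (spad_noise_sd < 0 || reflectance_noise_sd < 0) {
    stop("noise standard deviations must be >= 0")
  }
  for (st in stages) {
    rg <- leaf_ranges[[st]]
    if (is.null(rg) || length(rg) != 2 || rg[2] - rg[1] + 1 < 3) {
      stop("leaf range for stage ", st, " must cover at least 3 positions")
    }
  }
  structure(
    list(
      n_treatments = n_treatments,
      varieties = as.integer(varieties),
      reps = as.integer(reps),
      stages = stages,
      leaf_ranges = leaf_ranges[stages],
      spad_noise_sd = spad_noise_sd,
      reflectance_noise_sd = reflectance_noise_sd,
      seed = as.integer(seed)
    ),
    class = "campaign_config"
  )
}

#' Ground truth for a synthetic campaign
#'
#' Bundles the generating Lorentz parameters per (treatment, stage), the
#' designated sensitive leaf position per stage, and the per-stage linear
#' link from sensitive-leaf SPAD to the latent NDRE contrast
#' (`contrast = a0 + a1 * SPAD`).
#'
#' @param params data.frame of Lorentz triples, columns `n_treatment`,
#'   `stage`, `spad_m`, `n_m`, `b` (default [default_lorentz_params()]).
#' @param sensitive named integer vector stage -> leaf position
#'   (default [default_sensitive_positions()]).
#' @param link_a0,link_a1 intercept and slope of the SPAD-to-NDRE-contrast
#'   link, shared across stages. Defaults (-0.10, 0.012) place NDRE in
#'   roughly 0.2–0.6 for SPAD 25–60, a plausible vegetated-canopy range.
#' @return A list of class `ground_truth`.
#' @export
ground_truth <- function(params = default_lorentz_params(),
                         sensitive = default_sensitive_positions(),
                         link_a0 = -0.10,
                         link_a1 = 0.012) {
  if (any(params$spad_m <= 0) || any(params$b <= 0)) {
    stop("generating parameters require spad_m > 0 and b > 0")
  }
  structure(
    list(params = params, sensitive = sensitive,
         link = c(a0 = link_a0, a1 = link_a1)),
    class = "ground_truth"
  )
}

# derive a per-plot RNG seed from the campaign seed and a plot counter;
# kept below 2^31 - 1
plot_seed <- function(seed, counter, stream = 0L) {
  (as.numeric(seed) * 48271 + counter * 131 + stream * 7919) %% 2147483629
}

plot_layout <- function(config) {
  grid <- expand.grid(
    rep = seq_len(config$reps),
    variety = paste0("C", seq_len(config$varieties)),
    n_treatment = config$n_treatments,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid <- grid[, c("n_treatment", "variety", "rep")]
  grid$plot_id <- sprintf("%s_%s_r%d", grid$n_treatment, grid$variety, grid$rep)
  grid
}

#' Generate synthetic vertical SPAD profiles
#'
#' Draws one vertical SPAD profile per plot and stage: the Lorentz curve of
#' the plot's (treatment, stage) ground-truth triple evaluated at the
#' stage's integer leaf positions, plus additive Gaussian measurement noise,
#' truncated below at 0 (SPAD readings are non-negative). Deterministic for
#' a given `config$seed`; each plot consumes its own derived RNG stream.
#'
#' @param config a [campaign_config()].
#' @param truth a [ground_truth()]; must supply parameters for every
#'   (treatment, stage) combination in `config`.
#' @return Long-format data.frame with columns `plot_id`, `variety`,
#'   `n_treatment`, `stage`, `leaf_position`, `spad`.
#' @export
generate_profiles <- function(config, truth = ground_truth()) {
  stopifnot(inherits(config, "campaign_config"))
  key <- paste(truth$params$n_treatment, truth$params$stage, sep = "\r")
  need <- expand.grid(t = config$n_treatments, s = config$stages,
                      stringsAsFactors = FALSE)
  missing_keys <- setdiff(paste(need$t, need$s, sep = "\r"), key)
  if (length(missing_keys)) {
    stop("ground truth lacks Lorentz parameters for: ",
         paste(gsub("\r", "/", missing_keys), collapse = ", "))
  }

  plots <- plot_layout(config)
  out <- vector("list", nrow(plots) * length(config$stages))
  k <- 0L
  for (i in seq_len(nrow(plots))) {
    for (j in seq_along(config$stages)) {
      st <- config$stages[j]
      rg <- config$leaf_ranges[[st]]
      pos <- seq.int(rg[1], rg[2])
      row <- truth$params[key == paste(plots$n_treatment[i], st, sep = "\r"), ]
      mu <- lorentz_evaluate(pos, row$spad_m, row$n_m, row$b)
      set.seed(plot_seed(config$seed, (i - 1L) * 8L + j, stream = 1L))
      spad <- pmax(0, mu + stats::rnorm(length(pos), 0, config$spad_noise_sd))
      k <- k + 1L
      out[[k]] <- data.frame(
        plot_id = plots$plot_id[i], variety = plots$variety[i],
        n_treatment = plots$n_treatment[i], stage = st,
        leaf_position = pos, spad = spad, stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate plot reflectance co-varying with sensitive-leaf SPAD
#'
#' For every plot and stage, builds 5-band mean reflectance whose red-edge /
#' NIR contrast tracks the SPAD value at the stage's designated sensitive
#' leaf position: a latent contrast `c = a0 + a1 * SPAD(sensitive) + noise`
#' is clamped into (0.01, 0.99) and realized as NDRE by holding NIR at a
#' fixed vegetation level and solving for the red-edge band,
#' `re = nir * (1 - NDRE) / (1 + NDRE)`. Blue, green and red are nuisance
#' draws from fixed plausible ranges, independent of SPAD. All bands lie in
#' (0, 1). If the unclamped contrast falls outside (0, 1) for more than 10%
#' of plots a warning reports the count.
#'
#' @param profiles profile table from [generate_profiles()].
#' @param truth the [ground_truth()] used to generate `profiles`.
#' @param config the matching [campaign_config()].
#' @param nir_level fixed NIR reflectance (default 0.45).
#' @return data.frame with columns `plot_id`, `stage`, `blue`, `green`,
#'   `red`, `red_edge`, `nir`.
#' @export
generate_reflectance <- function(profiles, truth, config, nir_level = 0.45) {
  stopifnot(inherits(config, "campaign_config"))
  a0 <- truth$link[["a0"]]
  a1 <- truth$link[["a1"]]
  plots <- unique(profiles[, c("plot_id", "stage")])
  plots <- plots[order(match(plots$plot_id, unique(profiles$plot_id))), ]

  n_clamped <- 0L
  rows <- vector("list", nrow(plots))
  plot_index <- match(plots$plot_id, unique(profiles$plot_id))
  stage_index <- match(plots$stage, c("V6", "V9", "R1", "R2"))
  for (i in seq_len(nrow(plots))) {
    st <- plots$stage[i]
    sens <- truth$sensitive[[st]]
    sel <- profiles$plot_id == plots$plot_id[i] & profiles$stage == st &
      profiles$leaf_position == sens
    if (!any(sel)) {
      stop("profiles lack the sensitive leaf position ", sens,
           " for stage ", st, " (plot ", plots$plot_id[i], ")")
    }
    spad_s <- profiles$spad[sel][1]
    set.seed(plot_seed(config$seed, (plot_index[i] - 1L) * 8L + stage_index[i],
                       stream = 2L))
    contrast <- a0 + a1 * spad_s +
      stats::rnorm(1, 0, config$reflectance_noise_sd)
    if (contrast <= 0 || contrast >= 1) n_clamped <- n_clamped + 1L
    ndre <- min(max(contrast, 0.01), 0.99)
    re <- nir_level * (1 - ndre) / (1 + ndre)
    rows[[i]] <- data.frame(
      plot_id = plots$plot_id[i], stage = st,
      blue = stats::runif(1, 0.03, 0.06),
      green = stats::runif(1, 0.06, 0.12),
      red = stats::runif(1, 0.04, 0.10),
      red_edge = re, nir = nir_level, stringsAsFactors = FALSE
    )
  }
  if (n_clamped > 0.1 * nrow(plots)) {
    warning("latent NDRE contrast clamped for ", n_clamped, " of ",
            nrow(plots), " plots (>10%)")
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Write / read a campaign to plain-text files
#'
#' `write_campaign()` serializes a campaign to a directory:
#' `spad_profiles.csv` (long-format profiles), `plot_reflectance.csv`
#' (5-band plot means), and, when `truth` is supplied,
#' `ground_truth.json` (nested treatment -> stage -> Lorentz triple plus
#' stage -> sensitive leaf). `read_campaign()` reads the same files back
#' into identical structures; malformed numeric cells raise a parse error
#' naming the file and row.
#'
#' @param profiles,reflectance data.frames as produced by
#'   [generate_profiles()] and [generate_reflectance()].
#' @param path directory to create/use.
#' @param truth optional [ground_truth()] to serialize alongside.
#' @return `write_campaign()` the path, invisibly; `read_campaign()` a list
#'   with `profiles`, `reflectance` and (if present on disk) `truth`.
#' @export
write_campaign <- function(profiles, reflectance, path, truth = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(format_full(profiles), file.path(path, "spad_profiles.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(format_full(reflectance),
                   file.path(path, "plot_reflectance.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(truth)) {
    tr <- split(truth$params, truth$params$n_treatment)
    nested <- lapply(tr, function(d) {
      st <- split(d[, c("spad_m", "n_m", "b")], d$stage)
      lapply(st, function(r) list(spad_m = r$spad_m, n_m = r$n_m, b = r$b))
    })
    jsonlite::write_json(
      list(params = nested, sensitive_leaf = as.list(truth$sensitive),
           link = as.list(truth$link)),
      file.path(path, "ground_truth.json"), auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' @rdname write_campaign
#' @export
read_campaign <- function(path) {
  profiles <- read_checked_csv(
    file.path(path, "spad_profiles.csv"),
    c("plot_id", "variety", "n_treatment", "stage", "leaf_position", "spad"),
    numeric_cols = c("leaf_position", "spad")
  )
  profiles$leaf_position <- as.integer(profiles$leaf_position)
  reflectance <- read_checked_csv(
    file.path(path, "plot_reflectance.csv"),
    c("plot_id", "stage", "blue", "green", "red", "red_edge", "nir"),
    numeric_cols = c("blue", "green", "red", "red_edge", "nir")
  )
  out <- list(profiles = profiles, reflectance = reflectance)
  gt_path <- file.path(path, "ground_truth.json")
  if (file.exists(gt_path)) {
    raw <- jsonlite::read_json(gt_path, simplifyVector = FALSE)
    params <- do.call(rbind, unlist(lapply(names(raw$params), function(tr) {
      lapply(names(raw$params[[tr]]), function(st) {
        p <- raw$params[[tr]][[st]]
        data.frame(n_treatment = tr, stage = st, spad_m = p$spad_m,
                   n_m = p$n_m, b = p$b, stringsAsFactors = FALSE)
      })
    }), recursive = FALSE))
    rownames(params) <- NULL
    out$truth <- ground_truth(
      params = params,
      sensitive = vapply(raw$sensitive_leaf, as.integer, integer(1)),
      link_a0 = raw$link$a0, link_a1 = raw$link$a1
    )
  }
  out
}

# render double columns at 17 significant digits so the CSV round trip is
# bit-exact (integers stay as-is)
format_full <- function(d) {
  for (col in names(d)) {
    if (is.double(d[[col]])) d[[col]] <- sprintf("%.17g", d[[col]])
  }
  d
}

# read a CSV, enforce the expected header, and validate numeric columns
# cell-by-cell so a bad value is reported with its row number
read_checked_csv <- function(file, columns, numeric_cols) {
  if (!file.exists(file)) stop("file not found: ", file)
  d <- utils::read.csv(file, colClasses = "character",
                       stringsAsFactors = FALSE)
  miss <- setdiff(columns, names(d))
  if (length(miss)) {
    stop("malformed file ", basename(file), ": missing columns ",
         paste(miss, collapse = ", "))
  }
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !is.na(d[[col]]) & nzchar(d[[col]]))
    if (length(bad)) {
      stop("parse error in ", basename(file), ", column '", col,
           "', row ", bad[1], ": '", d[[col]][bad[1]], "' is not numeric")
    }
    d[[col]] <- v
  }
  d
}
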