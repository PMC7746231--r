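HRF_SHAPE <- 4      # gamma shape: mean 6 s, SD 3 s  => shape (6/3)^2
HRF_SCALE <- 1.5    # gamma scale: SD^2 / mean

#' Gamma hemodynamic response kernel
#'
#' The canonical gamma HRF with mean lag 6 s, SD 3 s and phase 0 s
#' (gamma shape 4, scale 1.5; continuous-kernel mode at
#' `(shape - 1) * scale = 4.5` s). The kernel is evaluated on a grid
#' oversampled by `oversample` relative to the TR, then decimated to TR
#' resolution and normalized (unit sum by default, unit peak optionally).
#'
#' @param tr Repetition time in seconds.
#' @param duration Kernel support in seconds.
#' @param oversample Oversampling factor for the internal fine grid.
#' @param normalize `"sum"` (default) or `"peak"`.
#' @return Numeric kernel sampled at TR resolution, with attributes
#'   `shape`, `scale`, `mode_s` and `tr`.
#' @export
hrf_kernel <- function(tr, duration = 32, oversample = 16L,
                       normalize = c("sum", "peak")) {
  stopifnot(tr > 0)
  normalize <- match.arg(normalize)
  fine <- hrf_fine(tr / oversample, duration)
  k <- fine[seq(1, length(fine), by = oversample)]
  k <- switch(normalize, sum = k / sum(k), peak = k / max(k))
  base::structure(k, shape = HRF_SHAPE, scale = HRF_SCALE,
                  mode_s = (HRF_SHAPE - 1) * HRF_SCALE, tr = tr)
}

# fine-grid kernel, unit sum at the fine resolution
hrf_fine <- function(dt, duration = 32) {
  t <- seq(0, duration, by = dt)
  k <- dgamma(t, shape = HRF_SHAPE, scale = HRF_SCALE)
  k / sum(k)
}

# convolve a fine-grid amplitude series with the HRF and decimate to TR
convolve_to_tr <- function(amplitude_fine, dt, n_volumes, oversample) {
  k <- hrf_fine(dt)
  full <- convolve(amplitude_fine, rev(k), type = "open")[seq_along(amplitude_fine)]
  full[1 + (seq_len(n_volumes) - 1) * oversample]
}

#' Build a model-based GLM design matrix
#'
#' Three task regressors: all trial onsets, and the two parametric
#' modulators in which each trial's 5-s boxcar is scaled by the trial's
#' prototype- or exemplar-model representational match before convolution
#' with the gamma HRF. Both model predictors sit in the same matrix so
#' shared variance is accounted for. Modulators are not mean-centered by
#' default (the onset regressor carries the mean); `center_modulators`
#' switches to the demeaned variant.
#'
#' @param events Tibble with `onset` (s) and optionally `duration` columns,
#'   one row per trial.
#' @param match_proto,match_exem Per-trial representational match values
#'   (see [representational_match()]), aligned with `events`.
#' @param n_volumes Number of volumes in the run.
#' @param tr Repetition time (s).
#' @param duration Event duration (s) used when `events` has no `duration`
#'   column.
#' @param motion Optional matrix/data frame of nuisance regressors
#'   (e.g., 6 motion parameters), `n_volumes` rows.
#' @param center_modulators Mean-center the match values before scaling.
#' @param oversample Oversampling factor for convolution.
#' @return A `design_matrix`: a tibble with `time`, `onset`, `proto_mod`,
#'   `exem_mod` (+ nuisance columns), with TR and event metadata in
#'   attributes.
#' @export
build_design <- function(events, match_proto, match_exem, n_volumes, tr = 2,
                         duration = 5, motion = NULL,
                         center_modulators = FALSE, oversample = 16L) {
  n_ev <- nrow(events)
  stopifnot(length(match_proto) == n_ev, length(match_exem) == n_ev)
  run_len <- n_volumes * tr
  if (n_ev > 0 && any(events$onset < 0 | events$onset >= run_len))
    stop("event onset outside the run", call. = FALSE)
  dur <- if ("duration" %in% names(events)) events$duration
         else rep(duration, n_ev)
  if (center_modulators && n_ev > 0) {
    match_proto <- match_proto - mean(match_proto)
    match_exem <- match_exem - mean(match_exem)
  }
  dt <- tr / oversample
  n_fine <- n_volumes * oversample
  boxcar <- function(amplitudes) {
    a <- numeric(n_fine)
    for (i in seq_len(n_ev)) {
      from <- 1 + floor(events$onset[i] / dt)
      to <- min(n_fine, floor((events$onset[i] + dur[i]) / dt))
      a[from:to] <- a[from:to] + amplitudes[i]
    }
    convolve_to_tr(a, dt, n_volumes, oversample)
  }
  out <- tibble::tibble(
    time = (seq_len(n_volumes) - 1) * tr,
    onset = if (n_ev > 0) boxcar(rep(1, n_ev)) else numeric(n_volumes),
    proto_mod = if (n_ev > 0) boxcar(match_proto) else numeric(n_volumes),
    exem_mod = if (n_ev > 0) boxcar(match_exem) else numeric(n_volumes)
  )
  if (!is.null(motion)) {
    motion <- as.data.frame(motion)
    stopifnot(nrow(motion) == n_volumes)
    names(motion) <- paste0("motion", seq_along(motion))
    out <- dplyr::bind_cols(out, motion)
  }
  base::structure(out, class = c("design_matrix", class(out)),
                  tr = tr, n_volumes = n_volumes,
                  center_modulators = center_modulators)
}

design_task_matrix <- function(design) {
  as.matrix(design[, intersect(c("onset", "proto_mod", "exem_mod"),
                               names(design))])
}

design_full_matrix <- function(design) {
  cbind(intercept = 1,
        as.matrix(design[, setdiff(names(design), "time"), drop = FALSE]))
}

#' Collinearity screen for a model-based design
#'
#' Computes the Pearson correlation between the convolved prototype and
#' exemplar modulator columns and the numerical rank of the task sub-matrix.
#' Runs with `|r|` above the threshold, or a rank-deficient task matrix
#' (e.g., no trial-by-trial variability in one predictor), are flagged for
#' exclusion.
#'
#' @param design A `design_matrix`.
#' @param r_threshold Exclusion threshold on `|r|`.
#' @return A one-row tibble: `r_proto_exem`, `rank_deficient`, `excluded`.
#' @export
collinearity_check <- function(design, r_threshold = 0.9) {
  x <- design_task_matrix(design)
  r <- suppressWarnings(cor(x[, "proto_mod"], x[, "exem_mod"]))
  task <- cbind(1, x)
  rank_deficient <- qr(task)$rank < ncol(task)
  if (is.na(r)) rank_deficient <- TRUE
  tibble::tibble(r_proto_exem = r, rank_deficient = rank_deficient,
                 excluded = rank_deficient || (!is.na(r) && abs(r) > r_threshold))
}

#' Ordinary least squares GLM on a voxel time-series matrix
#'
#' Fits `Y = X b + e` per voxel, where `X` is the design (plus an
#' intercept). Refuses rank-deficient designs, attaching the collinearity
#' report to the error.
#'
#' @param timeseries Numeric matrix, volumes x voxels (a vector is treated
#'   as one voxel).
#' @param design A `design_matrix`.
#' @return An object of class `glm_fit`: list with `betas` (regressors x
#'   voxels), `sigma2` (residual variance per voxel), `df_residual`.
#' @export
fit_glm <- function(timeseries, design) {
  y <- if (is.matrix(timeseries)) timeseries else matrix(timeseries, ncol = 1)
  x <- design_full_matrix(design)
  if (nrow(y) != nrow(x))
    stop("timeseries and design have different numbers of volumes",
         call. = FALSE)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    report <- collinearity_check(design)
    cond <- base::structure(
      class = c("protex_rank_deficient", "error", "condition"),
      list(message = "design matrix is rank deficient; refusing to fit",
           call = sys.call(-1), report = report))
    stop(cond)
  }
  betas <- qr.coef(qx, y)
  resid <- y - x %*% betas
  df <- nrow(y) - ncol(x)
  base::structure(
    list(betas = betas, sigma2 = colSums(resid^2) / df, df_residual = df,
         terms = colnames(x)),
    class = "glm_fit")
}

#' ROI effect size from voxelwise betas
#'
#' The normalized-beta effect size: the mean parameter estimate across
#' voxels divided by their standard deviation, computed per run and
#' averaged across the runs of a phase. De-weighs estimates with large
#' across-voxel uncertainty. Undefined (NA, with a warning) when the voxel
#' SD is zero.
#'
#' @param betas Numeric vector of per-voxel betas (one run), or
#'   concatenated across runs with `run` giving the run of each entry.
#' @param run Optional run labels aligned with `betas`.
#' @return The scalar effect size.
#' @export
roi_effect <- function(betas, run = NULL) {
  if (is.null(run)) run <- rep(1L, length(betas))
  per_run <- tapply(betas, run, function(b) {
    if (length(b) < 2) return(NA_real_)
    s <- sd(b)
    if (s == 0) NA_real_ else mean(b) / s
  })
  if (any(is.na(per_run))) {
    warning("ROI effect undefined in at least one run (zero voxel SD)")
    return(NA_real_)
  }
  mean(per_run)
}

#' Per-model ROI effects from fitted GLMs
#'
#' Extracts the prototype- and exemplar-modulator betas from one or more
#' run-level GLM fits of an ROI and returns the per-model normalized-beta
#' effect sizes averaged across the runs.
#'
#' @param fits A `glm_fit` or list of `glm_fit` (one per run).
#' @return A tibble: `model` (`"prototype"`, `"exemplar"`), `effect`.
#' @export
roi_model_effects <- function(fits) {
  if (inherits(fits, "glm_fit")) fits <- list(fits)
  grab <- function(term) {
    b <- unlist(lapply(fits, function(f) f$betas[term, ]))
    run <- rep(seq_along(fits), vapply(fits, function(f) ncol(f$betas),
                                       integer(1)))
    roi_effect(b, run)
  }
  tibble::tibble(model = c("prototype", "exemplar"),
                 effect = c(grab("proto_mod"), grab("exem_mod")))
}

#' Read a 4-D BOLD series (and optional ROI mask) into a matrix
#'
#' Thin NIfTI adapter: loads a 4-D volume and returns the volumes x voxels
#' matrix, restricted to a 3-D mask when given. Requires the RNifti package.
#'
#' @param bold_path Path to a 4-D NIfTI image.
#' @param mask_path Optional path to a 3-D mask image (nonzero = in ROI).
#' @return Numeric matrix, volumes x voxels.
#' @export
read_bold_matrix <- function(bold_path, mask_path = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("read_bold_matrix requires the RNifti package", call. = FALSE)
  img <- RNifti::readNifti(bold_path)
  d <- dim(img)
  stopifnot(length(d) == 4)
  mat <- t(matrix(img, nrow = prod(d[1:3]), ncol = d[4]))
  if (!is.null(mask_path)) {
    mask <- RNifti::readNifti(mask_path)
    stopifnot(length(dim(mask)) == 3, all(dim(mask) == d[1:3]))
    mat <- mat[, as.vector(mask != 0), drop = FALSE]
  }
  mat
}
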