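# Per-run GLM pattern estimation: canonical double-gamma HRF, event
# convolution on a microtime grid, framewise-displacement nuisance, and
# ordinary least squares with exemplar-wise regressors.

#' Default canonical HRF parameters
#'
#' SPM-convention double-gamma: response gamma with shape 6, undershoot
#' gamma with shape 16 (both rate 1/s), undershoot ratio 1/6, evaluated
#' over a 32 s window.
#'
#' @return a named list of HRF parameters.
#' @export
hrf_default <- function() {
  list(peak_delay = 6, undershoot_delay = 16, ratio = 1 / 6, duration = 32)
}

#' Sampled canonical double-gamma HRF kernel
#'
#' @param dt sampling step in seconds (> 0); use the scan TR for a
#'   volume-resolution kernel or a small value (e.g. 0.1) for microtime
#'   convolution.
#' @param params parameter list as from [hrf_default()].
#' @return numeric vector `h(t)` sampled at `t = 0, dt, 2*dt, ...` up to
#'   `params$duration`, normalized to unit peak.
#' @export
hrf_kernel <- function(dt, params = hrf_default()) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (params$duration <= 0) stop("HRF window must be positive", call. = FALSE)
  t <- seq(0, params$duration, by = dt)
  h <- stats::dgamma(t, shape = params$peak_delay, rate = 1) -
    params$ratio * stats::dgamma(t, shape = params$undershoot_delay, rate = 1)
  h / max(h)
}

# HRF-convolved indicator regressors on a 0.1 s microtime grid, sampled at
# volume midtimes (v - 0.5) * TR. `events` is a list of data.frames with
# columns onset, duration; one output column per list element.
convolve_events <- function(events, TR, n_vols, hrf = hrf_default(),
                            dt = 0.1) {
  total_s <- n_vols * TR
  n_grid <- ceiling(total_s / dt) + 1L
  kern <- hrf_kernel(dt, hrf)
  grid_t <- (seq_len(n_grid) - 1L) * dt
  frame_idx <- pmin(n_grid, floor(((seq_len(n_vols) - 0.5) * TR) / dt) + 1L)
  out <- vapply(events, function(ev) {
    u <- numeric(n_grid)
    for (i in seq_len(nrow(ev))) {
      on <- ev$onset[i]; off <- on + ev$duration[i]
      u[grid_t >= on & grid_t < off] <- 1
    }
    y <- stats::convolve(u, rev(kern), type = "open")[seq_len(n_grid)] * dt
    y[frame_idx]
  }, numeric(n_vols))
  matrix(out, n_vols, length(events),
         dimnames = list(NULL, names(events)))
}

# Condition regressors for the given condition ids (zero column if a
# condition has no trials -- callers decide whether that is an error).
convolve_conditions <- function(timeline, cond_ids, TR, n_vols,
                                hrf = hrf_default()) {
  ev <- lapply(cond_ids, function(id) {
    rows <- timeline$kind == "experimental" &
      !is.na(timeline$condition_id) & timeline$condition_id == id
    timeline[rows, c("onset", "duration"), drop = FALSE]
  })
  names(ev) <- cond_ids
  convolve_events(ev, TR, n_vols, hrf)
}

#' Framewise displacement from motion parameters
#'
#' FD at each timepoint is the sum of the absolute temporal derivatives of
#' the six rigid-body parameters, with the three rotations converted to arc
#' length on a sphere of radius `rotation_radius_mm`. The first timepoint
#' has FD 0 by convention.
#'
#' @param motion timepoint x 6 matrix: three translations (mm) then three
#'   rotations (radians).
#' @param rotation_radius_mm sphere radius for rotation-to-mm conversion.
#' @return numeric FD series of length `nrow(motion)`.
#' @export
framewise_displacement <- function(motion, rotation_radius_mm = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L || nrow(motion) < 2L || anyNA(motion))
    stop("motion must be a complete timepoint x 6 matrix with >= 2 timepoints",
         call. = FALSE)
  d <- abs(diff(motion))
  c(0, rowSums(d[, 1:3, drop = FALSE]) +
      rotation_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
}

#' Build a run's GLM design matrix
#'
#' One HRF-convolved regressor per condition present in the timeline (each
#' exemplar of each category, per domain, modeled separately), a single
#' pooled nuisance regressor for question trials, the framewise
#' displacement nuisance (dropped if identically zero, e.g. constant
#' motion), and an intercept. Null trials are left unmodeled as implicit
#' baseline.
#'
#' @param timeline a [build_trial_timeline()] events table.
#' @param TR repetition time in seconds.
#' @param motion optional timepoint x 6 motion matrix for the FD regressor.
#' @param n_vols number of volumes; default covers the timeline plus a 16 s
#'   HRF tail (must match `nrow(motion)` when motion is given).
#' @param hrf HRF parameters, see [hrf_default()].
#' @return an object of class `design_matrix`: list with `X` (timepoint x
#'   regressor, labeled), `condition_ids`, `n_vols`, `TR`.
#' @export
build_design_matrix <- function(timeline, TR = 2, motion = NULL,
                                n_vols = NULL, hrf = hrf_default()) {
  if (nrow(timeline) == 0L) stop("empty timeline", call. = FALSE)
  if (is.null(n_vols)) {
    n_vols <- if (!is.null(motion)) nrow(motion) else implied_volumes(timeline, TR)
  }
  if (!is.null(motion) && nrow(motion) != n_vols)
    stop("motion has ", nrow(motion), " timepoints but the design has ",
         n_vols, " volumes", call. = FALSE)
  conds <- attr(timeline, "conditions")
  cond_ids <- if (!is.null(conds)) conds$condition_id else
    unique(stats::na.omit(timeline$condition_id[timeline$kind == "experimental"]))
  Xc <- convolve_conditions(timeline, cond_ids, TR, n_vols, hrf)
  zero <- colSums(abs(Xc)) == 0
  if (any(zero))
    stop("rank error: condition(s) with zero trials: ",
         paste(cond_ids[zero], collapse = ", "), call. = FALSE)
  extras <- list()
  if (any(timeline$kind == "question")) {
    qev <- list(question = timeline[timeline$kind == "question",
                                    c("onset", "duration"), drop = FALSE])
    extras$question <- convolve_events(qev, TR, n_vols, hrf)[, 1]
  }
  if (!is.null(motion)) {
    fd <- framewise_displacement(motion)
    if (any(fd != 0)) extras$fd <- fd
  }
  X <- cbind(Xc, do.call(cbind, extras), intercept = rep(1, n_vols))
  structure(list(X = X, condition_ids = cond_ids, n_vols = n_vols, TR = TR),
            class = "design_matrix")
}

#' Fit the run GLM by ordinary least squares
#'
#' @param run_data timepoint x voxel data matrix.
#' @param design a [build_design_matrix()] object (or a bare matrix).
#' @return an object of class `glm_result`: `betas` (regressor x voxel,
#'   labeled), `residuals` (timepoint x voxel), `dof` (timepoints minus
#'   design rank), `condition_ids`.
#' @export
fit_glm <- function(run_data, design) {
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  run_data <- as.matrix(run_data)
  if (nrow(run_data) != nrow(X))
    stop("data has ", nrow(run_data), " rows but design has ", nrow(X),
         call. = FALSE)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("rank-deficient design matrix (rank ", qx$rank, " < ", ncol(X), ")",
         call. = FALSE)
  betas <- qr.coef(qx, run_data)
  rownames(betas) <- colnames(X)
  res <- run_data - X %*% betas
  structure(list(betas = betas, residuals = res,
                 dof = nrow(X) - qx$rank,
                 condition_ids = if (inherits(design, "design_matrix"))
                   design$condition_ids else colnames(X)),
            class = "glm_result")
}

#' Extract the condition x voxel pattern matrix from a GLM fit
#'
#' @param fit a [fit_glm()] result.
#' @return matrix of condition betas (the activity patterns entering the
#'   distance computation).
#' @export
condition_patterns <- function(fit) {
  stopifnot(inherits(fit, "glm_result"))
  fit$betas[fit$condition_ids, , drop = FALSE]
}
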