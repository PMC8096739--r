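# Ground-truth representational geometries and synthetic multi-voxel data:
# beta-level run patterns, or full BOLD time series with temporally and
# spatially correlated noise plus simulated head motion.

#' Specify the noise model of the synthetic scanner
#'
#' @param sigma per-voxel noise standard deviation (arbitrary units).
#' @param rho spatial correlation parameter. For `structure = "exchangeable"`
#'   every voxel pair shares correlation `rho`; for `"ar"` correlation decays
#'   as `rho^|i-j|` with voxel index distance.
#' @param structure spatial correlation structure.
#' @param temporal_ar lag-1 autocorrelation of the time-series noise
#'   (used only by [simulate_timeseries()]).
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(sigma = 1, rho = 0.3,
                       structure = c("exchangeable", "ar"),
                       temporal_ar = 0.4) {
  structure <- match.arg(structure)
  stopifnot(sigma >= 0, abs(rho) < 1, abs(temporal_ar) < 1)
  structure(list(sigma = sigma, rho = rho, structure = structure,
                 temporal_ar = temporal_ar), class = "noise_spec")
}

#' Voxel covariance matrix implied by a noise specification
#'
#' @param spec a [noise_spec()].
#' @param n_voxels number of voxels.
#' @return a symmetric positive definite `n_voxels` x `n_voxels` matrix.
#' @export
noise_cov_matrix <- function(spec, n_voxels) {
  stopifnot(inherits(spec, "noise_spec"), n_voxels >= 1)
  R <- switch(spec$structure,
    exchangeable = {
      if (n_voxels > 1 && spec$rho <= -1 / (n_voxels - 1))
        stop("exchangeable rho too negative for positive definiteness",
             call. = FALSE)
      m <- matrix(spec$rho, n_voxels, n_voxels); diag(m) <- 1; m
    },
    ar = spec$rho^abs(outer(seq_len(n_voxels), seq_len(n_voxels), "-"))
  )
  spec$sigma^2 * R
}

# K x P matrix of N(0, Sigma) rows given the upper Cholesky factor of Sigma.
rmvn_rows <- function(n, chol_sigma) {
  matrix(stats::rnorm(n * ncol(chol_sigma)), n) %*% chol_sigma
}

random_unit_rows <- function(n, p) {
  m <- matrix(stats::rnorm(n * p), n)
  m / sqrt(rowSums(m^2))
}

#' Construct a ground-truth representational geometry
#'
#' Each condition's mean activity pattern is a sum of seeded random
#' unit-norm component vectors, one per level of each factor the condition
#' carries, scaled by the matching effect size: a category component, a
#' domain component, a quadrant component, and an item component. Factorial
#' effect sizes therefore translate directly into the block structure of
#' the true representational dissimilarity matrix.
#'
#' @param conditions condition table from [make_stimulus_set()] (or any
#'   data.frame with `condition_id`, `item_id`, `category`, `domain`,
#'   `quadrant` columns).
#' @param effect_spec named nonnegative numeric vector with entries
#'   `category`, `domain`, `quadrant`, `item` (missing entries default 0).
#'   An optional `perception_gain` entry (default 1) multiplies the
#'   category/quadrant/item components of perception-domain conditions,
#'   emulating the sharper neural representations of perceived relative to
#'   imagined stimuli.
#' @param n_voxels number of voxels (>= 2).
#' @param seed integer seed.
#' @return an object of class `geometry`: list with `conditions`,
#'   `patterns` (condition x voxel matrix), `effect_spec`, `n_voxels`.
#' @export
make_geometry <- function(conditions, effect_spec = c(item = 1),
                          n_voxels = 60, seed = 1L) {
  stopifnot(n_voxels >= 2)
  gain <- if ("perception_gain" %in% names(effect_spec))
    effect_spec[["perception_gain"]] else 1
  if (gain < 0) stop("perception_gain must be nonnegative", call. = FALSE)
  effect_spec <- effect_spec[setdiff(names(effect_spec), "perception_gain")]
  full <- c(category = 0, domain = 0, quadrant = 0, item = 0)
  full[names(effect_spec)] <- effect_spec
  if (any(full < 0)) stop("effect sizes must be nonnegative", call. = FALSE)
  K <- nrow(conditions)
  patterns <- matrix(0, K, n_voxels,
                     dimnames = list(conditions$condition_id, NULL))
  factor_col <- c(category = "category", domain = "domain",
                  quadrant = "quadrant", item = "item_id")
  perc <- !is.na(conditions$domain) & conditions$domain == "perception"
  with_seed(seed, {
    for (f in names(factor_col)) {
      if (full[[f]] == 0) next
      lev <- conditions[[factor_col[[f]]]]
      if (all(is.na(lev))) next
      ul <- unique(stats::na.omit(lev))
      comp <- random_unit_rows(length(ul), n_voxels)
      rownames(comp) <- ul
      ok <- !is.na(lev)
      contrib <- full[[f]] * comp[lev[ok], , drop = FALSE]
      if (f != "domain" && gain != 1)
        contrib[perc[ok], ] <- gain * contrib[perc[ok], , drop = FALSE]
      patterns[ok, ] <- patterns[ok, ] + contrib
    }
  })
  full <- c(full, perception_gain = gain)
  structure(list(conditions = conditions, patterns = patterns,
                 effect_spec = full, n_voxels = n_voxels),
            class = "geometry")
}

#' Add seeded between-subject variability to a geometry
#'
#' Perturbs the true condition patterns with iid Gaussian noise of the
#' given scale, modelling idiosyncratic subject-level representational
#' geometry around the group mean.
#'
#' @param geometry a [make_geometry()] object.
#' @param sd perturbation standard deviation per voxel.
#' @param seed integer seed (use a per-subject child seed).
#' @return a perturbed `geometry`.
#' @export
perturb_geometry <- function(geometry, sd, seed) {
  stopifnot(inherits(geometry, "geometry"), sd >= 0)
  if (sd > 0) {
    with_seed(seed, {
      geometry$patterns <- geometry$patterns +
        matrix(stats::rnorm(length(geometry$patterns), sd = sd),
               nrow(geometry$patterns))
    })
  }
  geometry
}

#' True squared Mahalanobis RDM of a geometry
#'
#' Closed-form condition x condition matrix of squared Mahalanobis
#' distances between the true mean patterns under a given voxel noise
#' covariance (identity by default, i.e. squared Euclidean distances).
#'
#' @param geometry a [make_geometry()] object.
#' @param noise_cov voxel covariance matrix, or NULL for identity.
#' @return a symmetric matrix with zero diagonal of class `rdm`.
#' @export
true_rdm <- function(geometry, noise_cov = NULL) {
  U <- geometry$patterns
  if (!is.null(noise_cov)) U <- U %*% inv_sqrt_matrix(noise_cov)
  G <- tcrossprod(U)
  d <- outer(diag(G), diag(G), "+") - 2 * G
  d[d < 0] <- 0 # numerical noise
  diag(d) <- 0
  new_rdm(d, geometry$conditions)
}

#' Simulate beta-level run patterns
#'
#' Each run's condition x voxel pattern equals the geometry's true pattern
#' plus an independent Gaussian noise draw with the voxel covariance implied
#' by `noise`; runs are independent. This is the beta-level shortcut that
#' bypasses time-series simulation and the GLM.
#'
#' @param geometry a [make_geometry()] object.
#' @param n_runs number of runs/partitions M (>= 2; the cross-validated
#'   distance is undefined for fewer).
#' @param noise a [noise_spec()].
#' @param seed integer seed.
#' @return a `pattern_set`: list of per-run condition x voxel matrices plus
#'   the condition table.
#' @export
simulate_run_patterns <- function(geometry, n_runs, noise = noise_spec(),
                                  seed = 1L) {
  stopifnot(inherits(geometry, "geometry"))
  if (n_runs < 2) stop("n_runs must be >= 2 (cross-validation needs >= 2 partitions)",
                       call. = FALSE)
  K <- nrow(geometry$patterns); P <- ncol(geometry$patterns)
  cs <- if (noise$sigma > 0) chol(noise_cov_matrix(noise, P)) else NULL
  runs <- with_seed(seed, lapply(seq_len(n_runs), function(m) {
    u <- geometry$patterns
    if (!is.null(cs)) u <- u + rmvn_rows(K, cs)
    u
  }))
  pattern_set(runs, geometry$conditions)
}

#' Simulate six rigid-body motion parameters
#'
#' Seeded Gaussian random walk over timepoints: three translations (mm) and
#' three rotations (radians), each with step standard deviation
#' `amplitude`.
#'
#' @param n_timepoints number of volumes.
#' @param amplitude random-walk step SD (0 gives constant motion).
#' @param seed integer seed.
#' @return an `n_timepoints` x 6 matrix (columns tx, ty, tz, rx, ry, rz).
#' @export
simulate_motion <- function(n_timepoints, amplitude = 0.02, seed = 1L) {
  stopifnot(n_timepoints >= 1, amplitude >= 0)
  with_seed(seed, {
    steps <- matrix(stats::rnorm(n_timepoints * 6, sd = amplitude),
                    n_timepoints, 6)
    m <- apply(steps, 2, cumsum)
    m <- matrix(m, n_timepoints, 6)
    colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
    m
  })
}

#' Simulate one run's BOLD time series
#'
#' Forward model: the condition design matrix (HRF-convolved indicators
#' sampled at TR) multiplied by the geometry's true patterns, plus noise
#' with lag-1 temporal autocorrelation and the spatial covariance of
#' `noise`, at stationary marginal SD `noise$sigma`. Motion parameters are
#' simulated as an independent random walk and returned for use as the
#' framewise-displacement nuisance downstream (they do not corrupt the
#' signal).
#'
#' @param timeline a [build_trial_timeline()] events table (conditions must
#'   match the geometry's).
#' @param geometry a [make_geometry()] object.
#' @param TR repetition time in seconds (> 0).
#' @param hrf optional HRF parameter list, see [hrf_kernel()].
#' @param noise a [noise_spec()].
#' @param motion_amplitude random-walk step SD of the motion parameters.
#' @param seed integer seed.
#' @return list with `data` (timepoint x voxel), `motion` (timepoint x 6),
#'   `frame_times`, `TR`.
#' @export
simulate_timeseries <- function(timeline, geometry, TR = 2,
                                hrf = hrf_default(), noise = noise_spec(),
                                motion_amplitude = 0.02, seed = 1L) {
  if (TR <= 0) stop("TR must be positive", call. = FALSE)
  stopifnot(inherits(geometry, "geometry"))
  cond_ids <- geometry$conditions$condition_id
  tl_ids <- unique(stats::na.omit(timeline$condition_id[timeline$kind == "experimental"]))
  if (!all(tl_ids %in% cond_ids))
    stop("timeline and geometry do not share the same condition set",
         call. = FALSE)
  n_vols <- implied_volumes(timeline, TR)
  X <- convolve_conditions(timeline, cond_ids, TR, n_vols, hrf)
  signal <- X %*% geometry$patterns
  P <- ncol(signal)
  phi <- noise$temporal_ar
  eps <- with_seed(child_seed(seed, "noise"), {
    e <- matrix(stats::rnorm(n_vols * P), n_vols, P)
    if (phi != 0) {
      e <- apply(e, 2, function(col) stats::filter(col, phi, "recursive"))
      e <- matrix(e, n_vols, P) * sqrt(1 - phi^2) # restore unit marginal SD
    }
    if (noise$sigma > 0) {
      spat <- chol(noise_cov_matrix(noise_spec(sigma = 1, rho = noise$rho,
                                               structure = noise$structure), P))
      noise$sigma * (e %*% spat)
    } else e * 0
  })
  motion <- simulate_motion(n_vols, motion_amplitude,
                            seed = child_seed(seed, "motion"))
  list(data = signal + eps, motion = motion,
       frame_times = (seq_len(n_vols) - 0.5) * TR, TR = TR)
}

# Number of volumes needed to cover the timeline plus the HRF tail.
implied_volumes <- function(timeline, TR, tail_s = 16) {
  ceiling((max(timeline$onset + timeline$duration) + tail_s) / TR)
}
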