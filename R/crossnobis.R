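# The cross-validated Mahalanobis (crossnobis) estimator: shrinkage
# covariance estimation from GLM residuals, multivariate noise
# normalization (prewhitening), and the fold-averaged cross-validated
# distance.

#' Bundle per-run condition patterns into a pattern set
#'
#' @param runs list of M >= 2 condition x voxel matrices with identical
#'   dimensions and condition order.
#' @param conditions condition table (one row per pattern row).
#' @return an object of class `pattern_set`.
#' @export
pattern_set <- function(runs, conditions) {
  stopifnot(is.list(runs), length(runs) >= 1L)
  dims <- vapply(runs, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all runs must share condition and voxel counts", call. = FALSE)
  if (dims[1, 1] != nrow(conditions))
    stop("condition table does not match pattern rows", call. = FALSE)
  structure(list(runs = runs, conditions = conditions), class = "pattern_set")
}

#' @export
length.pattern_set <- function(x) length(x$runs)

new_rdm <- function(d, conditions, subject = NA_character_,
                    region = NA_character_) {
  dimnames(d) <- list(conditions$condition_id, conditions$condition_id)
  structure(d, conditions = conditions, subject = subject, region = region,
            class = c("rdm", "matrix"))
}

#' Shrinkage estimate of the voxel noise covariance
#'
#' Sample covariance of (column-centered) residuals, shrunk toward its
#' diagonal with a Ledoit-Wolf/Schaefer-Strimmer weight estimated from the
#' data (or a fixed weight). With any positive weight and positive voxel
#' variances the result is symmetric positive definite even when voxels
#' outnumber timepoints.
#'
#' @param residuals timepoint x voxel residual matrix (>= 2 timepoints), or
#'   a list of such matrices (one per run).
#' @param shrinkage `"auto"` for the data-driven weight, or a fixed number
#'   in [0, 1].
#' @param pool for list input: `"pooled"` (default) averages the per-run
#'   shrunk covariances into a single matrix (more stable for short runs);
#'   `"per_run"` returns one covariance per run.
#' @param dof effective degrees of freedom of the residuals (defaults to
#'   timepoints - 1); used to scale the sample covariance.
#' @return an object of class `noise_cov` (list with `sigma`, `lambda`,
#'   `dof`), or a list of them when `pool = "per_run"`.
#' @export
estimate_noise_cov <- function(residuals, shrinkage = "auto",
                               pool = c("pooled", "per_run"), dof = NULL) {
  pool <- match.arg(pool)
  if (is.list(residuals)) {
    covs <- lapply(residuals, estimate_noise_cov, shrinkage = shrinkage,
                   dof = dof)
    if (pool == "per_run") return(covs)
    sig <- Reduce(`+`, lapply(covs, `[[`, "sigma")) / length(covs)
    return(structure(list(sigma = sig,
                          lambda = mean(vapply(covs, `[[`, 0, "lambda")),
                          dof = sum(vapply(covs, `[[`, 0, "dof"))),
                     class = "noise_cov"))
  }
  X <- as.matrix(residuals)
  n <- nrow(X)
  if (n < 2L) stop("need >= 2 timepoints to estimate a covariance",
                   call. = FALSE)
  if (is.null(dof)) dof <- n - 1L
  Xc <- sweep(X, 2, colMeans(X))
  S <- crossprod(Xc) / dof
  v <- diag(S)
  lambda <- if (identical(shrinkage, "auto")) {
    # Schaefer-Strimmer optimal weight toward the diagonal target:
    # lambda* = sum_{i!=j} Var-hat(s_ij) / sum_{i!=j} s_ij^2,
    # with Var-hat(s_ij) from the moments of w_tij = x_ti * x_tj.
    Su <- crossprod(Xc) / (n - 1)
    WW <- crossprod(Xc^2)       # sum_t x_ti^2 x_tj^2
    Wbar <- crossprod(Xc) / n   # mean_t w_tij
    varS <- (n / ((n - 1)^3)) * (WW - n * Wbar^2)
    off <- row(Su) != col(Su)
    den <- sum((Su[off])^2)
    if (den <= 0) 1 else min(1, max(0, sum(varS[off]) / den))
  } else {
    s <- as.numeric(shrinkage)
    if (is.na(s) || s < 0 || s > 1) stop("shrinkage must be in [0, 1]",
                                         call. = FALSE)
    s
  }
  if (lambda == 0 && any(v <= 0))
    stop("zero-variance voxel with no shrinkage gives a singular covariance",
         call. = FALSE)
  sig <- (1 - lambda) * S
  diag(sig) <- v # shrinkage target: the diagonal of sample variances
  structure(list(sigma = sig, lambda = lambda, dof = dof),
            class = "noise_cov")
}

# Symmetric inverse square root with an eigenvalue floor for numerical
# stability.
inv_sqrt_matrix <- function(sigma, floor_ratio = 1e-10) {
  sigma <- if (inherits(sigma, "noise_cov")) sigma$sigma else as.matrix(sigma)
  e <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE)
  if (max(e$values) <= 0) stop("covariance is not positive definite",
                               call. = FALSE)
  lam <- pmax(e$values, floor_ratio * max(e$values))
  e$vectors %*% (t(e$vectors) / sqrt(lam))
}

#' Multivariate noise normalization (prewhitening)
#'
#' Transforms patterns by the symmetric inverse square root of the noise
#' covariance so that Euclidean geometry on the transformed patterns equals
#' Mahalanobis geometry under that covariance on the originals.
#'
#' @param patterns a condition x voxel matrix or a [pattern_set()].
#' @param noise_cov a [estimate_noise_cov()] result (or bare matrix), or --
#'   for a `pattern_set` -- a list of them, one per run.
#' @return the transformed matrix or pattern set.
#' @export
prewhiten <- function(patterns, noise_cov) {
  if (inherits(patterns, "pattern_set")) {
    Ws <- if (inherits(noise_cov, "noise_cov") || is.matrix(noise_cov)) {
      W <- inv_sqrt_matrix(noise_cov)
      rep(list(W), length(patterns$runs))
    } else {
      if (length(noise_cov) != length(patterns$runs))
        stop("need one covariance per run", call. = FALSE)
      lapply(noise_cov, inv_sqrt_matrix)
    }
    patterns$runs <- Map(function(u, W) u %*% W, patterns$runs, Ws)
    return(patterns)
  }
  W <- inv_sqrt_matrix(noise_cov)
  if (ncol(patterns) != nrow(W))
    stop("voxel dimensions of patterns and covariance disagree", call. = FALSE)
  patterns %*% W
}

#' Cross-validated Mahalanobis (crossnobis) RDM
#'
#' For prewhitened per-run patterns u_i^m, the distance between conditions
#' i and j is the average over all ordered run pairs (l, m), l != m, of the
#' inner product (u_i^m - u_j^m)' (u_i^l - u_j^l), divided by M(M-1).
#' Because the two factors come from independent partitions, the estimate
#' is unbiased for the true squared Mahalanobis distance: it is exactly
#' zero in expectation for identical conditions (meaningful zero point) and
#' can be negative when patterns are not consistent across runs. The
#' diagonal is exactly zero. Following the estimator's plain form there is
#' no division by the voxel count; set `normalize_voxels = TRUE` for the
#' distance-per-voxel convention when comparing regions of different size.
#'
#' @param patterns a [pattern_set()] with M >= 2 runs, already prewhitened
#'   (or generated under white noise).
#' @param normalize_voxels divide distances by the voxel count.
#' @param subject,region optional identifiers stored on the result.
#' @return a symmetric condition x condition matrix of class `rdm` with
#'   exactly zero diagonal.
#' @export
crossnobis_rdm <- function(patterns, normalize_voxels = FALSE,
                           subject = NA_character_, region = NA_character_) {
  stopifnot(inherits(patterns, "pattern_set"))
  M <- length(patterns$runs)
  if (M < 2L) stop("crossnobis needs M >= 2 partitions", call. = FALSE)
  A <- Reduce(`+`, patterns$runs)
  C <- tcrossprod(A) - Reduce(`+`, lapply(patterns$runs, tcrossprod))
  K <- C / (M * (M - 1))
  K <- (K + t(K)) / 2
  d <- outer(diag(K), diag(K), "+") - 2 * K
  diag(d) <- 0
  if (normalize_voxels) d <- d / ncol(patterns$runs[[1]])
  new_rdm(d, patterns$conditions, subject, region)
}

#' Crossnobis RDM straight from per-run GLM fits
#'
#' Convenience wrapper over the full estimator: estimates the (shrunk)
#' voxel noise covariance from each run's residuals, prewhitens each run's
#' condition patterns, and computes the cross-validated distance matrix.
#'
#' @param fits list of per-run [fit_glm()] results.
#' @param noise `"pooled"` (default) prewhitens every run with the average
#'   of the per-run shrunk covariances, `"per_run"` uses each run's own
#'   covariance, `"identity"` skips noise normalization.
#' @param shrinkage passed to [estimate_noise_cov()].
#' @param normalize_voxels,subject,region passed to [crossnobis_rdm()].
#' @param conditions condition table; defaults to the fit condition ids.
#' @return an `rdm`.
#' @export
crossnobis_from_glm <- function(fits, noise = c("pooled", "per_run", "identity"),
                                shrinkage = "auto", normalize_voxels = FALSE,
                                subject = NA_character_,
                                region = NA_character_, conditions = NULL) {
  noise <- match.arg(noise)
  pats <- lapply(fits, condition_patterns)
  if (is.null(conditions))
    conditions <- data.frame(condition_id = fits[[1]]$condition_ids,
                             stringsAsFactors = FALSE)
  ps <- pattern_set(pats, conditions)
  if (noise != "identity") {
    covs <- lapply(fits, function(f)
      estimate_noise_cov(f$residuals, shrinkage = shrinkage, dof = f$dof))
    nc <- if (noise == "pooled") {
      structure(list(sigma = Reduce(`+`, lapply(covs, `[[`, "sigma")) / length(covs),
                     lambda = mean(vapply(covs, `[[`, 0, "lambda")),
                     dof = sum(vapply(covs, `[[`, 0, "dof"))),
                class = "noise_cov")
    } else covs
    ps <- prewhiten(ps, nc)
  }
  crossnobis_rdm(ps, normalize_voxels = normalize_voxels,
                 subject = subject, region = region)
}
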