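# End-to-end synthetic study: per-subject, per-region data generation,
# crossnobis RDMs, question distances and the gated analysis.

#' Named effect-size presets
#'
#' Effect sizes are the norms of the factor component vectors of
#' [make_geometry()], in units of the per-voxel noise SD. The `"moderate"`
#' preset is calibrated so that, with the package defaults (40 voxels,
#' exchangeable noise rho = 0.3, the experiment's run count), per-subject
#' averaged distances give one-sample gate power above 90% at n = 19
#' subjects and the seed-level alpha.
#'
#' @param name preset name.
#' @return named numeric vector with entries category, domain, quadrant,
#'   item.
#' @export
effect_profile <- function(name = c("moderate", "strong", "weak", "null")) {
  switch(match.arg(name),
    null = c(category = 0, domain = 0, quadrant = 0, item = 0),
    weak = c(category = 0.6, domain = 0.6, quadrant = 0.3, item = 0.4,
             perception_gain = 1.5),
    moderate = c(category = 1.5, domain = 1.5, quadrant = 0.8, item = 1.0,
                 perception_gain = 1.5),
    strong = c(category = 3, domain = 3, quadrant = 1.5, item = 2,
               perception_gain = 1.5))
}

#' Simulate a full multi-subject, multi-region study
#'
#' For every subject and region: build the region's ground-truth geometry
#' (shared across subjects up to a seeded per-subject perturbation),
#' generate per-run data, and compute the crossnobis RDM. In
#' `mode = "patterns"` run patterns are drawn at the beta level and
#' prewhitened with the known generating covariance; in
#' `mode = "timeseries"` full BOLD runs are simulated from the experiment's
#' carry-over timelines, patterns and residuals are estimated by the GLM,
#' and noise normalization uses the pooled shrunk residual covariance.
#'
#' @param experiment 1, 2 or 3.
#' @param n_subjects number of subjects.
#' @param regions character vector of region ids; default
#'   [standard_regions()] of the experiment.
#' @param effect single effect-size vector, or a named list mapping each
#'   region to one (regions omitted from the list get the null profile).
#' @param n_voxels voxels per region.
#' @param n_runs number of runs; default the experiment's scan count.
#' @param noise a [noise_spec()].
#' @param subject_sd SD of the per-subject geometry perturbation.
#' @param mode `"patterns"` (fast, beta-level) or `"timeseries"` (full
#'   forward model + GLM).
#' @param subject_ids optional explicit subject ids (for cross-experiment
#'   overlap, reuse ids across studies).
#' @param seed integer master seed.
#' @return an object of class `study`: list with `rdms`
#'   (`rdms[[subject]][[region]]`), `conditions`, `experiment`, `regions`.
#' @export
simulate_study <- function(experiment, n_subjects = 19,
                           regions = standard_regions(experiment),
                           effect = effect_profile("moderate"),
                           n_voxels = 40, n_runs = NULL,
                           noise = noise_spec(), subject_sd = 0,
                           mode = c("patterns", "timeseries"),
                           subject_ids = NULL, seed = 1L) {
  mode <- match.arg(mode)
  layout <- experiment_layout(experiment)
  n_runs <- n_runs %||% layout$n_runs
  conditions <- make_stimulus_set(experiment)
  if (!is.list(effect)) effect <- stats::setNames(
    rep(list(effect), length(regions)), regions)
  subjects <- subject_ids %||% sprintf("s%02d", seq_len(n_subjects))
  region_geom <- lapply(regions, function(reg)
    make_geometry(conditions, effect[[reg]] %||% effect_profile("null"),
                  n_voxels, seed = child_seed(seed, "geom", experiment, reg)))
  names(region_geom) <- regions
  rdms <- lapply(subjects, function(subj) {
    per_region <- lapply(regions, function(reg) {
      g <- perturb_geometry(region_geom[[reg]], subject_sd,
                            seed = child_seed(seed, "subj", subj, reg))
      if (mode == "patterns") {
        ps <- simulate_run_patterns(g, n_runs, noise,
                                    seed = child_seed(seed, "pat", subj, reg))
        if (noise$sigma > 0 && noise$rho != 0)
          ps <- prewhiten(ps, noise_cov_matrix(noise, n_voxels))
        crossnobis_rdm(ps, subject = subj, region = reg)
      } else {
        fits <- lapply(seq_len(n_runs), function(r) {
          tl <- build_trial_timeline(experiment, r,
                                     seed = child_seed(seed, "tl", subj))
          sim <- simulate_timeseries(tl, g, noise = noise,
                                     seed = child_seed(seed, "ts", subj, reg, r))
          fit_glm(sim$data, build_design_matrix(tl, TR = sim$TR,
                                                motion = sim$motion))
        })
        crossnobis_from_glm(fits, noise = "pooled", subject = subj,
                            region = reg, conditions = conditions)
      }
    })
    names(per_region) <- regions
    per_region
  })
  names(rdms) <- subjects
  structure(list(rdms = rdms, conditions = conditions,
                 experiment = experiment, regions = regions),
            class = "study")
}

#' Per-subject question distances from one or more studies
#'
#' Evaluates each selection of a question on every study whose condition
#' labels support it (e.g. city pairs exist only in Experiment 1) and, when
#' a subject contributed the same (region, selection) cell in several
#' experiments, averages their values as for the repeat participants of
#' Experiments 1 and 2.
#'
#' @param spec a [question_spec()].
#' @param studies a `study` or list of `study` objects.
#' @param exclude_k SD multiplier of the exclusion rule (NULL disables).
#' @return a subject-distance data.frame (`subject`, `region`, `selection`,
#'   `value`).
#' @export
question_distances <- function(spec, studies, exclude_k = 2) {
  if (inherits(studies, "study")) studies <- list(studies)
  per_study <- lapply(studies, function(st) {
    ok <- Filter(function(nm) {
      sel <- spec$selections[[nm]]
      tryCatch(nrow(select_pairs(st$conditions, sel)) > 0,
               error = function(e) FALSE)
    }, names(spec$selections))
    if (length(ok) == 0L) return(NULL)
    subject_distances(st$rdms, spec$selections[ok], st$conditions,
                      exclude_k = exclude_k)
  })
  all <- do.call(rbind, per_study)
  if (is.null(all)) stop("no study supports any selection of the question",
                         call. = FALSE)
  agg <- stats::aggregate(value ~ subject + region + selection, all, mean,
                          na.action = stats::na.omit)
  agg[order(agg$selection, agg$region, agg$subject), ]
}

#' Simulate a study and run one question end to end
#'
#' Convenience wrapper: simulate the question's experiment(s), compute the
#' question distances and run the two-stage gated analysis.
#'
#' @param question question id ("q1a".."q3c") or a [question_spec()].
#' @param n_subjects subjects per experiment (vector recycled over the
#'   question's experiments; defaults to the published cohort sizes 15, 16
#'   and 19).
#' @param overlap number of subjects shared between the first and each
#'   later experiment of the question (2 subjects took part in both
#'   Experiments 1 and 2; their values are averaged across experiments).
#' @param seed integer master seed.
#' @param ... passed on to [simulate_study()].
#' @return a `question_result`.
#' @export
simulate_question <- function(question, n_subjects = NULL, overlap = 2,
                              seed = 1L, ...) {
  spec <- if (inherits(question, "question_spec")) question else
    load_question_specs()[[question]]
  if (is.null(spec)) stop("unknown question id", call. = FALSE)
  exps <- spec$experiments %||% 3
  cohort <- c("1" = 15L, "2" = 16L, "3" = 19L)
  n_subjects <- rep_len(n_subjects %||% cohort[as.character(exps)],
                        length(exps))
  next_id <- 1L
  studies <- vector("list", length(exps))
  first_ids <- NULL
  for (k in seq_along(exps)) {
    n <- n_subjects[k]
    if (k == 1L) {
      ids <- sprintf("s%03d", seq_len(n))
      next_id <- n + 1L
      first_ids <- ids
    } else {
      n_shared <- min(overlap, length(first_ids), n)
      fresh <- if (n > n_shared)
        sprintf("s%03d", next_id + seq_len(n - n_shared) - 1L) else character(0)
      next_id <- next_id + length(fresh)
      ids <- c(first_ids[seq_len(n_shared)], fresh)
    }
    studies[[k]] <- simulate_study(
      exps[k], n_subjects = n,
      regions = spec$regions %||% standard_regions(exps[k]),
      subject_ids = ids, seed = child_seed(seed, "study", exps[k]), ...)
  }
  run_question(spec, question_distances(spec, studies))
}
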