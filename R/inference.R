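# Two-stage region-gated inference: one-tailed one-sample gates against
# zero with seed-level Bonferroni correction, then paired/two-sample t
# tests or one-way ANOVA on the surviving regions with second-level
# Bonferroni correction.

test_result <- function(test, statistic, df, p, tail, n, df2 = NA_real_) {
  data.frame(test = test, statistic = unname(statistic), df = unname(df),
             df2 = df2, p = unname(p), tail = tail, n = n,
             stringsAsFactors = FALSE)
}

map_tail <- function(tail) {
  match.arg(tail, c("greater", "less", "two.sided"))
}

#' One-sample t test (gate test against zero)
#'
#' @param values numeric vector (n >= 2).
#' @param mu null value (0: the meaningful zero of the crossnobis
#'   distance).
#' @param tail "greater" (default; distances higher than zero), "less" or
#'   "two.sided".
#' @return one-row data.frame: `test`, `statistic`, `df`, `p`, `tail`, `n`.
#' @export
one_sample_t <- function(values, mu = 0, tail = "greater") {
  tail <- map_tail(tail)
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) stop("need at least 2 values", call. = FALSE)
  if (stats::sd(values) == 0) {
    warning("zero variance in one-sample t test")
    t <- if (mean(values) == mu) 0 else sign(mean(values) - mu) * Inf
    p <- switch(tail, greater = stats::pt(t, n - 1, lower.tail = FALSE),
                less = stats::pt(t, n - 1),
                two.sided = if (t == 0) 1 else 0)
    return(test_result("one_sample_t", t, n - 1, p, tail, n))
  }
  ht <- stats::t.test(values, mu = mu, alternative = tail)
  test_result("one_sample_t", ht$statistic, ht$parameter, ht$p.value, tail, n)
}

#' Paired t test (one-sample t on within-subject differences)
#'
#' @param values_a,values_b paired numeric vectors of equal length.
#' @param tail alternative for `values_a - values_b`.
#' @return one-row TestResult data.frame.
#' @export
paired_t <- function(values_a, values_b, tail = "greater") {
  if (length(values_a) != length(values_b))
    stop("paired samples must have equal length", call. = FALSE)
  out <- one_sample_t(values_a - values_b, mu = 0, tail = tail)
  out$test <- "paired_t"
  out
}

#' Two-sample t test
#'
#' @param values_a,values_b numeric vectors (each n >= 2).
#' @param tail alternative for `mean(values_a) - mean(values_b)`.
#' @param variance `"pooled"` (default, df = n_a + n_b - 2) or `"welch"`.
#' @return one-row TestResult data.frame.
#' @export
two_sample_t <- function(values_a, values_b, tail = "greater",
                         variance = c("pooled", "welch")) {
  tail <- map_tail(tail)
  variance <- match.arg(variance)
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  ht <- stats::t.test(values_a, values_b, alternative = tail,
                      var.equal = variance == "pooled")
  test_result("two_sample_t", ht$statistic, ht$parameter, ht$p.value, tail,
              length(values_a) + length(values_b))
}

#' One-way between-groups ANOVA
#'
#' @param groups list of >= 2 numeric vectors, each with n >= 2.
#' @return one-row TestResult data.frame (`statistic` is F, `df` the
#'   between-groups and `df2` the within-groups degrees of freedom).
#' @export
one_way_anova <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2L || any(vapply(groups, length, 0L) < 2L))
    stop("ANOVA needs >= 2 groups with >= 2 values each", call. = FALSE)
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  ht <- stats::oneway.test(y ~ g, var.equal = TRUE)
  test_result("one_way_anova", ht$statistic, ht$parameter[["num df"]],
              ht$p.value, "two.sided", length(y),
              df2 = ht$parameter[["denom df"]])
}

#' Seed-level Bonferroni-corrected alpha
#'
#' @param base_alpha family-wise alpha (default 0.05).
#' @param n_regions number of seed regions entering the analysis stage
#'   (>= 1).
#' @return the per-test alpha `base_alpha / n_regions`.
#' @examples
#' bonferroni_alpha(0.05, 8)  # 0.00625
#' bonferroni_alpha(0.05, 12) # 0.0041667
#' @export
bonferroni_alpha <- function(base_alpha = 0.05, n_regions) {
  if (length(n_regions) != 1L || is.na(n_regions) || n_regions < 1)
    stop("n_regions must be >= 1", call. = FALSE)
  stopifnot(base_alpha > 0, base_alpha <= 1)
  base_alpha / n_regions
}

#' Hemisphere-resolved standard analysis regions
#'
#' The regions are independent analysis units, one per hemisphere: the
#' scene-selective areas OPA, PPA, RSC plus the hippocampus for the
#' Experiment 1/2 analyses (8 regions, seed-level alpha 0.00625), adding
#' the face-selective FFA and OFA for Experiment 3 (12 regions, 0.00416).
#'
#' @param experiment 1, 2 or 3.
#' @return character vector of region ids like "OPA_LH".
#' @export
standard_regions <- function(experiment = 3) {
  base <- c("OPA", "PPA", "RSC", "HC")
  if (as.integer(experiment) == 3L) base <- c("FFA", "OFA", base)
  as.vector(t(outer(base, c("LH", "RH"), paste, sep = "_")))
}

#' Construct a question specification
#'
#' A declarative description of one two-stage analysis: which per-subject
#' averaged distances are gated against zero, at what seed-level alpha, and
#' which follow-up comparisons run on the regions that survive the gate.
#'
#' @param question_id identifier such as "q1a".
#' @param selections named list of [cell_selection()] objects the question
#'   uses.
#' @param gates character vector of selection names gated with one-sample
#'   t tests (one test per region per gate).
#' @param gate_alpha list(base, divisor); `divisor = NULL` uses the number
#'   of gated regions.
#' @param followups list of follow-up descriptions; each a list with
#'   `name`, `type` ("paired_t", "two_sample_t", "anova", or "auto_group"
#'   which picks a two-sample t for two eligible groups and an ANOVA for
#'   more), selection names `a`/`b` (t tests) or `groups` (ANOVA /
#'   auto_group), `tail`, `requires` (gate selections that must be
#'   significant for a region to be eligible), optional `min_required`
#'   (eligibility needs at least this many of `requires`; default all),
#'   optional `regions` (restrict the candidate regions), and `alpha`
#'   (list(base, divisor); `divisor = NULL` uses the eligible-region
#'   count).
#' @param regions character vector of region ids (default: whatever the
#'   distance table contains).
#' @param experiments experiments feeding the question (metadata).
#' @return an object of class `question_spec`.
#' @export
question_spec <- function(question_id, selections, gates,
                          gate_alpha = list(base = 0.05, divisor = NULL),
                          followups = list(), regions = NULL,
                          experiments = NULL) {
  stopifnot(all(gates %in% names(selections)))
  for (fu in followups) {
    stopifnot(!is.null(fu$name), !is.null(fu$type))
    if (!all(fu$requires %in% gates))
      stop("follow-up '", fu$name, "' requires non-gated selections",
           call. = FALSE)
  }
  structure(list(question_id = question_id, selections = selections,
                 gates = gates, gate_alpha = gate_alpha,
                 followups = followups, regions = regions,
                 experiments = experiments),
            class = "question_spec")
}

#' Run one question's two-stage gated analysis
#'
#' Stage 1: per region and gated selection, a one-tailed one-sample t test
#' of the subject distances against zero at the seed-level
#' Bonferroni-corrected alpha. Stage 2: each follow-up comparison runs only
#' on the regions meeting its eligibility rule (all -- or at least
#' `min_required` -- of its required gates significant), at
#' `base / divisor` where the divisor defaults to the eligible-region
#' count. Paired comparisons drop subjects listwise (the dropped count is
#' recorded in `n`).
#'
#' @param spec a [question_spec()].
#' @param distances subject-distance table with columns `subject`,
#'   `region`, `selection`, `value` (as from [subject_distances()]).
#' @return an object of class `question_result`: list with `question_id`,
#'   `gates` and `followups` data.frames (columns region, selection/name,
#'   statistic, df, p, alpha, significant) and `eligible` (named list of
#'   eligible regions per follow-up).
#' @export
run_question <- function(spec, distances) {
  stopifnot(inherits(spec, "question_spec"))
  need <- c("subject", "region", "selection", "value")
  if (!all(need %in% names(distances)))
    stop("distances must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  regions <- spec$regions %||% sort(unique(distances$region))
  missing_sel <- setdiff(spec$gates, unique(distances$selection))
  if (length(missing_sel))
    stop("distances lack gated selection(s): ",
         paste(missing_sel, collapse = ", "), call. = FALSE)
  if (!all(regions %in% distances$region))
    stop("distances lack region(s): ",
         paste(setdiff(regions, distances$region), collapse = ", "),
         call. = FALSE)
  grab <- function(reg, sel) {
    d <- distances[distances$region == reg & distances$selection == sel, ]
    stats::setNames(d$value, d$subject)
  }
  gate_alpha <- bonferroni_alpha(spec$gate_alpha$base,
                                 spec$gate_alpha$divisor %||% length(regions))
  gates <- do.call(rbind, lapply(spec$gates, function(sel) {
    do.call(rbind, lapply(regions, function(reg) {
      v <- grab(reg, sel)
      tr <- one_sample_t(v[!is.na(v)], tail = "greater")
      cbind(data.frame(region = reg, selection = sel,
                       stringsAsFactors = FALSE),
            tr, alpha = gate_alpha, significant = tr$p < gate_alpha)
    }))
  }))
  gate_sig <- function(reg, sel)
    any(gates$significant[gates$region == reg & gates$selection == sel])
  eligible <- list()
  fu_rows <- list()
  for (fu in spec$followups) {
    cand <- intersect(fu$regions %||% regions, regions)
    req <- fu$requires %||% character(0)
    min_req <- fu$min_required %||% length(req)
    elig <- cand[vapply(cand, function(reg)
      sum(vapply(req, gate_sig, TRUE, reg = reg)) >= min_req, TRUE)]
    eligible[[fu$name]] <- elig
    if (length(elig) == 0L) next
    alpha <- bonferroni_alpha(fu$alpha$base %||% 0.05,
                              fu$alpha$divisor %||% length(elig))
    for (reg in elig) {
      tr <- switch(fu$type,
        paired_t = {
          a <- grab(reg, fu$a); b <- grab(reg, fu$b)
          ids <- intersect(names(a)[!is.na(a)], names(b)[!is.na(b)])
          paired_t(a[ids], b[ids], tail = fu$tail %||% "greater")
        },
        two_sample_t = {
          two_sample_t(grab(reg, fu$a), grab(reg, fu$b),
                       tail = fu$tail %||% "greater")
        },
        anova = one_way_anova(lapply(fu$groups, grab, reg = reg)),
        auto_group = {
          sig <- Filter(function(sel) gate_sig(reg, sel), fu$groups)
          if (length(sig) == 2L)
            two_sample_t(grab(reg, sig[[1]]), grab(reg, sig[[2]]),
                         tail = fu$tail %||% "greater")
          else one_way_anova(lapply(sig, grab, reg = reg))
        },
        stop("unknown follow-up type: ", fu$type, call. = FALSE))
      fu_rows[[length(fu_rows) + 1L]] <- cbind(
        data.frame(name = fu$name, region = reg, stringsAsFactors = FALSE),
        tr, alpha = alpha, significant = tr$p < alpha)
    }
  }
  followups <- if (length(fu_rows)) do.call(rbind, fu_rows) else NULL
  # gate discipline: a follow-up row must belong to an eligible region
  if (!is.null(followups)) {
    for (nm in unique(followups$name))
      stopifnot(all(followups$region[followups$name == nm] %in% eligible[[nm]]))
  }
  structure(list(question_id = spec$question_id, gates = gates,
                 followups = followups, eligible = eligible,
                 gate_alpha = gate_alpha),
            class = "question_result")
}

#' @export
print.question_result <- function(x, ...) {
  cat("Question", x$question_id, "- stage 1 gates (alpha =",
      format(x$gate_alpha, digits = 4), "):\n")
  print(x$gates[, c("region", "selection", "statistic", "df", "p",
                    "significant")], digits = 4)
  if (is.null(x$followups)) {
    cat("No region met a follow-up eligibility rule; stage 2 empty.\n")
  } else {
    cat("Stage 2 follow-ups:\n")
    print(x$followups[, c("name", "region", "test", "statistic", "df", "p",
                          "alpha", "significant")], digits = 4)
  }
  invisible(x)
}

#' Load question specifications from a YAML config
#'
#' Reads a declarative config (see the packaged
#' `inst/extdata/questions.yaml` describing Q1a-Q3c) into
#' [question_spec()] objects with [cell_selection()] predicates.
#'
#' @param path YAML file; default the packaged Q1a-Q3c fixture.
#' @return named list of `question_spec` objects.
#' @export
load_question_specs <- function(path = NULL) {
  path <- path %||% system.file("extdata", "questions.yaml",
                                package = "crossnobis")
  cfg <- yaml::read_yaml(path)
  lapply(cfg, function(q) {
    sels <- lapply(q$selections, function(s)
      cell_selection(category = s$category %||% "ignore",
                     domain = s$domain %||% "ignore",
                     quadrant = s$quadrant %||% "ignore",
                     restrict = s$restrict %||% list()))
    fus <- lapply(q$followups, function(fu) {
      fu$requires <- unlist(fu$requires)
      fu$groups <- unlist(fu$groups)
      fu$regions <- unlist(fu$regions)
      fu
    })
    question_spec(question_id = q$id, selections = sels,
                  gates = unlist(q$gates),
                  gate_alpha = list(base = q$gate_alpha$base %||% 0.05,
                                    divisor = q$gate_alpha$divisor),
                  followups = fus, regions = unlist(q$regions),
                  experiments = unlist(q$experiments))
  })
}
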