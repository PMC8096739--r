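# From per-subject RDMs to per-question averaged distances: factor-based
# cell selection, the +/- 2 SD exclusion rule pooled across subjects and
# stimulus pairs, within-subject averaging, and merging of subjects who
# took part in two experiments.

#' Define a selection of RDM cells by factor predicates
#'
#' A predicate over unordered condition pairs: for each of the three
#' factors (category, domain, quadrant) a pair can be required to agree
#' (`"same"`), to differ (`"different"`), or the factor can be ignored.
#' An optional restriction limits both members of the pair to given factor
#' levels (e.g. only perception, or only buildings).
#'
#' @param category,domain,quadrant one of "ignore", "same", "different".
#' @param restrict named list of allowed levels per factor, e.g.
#'   `list(domain = "perception", category = "building")`.
#' @param label optional human-readable selection label.
#' @return an object of class `cell_selection`.
#' @export
cell_selection <- function(category = "ignore", domain = "ignore",
                           quadrant = "ignore", restrict = list(),
                           label = NULL) {
  chk <- function(x) match.arg(x, c("ignore", "same", "different"))
  sel <- list(category = chk(category), domain = chk(domain),
              quadrant = chk(quadrant), restrict = restrict)
  sel$label <- label %||% paste0(
    paste(Filter(Negate(is.null), lapply(names(sel)[1:3], function(f)
      if (sel[[f]] != "ignore") paste0(f, "=", sel[[f]]))), collapse = ","),
    if (length(restrict))
      paste0("|", paste(names(restrict),
                        vapply(restrict, paste, "", collapse = "+"),
                        sep = ":", collapse = ",")))
  structure(sel, class = "cell_selection")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select the unordered condition pairs matching a predicate
#'
#' Enumerates all C(n, 2) unordered pairs of distinct conditions and keeps
#' exactly those satisfying every clause of the selection. Diagonal cells
#' (a condition with itself) are never selected.
#'
#' @param conditions condition table with the factor columns the predicate
#'   references.
#' @param selection a [cell_selection()].
#' @return a data.frame with integer columns `i`, `j` (i < j, row indices
#'   into `conditions`).
#' @export
select_pairs <- function(conditions, selection) {
  stopifnot(inherits(selection, "cell_selection"))
  n <- nrow(conditions)
  factors <- c("category", "domain", "quadrant")
  for (f in factors) {
    if (selection[[f]] != "ignore" &&
        (!f %in% names(conditions) || all(is.na(conditions[[f]]))))
      stop("predicate references factor '", f,
           "' absent from the condition labels", call. = FALSE)
  }
  keep_cond <- rep(TRUE, n)
  for (f in names(selection$restrict))
    keep_cond <- keep_cond & conditions[[f]] %in% selection$restrict[[f]]
  idx <- which(keep_cond)
  if (length(idx) < 2L) return(data.frame(i = integer(0), j = integer(0)))
  pairs <- t(utils::combn(idx, 2L))
  ok <- rep(TRUE, nrow(pairs))
  for (f in factors) {
    if (selection[[f]] == "ignore") next
    a <- conditions[[f]][pairs[, 1]]
    b <- conditions[[f]][pairs[, 2]]
    same <- !is.na(a) & !is.na(b) & a == b
    diff <- !is.na(a) & !is.na(b) & a != b
    ok <- ok & if (selection[[f]] == "same") same else diff
  }
  data.frame(i = pairs[ok, 1], j = pairs[ok, 2])
}

#' Mask distances beyond k standard deviations of their group
#'
#' Implements the exclusion rule applied before within-subject averaging:
#' within each group (in the analysis, one group per category x domain cell,
#' pooling values across subjects and stimulus pairs), values strictly
#' below mean - k*SD or strictly above mean + k*SD are masked. Values
#' exactly at the boundary are retained.
#'
#' @param values numeric vector of pooled cell distances.
#' @param group grouping vector (same length); a single group by default.
#' @param k number of standard deviations (default 2).
#' @return logical vector, TRUE = keep.
#' @export
exclude_outliers <- function(values, group = rep(1L, length(values)), k = 2) {
  stopifnot(length(values) == length(group), k >= 0)
  keep <- rep(TRUE, length(values))
  for (g in unique(group)) {
    sel <- group == g
    if (sum(sel) < 2L)
      stop("exclusion group with fewer than 2 values", call. = FALSE)
    m <- mean(values[sel]); s <- stats::sd(values[sel])
    if (is.na(s) || s == 0) next
    keep[sel] <- abs(values[sel] - m) <= k * s
  }
  keep
}

#' Average selected RDM cells within a subject
#'
#' @param rdm a crossnobis `rdm` (square matrix).
#' @param pairs pair table from [select_pairs()].
#' @param mask optional logical vector (one per pair); FALSE cells are
#'   excluded from the mean.
#' @return the arithmetic mean of the included cells, or NA (with a
#'   warning) if every cell was masked.
#' @export
average_cells <- function(rdm, pairs, mask = NULL) {
  if (nrow(pairs) == 0L) stop("empty pair selection", call. = FALSE)
  vals <- rdm[cbind(pairs$i, pairs$j)]
  if (!is.null(mask)) vals <- vals[mask]
  if (length(vals) == 0L) {
    warning("all selected cells were excluded; returning NA")
    return(NA_real_)
  }
  mean(vals)
}

#' Per-subject averaged distances for a set of selections
#'
#' For every (region, selection) combination: gather the selected RDM cells
#' of all subjects, apply the +/- 2 SD exclusion pooled across subjects and
#' pairs within that selection (per region), then average the surviving
#' cells within each subject.
#'
#' @param rdms nested list: `rdms[[subject]][[region]]` is an `rdm`; all
#'   subjects share the condition table.
#' @param selections named list of [cell_selection()] objects.
#' @param conditions condition table matching the RDMs.
#' @param exclude_k SD multiplier of the exclusion rule (NULL disables it).
#' @return a data.frame with columns `subject`, `region`, `selection`,
#'   `value`, `n_cells`, `n_excluded`.
#' @export
subject_distances <- function(rdms, selections, conditions, exclude_k = 2) {
  subjects <- names(rdms)
  regions <- names(rdms[[1]])
  out <- list()
  for (sel_name in names(selections)) {
    pairs <- select_pairs(conditions, selections[[sel_name]])
    for (reg in regions) {
      vals <- lapply(subjects, function(s)
        rdms[[s]][[reg]][cbind(pairs$i, pairs$j)])
      pooled <- unlist(vals)
      keep <- if (is.null(exclude_k)) rep(TRUE, length(pooled)) else
        exclude_outliers(pooled, k = exclude_k)
      km <- matrix(keep, nrow = nrow(pairs))
      for (si in seq_along(subjects)) {
        v <- vals[[si]][km[, si]]
        out[[length(out) + 1L]] <- data.frame(
          subject = subjects[si], region = reg, selection = sel_name,
          value = if (length(v)) mean(v) else NA_real_,
          n_cells = length(v), n_excluded = sum(!km[, si]),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Merge subjects who took part in more than one experiment
#'
#' Subjects present in several experiments contribute a single row whose
#' value is the arithmetic mean of their per-experiment values; all other
#' subjects pass through unchanged.
#'
#' @param values_by_experiment list of data.frames, each with columns
#'   `subject` and `value` (plus any shared metadata columns); a subject id
#'   may appear at most once per experiment.
#' @return a data.frame with one row per unique subject (columns `subject`,
#'   `value`, `n_experiments`).
#' @export
merge_repeat_subjects <- function(values_by_experiment) {
  for (df in values_by_experiment) {
    if (anyDuplicated(df$subject))
      stop("subject id duplicated within one experiment", call. = FALSE)
  }
  all <- do.call(rbind, lapply(values_by_experiment,
                               function(df) df[, c("subject", "value")]))
  agg <- stats::aggregate(value ~ subject, all, mean)
  n <- stats::aggregate(value ~ subject, all, length)
  data.frame(subject = agg$subject, value = agg$value,
             n_experiments = n$value, stringsAsFactors = FALSE)
}
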