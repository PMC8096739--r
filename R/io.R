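# Readers and writers: long-form RDM tables, subject-distance tables, and
# the optional NIfTI beta-map ingestion path for user-supplied data.

#' Write RDMs as a long-form TSV
#'
#' One row per unordered condition pair per subject and region:
#' `subject, region, condition_i, condition_j, distance`.
#'
#' @param rdms a single `rdm`, or a nested list `rdms[[subject]][[region]]`.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_rdm_tsv <- function(rdms, path) {
  if (inherits(rdms, "rdm")) {
    rdms <- list(list(rdms))
    names(rdms) <- attr(rdms[[1]][[1]], "subject")
    names(rdms[[1]]) <- attr(rdms[[1]][[1]], "region")
  }
  rows <- list()
  for (subj in names(rdms)) for (reg in names(rdms[[subj]])) {
    d <- rdms[[subj]][[reg]]
    idx <- which(upper.tri(d), arr.ind = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      subject = subj, region = reg,
      condition_i = rownames(d)[idx[, 1]],
      condition_j = colnames(d)[idx[, 2]],
      distance = d[idx], stringsAsFactors = FALSE)
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a long-form RDM TSV back into square matrices
#'
#' @param path TSV written by [write_rdm_tsv()].
#' @param conditions optional condition table fixing the condition order.
#' @return nested list `rdms[[subject]][[region]]` of `rdm` matrices.
#' @export
read_rdm_tsv <- function(path, conditions = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  ids <- if (!is.null(conditions)) conditions$condition_id else
    sort(unique(c(df$condition_i, df$condition_j)))
  if (is.null(conditions))
    conditions <- data.frame(condition_id = ids, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$subject), function(ds) {
    lapply(split(ds, ds$region), function(dr) {
      d <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
      d[cbind(dr$condition_i, dr$condition_j)] <- dr$distance
      d[cbind(dr$condition_j, dr$condition_i)] <- dr$distance
      new_rdm(d, conditions, dr$subject[1], dr$region[1])
    })
  })
  out
}

#' Write a subject-distance table as TSV
#'
#' @param distances data.frame from [subject_distances()] or
#'   [question_distances()].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_distances_tsv <- function(distances, path) {
  utils::write.table(distances, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a subject-distance TSV
#'
#' @param path TSV path.
#' @return data.frame with at least `subject`, `region`, `selection`,
#'   `value`.
#' @export
read_distances_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Build a pattern set from NIfTI beta maps and an ROI mask
#'
#' Ingestion path for user-supplied data: per run, a 4D NIfTI of beta
#' volumes (one volume per condition, in the order of the label table), a
#' 3D ROI mask (nonzero voxels are included), and a condition-label table
#' with a `condition_id` column. Requires the RNifti package.
#'
#' @param beta_files character vector of per-run 4D NIfTI paths.
#' @param mask_file 3D NIfTI mask path.
#' @param labels condition table (data.frame or TSV path) whose rows match
#'   the 4th dimension of each beta file.
#' @return a [pattern_set()].
#' @export
read_beta_nifti <- function(beta_files, mask_file, labels) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("read_beta_nifti() requires the RNifti package", call. = FALSE)
  if (is.character(labels))
    labels <- utils::read.table(labels, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
  mask <- as.array(RNifti::readNifti(mask_file)) != 0
  runs <- lapply(beta_files, function(f) {
    vol <- as.array(RNifti::readNifti(f))
    if (length(dim(vol)) != 4L || dim(vol)[4] != nrow(labels))
      stop("beta file ", f, " does not match the label table", call. = FALSE)
    t(apply(vol, 4, function(v) v[mask]))
  })
  pattern_set(runs, labels)
}
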