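# Cohort container: per-patient pathology and genomic embedding bags plus
# the survival table. Bags are ragged (variable N patches, K pathways) and
# stored unpadded. On disk the cohort is a directory: `meta.json` holds the
# layout version, interval count and interval edges; `survival.csv` the
# per-patient table; `patients/<id>/{pathology,genomic}.csv` the bag
# matrices, written at full double precision so a write/read round trip is
# bit-identical. Censoring convention everywhere: censor = 0 observed
# death, censor = 1 censored at last follow-up.

COHORT_LAYOUT_VERSION <- 1L

#' Construct one patient record
#'
#' @param patient_id unique id string (letters, digits, `.`, `_`, `-`).
#' @param pathology N x d_path numeric matrix of patch embeddings.
#' @param genomic K x d_gen numeric matrix of pathway embeddings.
#' @param time positive follow-up time in months.
#' @param censor 0 = death observed, 1 = censored.
#' @param bin_label optional discrete interval label (set by
#'   [assign_bins()]).
#' @return list of class `msurv_record`.
#' @export
patient_record <- function(patient_id, pathology, genomic, time, censor,
                           bin_label = NA_integer_) {
  rec <- structure(list(patient_id = patient_id,
                        pathology = as.matrix(pathology),
                        genomic = as.matrix(genomic),
                        time = as.numeric(time), censor = as.integer(censor),
                        bin_label = as.integer(bin_label)),
                   class = "msurv_record")
  validate_record(rec)
  rec
}

validate_record <- function(rec, t_bins = NULL) {
  id <- rec$patient_id
  if (!is.character(id) || length(id) != 1L || !grepl("^[A-Za-z0-9._-]+$", id))
    stop("invalid patient_id: ", format(id))
  if (nrow(rec$pathology) < 1L || nrow(rec$genomic) < 1L)
    stop("patient ", id, ": bags must contain at least one instance")
  if (!all(is.finite(rec$pathology)) || !all(is.finite(rec$genomic)))
    stop("patient ", id, ": non-finite values in a bag")
  if (!is.finite(rec$time) || rec$time <= 0)
    stop("patient ", id, ": time must be positive")
  if (!rec$censor %in% c(0L, 1L))
    stop("patient ", id, ": censor must be 0 (death observed) or 1 (censored)")
  if (!is.na(rec$bin_label) && !is.null(t_bins) &&
      (rec$bin_label < 1L || rec$bin_label > t_bins))
    stop("patient ", id, ": bin_label outside 1..", t_bins)
  invisible(rec)
}

#' Construct a cohort from patient records
#'
#' @param records list of [patient_record()]s with unique ids.
#' @param t_bins number of discrete time intervals (default 4).
#' @param bin_edges optional strictly ascending numeric vector of length
#'   `t_bins - 1`.
#' @return list of class `msurv_cohort`.
#' @export
new_cohort <- function(records, t_bins = 4L, bin_edges = NULL) {
  co <- structure(list(records = records, t_bins = as.integer(t_bins),
                       bin_edges = bin_edges),
                  class = "msurv_cohort")
  validate_cohort(co)
  co
}

validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "msurv_cohort"))
  if (length(cohort$records) == 0) stop("no patients in cohort")
  ids <- vapply(cohort$records, function(r) r$patient_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate patient_id: ",
                               ids[duplicated(ids)][1])
  if (!is.null(cohort$bin_edges)) {
    if (length(cohort$bin_edges) != cohort$t_bins - 1L)
      stop("bin_edges must have length t_bins - 1")
    if (any(diff(cohort$bin_edges) <= 0))
      stop("bin_edges must be strictly ascending")
  }
  for (r in cohort$records) validate_record(r, cohort$t_bins)
  invisible(cohort)
}

#' Survival table of a cohort
#'
#' @param cohort an `msurv_cohort`.
#' @return tibble with `patient_id`, `time_months`, `censor`, `bin_label`,
#'   `n_patches`, `n_pathways`.
#' @export
cohort_table <- function(cohort) {
  dplyr::bind_rows(purrr::map(cohort$records, function(r) {
    tibble::tibble(patient_id = r$patient_id, time_months = r$time,
                   censor = r$censor, bin_label = r$bin_label,
                   n_patches = nrow(r$pathology),
                   n_pathways = nrow(r$genomic))
  }))
}

#' Assign discrete interval labels to a cohort
#'
#' Labels every record by the interval containing its follow-up time
#' (see [discretize_times()] for the edge convention) and stores the
#' edges on the cohort. Edges may come from a different (training)
#' cohort to avoid fold leakage.
#'
#' @param cohort an `msurv_cohort`.
#' @param bin_edges strictly ascending edges of length `t_bins - 1`; if
#'   NULL, computed from this cohort's uncensored times.
#' @return the relabeled cohort.
#' @export
assign_bins <- function(cohort, bin_edges = NULL) {
  tab <- cohort_table(cohort)
  if (is.null(bin_edges)) {
    bin_edges <- discretize_times(tab$time_months, tab$censor,
                                  cohort$t_bins)$bin_edges
  }
  for (i in seq_along(cohort$records)) {
    cohort$records[[i]]$bin_label <-
      findInterval(cohort$records[[i]]$time, bin_edges) + 1L
  }
  cohort$bin_edges <- as.numeric(bin_edges)
  validate_cohort(cohort)
  cohort
}

write_matrix_txt <- function(m, path) {
  lines <- apply(matrix(sprintf("%.17g", m), nrow(m)), 1, paste, collapse = ",")
  writeLines(lines, path)
}

read_matrix_txt <- function(path) {
  m <- as.matrix(data.table::fread(path, header = FALSE))
  dimnames(m) <- NULL
  m
}

#' Write a cohort container to disk
#'
#' Directory layout: `meta.json` (layout_version, t_bins, bin_edges),
#' `survival.csv` (patient_id, time_months, censor, bin_label) and
#' `patients/<id>/{pathology,genomic}.csv`. Values round-trip
#' bit-identically through [read_cohort()].
#'
#' @param cohort a validated `msurv_cohort`.
#' @param path target directory (created; must not already exist unless
#'   `overwrite = TRUE`).
#' @param overwrite replace an existing container.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, overwrite = FALSE) {
  validate_cohort(cohort)
  if (dir.exists(path)) {
    if (!overwrite) stop("path already exists: ", path)
    unlink(path, recursive = TRUE)
  }
  dir.create(path, recursive = TRUE)
  meta <- list(layout_version = COHORT_LAYOUT_VERSION, t_bins = cohort$t_bins,
               bin_edges = cohort$bin_edges)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = I(17), null = "null")
  surv <- cohort_table(cohort)[, c("patient_id", "time_months",
                                   "censor", "bin_label")]
  # full-precision decimal so the follow-up times round-trip exactly
  surv$time_months <- sprintf("%.17g", surv$time_months)
  data.table::fwrite(surv, file.path(path, "survival.csv"))
  for (r in cohort$records) {
    pdir <- file.path(path, "patients", r$patient_id)
    dir.create(pdir, recursive = TRUE)
    write_matrix_txt(r$pathology, file.path(pdir, "pathology.csv"))
    write_matrix_txt(r$genomic, file.path(pdir, "genomic.csv"))
  }
  invisible(path)
}

#' Read a cohort container from disk
#'
#' Validates the layout version and every record invariant on load; a
#' patient directory missing a modality file is a structured error naming
#' the patient.
#'
#' @param path container directory written by [write_cohort()].
#' @return `msurv_cohort`.
#' @export
read_cohort <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) stop("not a cohort container: ", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$layout_version) ||
      meta$layout_version != COHORT_LAYOUT_VERSION)
    stop("cohort layout version mismatch: found ",
         format(meta$layout_version), ", expected ", COHORT_LAYOUT_VERSION)
  surv <- data.table::fread(file.path(path, "survival.csv"))
  if (nrow(surv) == 0) stop("no patients in cohort container")
  records <- purrr::map(seq_len(nrow(surv)), function(i) {
    id <- as.character(surv$patient_id[i])
    pdir <- file.path(path, "patients", id)
    pp <- file.path(pdir, "pathology.csv")
    gp <- file.path(pdir, "genomic.csv")
    if (!file.exists(pp)) stop("patient ", id, ": missing pathology bag")
    if (!file.exists(gp)) stop("patient ", id, ": missing genomic bag")
    patient_record(id, read_matrix_txt(pp), read_matrix_txt(gp),
                   time = surv$time_months[i], censor = surv$censor[i],
                   bin_label = surv$bin_label[i])
  })
  edges <- meta$bin_edges
  if (length(edges) == 0) edges <- NULL
  new_cohort(records, t_bins = meta$t_bins, bin_edges = edges)
}

#' @export
print.msurv_cohort <- function(x, ...) {
  tab <- cohort_table(x)
  cat("<msurv_cohort>", nrow(tab), "patients |",
      round(100 * mean(tab$censor == 1), 1), "% censored | t_bins =",
      x$t_bins, "\n")
  invisible(x)
}
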