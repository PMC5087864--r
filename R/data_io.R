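# Reading, writing and validating probes-x-patients copy-number datasets.
#
# On-disk formats (all plain TSV):
#   * copy-number matrix: header "probe_id" + patient ids, one row per probe,
#     log2 relative copy number, empty field or "NA" = missing;
#   * probe annotation: BED-like, columns probe_id, chrom, start, end
#     (0-based, half-open);
#   * centromere table: chrom, centromere_start, centromere_end;
#   * clinical table: one row per patient, controlled vocabulary in README.

#' Construct a copy-number dataset
#'
#' A copy-number dataset couples a probes-x-patients matrix of log2 relative
#' copy numbers with a genome-sorted probe annotation. It is the container
#' consumed by [median_center()], [validate_pair()] and [compute_gsvd()].
#'
#' @param values numeric matrix, probes in rows, patients in columns. `NA`
#'   encodes missing measurements (never imputed).
#' @param probes data.frame with columns `probe_id`, `chrom`, `start`, `end`
#'   and optionally `arm`; one row per matrix row. Coordinates are 0-based,
#'   half-open.
#' @param patients character vector of patient ids; defaults to
#'   `colnames(values)`.
#' @param sort sort probes (and matrix rows) into genome order.
#' @return an object of class `cn_dataset` with elements `values`, `probes`,
#'   `patients`.
#' @export
cn_dataset <- function(values, probes, patients = colnames(values),
                       sort = TRUE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  probes <- as.data.frame(probes)
  req <- c("probe_id", "chrom", "start", "end")
  if (!all(req %in% names(probes))) {
    stop("probe annotation must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(probes) != nrow(values)) {
    stop("annotation has ", nrow(probes), " probes but matrix has ",
         nrow(values), " rows")
  }
  if (is.null(patients)) {
    stop("patient ids are required (matrix column names or `patients`)")
  }
  patients <- as.character(patients)
  if (anyDuplicated(patients)) {
    stop("duplicate patient id(s): ",
         paste(unique(patients[duplicated(patients)]), collapse = ", "))
  }
  if (anyDuplicated(probes$probe_id)) {
    stop("duplicate probe id(s): ",
         paste(unique(probes$probe_id[duplicated(probes$probe_id)])[1:5],
               collapse = ", "))
  }
  if (any(probes$end <= probes$start)) {
    stop("probe intervals must satisfy end > start")
  }
  if (any(probes$start < 0)) stop("probe starts must be non-negative")
  rnk <- chrom_rank(probes$chrom) # errors on unknown chromosome
  if (sort) {
    ord <- order(rnk, probes$start, probes$end, probes$probe_id)
    probes <- probes[ord, , drop = FALSE]
    values <- values[ord, , drop = FALSE]
  }
  rownames(values) <- probes$probe_id
  colnames(values) <- patients
  rownames(probes) <- NULL
  structure(list(values = values, probes = probes, patients = patients),
            class = "cn_dataset")
}

#' @export
print.cn_dataset <- function(x, ...) {
  cat(sprintf("<cn_dataset> %d probes x %d patients, %d chromosome(s), %d missing value(s)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$probes$chrom)), sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.cn_dataset <- function(x) dim(x$values)

# Accept a cn_dataset or a bare matrix in numerical code paths.
cn_values <- function(x) {
  if (inherits(x, "cn_dataset")) x$values else as.matrix(x)
}

#' Read a centromere table
#'
#' @param path TSV with columns `chrom`, `centromere_start`, `centromere_end`
#'   (0-based, half-open).
#' @return data.frame with those columns.
#' @export
read_centromeres <- function(path) {
  cen <- read_tsv(path)
  req <- c("chrom", "centromere_start", "centromere_end")
  if (!all(req %in% names(cen))) {
    stop("centromere table must have columns: ", paste(req, collapse = ", "))
  }
  cen
}

#' Assign chromosome arms from a centromere table
#'
#' A probe is on the p arm when its interval midpoint lies before the
#' centromere midpoint, and on the q arm otherwise. Chromosomes absent from
#' the table get `NA` arms.
#'
#' @param probes probe annotation data.frame.
#' @param centromeres data.frame as returned by [read_centromeres()].
#' @return `probes` with an `arm` column ("p"/"q"/NA).
#' @export
assign_arms <- function(probes, centromeres) {
  mid <- (probes$start + probes$end) / 2
  cmid <- setNames((centromeres$centromere_start +
                      centromeres$centromere_end) / 2,
                   centromeres$chrom)
  cm <- cmid[probes$chrom]
  probes$arm <- ifelse(is.na(cm), NA_character_,
                       ifelse(mid < cm, "p", "q"))
  probes
}

#' Read a probe annotation table
#'
#' @param path BED-like TSV: `probe_id`, `chrom`, `start`, `end`. A header
#'   row is optional and auto-detected.
#' @param centromeres optional centromere data.frame; when given, arms are
#'   assigned via [assign_arms()].
#' @return probe annotation data.frame.
#' @export
read_probe_annotation <- function(path, centromeres = NULL) {
  first <- strsplit(readLines(path, n = 1), "\t")[[1]]
  has_header <- suppressWarnings(is.na(as.numeric(first[3])))
  ann <- as.data.frame(data.table::fread(path, sep = "\t",
                                         header = has_header))
  if (!has_header) names(ann)[1:4] <- c("probe_id", "chrom", "start", "end")
  ann <- ann[, c("probe_id", "chrom", "start", "end")]
  ann$probe_id <- as.character(ann$probe_id)
  if (!is.null(centromeres)) ann <- assign_arms(ann, centromeres)
  ann
}

#' Read a copy-number matrix with its probe annotation
#'
#' Probes present in the matrix but absent from the annotation are dropped
#' with a warning naming the count; if the dropped fraction exceeds
#' `max_unannotated` the read fails. The returned dataset is sorted into
#' genome order.
#'
#' @param path TSV, header `probe_id` followed by patient ids.
#' @param annotation_path BED-like probe annotation TSV.
#' @param centromere_path optional centromere TSV for arm assignment.
#' @param max_unannotated maximal tolerated fraction of unannotated probes.
#' @return a [cn_dataset()].
#' @export
read_copy_number <- function(path, annotation_path, centromere_path = NULL,
                             max_unannotated = 0.5) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = c("NA", ""))
  ids <- as.character(dt[[1]])
  pat <- names(dt)[-1]
  if (anyDuplicated(pat)) {
    stop("duplicate patient column id(s) in ", path, ": ",
         paste(unique(pat[duplicated(pat)]), collapse = ", "))
  }
  if (anyDuplicated(ids)) {
    stop("duplicate probe id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)])[1:5], collapse = ", "))
  }
  vals <- as.matrix(dt[, -1, with = FALSE])
  rownames(vals) <- ids
  cen <- if (!is.null(centromere_path)) read_centromeres(centromere_path)
  ann <- read_probe_annotation(annotation_path, centromeres = cen)
  keep <- ids %in% ann$probe_id
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    if (n_drop / length(ids) > max_unannotated) {
      stop(n_drop, "/", length(ids), " matrix probes lack annotation ",
           "(> max_unannotated = ", max_unannotated, ")")
    }
    warning(n_drop, " probe(s) without annotation dropped from ", path)
    vals <- vals[keep, , drop = FALSE]
    ids <- ids[keep]
  }
  ann <- ann[match(ids, ann$probe_id), , drop = FALSE]
  cn_dataset(vals, ann, patients = pat)
}

#' Write a copy-number dataset back to TSV
#'
#' Inverse of [read_copy_number()]; `read -> write -> read` round-trips
#' values and ids exactly.
#'
#' @param dataset a [cn_dataset()].
#' @param path output matrix TSV.
#' @param annotation_path optional output annotation TSV.
#' @export
write_copy_number <- function(dataset, path, annotation_path = NULL) {
  vals <- apply(dataset$values, 2, num_full)
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = nrow(dataset$values))
  colnames(vals) <- dataset$patients
  df <- data.frame(probe_id = dataset$probes$probe_id,
                   vals, check.names = FALSE)
  write_tsv(df, path)
  if (!is.null(annotation_path)) {
    cols <- intersect(c("probe_id", "chrom", "start", "end", "arm"),
                      names(dataset$probes))
    write_tsv(dataset$probes[, cols], annotation_path)
  }
  invisible(path)
}

#' Read a clinical annotation table
#'
#' One row per patient. Recognised columns (all optional except
#' `patient_id`): `survival_time` (months), `event` (0/1/TRUE/FALSE),
#' `chemotherapy`, `radiation`, `age_group`, `grade`, `mgmt_status`,
#' `idh1_status`, `gender`, `batch`.
#'
#' @param path TSV path.
#' @return data.frame keyed by `patient_id`.
#' @export
read_clinical <- function(path) {
  cl <- read_tsv(path)
  if (!"patient_id" %in% names(cl)) stop("clinical table needs `patient_id`")
  if (anyDuplicated(cl$patient_id)) stop("duplicate patient_id in clinical table")
  if ("event" %in% names(cl)) cl$event <- as.logical(cl$event)
  cl
}

#' Read a segment table
#'
#' @param path TSV with columns `chrom`, `start`, `end`, `probe_count`
#'   (0-based, half-open coordinates).
#' @return data.frame of segments.
#' @export
read_segments <- function(path) {
  seg <- read_tsv(path)
  req <- c("chrom", "start", "end", "probe_count")
  if (!all(req %in% names(seg))) {
    stop("segment table must have columns: ", paste(req, collapse = ", "))
  }
  seg
}

#' Median-center each patient profile
#'
#' Subtracts from every patient column its median over non-missing probes.
#' Missing values stay missing and are excluded from the median.
#'
#' @param dataset a [cn_dataset()] (or bare matrix).
#' @return object of the same type with each column median-zero.
#' @export
median_center <- function(dataset) {
  v <- cn_values(dataset)
  n_ok <- colSums(!is.na(v))
  if (any(n_ok == 0)) {
    ids <- colnames(v)[n_ok == 0] %||% which(n_ok == 0)
    stop("patient profile(s) fully missing: ", paste(ids, collapse = ", "))
  }
  med <- apply(v, 2, median, na.rm = TRUE)
  v <- sweep(v, 2, med)
  if (inherits(dataset, "cn_dataset")) {
    dataset$values <- v
    dataset
  } else v
}

#' Drop probes with any missing value
#'
#' The decomposition requires complete data; probes missing in any patient
#' are removed here, with the count reported.
#'
#' @param dataset a [cn_dataset()].
#' @param quiet suppress the message.
#' @return filtered dataset.
#' @export
drop_missing_probes <- function(dataset, quiet = FALSE) {
  stopifnot(inherits(dataset, "cn_dataset"))
  keep <- complete.cases(dataset$values)
  n_drop <- sum(!keep)
  if (n_drop > 0 && !quiet) {
    message(n_drop, " probe(s) with missing values dropped")
  }
  dataset$values <- dataset$values[keep, , drop = FALSE]
  dataset$probes <- dataset$probes[keep, , drop = FALSE]
  rownames(dataset$probes) <- NULL
  dataset
}

# Numerical column rank via eigenvalues of the N x N cross-product
# (cheap for M >> N). The cross-product squares the conditioning, so the
# N * eps * largest tolerance is applied on the eigenvalue scale.
numeric_rank <- function(values) {
  v <- values[complete.cases(values), , drop = FALSE]
  if (nrow(v) < ncol(v)) return(list(rank = 0L, n = ncol(values)))
  ev <- eigen(crossprod(v), symmetric = TRUE, only.values = TRUE)$values
  tol <- ncol(v) * .Machine$double.eps * max(ev)
  list(rank = sum(ev > tol), n = ncol(values))
}

#' Validate a patient-matched tumor/normal pair
#'
#' Asserts the structural contract of the comparative decomposition: both
#' datasets list the same patients in the same order, and each matrix has
#' full numerical column rank (rank N). Probe counts may differ.
#'
#' @param tumor,normal [cn_dataset()] objects.
#' @return invisibly, `list(tumor, normal)` on success.
#' @export
validate_pair <- function(tumor, normal) {
  stopifnot(inherits(tumor, "cn_dataset"), inherits(normal, "cn_dataset"))
  if (!identical(tumor$patients, normal$patients)) {
    only_t <- setdiff(tumor$patients, normal$patients)
    only_n <- setdiff(normal$patients, tumor$patients)
    if (length(only_t) || length(only_n)) {
      stop("patient mismatch; tumor-only: {",
           paste(only_t, collapse = ", "), "}, normal-only: {",
           paste(only_n, collapse = ", "), "}")
    }
    stop("patient lists contain the same ids but in different order")
  }
  for (nm in c("tumor", "normal")) {
    d <- if (nm == "tumor") tumor else normal
    r <- numeric_rank(d$values)
    if (r$rank < r$n) {
      stop(nm, " dataset is rank deficient (numerical rank ", r$rank,
           " < N = ", r$n, ")")
    }
  }
  invisible(list(tumor = tumor, normal = normal))
}
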