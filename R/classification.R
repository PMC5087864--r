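# Binary low/high patient classification by pattern weight.
#
# Discovery cohorts are classified by the probelet coefficient of the
# pattern component; validation and cross-cohort classification use the
# Pearson correlation of the pattern arraylet with each patient's profile.
# A correlation-scale base cutoff (0.15 in the published glioblastoma
# classifier) is moved onto the coefficient scale by multiplying with the
# 2-norm of the discovery correlations — the unit-norm probelet is, up to
# noise, the correlation vector divided by that norm, so the two
# formulations label the same patients.

#' Correlate a pattern with every patient profile
#'
#' Pearson correlation of the arraylet pattern with each patient column,
#' computed over the probes non-missing in that patient. Patients with
#' fewer than `min_probes` usable probes, or with zero variance over them,
#' get a missing score (the latter with a warning).
#'
#' @param pattern numeric arraylet vector in the profiles' probe space.
#' @param profiles a [cn_dataset()] or bare matrix, probes x patients.
#' @param min_probes minimal overlapping probe count for a valid score.
#' @return named numeric vector of correlations (NA = no valid score).
#' @export
correlate_pattern <- function(pattern, profiles, min_probes = 100L) {
  v <- cn_values(profiles)
  if (length(pattern) != nrow(v)) {
    stop("pattern length (", length(pattern),
         ") != number of probes (", nrow(v), ")")
  }
  out <- setNames(rep(NA_real_, ncol(v)),
                  colnames(v) %||% paste0("patient", seq_len(ncol(v))))
  for (j in seq_len(ncol(v))) {
    ok <- !is.na(v[, j])
    if (sum(ok) < min_probes) next
    if (sd(v[ok, j]) == 0 || sd(pattern[ok]) == 0) {
      warning("zero-variance profile for patient ", names(out)[j],
              "; score set to missing")
      next
    }
    out[j] <- cor(pattern[ok], v[ok, j])
  }
  out
}

#' Scale a correlation cutoff to the coefficient scale
#'
#' Multiplies the base cutoff by the Euclidean 2-norm of the discovery
#' correlations.
#'
#' @param base_cutoff correlation-scale cutoff (e.g. 0.15).
#' @param correlations non-empty numeric vector without missing values.
#' @return the scaled cutoff.
#' @export
scale_cutoff <- function(base_cutoff, correlations) {
  if (length(correlations) == 0) stop("empty correlation vector")
  if (anyNA(correlations)) stop("correlations contain missing values")
  base_cutoff * sqrt(sum(correlations^2))
}

#' Classify patients into low/high pattern-weight groups
#'
#' Strictly above the cutoff is `"high"`; at or below is `"low"` (boundary
#' ties go to low). Patients with missing scores are excluded with a
#' message listing their ids.
#'
#' @param scores named numeric vector (probelet coefficients or
#'   correlations).
#' @param cutoff classification cutoff on the scores' scale.
#' @param mode `"coefficient"` or `"correlation"` — recorded, not acted on.
#' @return a `patient_classification`: data.frame `table` (`patient_id`,
#'   `score`, `label`) plus `cutoff` and `mode`.
#' @export
classify <- function(scores, cutoff, mode = c("coefficient", "correlation")) {
  mode <- match.arg(mode)
  ids <- names(scores) %||% paste0("patient", seq_along(scores))
  miss <- is.na(scores)
  if (all(miss)) warning("all scores missing; empty classification")
  else if (any(miss)) {
    message("excluding ", sum(miss), " patient(s) with missing scores: ",
            paste(ids[miss], collapse = ", "))
  }
  tab <- data.frame(patient_id = ids[!miss], score = scores[!miss],
                    label = ifelse(scores[!miss] > cutoff, "high", "low"),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab, cutoff = cutoff, mode = mode),
            class = "patient_classification")
}

#' @export
print.patient_classification <- function(x, ...) {
  cat(sprintf("<patient_classification> mode %s, cutoff %.4g: %d high / %d low\n",
              x$mode, x$cutoff, sum(x$table$label == "high"),
              sum(x$table$label == "low")))
  invisible(x)
}

#' Write a classification table to TSV
#'
#' @param classification a `patient_classification`.
#' @param path output path.
#' @export
write_classification <- function(classification, path) {
  tab <- classification$table
  tab$score <- num_fmt(tab$score)
  tab$mode <- classification$mode
  tab$cutoff <- num_fmt(classification$cutoff)
  write_tsv(tab, path)
}
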