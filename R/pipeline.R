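# End-to-end discovery and validation flows.
#
# Discovery: median-center -> validate the pair -> GSVD -> canonical
# component labels -> pick the pattern component (the most tumor-exclusive
# component whose probelet is not enriched in a batch annotation) -> CNA
# calls from its tumor arraylet -> classify patients by probelet
# coefficient with the norm-scaled cutoff -> orient the pattern so "high"
# is the shorter-survival group -> survival report.
#
# Validation: median-center -> correlate the discovery arraylet with each
# profile (missing-aware) -> classify at a fixed cutoff -> survival report.
#
# Both flows are deterministic given their inputs, and `run_discovery()`
# writes byte-identical outputs on identical reruns.

#' Discovery run configuration
#'
#' Inputs may be in-memory objects or file paths; paths are loaded with the
#' package readers.
#'
#' @param tumor,normal [cn_dataset()]s, or paths to matrix TSVs.
#' @param clinical clinical data.frame or TSV path.
#' @param annotation,centromeres annotation/centromere TSV paths (only
#'   needed when `tumor`/`normal` are paths).
#' @param segments optional segment table (data.frame or TSV path).
#' @param out_dir optional output directory; when given, all intermediates
#'   and a `report.json` are persisted.
#' @param base_cutoff correlation-scale classification cutoff.
#' @param exclude baseline exclusion regions (see [compute_baseline()]).
#' @param thresholds an [exclusivity_thresholds()] list.
#' @param min_segment_probes minimal probes per retained segment.
#' @param batch_annotation clinical column marking the batch; components
#'   enriched in it are skipped when picking the pattern.
#' @param batch_alpha enrichment level below which a component counts as
#'   batch-driven.
#' @param component optional explicit pattern component index, overriding
#'   the heuristic.
#' @param seed seed recorded in the report (the discovery flow itself is
#'   deterministic).
#' @return a `discovery_config` list.
#' @export
discovery_config <- function(tumor, normal, clinical,
                             annotation = NULL, centromeres = NULL,
                             segments = NULL, out_dir = NULL,
                             base_cutoff = 0.15,
                             exclude = c("chr7", "chr10", "chr9p"),
                             thresholds = exclusivity_thresholds(),
                             min_segment_probes = 5L,
                             batch_annotation = "batch",
                             batch_alpha = 0.001,
                             component = NULL,
                             seed = 1L) {
  for (p in c(tumor, normal, clinical, annotation, centromeres, segments)) {
    if (is.character(p) && length(p) == 1 && !file.exists(p)) {
      stop("input file does not exist: ", p)
    }
  }
  structure(list(tumor = tumor, normal = normal, clinical = clinical,
                 annotation = annotation, centromeres = centromeres,
                 segments = segments, out_dir = out_dir,
                 base_cutoff = base_cutoff, exclude = exclude,
                 thresholds = thresholds,
                 min_segment_probes = min_segment_probes,
                 batch_annotation = batch_annotation,
                 batch_alpha = batch_alpha, component = component,
                 seed = seed),
            class = "discovery_config")
}

load_dataset <- function(x, config) {
  if (inherits(x, "cn_dataset")) return(x)
  read_copy_number(x, config$annotation, config$centromeres)
}

load_clinical <- function(x) {
  if (is.data.frame(x)) x else read_clinical(x)
}

# How strongly a probelet separates the batch annotation's levels (small P
# = batch-like). A batch effect expresses as a location shift of the
# coefficients, so the Mann-Whitney P across the two batch levels is the
# primary criterion; the sign-split hypergeometric is the fallback for
# annotations with more than two levels.
batch_p <- function(probelet, clinical, annotation) {
  if (is.null(annotation) || !annotation %in% names(clinical)) return(1)
  enr <- annotate_probelet(probelet, clinical, annotation)
  if (is.na(enr$mann_whitney_p)) min(enr$table$p_hyper)
  else enr$mann_whitney_p
}

#' Run the discovery flow
#'
#' @param config a [discovery_config()].
#' @return a `discovery_report` list: `gsvd_summary`, `component` (chosen
#'   pattern component), `component_labels`, `baseline`, `calls`
#'   (chromosome/arm/segment/probe tables), `correlations`, `cutoff`,
#'   `classification`, `survival`, `oriented` (whether the pattern sign was
#'   flipped post hoc), `dropped_probes`, `seed`.
#' @export
run_discovery <- function(config) {
  stopifnot(inherits(config, "discovery_config"))
  tumor <- load_dataset(config$tumor, config)
  normal <- load_dataset(config$normal, config)
  clinical <- load_clinical(config$clinical)
  segments <- config$segments
  if (is.character(segments)) segments <- read_segments(segments)

  tumor <- median_center(tumor)
  normal <- median_center(normal)
  n_before <- nrow(tumor$values) + nrow(normal$values)
  tumor <- drop_missing_probes(tumor, quiet = TRUE)
  normal <- drop_missing_probes(normal, quiet = TRUE)
  dropped <- n_before - nrow(tumor$values) - nrow(normal$values)
  validate_pair(tumor, normal)

  model <- compute_gsvd(tumor, normal)
  labels <- classify_components(model, config$thresholds)

  clin <- clinical[match(model$patients, clinical$patient_id), , drop = FALSE]
  if (anyNA(clin$patient_id)) {
    stop("clinical table is missing patient(s): ",
         paste(setdiff(model$patients, clinical$patient_id), collapse = ", "))
  }

  chosen <- config$component
  if (is.null(chosen)) {
    # candidates: the tumor-exclusive components (all components, in theta
    # order, when none is exclusive). Skip batch-driven candidates; if every
    # candidate is flagged (batch confounded with the biology), fall back to
    # the least batch-enriched candidate rather than to a noise component.
    cand <- which(labels == "tumor_exclusive")
    if (!length(cand)) cand <- seq_along(model$theta)
    pvals <- vapply(cand, function(j) {
      batch_p(model$V[, j], clin, config$batch_annotation)
    }, 0)
    ok <- pvals >= config$batch_alpha
    chosen <- if (any(ok)) cand[which(ok)[1]] else cand[which.max(pvals)]
  }

  pattern <- model$U1[, chosen]
  probelet <- model$V[, chosen]

  correlations <- correlate_pattern(pattern, tumor,
                                    min_probes = min(100L, nrow(tumor$values)))
  if (anyNA(correlations)) {
    stop("discovery correlations contain missing scores")
  }
  cutoff <- scale_cutoff(config$base_cutoff, correlations)
  corr_norm <- sqrt(sum(correlations^2))
  # probelet coefficients re-expressed on the correlation scale: the
  # unit-norm probelet times ||correlations|| tracks the correlations
  # themselves, so the scaled cutoff applies to it directly.
  scores <- setNames(probelet * corr_norm, model$patients)
  cls <- classify(scores, cutoff, mode = "coefficient")

  records <- survival_records(clin$patient_id, clin$survival_time,
                              clin$event)
  oriented <- FALSE
  grp <- cls$table$label[match(records$patient_id, cls$table$patient_id)]
  if (length(unique(grp)) == 2) {
    med <- vapply(c("low", "high"), function(g) {
      m <- km_curve(records[grp == g, , drop = FALSE])$median
      if (is.na(m)) Inf else m
    }, 0)
    if (med[["high"]] > med[["low"]]) {
      # orient the pattern so that "high" weight carries the worse outcome
      oriented <- TRUE
      pattern <- -pattern
      probelet <- -probelet
      scores <- -scores
      correlations <- -correlations
      cls <- classify(scores, cutoff, mode = "coefficient")
      grp <- cls$table$label[match(records$patient_id, cls$table$patient_id)]
    }
  }
  records$group <- grp

  baseline <- compute_baseline(pattern, tumor$probes,
                               exclude = config$exclude)
  chroms <- unique(tumor$probes$chrom)
  chrom_calls <- do.call(rbind, lapply(chroms, function(ch) {
    call_chromosome_or_arm(pattern, tumor$probes, baseline, ch)
  }))
  arm_calls <- NULL
  if ("arm" %in% names(tumor$probes) && !anyNA(tumor$probes$arm)) {
    arms <- unique(paste0(tumor$probes$chrom, tumor$probes$arm))
    arm_calls <- do.call(rbind, lapply(arms, function(a) {
      call_chromosome_or_arm(pattern, tumor$probes, baseline, a)
    }))
  }
  seg_calls <- NULL
  if (!is.null(segments)) {
    segments <- filter_segments(segments, config$min_segment_probes)
    if (nrow(segments)) {
      seg_calls <- call_segments(pattern, tumor$probes, baseline, segments)
    }
  }
  probe_calls <- call_probes(pattern, tumor$probes, baseline)

  surv <- if (length(unique(records$group)) == 2) {
    survival_report(records,
                    scores = cls$table$score[match(records$patient_id,
                                                   cls$table$patient_id)])
  } else NULL

  report <- structure(list(
    gsvd_summary = summary(model, config$thresholds),
    component = chosen,
    component_labels = labels,
    model = model,
    pattern = pattern,
    probelet = probelet,
    baseline = baseline,
    calls = list(chromosome = chrom_calls, arm = arm_calls,
                 segment = seg_calls, probe = probe_calls),
    correlations = correlations,
    cutoff = cutoff,
    classification = cls,
    survival = surv,
    oriented = oriented,
    dropped_probes = dropped,
    seed = config$seed
  ), class = "discovery_report")

  if (!is.null(config$out_dir)) {
    write_discovery_report(report, tumor, config)
  }
  report
}

# Persist all intermediates; formatting is fixed so identical runs give
# byte-identical files.
write_discovery_report <- function(report, tumor, config) {
  dir <- config$out_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gsvd(report$model, dir, config$thresholds)
  region_calls <- report$calls[c("chromosome", "arm", "segment")]
  region_calls <- do.call(rbind, region_calls[!vapply(region_calls, is.null,
                                                      TRUE)])
  region_calls$genomic_dev <- num_fmt(region_calls$genomic_dev)
  region_calls$chrom_dev <- num_fmt(region_calls$chrom_dev)
  write_tsv(region_calls, file.path(dir, "cna_calls.tsv"))
  pc <- report$calls$probe
  pc$genomic_dev <- num_fmt(pc$genomic_dev)
  pc$chrom_dev <- num_fmt(pc$chrom_dev)
  write_tsv(pc, file.path(dir, "probe_calls.tsv"))
  write_classification(report$classification,
                       file.path(dir, "classification.tsv"))
  json <- list(
    seed = report$seed,
    component = report$component,
    component_labels = report$component_labels,
    theta = round(report$gsvd_summary$theta, 10),
    entropy = round(unname(report$model$entropy), 10),
    cutoff = round(report$cutoff, 10),
    oriented = report$oriented,
    dropped_probes = report$dropped_probes,
    n_high = sum(report$classification$table$label == "high"),
    n_low = sum(report$classification$table$label == "low")
  )
  if (!is.null(report$survival)) {
    json$survival <- list(
      groups = report$survival$groups,
      logrank_p = report$survival$logrank$p,
      hazard_ratio = report$survival$cox$hr[1],
      hr_ci = c(report$survival$cox$ci_low[1],
                report$survival$cox$ci_high[1]),
      concordance = report$survival$concordance
    )
  }
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(dir)
}

#' Run the validation flow
#'
#' Classifies an independent cohort by correlating a discovery pattern with
#' each (median-centered) profile, then reports survival by group. When the
#' validation probe space differs from the pattern's, supply `pairs` and
#' `side` to project the pattern through a cross-platform probe matching.
#'
#' @param profiles a [cn_dataset()] (or matrix) of validation tumor
#'   profiles; missing values allowed.
#' @param pattern discovery arraylet vector (in its native probe space).
#' @param clinical clinical data.frame or TSV path.
#' @param cutoff fixed correlation cutoff (e.g. the discovery
#'   `base_cutoff`, or a rescaled value).
#' @param pairs optional pair table from [match_probes()] used to project
#'   `pattern` and the profiles onto a common probe subset.
#' @param side which side of `pairs` the `pattern` lives on (`"a"` or
#'   `"b"`); the profiles are taken from the other side.
#' @param min_probes minimal overlapping probes per valid correlation.
#' @return a `validation_report` list: `correlations`, `classification`,
#'   `survival`.
#' @export
run_validation <- function(profiles, pattern, clinical, cutoff = 0.15,
                           pairs = NULL, side = c("a", "b"),
                           min_probes = 100L) {
  side <- match.arg(side)
  clinical <- load_clinical(clinical)
  v <- cn_values(profiles)
  if (ncol(v) == 0) stop("empty validation cohort")
  if (!is.null(pairs)) {
    pattern <- project_profile(pattern, pairs, side)
    other <- if (side == "a") "b" else "a"
    v <- apply(v, 2, project_profile, pairs = pairs, side = other)
  }
  if (length(pattern) != nrow(v)) {
    stop("probe-space mismatch between pattern and profiles; ",
         "supply a `pairs` table from match_probes()")
  }
  v <- median_center(v)
  correlations <- correlate_pattern(pattern, v,
                                    min_probes = min(min_probes, nrow(v)))
  cls <- classify(correlations, cutoff, mode = "correlation")
  clin <- clinical[match(cls$table$patient_id, clinical$patient_id), ,
                   drop = FALSE]
  surv <- NULL
  if (!anyNA(clin$patient_id) && length(unique(cls$table$label)) == 2) {
    records <- survival_records(clin$patient_id, clin$survival_time,
                                clin$event, group = cls$table$label)
    surv <- survival_report(records, scores = cls$table$score)
  }
  structure(list(correlations = correlations, classification = cls,
                 survival = surv),
            class = "validation_report")
}
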