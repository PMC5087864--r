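# One-to-one cross-platform probe matching by genomic overlap.
#
# Two platforms' probe annotations (0-based, half-open intervals) are paired
# greedily: platform A is scanned in genome order, and each A probe takes
# the not-yet-matched overlapping B probe preferred by the tie-break. Every
# retained pair overlaps by at least one base on the same chromosome, and
# each probe of either platform appears in at most one pair.
#
# Tie-break ("start" anchor, the default): the B probe whose start is
# nearest the A probe's start; residual ties go to the smaller B start, then
# the smaller B index. The "end" anchor variant uses end coordinates
# instead; the published rule is direction-ambiguous, so both are offered.

check_genome_sorted <- function(ann, label) {
  if (nrow(ann) < 2) return(invisible(TRUE))
  r <- chrom_rank(ann$chrom)
  dr <- diff(r)
  ds <- diff(ann$start)
  if (any(dr < 0) || any(dr == 0 & ds < 0)) {
    stop("annotation ", label, " is not genome-sorted")
  }
  invisible(TRUE)
}

#' Match probes across two platforms by overlap
#'
#' @param annotation_a,annotation_b genome-sorted probe annotations
#'   (`probe_id`, `chrom`, `start`, `end`; 0-based half-open).
#' @param anchor `"start"` (default) or `"end"`: the coordinate used to
#'   break ties among multiple overlapping candidates.
#' @return data.frame of pairs: `index_a`, `index_b` (row indices into the
#'   annotations), `probe_a`, `probe_b`, `chrom`, `overlap` (bp, >= 1).
#' @export
match_probes <- function(annotation_a, annotation_b,
                         anchor = c("start", "end")) {
  anchor <- match.arg(anchor)
  check_genome_sorted(annotation_a, "A")
  check_genome_sorted(annotation_b, "B")
  out <- vector("list", 0L)
  for (ch in intersect(unique(annotation_a$chrom),
                       unique(annotation_b$chrom))) {
    ia <- which(annotation_a$chrom == ch)
    ib <- which(annotation_b$chrom == ch)
    as_ <- annotation_a$start[ia]; ae <- annotation_a$end[ia]
    bs <- annotation_b$start[ib]; be <- annotation_b$end[ib]
    used <- rep(FALSE, length(ib))
    res_a <- integer(0); res_b <- integer(0); ov <- integer(0)
    for (j in seq_along(ia)) {
      cand <- which(!used & bs < ae[j] & be > as_[j])
      if (!length(cand)) next
      if (anchor == "start") {
        dist <- abs(bs[cand] - as_[j])
      } else {
        dist <- abs(be[cand] - ae[j])
      }
      pick <- cand[order(dist, bs[cand], cand)][1]
      used[pick] <- TRUE
      res_a <- c(res_a, j); res_b <- c(res_b, pick)
      ov <- c(ov, min(ae[j], be[pick]) - max(as_[j], bs[pick]))
    }
    if (length(res_a)) {
      out[[length(out) + 1L]] <- data.frame(
        index_a = ia[res_a], index_b = ib[res_b],
        probe_a = annotation_a$probe_id[ia[res_a]],
        probe_b = annotation_b$probe_id[ib[res_b]],
        chrom = ch, overlap = ov, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(index_a = integer(), index_b = integer(),
                      probe_a = character(), probe_b = character(),
                      chrom = character(), overlap = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Restrict pairs to consistently aberrated probes
#'
#' Keeps the pairs whose two probes carry the same non-trivial call on
#' their respective patterns: both gain, or both loss. Discordant and
#' uncalled pairs are dropped.
#'
#' @param pairs data.frame from [match_probes()].
#' @param calls_a,calls_b per-probe call tables from [call_probes()] on
#'   platform A's and B's patterns (one row per annotation row).
#' @return the filtered pair data.frame.
#' @export
consistent_pairs <- function(pairs, calls_a, calls_b) {
  if (max(pairs$index_a, 0) > nrow(calls_a) ||
      max(pairs$index_b, 0) > nrow(calls_b)) {
    stop("call table shorter than the annotation the pairs index into")
  }
  da <- calls_a$direction[pairs$index_a]
  db <- calls_b$direction[pairs$index_b]
  keep <- da == db & da %in% c("gain", "loss")
  pairs[keep, , drop = FALSE]
}

#' Project a profile onto the paired probe subset
#'
#' @param profile numeric vector indexed by one platform's probes (missing
#'   values preserved).
#' @param pairs data.frame from [match_probes()].
#' @param side `"a"` or `"b"`: which platform `profile` is indexed by.
#' @return the profile restricted to the paired probes, in pair order.
#' @export
project_profile <- function(profile, pairs, side = c("a", "b")) {
  side <- match.arg(side)
  idx <- if (side == "a") pairs$index_a else pairs$index_b
  if (length(idx) && max(idx) > length(profile)) {
    stop("pair index exceeds profile length")
  }
  profile[idx]
}

#' Write a pair table to TSV
#'
#' @param pairs data.frame from [match_probes()].
#' @param path output path.
#' @export
write_pairs <- function(pairs, path) {
  write_tsv(pairs[, c("probe_a", "probe_b", "chrom", "overlap")], path)
}
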