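# Gain/loss calling on an arraylet pattern.
#
# All rules are deviations from means in units of standard deviations, so
# calls are invariant to adding a constant to the pattern or scaling it by
# a positive factor:
#   * chromosome/arm: |region mean - genomic mean| > 2 * genomic sd;
#   * segment/probe:  the same genomic rule, OR |deviation from the
#     chromosome mean| > 1 * chromosome sd when that deviation has the same
#     sign as the deviation from the genomic mean ("consistent");
#   * all inequalities strict; boundary equality yields no call.
# The genomic baseline is computed over the autosomes, minus configured
# outlier regions (default chr7, chr10 and arm 9p, the regions dominating
# the astrocytoma pattern).

# Parse "chr7" (whole chromosome) or "chr9p"/"9p" (arm) region names.
parse_region <- function(region) {
  region <- as.character(region)
  if (grepl("[pq]$", region)) {
    chrom <- sub("[pq]$", "", region)
    if (!grepl("^chr", chrom)) chrom <- paste0("chr", chrom)
    list(chrom = chrom, arm = substring(region, nchar(region)))
  } else {
    chrom <- if (grepl("^chr", region)) region else paste0("chr", region)
    list(chrom = chrom, arm = NULL)
  }
}

region_mask <- function(probes, region) {
  r <- parse_region(region)
  m <- probes$chrom == r$chrom
  if (!is.null(r$arm)) {
    if (!"arm" %in% names(probes) || anyNA(probes$arm[m])) {
      stop("arm-level region '", region,
           "' requires an `arm` column in the annotation")
    }
    m <- m & probes$arm == r$arm
  }
  m
}

#' Genomic and per-chromosome baseline of a pattern
#'
#' The genomic mean and standard deviation are computed over autosomal
#' probes outside the excluded regions (the X chromosome is always
#' excluded). Per-chromosome statistics use all probes of each chromosome.
#'
#' @param pattern numeric arraylet vector, one value per probe.
#' @param probes probe annotation data.frame (needs `arm` for arm-level
#'   exclusions).
#' @param exclude character vector of chromosome or arm names excluded from
#'   the genomic baseline (default the astrocytoma outliers).
#' @return a `genomic_baseline` list: `genomic_mean`, `genomic_std`,
#'   `per_chromosome` (data.frame), `excluded_regions`.
#' @export
compute_baseline <- function(pattern, probes,
                             exclude = c("chr7", "chr10", "chr9p")) {
  if (length(pattern) != nrow(probes)) {
    stop("pattern length (", length(pattern), ") != probe count (",
         nrow(probes), ")")
  }
  use <- is_autosome(probes$chrom)
  for (reg in exclude) use <- use & !region_mask(probes, reg)
  if (sum(use) < 2) stop("fewer than 2 probes remain for the genomic baseline")
  gm <- mean(pattern[use])
  gs <- sd(pattern[use])
  if (!is.finite(gs) || gs <= 0) {
    stop("degenerate baseline: genomic standard deviation is zero")
  }
  chroms <- unique(probes$chrom)
  per <- data.frame(
    chrom = chroms,
    mean = vapply(chroms, function(ch) mean(pattern[probes$chrom == ch]), 0),
    sd = vapply(chroms, function(ch) {
      x <- pattern[probes$chrom == ch]
      if (length(x) > 1) sd(x) else NA_real_
    }, 0),
    n = vapply(chroms, function(ch) sum(probes$chrom == ch), 0L),
    row.names = NULL
  )
  structure(list(genomic_mean = gm, genomic_std = gs,
                 per_chromosome = per, excluded_regions = exclude),
            class = "genomic_baseline")
}

#' @export
print.genomic_baseline <- function(x, ...) {
  cat(sprintf("<genomic_baseline> mean %.4g, sd %.4g (excluding %s)\n",
              x$genomic_mean, x$genomic_std,
              paste(x$excluded_regions, collapse = ", ")))
  invisible(x)
}

chrom_stats <- function(baseline, chrom) {
  i <- match(chrom, baseline$per_chromosome$chrom)
  if (is.na(i)) stop("chromosome ", chrom, " absent from baseline")
  baseline$per_chromosome[i, ]
}

cna_call_row <- function(kind, region, chrom, start, end, direction,
                         genomic_dev, chrom_dev, rule) {
  data.frame(region_kind = kind, region = region, chrom = chrom,
             start = start, end = end, direction = direction,
             genomic_dev = genomic_dev, chrom_dev = chrom_dev,
             rule = rule, stringsAsFactors = FALSE)
}

#' Call a gain or loss in a chromosome or chromosome arm
#'
#' Fires when the region mean deviates from the genomic mean by strictly
#' more than twice the genomic standard deviation.
#'
#' @param pattern arraylet vector.
#' @param probes probe annotation.
#' @param baseline a [compute_baseline()] result.
#' @param region region name, e.g. `"chr7"` or `"chr9p"`.
#' @return one-row data.frame: region, `direction` (gain/loss/none),
#'   `genomic_dev` (multiples of genomic sd), `rule`.
#' @export
call_chromosome_or_arm <- function(pattern, probes, baseline, region) {
  m <- region_mask(probes, region)
  if (!any(m)) stop("region ", region, " contains no probes")
  dev <- (mean(pattern[m]) - baseline$genomic_mean) / baseline$genomic_std
  dir <- if (dev > 2) "gain" else if (dev < -2) "loss" else "none"
  r <- parse_region(region)
  cna_call_row(if (is.null(r$arm)) "chromosome" else "arm", region,
               r$chrom, min(probes$start[m]), max(probes$end[m]),
               dir, dev, NA_real_,
               if (dir == "none") "none" else "genomic")
}

segment_probe_direction <- function(value_mean, baseline, chrom) {
  gd <- (value_mean - baseline$genomic_mean) / baseline$genomic_std
  cs <- chrom_stats(baseline, chrom)
  cd <- if (is.finite(cs$sd) && cs$sd > 0) (value_mean - cs$mean) / cs$sd
        else NA_real_
  if (gd > 2) {
    list(direction = "gain", rule = "genomic", gd = gd, cd = cd)
  } else if (gd < -2) {
    list(direction = "loss", rule = "genomic", gd = gd, cd = cd)
  } else if (!is.na(cd) && abs(cd) > 1 && sign(cd) == sign(gd) && gd != 0) {
    list(direction = if (cd > 0) "gain" else "loss",
         rule = "chromosomal", gd = gd, cd = cd)
  } else {
    list(direction = "none", rule = "none", gd = gd, cd = cd)
  }
}

# A segment's probes: those whose interval midpoint lies in [start, end).
segment_probe_mask <- function(probes, segment) {
  mid <- (probes$start + probes$end) / 2
  probes$chrom == segment$chrom & mid >= segment$start & mid < segment$end
}

#' Call a gain or loss in a genomic segment
#'
#' Genomic 2-sd rule first; otherwise the chromosomal 1-sd rule, which only
#' fires when the chromosomal deviation's sign matches the sign of the
#' segment's deviation from the genomic mean. A segment's probes are those
#' whose interval midpoint lies inside the half-open segment.
#'
#' @param pattern arraylet vector.
#' @param probes probe annotation.
#' @param baseline a [compute_baseline()] result.
#' @param segment list or one-row data.frame with `chrom`, `start`, `end`.
#' @return one-row call data.frame (see [call_chromosome_or_arm()]), with
#'   `chrom_dev` in multiples of the chromosome sd.
#' @export
call_segment <- function(pattern, probes, baseline, segment) {
  segment <- as.list(segment)
  m <- segment_probe_mask(probes, segment)
  if (!any(m)) {
    stop(sprintf("segment %s:%d-%d overlaps no probes",
                 segment$chrom, segment$start, segment$end))
  }
  res <- segment_probe_direction(mean(pattern[m]), baseline, segment$chrom)
  cna_call_row("segment",
               sprintf("%s:%d-%d", segment$chrom, segment$start, segment$end),
               segment$chrom, segment$start, segment$end,
               res$direction, res$gd, res$cd, res$rule)
}

#' Call all segments of a segment table
#'
#' @param pattern,probes,baseline as in [call_segment()].
#' @param segments data.frame with `chrom`, `start`, `end` (one row per
#'   segment).
#' @return data.frame of calls, one row per segment.
#' @export
call_segments <- function(pattern, probes, baseline, segments) {
  do.call(rbind, lapply(seq_len(nrow(segments)), function(i) {
    call_segment(pattern, probes, baseline, segments[i, ])
  }))
}

#' Per-probe gain/loss calls
#'
#' Applies the segment rules to single probes, vectorised over the genome.
#'
#' @param pattern arraylet vector.
#' @param probes probe annotation.
#' @param baseline a [compute_baseline()] result.
#' @return data.frame with one row per probe: `probe_id`, `direction`,
#'   `genomic_dev`, `chrom_dev`, `rule`.
#' @export
call_probes <- function(pattern, probes, baseline) {
  if (length(pattern) != nrow(probes)) stop("pattern/annotation length mismatch")
  gd <- (pattern - baseline$genomic_mean) / baseline$genomic_std
  pc <- baseline$per_chromosome
  i <- match(probes$chrom, pc$chrom)
  if (anyNA(i)) stop("chromosome(s) absent from baseline")
  csd <- pc$sd[i]
  cd <- ifelse(is.finite(csd) & csd > 0, (pattern - pc$mean[i]) / csd,
               NA_real_)
  dir <- rep("none", length(pattern))
  rule <- rep("none", length(pattern))
  gen <- abs(gd) > 2
  dir[gen] <- ifelse(gd[gen] > 0, "gain", "loss")
  rule[gen] <- "genomic"
  chr <- !gen & !is.na(cd) & abs(cd) > 1 & sign(cd) == sign(gd) & gd != 0
  dir[chr] <- ifelse(cd[chr] > 0, "gain", "loss")
  rule[chr] <- "chromosomal"
  data.frame(probe_id = probes$probe_id, chrom = probes$chrom,
             start = probes$start, end = probes$end,
             direction = dir, genomic_dev = gd, chrom_dev = cd,
             rule = rule, stringsAsFactors = FALSE)
}

#' Filter a segment table by probe support
#'
#' @param segments data.frame with a `probe_count` column.
#' @param min_probes minimal probe count retained (default 5).
#' @return the filtered table.
#' @export
filter_segments <- function(segments, min_probes = 5L) {
  if (!"probe_count" %in% names(segments)) {
    stop("segment table lacks a `probe_count` column")
  }
  segments[segments$probe_count >= min_probes, , drop = FALSE]
}

# Best binary split of x (boundary after index k): two-sample mean-shift
# statistic |mean(left) - mean(right)| * sqrt(k (n-k) / n), computed for
# all admissible k at once via cumulative sums.
best_split_stat <- function(x, min_seg) {
  n <- length(x)
  if (n < 2 * min_seg) return(NULL)
  k <- seq.int(min_seg, n - min_seg)
  cs <- cumsum(x)
  ml <- cs[k] / k
  mr <- (cs[n] - cs[k]) / (n - k)
  stat <- abs(ml - mr) * sqrt(k * (n - k) / n)
  j <- which.max(stat)
  list(k = k[j], stat = stat[j])
}

#' Simple change-point segmentation of an arraylet
#'
#' Recursive binary segmentation with a permutation test at each split —
#' a lightweight stand-in for circular binary segmentation, intended for
#' arraylet visualization only. Splits never cross chromosome boundaries.
#'
#' @param pattern arraylet vector, genome-ordered.
#' @param probes probe annotation.
#' @param alpha permutation-test level per split (default 0.01).
#' @param n_perm permutations per candidate split (default 1000).
#' @param min_seg minimal probes per resulting segment (default 5).
#' @param seed optional seed for the permutation RNG; the caller's RNG
#'   state is restored afterwards.
#' @return data.frame of accepted change points: `chrom`, `index_in_chrom`
#'   (last probe of the left segment), `index_global`, `position` (genomic
#'   end of that probe).
#' @export
segment_arraylet <- function(pattern, probes, alpha = 0.01, n_perm = 1000L,
                             min_seg = 5L, seed = NULL) {
  if (length(pattern) != nrow(probes)) stop("pattern/annotation length mismatch")
  with_seed(seed, {
    out <- list()
    recurse <- function(x, offset) {
      bs <- best_split_stat(x, min_seg)
      if (is.null(bs)) return(invisible())
      exceed <- 0L
      for (p in seq_len(n_perm)) {
        pb <- best_split_stat(sample(x), min_seg)
        if (pb$stat >= bs$stat) exceed <- exceed + 1L
      }
      pval <- (1 + exceed) / (n_perm + 1)
      if (pval < alpha) {
        out[[length(out) + 1L]] <<- offset + bs$k
        recurse(x[seq_len(bs$k)], offset)
        recurse(x[-seq_len(bs$k)], offset + bs$k)
      }
      invisible()
    }
    chroms <- unique(probes$chrom)
    res <- list()
    for (ch in chroms) {
      idx <- which(probes$chrom == ch)
      out <- list()
      recurse(pattern[idx], 0L)
      if (length(out)) {
        loc <- sort(unlist(out))
        res[[ch]] <- data.frame(
          chrom = ch, index_in_chrom = loc, index_global = idx[1] - 1L + loc,
          position = probes$end[idx[1] - 1L + loc]
        )
      }
    }
    if (!length(res)) {
      data.frame(chrom = character(), index_in_chrom = integer(),
                 index_global = integer(), position = numeric())
    } else {
      r <- do.call(rbind, res)
      rownames(r) <- NULL
      r
    }
  })
}
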