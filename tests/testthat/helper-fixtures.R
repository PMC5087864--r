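# Shared fixtures and independent oracles. Every oracle here re-derives its
# quantity from first principles (enumeration, brute force, closed form) and
# never calls the package code path it checks.

# --- fixtures ---------------------------------------------------------------

make_probes <- function(n_per_chrom, width = 25L, spacing = 1000L) {
  do.call(rbind, lapply(names(n_per_chrom), function(ch) {
    n <- n_per_chrom[[ch]]
    start <- (seq_len(n) - 1L) * spacing
    data.frame(probe_id = sprintf("%s_p%04d", ch, seq_len(n)),
               chrom = ch, start = start, end = start + width,
               arm = rep(c("p", "q"), c(ceiling(n / 2), floor(n / 2))),
               stringsAsFactors = FALSE)
  }))
}

make_dataset <- function(values, n_per_chrom = NULL) {
  values <- as.matrix(values)
  if (is.null(n_per_chrom)) n_per_chrom <- c(chr1 = nrow(values))
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("PT%03d", seq_len(ncol(values)))
  }
  cn_dataset(values, make_probes(n_per_chrom), sort = FALSE)
}

random_pair <- function(m1, m2, n, seed = 1) {
  set.seed(seed)
  d1 <- matrix(rnorm(m1 * n), m1, n)
  d2 <- matrix(rnorm(m2 * n), m2, n)
  colnames(d1) <- colnames(d2) <- sprintf("PT%03d", seq_len(n))
  list(d1 = d1, d2 = d2)
}

# --- oracles ----------------------------------------------------------------

# Generalized eigenproblem oracle for the GSVD: the sorted squared ratios
# (sigma1/sigma2)^2 equal the sorted eigenvalues of (D2'D2)^-1 (D1'D1).
oracle_gsvd_ratios <- function(d1, d2) {
  sort(Re(eigen(solve(crossprod(d2), crossprod(d1)))$values))
}

# Brute-force probe matching: full A x B overlap matrix, then the
# documented greedy resolution (A scanned in genome order, nearest-anchor
# tie-break).
oracle_match <- function(ann_a, ann_b, anchor = "start") {
  na <- nrow(ann_a); nb <- nrow(ann_b)
  ov <- outer(ann_a$end, ann_b$end, pmin) -
    outer(ann_a$start, ann_b$start, pmax)
  ov[ov < 1] <- 0L
  ov[outer(ann_a$chrom, ann_b$chrom, "!=")] <- 0L
  used <- rep(FALSE, nb)
  res <- NULL
  for (i in seq_len(na)) {
    cand <- which(ov[i, ] > 0 & !used)
    if (!length(cand)) next
    dist <- if (anchor == "start") abs(ann_b$start[cand] - ann_a$start[i])
            else abs(ann_b$end[cand] - ann_a$end[i])
    pick <- cand[order(dist, ann_b$start[cand], cand)][1]
    used[pick] <- TRUE
    res <- rbind(res, data.frame(index_a = i, index_b = pick,
                                 overlap = ov[i, pick]))
  }
  res
}

# Hand-coded per-probe gain/loss rule evaluator (independent of call_probes).
oracle_probe_calls <- function(pattern, probes, gm, gs, chrom_means,
                               chrom_sds) {
  vapply(seq_along(pattern), function(i) {
    gd <- (pattern[i] - gm) / gs
    cm <- chrom_means[[probes$chrom[i]]]
    cs <- chrom_sds[[probes$chrom[i]]]
    cd <- (pattern[i] - cm) / cs
    if (gd > 2) "gain"
    else if (gd < -2) "loss"
    else if (abs(cd) > 1 && sign(cd) == sign(gd) && gd != 0) {
      if (cd > 0) "gain" else "loss"
    } else "none"
  }, "")
}

# Product-limit estimator by hand (no censoring handling shortcuts).
oracle_km <- function(time, event) {
  ut <- sort(unique(time[event]))
  s <- 1
  surv <- numeric(length(ut))
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  med <- if (any(surv <= 0.5 + 1e-12)) ut[which(surv <= 0.5 + 1e-12)[1]]
         else NA_real_
  list(time = ut, surv = surv, median = med)
}

# Two-group log-rank statistic from the hypergeometric moments at each
# distinct event time.
oracle_logrank_stat <- function(time, event, group) {
  g <- as.integer(factor(group)) # 1/2
  ut <- sort(unique(time[event]))
  obs <- 0; expd <- 0; varsum <- 0
  for (t in ut) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & g == 1)
    d <- sum(time == t & event); d1 <- sum(time == t & event & g == 1)
    obs <- obs + d1
    expd <- expd + d * n1 / n
    if (n > 1) varsum <- varsum + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (obs - expd)^2 / varsum
}

# Concordance by exhaustive pair enumeration.
oracle_cindex <- function(time, event, scores) {
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (time[i] == time[j]) next
      s <- if (time[i] < time[j]) i else j # shorter
      l <- if (s == i) j else i
      if (!event[s]) next
      den <- den + 1
      if (scores[s] > scores[l]) num <- num + 1
      else if (scores[s] == scores[l]) num <- num + 0.5
    }
  }
  if (den == 0) NA_real_ else num / den
}

# Hypergeometric upper tail by exhaustive subset enumeration.
oracle_hyper <- function(N, K, n, k) {
  subsets <- utils::combn(N, n)
  annotated <- seq_len(K)
  hits <- apply(subsets, 2, function(s) sum(s %in% annotated))
  mean(hits >= k)
}

# Exact two-sided Mann-Whitney P by enumeration of all group labelings.
oracle_mw <- function(a, b) {
  x <- c(a, b)
  na <- length(a)
  u_of <- function(idx) {
    sum(vapply(x[idx], function(v) sum(v > x[-idx]), 0))
  }
  u_obs <- u_of(seq_len(na))
  labelings <- utils::combn(length(x), na)
  us <- apply(labelings, 2, u_of)
  mu <- na * (length(x) - na) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}
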