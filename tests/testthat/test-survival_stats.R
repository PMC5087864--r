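# survival_stats: KM, log-rank, Cox, concordance, enrichment tests.

test_that("KM curve matches the hand product-limit and median convention", {
  rec <- survival_records(paste0("p", 1:4), c(1, 2, 3, 4), rep(TRUE, 4))
  km <- km_curve(rec)
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$median, 2)

  # all censored: flat curve, undefined median
  rec2 <- survival_records(paste0("p", 1:3), c(5, 6, 7), rep(FALSE, 3))
  km2 <- km_curve(rec2)
  expect_true(all(km2$surv == 1))
  expect_true(is.na(km2$median))

  # single event
  rec3 <- survival_records("p1", 5, TRUE)
  expect_equal(km_curve(rec3)$median, 5)

  # censoring handled as the oracle does
  set.seed(6)
  time <- round(rexp(30, 0.1), 2) + 0.01
  event <- runif(30) < 0.7
  rec4 <- survival_records(paste0("p", 1:30), time, event)
  km4 <- km_curve(rec4)
  ora <- oracle_km(time, event)
  expect_equal(km4$surv[km4$n_event > 0], ora$surv, tolerance = 1e-12)
  expect_equal(km4$median, ora$median)

  expect_error(survival_records("x", 0, TRUE), "positive")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(41)
  time <- sort(sample(1:100, 20))
  rec <- survival_records(paste0("p", 1:20), time, rep(TRUE, 20))
  km <- km_curve(rec)
  emp <- vapply(km$time, function(t) mean(time > t), 0)
  expect_equal(km$surv, emp, tolerance = 1e-12)
})

test_that("log-rank statistic matches the hypergeometric-moments oracle", {
  # identical groups: statistic 0, P 1
  t_ <- c(1, 2, 3, 1, 2, 3)
  rec <- survival_records(paste0("p", 1:6), t_, rep(TRUE, 6),
                          group = rep(c("a", "b"), each = 3))
  lr <- log_rank(rec)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1, tolerance = 1e-12)

  # complete separation toy: statistic equals the hand-coded evaluator and
  # attains the maximum over all C(4,2) relabelings
  time4 <- c(1, 2, 10, 20)
  grp4 <- c("a", "a", "b", "b")
  rec4 <- survival_records(paste0("p", 1:4), time4, rep(TRUE, 4),
                           group = grp4)
  lr4 <- log_rank(rec4)
  expect_equal(lr4$statistic, oracle_logrank_stat(time4, rep(TRUE, 4), grp4),
               tolerance = 1e-10)
  labelings <- utils::combn(4, 2)
  stats_all <- apply(labelings, 2, function(idx) {
    g <- rep("b", 4); g[idx] <- "a"
    oracle_logrank_stat(time4, rep(TRUE, 4), g)
  })
  expect_equal(lr4$statistic, max(stats_all), tolerance = 1e-10)
  expect_equal(lr4$p, pchisq(lr4$statistic, 1, lower.tail = FALSE))

  # larger random case against the oracle
  set.seed(12)
  time <- rexp(40, 0.05)
  event <- runif(40) < 0.8
  grp <- rep(c("a", "b"), 20)
  rec5 <- survival_records(paste0("p", 1:40), time, event, group = grp)
  expect_equal(log_rank(rec5)$statistic,
               oracle_logrank_stat(time, event, grp), tolerance = 1e-8)

  # degenerate inputs
  expect_error(log_rank(survival_records("x", 1, TRUE, group = "a")),
               "two non-empty groups")
  recc <- survival_records(paste0("p", 1:4), 1:4, rep(FALSE, 4),
                           group = c("a", "a", "b", "b"))
  expect_warning(lrc <- log_rank(recc), "no events")
  expect_equal(lrc$p, 1)
})

test_that("null log-rank P values are approximately uniform", {
  set.seed(77)
  n <- 40
  time <- rexp(n, 0.05)
  event <- runif(n) < 0.7
  ps <- replicate(400, {
    grp <- sample(rep(c("a", "b"), each = n / 2))
    log_rank(survival_records(paste0("p", 1:n), time, event,
                              group = grp))$p
  })
  ks <- max(abs(sort(ps) - (seq_along(ps) - 0.5) / length(ps)))
  expect_lt(ks, 0.08)
})

test_that("Cox fits recover planted hazard ratios", {
  # identical groups -> HR ~ 1 inside its CI
  set.seed(22)
  n <- 120
  time <- rexp(n, 0.05)
  rec <- survival_records(paste0("p", 1:n), time, rep(TRUE, n))
  rec$group <- factor(rep(c("low", "high"), n / 2), c("low", "high"))
  fit <- cox_fit(rec, "group")
  expect_true(fit$ci_low[1] < 1 && 1 < fit$ci_high[1])

  # planted HR = 5 with ~30% censoring: point estimate in a wide band
  set.seed(20)
  grp <- rep(c(0, 1), each = 100)
  t_ev <- rexp(200, 0.02 * 5^grp)
  t_c <- rexp(200, 0.012)
  rec2 <- survival_records(paste0("p", 1:200), pmin(t_ev, t_c),
                           t_ev <= t_c)
  rec2$group <- factor(ifelse(grp == 1, "high", "low"), c("low", "high"))
  fit2 <- cox_fit(rec2, "group")
  expect_gt(fit2$hr[1], 3)
  expect_lt(fit2$hr[1], 8)

  # bivariate fit: each HR inside the corresponding univariate CI
  set.seed(21)
  cov2 <- factor(sample(c("no", "yes"), 200, replace = TRUE))
  rate <- 0.02 * 5^grp * 2^(cov2 == "yes")
  t_ev <- rexp(200, rate)
  rec3 <- survival_records(paste0("p", 1:200), t_ev, rep(TRUE, 200))
  rec3$group <- factor(ifelse(grp == 1, "high", "low"), c("low", "high"))
  rec3$cov2 <- cov2
  uni_g <- cox_fit(rec3, "group")
  uni_c <- cox_fit(rec3, "cov2")
  bi <- cox_fit(rec3, c("group", "cov2"))
  expect_true(bi$hr[1] > uni_g$ci_low[1] && bi$hr[1] < uni_g$ci_high[1])
  expect_true(bi$hr[2] > uni_c$ci_low[2 - 1] && bi$hr[2] < uni_c$ci_high[1])

  # complete separation is flagged, not hidden
  rec4 <- survival_records(paste0("p", 1:6), c(1, 2, 3, 10, 11, 12),
                           rep(TRUE, 6))
  rec4$group <- factor(rep(c("high", "low"), each = 3), c("low", "high"))
  fit4 <- cox_fit(rec4, "group")
  expect_true(fit4$flagged[1])
  expect_error(cox_fit(rec4, c("a", "b", "c")), "univariate and bivariate")
})

test_that("concordance matches brute-force enumeration and endpoints", {
  # perfect risk ordering
  rec <- survival_records(paste0("p", 1:5), c(5, 4, 3, 2, 1), rep(TRUE, 5))
  expect_equal(concordance_index(rec, 1:5), 1)
  # constant score
  expect_equal(concordance_index(rec, rep(1, 5)), 0.5)
  # 4-patient toy vs enumeration
  rec4 <- survival_records(paste0("p", 1:4), c(2, 1, 3, 3),
                           c(TRUE, TRUE, FALSE, TRUE))
  sc <- c(0.3, 0.9, 0.1, 0.1)
  expect_equal(concordance_index(rec4, sc),
               oracle_cindex(rec4$time, rec4$event, sc))
  # random fuzz vs enumeration
  set.seed(33)
  for (i in 1:10) {
    n <- sample(5:12, 1)
    r <- survival_records(paste0("p", 1:n), sample(1:8, n, replace = TRUE),
                          runif(n) < 0.7)
    s <- sample(1:4, n, replace = TRUE)
    expect_equal(concordance_index(r, s),
                 oracle_cindex(r$time, r$event, s))
  }
  # no comparable pairs
  recc <- survival_records(paste0("p", 1:3), c(1, 1, 1), rep(TRUE, 3))
  expect_warning(ci <- concordance_index(recc, 1:3), "no comparable")
  expect_true(is.na(ci))
})

test_that("hypergeometric tail equals subset enumeration", {
  expect_equal(hypergeometric_enrichment(10, 4, 5, 0), 1)
  expect_equal(hypergeometric_enrichment(5, 2, 2, 2), 0.1)
  expect_equal(hypergeometric_enrichment(4, 2, 2, 1), 5 / 6)
  expect_error(hypergeometric_enrichment(4, 2, 2, 3), "invalid")
  for (N in 3:8) {
    for (K in 1:N) {
      for (n in 1:N) {
        for (k in 0:min(n, K)) {
          expect_equal(hypergeometric_enrichment(N, K, n, k),
                       oracle_hyper(N, K, n, k), tolerance = 1e-12,
                       info = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
        }
      }
    }
  }
})

test_that("Mann-Whitney exact P equals labeling enumeration", {
  out <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(out$u, 0)
  expect_equal(out$p, 1 / 3, tolerance = 1e-12)
  set.seed(51)
  for (i in 1:8) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    x <- sample(1:100, na + nb) # distinct values, exact path
    a <- x[seq_len(na)]; b <- x[-seq_len(na)]
    expect_equal(mann_whitney(a, b)$p, oracle_mw(a, b), tolerance = 1e-9)
  }
  # identical samples (ties force the normal approximation): P = 1
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p, 1)
})

test_that("Mann-Whitney null P values are approximately uniform", {
  set.seed(99)
  ps <- replicate(500, {
    mann_whitney(rnorm(25), rnorm(25))$p
  })
  ks <- max(abs(sort(ps) - (seq_along(ps) - 0.5) / length(ps)))
  expect_lt(ks, 0.08)
})

test_that("annotate_probelet flags a gender-coding probelet", {
  set.seed(61)
  gender <- rep(c("female", "male"), each = 10)
  probelet <- ifelse(gender == "female", 0.3, -0.3) + rnorm(20, sd = 0.01)
  clin <- data.frame(patient_id = paste0("p", 1:20), gender = gender)
  out <- annotate_probelet(probelet, clin, "gender")
  # the high subset is exactly the females: minimum achievable tail P
  best <- out$table[out$table$level == "female" & out$table$subset == "high", ]
  expect_equal(best$k, 10)
  expect_equal(best$p_hyper, 1 / choose(20, 10), tolerance = 1e-12)
  expect_lt(out$mann_whitney_p, 1e-4)

  # annotation independent of the probelet: median P moderate
  set.seed(62)
  meds <- replicate(100, {
    ann <- sample(gender)
    clin2 <- data.frame(patient_id = paste0("p", 1:20), gender = ann)
    min(annotate_probelet(probelet, clin2, "gender")$table$p_hyper)
  })
  expect_gt(median(meds), 0.05)

  # constant probelet: Mann-Whitney P = 1
  out3 <- annotate_probelet(rep(1, 20), clin, "gender")
  expect_equal(out3$mann_whitney_p, 1)
  expect_error(annotate_probelet(probelet, clin, "nope"), "absent")
})

test_that("survival_report bundles groups, log-rank, Cox and concordance", {
  set.seed(71)
  n <- 80
  grp <- rep(c("low", "high"), each = n / 2)
  time <- rexp(n, ifelse(grp == "high", 0.08, 0.02))
  rec <- survival_records(paste0("p", 1:n), time, rep(TRUE, n), group = grp)
  rep_ <- survival_report(rec, scores = as.numeric(grp == "high"))
  expect_equal(rep_$groups$group, c("low", "high"))
  expect_lt(rep_$logrank$p, 0.01)
  expect_gt(rep_$cox$hr[1], 1)
  expect_gt(rep_$concordance, 0.5)
  expect_gt(rep_$groups$km_median[1], rep_$groups$km_median[2])
})
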