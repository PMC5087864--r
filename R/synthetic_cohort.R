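# Synthetic paired tumor/normal cohorts with planted structure.
#
# The generator plants, in log2 copy-number units:
#   * a tumor-exclusive genome-wide CNA pattern (gains/losses over
#     configured regions) carried strongly by a "high" patient subgroup and
#     linked to shorter survival;
#   * a male-specific X-chromosome deletion present in BOTH tumor and
#     normal profiles (a germline CNV, the planted "common" component);
#   * a tumor-exclusive batch effect: a fixed random probe vector added to
#     the tumor profiles of a random patient subset (a hybridization-plate
#     artifact);
#   * i.i.d. Gaussian probe noise, independent between tumor and normal.
# Survival is exponential with group-specific rates (closed-form hazard
# ratio), censored by an independent exponential time whose rate is solved
# to hit the requested censoring fraction in expectation.

#' Parameters of a synthetic cohort
#'
#' Defaults state a small but realistic world: a 4-autosome + chrX genome
#' of 2,200 probes, 60 patients, pattern amplitude three times the probe
#' noise, half the patients carrying the pattern, a 63-month median
#' survival in the low group and a hazard ratio of 9 for the high group.
#'
#' @param n_patients number of patients.
#' @param n_probes named integer vector: probes per chromosome.
#' @param pattern_amplitude planted CNA magnitude (log2 units).
#' @param pattern_regions named character vector mapping regions
#'   (chromosome or arm names) to `"gain"`/`"loss"`.
#' @param fraction_high proportion of patients carrying the pattern.
#' @param x_deletion_amplitude male X-deletion magnitude (log2 units).
#' @param male_fraction proportion of male patients.
#' @param batch_effect_amplitude sd of the tumor-only batch probe vector.
#' @param batch_fraction proportion of patients in the affected batch.
#' @param noise_sd i.i.d. probe noise sd (log2 units).
#' @param survival list: `median_low` (months), `hazard_ratio` (high vs
#'   low), `censoring` (fraction in `[0, 1)`).
#' @param seed integer RNG seed.
#' @return validated `cohort_params` list.
#' @export
cohort_params <- function(n_patients = 60L,
                          n_probes = c(chr1 = 500L, chr2 = 500L,
                                       chr3 = 500L, chr4 = 500L,
                                       chrX = 200L),
                          pattern_amplitude = 0.3,
                          pattern_regions = c(chr1 = "gain", chr2 = "loss",
                                              chr3p = "gain"),
                          fraction_high = 0.5,
                          x_deletion_amplitude = 0.5,
                          male_fraction = 0.5,
                          batch_effect_amplitude = 0.05,
                          batch_fraction = 0.5,
                          noise_sd = 0.1,
                          survival = list(median_low = 63,
                                          hazard_ratio = 9,
                                          censoring = 0.3),
                          seed = 1L) {
  p <- list(n_patients = as.integer(n_patients), n_probes = n_probes,
            pattern_amplitude = pattern_amplitude,
            pattern_regions = pattern_regions,
            fraction_high = fraction_high,
            x_deletion_amplitude = x_deletion_amplitude,
            male_fraction = male_fraction,
            batch_effect_amplitude = batch_effect_amplitude,
            batch_fraction = batch_fraction,
            noise_sd = noise_sd, survival = survival,
            seed = as.integer(seed))
  amps <- c(p$pattern_amplitude, p$x_deletion_amplitude,
            p$batch_effect_amplitude)
  fracs <- c(p$fraction_high, p$male_fraction, p$batch_fraction)
  if (any(amps < 0)) stop("amplitudes must be non-negative")
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (p$noise_sd <= 0) stop("noise_sd must be positive")
  if (is.null(names(p$n_probes))) stop("n_probes must be a named vector")
  sv <- p$survival
  if (sv$median_low <= 0 || sv$hazard_ratio <= 0 ||
      sv$censoring < 0 || sv$censoring >= 1) {
    stop("invalid survival parameters")
  }
  if (!all(p$pattern_regions %in% c("gain", "loss"))) {
    stop("pattern_regions values must be 'gain' or 'loss'")
  }
  structure(p, class = "cohort_params")
}

# Synthetic genome: probes of width 25 bp every 1000 bp; the centromere
# splits each chromosome in half, giving two callable arms.
synthetic_genome <- function(n_probes) {
  probes <- do.call(rbind, lapply(names(n_probes), function(ch) {
    n <- n_probes[[ch]]
    start <- (seq_len(n) - 1L) * 1000L
    data.frame(probe_id = sprintf("%s_p%05d", ch, seq_len(n)),
               chrom = ch, start = start, end = start + 25L,
               stringsAsFactors = FALSE)
  }))
  centromeres <- data.frame(
    chrom = names(n_probes),
    centromere_start = as.integer(n_probes %/% 2L) * 1000L - 500L,
    centromere_end = as.integer(n_probes %/% 2L) * 1000L + 500L,
    row.names = NULL
  )
  probes <- assign_arms(probes, centromeres)
  list(probes = probes, centromeres = centromeres)
}

# Planted pattern vector: +/- amplitude over the configured regions.
planted_pattern <- function(probes, regions, amplitude) {
  pat <- numeric(nrow(probes))
  for (reg in names(regions)) {
    m <- region_mask(probes, reg)
    pat[m] <- pat[m] + if (regions[[reg]] == "gain") amplitude else -amplitude
  }
  pat
}

# Censoring rate l_c with  mean_i l_c / (l_i + l_c) = target.
solve_censoring_rate <- function(rates, target) {
  if (target == 0) return(0)
  f <- function(lc) mean(lc / (rates + lc)) - target
  uniroot(f, lower = 1e-12, upper = 1e6, tol = 1e-12)$root
}

#' Generate a synthetic paired cohort
#'
#' Fully reproducible from `params$seed`; the caller's RNG state is left
#' untouched. See the module comment for the planted structure.
#'
#' @param params a [cohort_params()] list.
#' @return list of class `synthetic_cohort`: `tumor` and `normal`
#'   ([cn_dataset()]s), `clinical` (data.frame), `centromeres`, and `truth`
#'   (planted pattern, per-patient weights, groups, gender, batch and
#'   survival generator parameters).
#' @export
generate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  with_seed(params$seed, {
    gen <- synthetic_genome(params$n_probes)
    probes <- gen$probes
    m <- nrow(probes)
    n <- params$n_patients
    ids <- sprintf("PT%03d", seq_len(n))

    n_high <- round(params$fraction_high * n)
    group <- sample(rep(c("high", "low"), c(n_high, n - n_high)))
    weight <- as.numeric(group == "high")
    gender <- ifelse(runif(n) < params$male_fraction, "male", "female")
    batch <- ifelse(runif(n) < params$batch_fraction, "plate2", "plate1")

    pattern <- planted_pattern(probes, params$pattern_regions,
                               params$pattern_amplitude)
    x_probes <- probes$chrom == "chrX"
    xdel <- -params$x_deletion_amplitude * as.numeric(x_probes)
    batch_vec <- rnorm(m, sd = params$batch_effect_amplitude)

    shared <- outer(xdel, as.numeric(gender == "male"))
    tumor_vals <- outer(pattern, weight) + shared +
      outer(batch_vec, as.numeric(batch == "plate2")) +
      matrix(rnorm(m * n, sd = params$noise_sd), m, n)
    normal_vals <- shared + matrix(rnorm(m * n, sd = params$noise_sd), m, n)
    colnames(tumor_vals) <- ids
    colnames(normal_vals) <- ids

    sv <- params$survival
    rate_low <- log(2) / sv$median_low
    rates <- ifelse(group == "high", sv$hazard_ratio * rate_low, rate_low)
    t_event <- rexp(n, rates)
    if (sv$censoring > 0) {
      rate_c <- solve_censoring_rate(rates, sv$censoring)
      t_cens <- rexp(n, rate_c)
      time <- pmin(t_event, t_cens)
      event <- t_event <= t_cens
    } else {
      time <- t_event
      event <- rep(TRUE, n)
    }

    clinical <- data.frame(
      patient_id = ids,
      survival_time = time,
      event = event,
      chemotherapy = sample(c("yes", "no"), n, replace = TRUE),
      radiation = sample(c("yes", "no"), n, replace = TRUE),
      age_group = sample(c("young", "old"), n, replace = TRUE),
      grade = sample(c("II", "III"), n, replace = TRUE),
      mgmt_status = sample(c("methylated", "unmethylated"), n, replace = TRUE),
      idh1_status = sample(c("mutant", "wildtype"), n, replace = TRUE),
      gender = gender,
      batch = batch,
      stringsAsFactors = FALSE
    )

    structure(list(
      tumor = cn_dataset(tumor_vals, probes, patients = ids, sort = FALSE),
      normal = cn_dataset(normal_vals, probes, patients = ids, sort = FALSE),
      clinical = clinical,
      centromeres = gen$centromeres,
      truth = list(pattern = pattern, weight = weight, group = group,
                   gender = gender, batch = batch, xdel = xdel,
                   batch_vec = batch_vec,
                   survival = list(rate_low = rate_low,
                                   hazard_ratio = sv$hazard_ratio,
                                   censoring = sv$censoring)),
      params = params
    ), class = "synthetic_cohort")
  })
}

#' Write a synthetic cohort to disk
#'
#' Emits the TSV formats the readers consume: `tumor.tsv`, `normal.tsv`,
#' `annotation.tsv`, `centromeres.tsv`, `clinical.tsv`, plus
#' `truth_pattern.tsv` and `truth_patients.tsv`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if absent).
#' @return invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_copy_number(cohort$tumor, file.path(dir, "tumor.tsv"),
                    file.path(dir, "annotation.tsv"))
  write_copy_number(cohort$normal, file.path(dir, "normal.tsv"))
  write_tsv(cohort$centromeres, file.path(dir, "centromeres.tsv"))
  write_tsv(cohort$clinical, file.path(dir, "clinical.tsv"))
  write_tsv(data.frame(probe_id = cohort$tumor$probes$probe_id,
                       pattern = cohort$truth$pattern),
            file.path(dir, "truth_pattern.tsv"))
  write_tsv(data.frame(patient_id = cohort$clinical$patient_id,
                       group = cohort$truth$group,
                       weight = cohort$truth$weight,
                       gender = cohort$truth$gender,
                       batch = cohort$truth$batch),
            file.path(dir, "truth_patients.tsv"))
  invisible(dir)
}

#' Recovery metrics of a decomposition against the planted truth
#'
#' Locates the tumor arraylet best matching the planted CNA pattern and the
#' normal arraylet best matching the planted X-deletion, and reports how
#' faithfully the decomposition and classification recover the plant.
#'
#' @param model a `gsvd_model` computed on the cohort.
#' @param classification optional `patient_classification` of the cohort.
#' @param truth the `truth` element of a `synthetic_cohort`.
#' @param thresholds an [exclusivity_thresholds()] list.
#' @return list: `pattern_component`, `pattern_correlation` (absolute),
#'   `pattern_theta`, `pattern_label`, `label_accuracy` (best over the two
#'   sign orientations; NA without a classification), `common_component`,
#'   `common_theta`, `common_label`.
#' @export
evaluate_recovery <- function(model, classification = NULL, truth,
                              thresholds = exclusivity_thresholds()) {
  if (nrow(model$U1) != length(truth$pattern)) {
    stop("model probe dimension != planted pattern length")
  }
  labels <- classify_components(model, thresholds)
  pat_cor <- abs(cor(model$U1, truth$pattern))
  ip <- which.max(pat_cor)
  xd_cor <- abs(cor(model$U2, truth$xdel))
  ix <- which.max(xd_cor)
  acc <- NA_real_
  if (!is.null(classification)) {
    tab <- classification$table
    tg <- truth$group[match(tab$patient_id,
                            sprintf("PT%03d", seq_along(truth$group)))]
    if (anyNA(tg)) stop("classification patients do not match the cohort")
    a <- mean(tab$label == tg)
    acc <- max(a, 1 - a) # probelet sign, hence high/low polarity, is arbitrary
  }
  list(pattern_component = ip,
       pattern_correlation = pat_cor[ip],
       pattern_theta = model$theta[ip],
       pattern_label = labels[ip],
       label_accuracy = acc,
       common_component = ix,
       common_theta = model$theta[ix],
       common_label = labels[ix])
}
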