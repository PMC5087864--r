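# Comparative generalized singular value decomposition.
#
# Two column-matched matrices D1 (M1 x N) and D2 (M2 x N), both of full
# column rank, are factored exactly as
#
#     D_i = U_i %*% diag(sigma_i) %*% t(V),   i = 1, 2,
#
# with a single set of unit-norm, not necessarily orthogonal "probelets"
# (columns of V, patterns across patients) and dataset-specific orthonormal
# "arraylets" (columns of U_i, patterns across the genome). The ratio
# sigma_1n / sigma_2n measures how much probelet n belongs to dataset 1
# versus dataset 2; the angular distance
#
#     theta_n = atan(sigma_1n / sigma_2n) - pi/4  in  [-pi/4, pi/4]
#
# is ~ +pi/4 for dataset-1-exclusive components, ~ -pi/4 for dataset-2-
# exclusive components and ~ 0 for components common to both.
#
# Algorithm: thin QR of the stacked (M1+M2) x N matrix, then the cosine-sine
# decomposition of the partitioned orthonormal factor (SVD of the top block,
# QR of the rotated bottom block), then V from the invertible triangular
# factor with rows rescaled to unit norm, the norms being absorbed into the
# generalized singular values. Numerically stable for M >> N.

#' Angular distance between paired generalized singular values
#'
#' `atan(sigma1/sigma2) - pi/4`, mapped to `[-pi/4, pi/4]`. `sigma2 = 0`
#' gives `+pi/4` (dataset-1 exclusive), `sigma1 = 0` gives `-pi/4`.
#' Vectorised.
#'
#' @param sigma1,sigma2 non-negative numerics of equal length.
#' @return angular distances in radians.
#' @export
angular_distance <- function(sigma1, sigma2) {
  if (any(sigma1 < 0) || any(sigma2 < 0)) stop("sigma must be non-negative")
  if (any(sigma1 == 0 & sigma2 == 0)) {
    stop("angular distance undefined for sigma1 = sigma2 = 0")
  }
  ifelse(sigma2 == 0, pi / 4, atan(sigma1 / sigma2) - pi / 4)
}

#' Generalized fraction of information per component
#'
#' `p_n = sigma_n^2 / sum(sigma^2)`: the probability-like share of a
#' dataset's overall information captured by each component.
#'
#' @param sigma non-negative vector of generalized singular values.
#' @return probability vector summing to 1.
#' @export
generalized_fractions <- function(sigma) {
  if (any(sigma < 0)) stop("sigma must be non-negative")
  tot <- sum(sigma^2)
  if (tot == 0) stop("all generalized singular values are zero")
  sigma^2 / tot
}

#' Generalized normalized Shannon entropy
#'
#' `d = -(log N)^-1 * sum(p log p)` with `0 log 0 := 0`. Zero for a dataset
#' whose information sits in a single component; one when all components
#' carry equal information.
#'
#' @param fractions probability vector of length N >= 2.
#' @return entropy in `[0, 1]`.
#' @export
generalized_entropy <- function(fractions) {
  n <- length(fractions)
  if (n < 2) stop("entropy needs at least 2 components (log N > 0)")
  if (any(fractions < -1e-12) || abs(sum(fractions) - 1) > 1e-8) {
    stop("`fractions` is not a probability vector")
  }
  p <- pmax(fractions, 0)
  terms <- ifelse(p > 0, p * log(p), 0)
  -sum(terms) / log(n)
}

#' Exclusivity thresholds on the angular distance
#'
#' Components with `theta` beyond `exclusive_min` are called exclusive to
#' one dataset; components with `|theta|` below `common_max` are called
#' common to both. The defaults are the bands used to read the astrocytoma
#' decomposition: exclusive beyond `2*pi/15`, common within `pi/16`.
#'
#' @param exclusive_min,common_max radians, `0 < common_max < exclusive_min
#'   <= pi/4`.
#' @return list with the two thresholds.
#' @export
exclusivity_thresholds <- function(exclusive_min = 2 * pi / 15,
                                   common_max = pi / 16) {
  if (!(0 < common_max && common_max < exclusive_min &&
        exclusive_min <= pi / 4 + 1e-12)) {
    stop("need 0 < common_max < exclusive_min <= pi/4")
  }
  list(exclusive_min = exclusive_min, common_max = common_max)
}

#' Comparative GSVD of a patient-matched pair
#'
#' @param tumor,normal [cn_dataset()] objects (or bare matrices) with
#'   identical patient columns and no missing values; drop incomplete probes
#'   first with [drop_missing_probes()].
#' @param check verify reconstruction and orthonormality at `tol` and stop
#'   on failure.
#' @param tol relative tolerance for the self-check.
#' @return a `gsvd_model`: orthonormal arraylets `U1` (M1 x N), `U2`
#'   (M2 x N); generalized singular values `sigma1`, `sigma2`; unit-norm
#'   probelets `V` (N x N); `theta`; per-dataset `fractions` and `entropy`;
#'   `patients`. Components are canonicalized: sorted by decreasing
#'   `theta` and sign-fixed (see [canonicalize()]).
#' @export
compute_gsvd <- function(tumor, normal, check = TRUE, tol = 1e-8) {
  d1 <- cn_values(tumor)
  d2 <- cn_values(normal)
  if (inherits(tumor, "cn_dataset") && inherits(normal, "cn_dataset") &&
      !identical(tumor$patients, normal$patients)) {
    stop("patient lists differ; run validate_pair() first")
  }
  if (anyNA(d1) || anyNA(d2)) {
    stop("missing values present; drop incomplete probes before the GSVD")
  }
  n <- ncol(d1)
  if (ncol(d2) != n) stop("datasets must have the same number of columns")
  m1 <- nrow(d1)
  if (m1 < n || nrow(d2) < n) stop("each dataset needs at least N rows")

  qr_s <- qr(rbind(d1, d2))
  r_s <- qr.R(qr_s)
  dr <- abs(diag(r_s))
  if (min(dr) <= n * .Machine$double.eps * max(dr)) {
    stop("stacked matrix is numerically rank deficient; ",
         "the pair does not admit a full-rank GSVD")
  }
  q_all <- qr.Q(qr_s)
  q1 <- q_all[seq_len(m1), , drop = FALSE]
  q2 <- q_all[-seq_len(m1), , drop = FALSE]

  # CS decomposition of the partitioned orthonormal factor:
  # q1 = U1 diag(c) t(W); then q2 W has orthogonal columns with norms s,
  # recovered via an (unpivoted) Householder QR whose triangular factor is
  # diagonal up to rounding.
  sv <- svd(q1)
  u1 <- sv$u
  cosv <- pmin(sv$d, 1)
  w <- sv$v
  qr_t <- qr(q2 %*% w)
  u2 <- qr.Q(qr_t)
  sinv <- diag(qr.R(qr_t))
  neg <- sinv < 0
  if (any(neg)) {
    u2[, neg] <- -u2[, neg]
    sinv <- abs(sinv)
  }

  x <- crossprod(w, r_s)            # t(W) %*% R; V^T up to row norms
  rn <- sqrt(rowSums(x^2))          # > 0 since R invertible
  v <- t(x / rn)
  sigma1 <- cosv * rn
  sigma2 <- sinv * rn

  model <- structure(list(
    U1 = u1, U2 = u2,
    sigma1 = sigma1, sigma2 = sigma2,
    V = v,
    theta = angular_distance(sigma1, sigma2),
    fractions = list(tumor = generalized_fractions(sigma1),
                     normal = generalized_fractions(sigma2)),
    entropy = c(tumor = generalized_entropy(generalized_fractions(sigma1)),
                normal = generalized_entropy(generalized_fractions(sigma2))),
    patients = if (inherits(tumor, "cn_dataset")) tumor$patients
               else colnames(d1)
  ), class = "gsvd_model")
  model <- canonicalize(model)

  if (check) {
    err1 <- reconstruction_error(d1, model$U1, model$sigma1, model$V)
    err2 <- reconstruction_error(d2, model$U2, model$sigma2, model$V)
    ort1 <- max(abs(crossprod(model$U1) - diag(n)))
    ort2 <- max(abs(crossprod(model$U2) - diag(n)))
    if (max(err1, err2) > tol || max(ort1, ort2) > tol) {
      stop(sprintf(paste0("GSVD self-check failed (reconstruction %.2e/",
                          "%.2e, orthonormality %.2e/%.2e)"),
                   err1, err2, ort1, ort2))
    }
  }
  model
}

# Relative Frobenius reconstruction error of D ~ U diag(s) V^T.
reconstruction_error <- function(d, u, sigma, v) {
  rec <- u %*% (sigma * t(v))
  sqrt(sum((d - rec)^2)) / sqrt(sum(d^2))
}

#' Canonicalize a GSVD model
#'
#' Sorts components by decreasing angular distance (ties: decreasing
#' `sigma1`, then original index) and fixes the `+/-1` phase of each
#' component so that the probelet entry largest in magnitude is positive;
#' the sign flip is applied jointly to the probelet and both arraylets, so
#' the factorization is preserved. Idempotent.
#'
#' @param model a `gsvd_model`.
#' @return the canonicalized model.
#' @export
canonicalize <- function(model) {
  stopifnot(inherits(model, "gsvd_model"))
  n <- length(model$theta)
  ord <- order(-model$theta, -model$sigma1, seq_len(n))
  model$U1 <- model$U1[, ord, drop = FALSE]
  model$U2 <- model$U2[, ord, drop = FALSE]
  model$V <- model$V[, ord, drop = FALSE]
  model$sigma1 <- model$sigma1[ord]
  model$sigma2 <- model$sigma2[ord]
  model$theta <- model$theta[ord]
  model$fractions$tumor <- model$fractions$tumor[ord]
  model$fractions$normal <- model$fractions$normal[ord]
  for (j in seq_len(n)) {
    k <- which.max(abs(model$V[, j]))
    if (model$V[k, j] < 0) {
      model$V[, j] <- -model$V[, j]
      model$U1[, j] <- -model$U1[, j]
      model$U2[, j] <- -model$U2[, j]
    }
  }
  model
}

#' Label components by tumor/normal exclusivity
#'
#' @param model canonicalized `gsvd_model`.
#' @param thresholds an [exclusivity_thresholds()] list.
#' @return character vector per component: `"tumor_exclusive"`,
#'   `"normal_exclusive"`, `"common"` or `"intermediate"`.
#' @export
classify_components <- function(model, thresholds = exclusivity_thresholds()) {
  th <- model$theta
  out <- rep("intermediate", length(th))
  out[th > thresholds$exclusive_min] <- "tumor_exclusive"
  out[th < -thresholds$exclusive_min] <- "normal_exclusive"
  out[abs(th) < thresholds$common_max] <- "common"
  out
}

#' @export
print.gsvd_model <- function(x, ...) {
  n <- length(x$theta)
  cat(sprintf("<gsvd_model> N = %d components; M1 = %d, M2 = %d probes\n",
              n, nrow(x$U1), nrow(x$U2)))
  cat(sprintf("  entropy: tumor %.3f, normal %.3f\n",
              x$entropy[["tumor"]], x$entropy[["normal"]]))
  k <- min(n, 5)
  cat(sprintf("  theta (top %d): %s\n", k,
              paste(sprintf("%.3f", x$theta[seq_len(k)]), collapse = ", ")))
  invisible(x)
}

#' Summarise a GSVD model as a data.frame
#'
#' One row per component: generalized singular values, angular distance,
#' per-dataset information fractions and the exclusivity label.
#'
#' @param object a `gsvd_model`.
#' @param thresholds an [exclusivity_thresholds()] list.
#' @param ... unused.
#' @return data.frame with columns `component`, `sigma1`, `sigma2`, `theta`,
#'   `fraction_tumor`, `fraction_normal`, `label`.
#' @export
summary.gsvd_model <- function(object, thresholds = exclusivity_thresholds(),
                               ...) {
  data.frame(
    component = seq_along(object$theta),
    sigma1 = object$sigma1,
    sigma2 = object$sigma2,
    theta = object$theta,
    fraction_tumor = object$fractions$tumor,
    fraction_normal = object$fractions$normal,
    label = classify_components(object, thresholds)
  )
}

#' Serialize a GSVD model to TSV files
#'
#' Writes `gsvd_summary.tsv` (per-component statistics), `probelets.tsv`
#' (patients x components) and `arraylets_tumor.tsv` / `arraylets_normal.tsv`
#' (probes x components) into `dir`.
#'
#' @param model a `gsvd_model`.
#' @param dir output directory (created if absent).
#' @param thresholds an [exclusivity_thresholds()] list.
#' @return invisibly, the directory.
#' @export
write_gsvd <- function(model, dir, thresholds = exclusivity_thresholds()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  smry <- summary(model, thresholds)
  num <- vapply(smry, is.numeric, logical(1)) & names(smry) != "component"
  smry[num] <- lapply(smry[num], num_fmt)
  write_tsv(smry, file.path(dir, "gsvd_summary.tsv"))
  pl <- data.frame(patient_id = model$patients %||%
                     paste0("patient", seq_len(nrow(model$V))),
                   apply(model$V, 2, num_fmt), check.names = FALSE)
  names(pl)[-1] <- paste0("probelet_", seq_len(ncol(model$V)))
  write_tsv(pl, file.path(dir, "probelets.tsv"))
  for (side in c("tumor", "normal")) {
    u <- if (side == "tumor") model$U1 else model$U2
    au <- as.data.frame(apply(u, 2, num_fmt))
    names(au) <- paste0("arraylet_", seq_len(ncol(u)))
    write_tsv(au, file.path(dir, paste0("arraylets_", side, ".tsv")))
  }
  invisible(dir)
}
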