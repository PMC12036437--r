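# Synthetic cohort generator: plants a small number of latent factors
# shared between the phenotype and connectivity domains, then emits the
# same raw material the real pipeline starts from -- skewed drinking
# variables, instrument-range urgency scores, paired seeking counts,
# Bernoulli-style pedigrees, and per-subject connectivity (edge values
# directly, or regional time series drawn from planted correlation
# matrices).  Ground truth (loadings, supports, latent scores) is returned
# for recovery scoring.

.pheno_vars <- c("Sex", "Age", "Education", "FHD", "AUD_Symptoms",
                 "Drinking", "Urgency", "AlcoholSeeking")

#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror the study conditions the pipeline is designed for:
#' 55 subjects, a 145-region triple-network space, planted factors whose
#' phenotype supports echo the drinking/age, family-history/urgency and
#' alcohol-seeking/sex associations, 5\% edge support per factor, and a
#' signal scale calibrated so the leading singular value of the noiseless
#' cross-covariance is three times the expected leading noise singular
#' value.
#'
#' @param n_subjects Cohort size (default 55).
#' @param network_sizes Named integer vector \code{c(SN=, FPN=, DMN=)}
#'   (default 45/50/50, summing to 145).
#' @param n_factors Number of planted latent factors K (default 3).
#' @param phenotype_support List of K character vectors (at most 3
#'   variables each) naming the phenotype variables each factor loads on.
#'   Defaults: factor 1 Drinking + Age, factor 2 FHD + Urgency, factor 3
#'   AlcoholSeeking + Sex (recycled/truncated for other K).
#' @param edge_blocks List of K character vectors naming the TNM blocks
#'   each factor's edge support is drawn from.  Defaults: factor 1
#'   SN-FPN + SN-DMN, factor 2 SN-FPN, factor 3 SN-DMN.
#' @param edge_support_fraction Fraction of all allowed edges in each
#'   factor's support (default 0.05).
#' @param factor_strengths Relative strength multipliers, length K
#'   (default linearly decreasing from 1 to 0.6 so component order is
#'   well defined).
#' @param snr Ratio of the planted leading cross-covariance singular value
#'   to the expected leading noise singular value (default 3).
#' @param noise_sd_x Edge-level noise SD (default 0.1, on the correlation
#'   scale).
#' @param noise_sd_raw SD of the noise added to each phenotype target
#'   before mapping to raw instrument scales (default 0.05).
#' @param timeseries Generate regional time series instead of direct edge
#'   values (default \code{FALSE}).
#' @param ts_length Time points per subject when \code{timeseries} is on
#'   (default 616).
#' @param seed Integer seed (mandatory).
#' @return A \code{"cohort_config"} list.
#' @export
cohort_config <- function(n_subjects = 55,
                          network_sizes = c(SN = 45, FPN = 50, DMN = 50),
                          n_factors = 3,
                          phenotype_support = NULL,
                          edge_blocks = NULL,
                          edge_support_fraction = 0.05,
                          factor_strengths = NULL,
                          snr = 3,
                          noise_sd_x = 0.1,
                          noise_sd_raw = 0.05,
                          timeseries = FALSE,
                          ts_length = 616,
                          seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  stopifnot(all(c("SN", "FPN", "DMN") %in% names(network_sizes)),
            all(network_sizes >= 1), n_factors >= 1)
  default_support <- list(c("Drinking", "Age"), c("FHD", "Urgency"),
                          c("AlcoholSeeking", "Sex"))
  default_blocks <- list(c("SN-FPN", "SN-DMN"), "SN-FPN", "SN-DMN")
  if (is.null(phenotype_support)) {
    phenotype_support <- default_support[
      ((seq_len(n_factors) - 1) %% 3) + 1]
  }
  if (is.null(edge_blocks)) {
    edge_blocks <- default_blocks[((seq_len(n_factors) - 1) %% 3) + 1]
  }
  if (is.null(factor_strengths)) {
    factor_strengths <- if (n_factors == 1) 1 else
      seq(1, 0.6, length.out = n_factors)
  }
  stopifnot(length(phenotype_support) == n_factors,
            length(edge_blocks) == n_factors,
            length(factor_strengths) == n_factors)
  for (s in phenotype_support) {
    stopifnot(length(s) >= 1, length(s) <= 3, all(s %in% .pheno_vars))
  }
  for (b in edge_blocks) {
    stopifnot(all(b %in% c("SN-SN", "FPN-FPN", "DMN-DMN",
                           "SN-FPN", "SN-DMN")))
  }
  structure(list(
    n_subjects = n_subjects, network_sizes = network_sizes,
    n_factors = n_factors, phenotype_support = phenotype_support,
    edge_blocks = edge_blocks,
    edge_support_fraction = edge_support_fraction,
    factor_strengths = factor_strengths, snr = snr,
    noise_sd_x = noise_sd_x, noise_sd_raw = noise_sd_raw,
    timeseries = timeseries, ts_length = ts_length, seed = seed
  ), class = "cohort_config")
}

# synthetic region table covering the three TNM networks
synthetic_regions <- function(network_sizes) {
  subnet_of <- list(SN = c("VentAttnA", "VentAttnB"),
                    FPN = c("ContA", "ContB", "ContC"),
                    DMN = c("DefaultA", "DefaultB", "DefaultC"))
  nm <- sub <- character(0)
  for (net in c("SN", "FPN", "DMN")) {
    n <- network_sizes[[net]]
    subs <- rep(subnet_of[[net]], length.out = n)
    hemi <- rep(c("LH", "RH"), length.out = n)
    nm <- c(nm, sprintf("%s_%s_%d", hemi, subs, seq_len(n)))
    sub <- c(sub, subs)
  }
  restrict_tnm(region_table(nm, sub))
}

# map a standard-normal target column to raw instrument scales
.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# pedigree of 2 parents + 4 grandparents whose family-history density best
# matches a target density in [0, 1/3]
match_pedigree <- function(target_fhd) {
  combos <- expand.grid(a_parent = 0:2, a_grand = 0:4)
  combos$fhd <- (0.5 * combos$a_parent + 0.25 * combos$a_grand) / 6
  combos <- combos[order(combos$fhd, combos$a_parent + combos$a_grand), ]
  k <- vapply(target_fhd,
              function(t) which.min(abs(combos$fhd - t)), integer(1))
  combos[k, , drop = FALSE]
}

#' Generate a synthetic cohort with planted cross-domain structure
#'
#' Draws standard-normal latent factor scores shared by both domains.
#' Phenotype targets are affine-noisy functions of the factors mapped onto
#' realistic raw instrument scales (log-normal drinking variables,
#' integer urgency scores, paired work counts whose contrasts recover the
#' seeking factor, pedigrees whose family-history density tracks its
#' target); the connectivity domain carries sparse block-restricted edge
#' loadings on the same factors.  With the time-series route, per-subject
#' regional series are drawn from planted correlation matrices (base
#' correlation plus the subject's edge deviations, repaired to the nearest
#' positive-definite correlation matrix).
#'
#' @param config A \code{\link{cohort_config}}.
#' @return Object of class \code{"tnm_cohort"}: \code{raw} (raw phenotype
#'   data frame), \code{pedigree} (long-format pedigree), \code{regions},
#'   \code{edges}, \code{X} (subjects x edges connectivity matrix;
#'   computed from sample FC when the time-series route is on),
#'   \code{timeseries} (list of T x N matrices or \code{NULL}),
#'   \code{truth} (latent scores, loadings, supports, calibration).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  regions <- synthetic_regions(config$network_sizes)
  edges <- build_edge_index(regions)
  p <- nrow(edges)
  n <- config$n_subjects
  K <- config$n_factors
  q <- length(.pheno_vars)

  with_seed(config$seed, {
    L <- matrix(stats::rnorm(n * K), n, K)      # latent factor scores

    # phenotype targets: supported columns = factor + noise, rest pure noise
    B <- matrix(0, q, K, dimnames = list(.pheno_vars, NULL))
    for (k in seq_len(K)) B[config$phenotype_support[[k]], k] <- 1
    tgt <- L %*% t(B) + matrix(stats::rnorm(n * q), n, q) *
      ifelse(rep(rowSums(abs(B)) > 0, each = n), config$noise_sd_raw, 1)
    colnames(tgt) <- .pheno_vars
    tgt <- apply(tgt, 2, function(x) (x - mean(x)) / stats::sd(x))

    # sparse block-restricted edge loadings, unit-norm columns
    m_support <- max(1L, round(config$edge_support_fraction * p))
    A <- matrix(0, p, K)
    for (k in seq_len(K)) {
      pool <- which(edges$block %in% config$edge_blocks[[k]])
      if (m_support > length(pool)) {
        stop(sprintf(
          "factor %d: requested edge support (%d) exceeds capacity of its blocks (%d)",
          k, m_support, length(pool)), call. = FALSE)
      }
      supp <- sort(sample(pool, m_support))
      vals <- stats::rnorm(m_support)
      A[supp, k] <- vals / sqrt(sum(vals^2))
    }

    # calibration: leading noise singular value of the cross-covariance of
    # an n x p Gaussian noise matrix against unit-variance phenotype
    # columns is approximately sd_x * sqrt(n) * (sqrt(p) + sqrt(q)); the
    # noiseless signal contributes about alpha * n per factor
    noise_sv <- config$noise_sd_x * sqrt(n) * (sqrt(p) + sqrt(q))
    alpha <- config$snr * noise_sv / n
    alphas <- alpha * config$factor_strengths

    base_edge <- ifelse(edges$block %in% c("SN-SN", "FPN-FPN", "DMN-DMN"),
                        0.25, 0.10)
    signal <- L %*% t(sweep(A, 2, alphas, "*"))
    X <- sweep(signal, 2, base_edge, "+") +
      matrix(stats::rnorm(n * p, sd = config$noise_sd_x), n, p)

    ts_list <- NULL
    if (config$timeseries) {
      N <- nrow(regions)
      R0 <- rebuild_matrix(base_edge, edges, N); diag(R0) <- 1
      ts_list <- vector("list", n)
      for (s in seq_len(n)) {
        Rs <- rebuild_matrix(base_edge + signal[s, ], edges, N)
        diag(Rs) <- 1
        Rs <- nearest_pd_correlation(Rs)
        ch <- chol(Rs)
        ts_list[[s]] <- matrix(stats::rnorm(config$ts_length * N),
                               config$ts_length, N) %*% ch
        colnames(ts_list[[s]]) <- regions$name
      }
      fcs <- lapply(ts_list, compute_fc)
      X <- stack_cohort(fcs, edges,
                        subject_ids = sprintf("sub%03d", seq_len(n)))
    } else {
      rownames(X) <- sprintf("sub%03d", seq_len(n))
      attr(X, "edge_index") <- edges
    }

    # --- raw phenotype records from the targets -------------------------
    sid <- sprintf("sub%03d", seq_len(n))
    nz <- function(v) tgt[, v] +
      stats::rnorm(n, sd = config$noise_sd_raw)
    sex <- ifelse(tgt[, "Sex"] > stats::median(tgt[, "Sex"]),
                  "male", "female")
    age <- .clamp(round(32.2 + 9.9 * nz("Age"), 1), 21, 55)
    education <- .clamp(round(15.4 + 2.1 * nz("Education")), 11, 20)
    aud <- .clamp(round(2.5 + 2.4 * nz("AUD_Symptoms")), 0, 11)

    drink_scales <- list(tlfb_ddd = c(1.6, 0.5), tlfb_ddw = c(0.8, 0.6),
                         tlfb_dw = c(2.7, 0.9), tlfb_gdd = c(2.2, 0.55),
                         ldh_kg = c(4.6, 1.2))
    drink <- lapply(drink_scales, function(ms) {
      pmax(0, expm1(ms[1] + ms[2] * nz("Drinking")))
    })

    pur <- .clamp(round(6.6 + 2.5 * nz("Urgency")), 4, 16)
    nur <- .clamp(round(8.1 + 2.6 * nz("Urgency")), 4, 16)

    n_base <- pmax(0, round(200 + 120 * stats::rnorm(n)))
    a_base <- pmax(0, round(180 + 110 * stats::rnorm(n)))
    n_ap <- round(54 + 150 * nz("AlcoholSeeking"))
    a_ap <- round(90 + 150 * nz("AlcoholSeeking"))
    n_cwa <- pmax(0, n_base + n_ap); n_cww <- n_base
    a_cwa <- pmax(0, a_base + a_ap); a_cww <- a_base

    # pedigree: quantile-matched densities over a skewed target in
    # [0, 1/3] (2 parents + 4 grandparents per subject)
    fhd_target <- (1 / 3) * stats::pnorm(nz("FHD"))^3
    ped_counts <- match_pedigree(fhd_target)
    ped <- do.call(rbind, lapply(seq_len(n), function(s) {
      data.frame(
        subject_id = sid[s],
        relationship = c("parent", "parent", rep("grandparent", 4)),
        affected = c(seq_len(2) <= ped_counts$a_parent[s],
                     seq_len(4) <= ped_counts$a_grand[s]),
        stringsAsFactors = FALSE)
    }))

    raw <- data.frame(
      subject_id = sid, sex = sex, age = age, education = education,
      aud_symptoms = aud,
      tlfb_ddd = drink$tlfb_ddd, tlfb_ddw = drink$tlfb_ddw,
      tlfb_dw = drink$tlfb_dw, tlfb_gdd = drink$tlfb_gdd,
      ldh_kg = drink$ldh_kg,
      pur = pur, nur = nur,
      n_cwa = n_cwa, n_cww = n_cww, a_cwa = a_cwa, a_cww = a_cww,
      stringsAsFactors = FALSE)

    truth <- list(
      latent = L,
      phenotype_loadings = B,
      edge_loadings = A,
      phenotype_support = lapply(config$phenotype_support,
                                 function(s) match(s, .pheno_vars)),
      edge_support = lapply(seq_len(K),
                            function(k) which(A[, k] != 0)),
      alphas = alphas, noise_sd_x = config$noise_sd_x,
      noise_sd_raw = config$noise_sd_raw,
      targets = tgt, config = config)

    structure(list(raw = raw, pedigree = ped, regions = regions,
                   edges = edges, X = X, timeseries = ts_list,
                   truth = truth),
              class = "tnm_cohort")
  })
}

#' Repair a symmetric matrix to the nearest positive-definite correlation
#' matrix
#'
#' Floors the eigenvalues at \code{floor} and renormalizes the diagonal to
#' one.
#'
#' @param R Symmetric matrix with unit diagonal (approximately).
#' @param floor Eigenvalue floor (default 1e-6).
#' @return Positive-definite correlation matrix.
#' @export
nearest_pd_correlation <- function(R, floor = 1e-6) {
  R <- (R + t(R)) / 2
  eg <- eigen(R, symmetric = TRUE)
  vals <- pmax(eg$values, floor)
  out <- eg$vectors %*% (vals * t(eg$vectors))
  d <- sqrt(diag(out))
  out <- out / (d %o% d)
  (out + t(out)) / 2
}

#' Score a fitted model against the generator's ground truth
#'
#' Matches fitted components to planted factors greedily on the absolute
#' correlation between the connectivity latent scores and the planted
#' factor scores, then reports per matched pair: support
#' precision/recall/F1 in both domains, absolute latent-score
#' correlations, and absolute loading cosines.
#'
#' @param model A fitted \code{"rpls_model"} on the cohort.
#' @param truth The \code{truth} element of a \code{"tnm_cohort"}.
#' @return Data frame with one row per matched (component, factor) pair.
#' @export
recovery_report <- function(model, truth) {
  K_fit <- length(model$components)
  K_true <- ncol(truth$latent)
  cors <- matrix(0, K_fit, K_true)
  for (a in seq_len(K_fit)) for (b in seq_len(K_true)) {
    cors[a, b] <- abs(stats::cor(model$components[[a]]$phi,
                                 truth$latent[, b]))
  }
  # greedy matching on |score correlation|
  pairs <- list()
  cc <- cors
  for (step in seq_len(min(K_fit, K_true))) {
    k <- arrayInd(which.max(cc), dim(cc))
    pairs[[step]] <- k
    cc[k[1], ] <- -1; cc[, k[2]] <- -1
  }
  prf <- function(fit_supp, true_supp) {
    tp <- length(intersect(fit_supp, true_supp))
    prec <- if (length(fit_supp)) tp / length(fit_supp) else 0
    rec <- if (length(true_supp)) tp / length(true_supp) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(prec, rec, f1)
  }
  coss <- function(a, b) {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) return(0)
    abs(sum(a * b)) / (na * nb)
  }
  rows <- lapply(pairs, function(k) {
    cmp <- model$components[[k[1]]]
    e <- prf(which(cmp$u != 0), truth$edge_support[[k[2]]])
    f <- prf(which(cmp$v != 0), truth$phenotype_support[[k[2]]])
    data.frame(
      component = k[1], factor = k[2],
      score_cor_x = cors[k[1], k[2]],
      score_cor_y = abs(stats::cor(cmp$psi, truth$latent[, k[2]])),
      edge_precision = e[1], edge_recall = e[2], edge_f1 = e[3],
      pheno_precision = f[1], pheno_recall = f[2], pheno_f1 = f[3],
      edge_cosine = coss(cmp$u, truth$edge_loadings[, k[2]]),
      pheno_cosine = coss(cmp$v, truth$phenotype_loadings[, k[2]]))
  })
  do.call(rbind, rows)
}
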