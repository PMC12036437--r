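# Phenotype-domain derivation: family-history density, log transforms of
# skewed drinking variables, alcohol-preference contrasts, z-scoring and
# Kaiser-rule PCA compression into the 8-variable phenotype table.

.fhd_weights <- c(parent = 0.5, full_sibling = 0.5,
                  grandparent = 0.25, parent_sibling = 0.25)

#' Family history density of alcohol use disorder
#'
#' Weighted density of affected biological relatives: affected parents and
#' full siblings contribute 0.5 each, affected grandparents and siblings of
#' parents 0.25 each, unaffected relatives 0.  The score is the sum of the
#' weights divided by the number of counted relatives, so it lies in
#' [0, 0.5].
#'
#' @param relationship Character vector, one entry per counted relative;
#'   each one of \code{"parent"}, \code{"full_sibling"},
#'   \code{"grandparent"}, \code{"parent_sibling"}.
#' @param affected Logical vector of the same length: lifetime alcohol
#'   dependence status per relative.
#' @return The family history density (unitless).
#' @examples
#' # one affected parent, one unaffected parent, one affected grandparent,
#' # three unaffected grandparents: (0.5 + 0.25) / 6 = 0.125
#' compute_fhd(c("parent", "parent", rep("grandparent", 4)),
#'             c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))
#' @export
compute_fhd <- function(relationship, affected) {
  if (length(relationship) == 0L) {
    stop("family history density is undefined for an empty pedigree",
         call. = FALSE)
  }
  stopifnot(length(relationship) == length(affected), is.logical(affected))
  bad <- setdiff(unique(relationship), names(.fhd_weights))
  if (length(bad)) {
    stop("unrecognized relationship(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sum(.fhd_weights[relationship] * affected) / length(relationship)
}

#' Log transform for skewed drinking variables
#'
#' Elementwise \code{log(1 + x)}.  The offset of one keeps zero counts
#' (e.g. zero drinking days per week) finite and maps 0 to 0, and is
#' near-logarithmic for the large values where the skew lives.
#'
#' @param x Nonnegative numeric vector.
#' @return Transformed vector.
#' @export
log_transform_drinking <- function(x) {
  if (any(x < 0, na.rm = TRUE)) {
    stop("drinking variables must be nonnegative", call. = FALSE)
  }
  log1p(x)
}

#' Alcohol preference contrast
#'
#' Completed work trials for alcohol minus trials for water within a
#' self-administration condition; positive values indicate preference for
#' working toward alcohol.
#'
#' @param cwa Cumulative work (trial count) for alcohol.
#' @param cww Cumulative work for water.
#' @return \code{cwa - cww} (trial-count difference).
#' @export
alcohol_preference <- function(cwa, cww) {
  if (any(cwa < 0) || any(cww < 0)) {
    stop("trial counts must be nonnegative", call. = FALSE)
  }
  cwa - cww
}

#' Z-score a numeric vector
#'
#' Standardizes to mean 0 and sample standard deviation 1 (n - 1
#' denominator).
#'
#' @param x Numeric vector.
#' @param name Variable name used in the error for constant input.
#' @return Standardized vector.
#' @export
zscore <- function(x, name = deparse(substitute(x))) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop(sprintf("cannot z-score constant variable '%s'", name),
         call. = FALSE)
  }
  (x - mean(x)) / s
}

# z-score every column of a matrix; attaches centers/scales for reuse
zscore_columns <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  if (any(sdv == 0)) {
    nm <- colnames(X)[sdv == 0]
    if (is.null(nm)) nm <- which(sdv == 0)
    stop("constant column(s): ", paste(nm, collapse = ", "), call. = FALSE)
  }
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  attr(Z, "center") <- mu
  attr(Z, "scale") <- sdv
  Z
}

#' Kaiser-rule PCA compression of a standardized variable group
#'
#' Eigendecomposition of the correlation matrix of the input columns;
#' components with eigenvalue greater than one are retained (Kaiser rule).
#' Each retained component is oriented so that the sum of its loadings is
#' positive, removing the sign indeterminacy of eigenvectors.
#'
#' @param Z n x m matrix of standardized columns (m >= 2).
#' @return List with \code{scores} (n x k), \code{eigenvalues} (length m),
#'   \code{loadings} (m x k), \code{explained} (variance fractions, length
#'   m).
#' @export
pca_compress <- function(Z) {
  Z <- as.matrix(Z)
  if (ncol(Z) < 2) stop("PCA compression needs at least 2 columns",
                        call. = FALSE)
  R <- stats::cor(Z)
  eg <- eigen(R, symmetric = TRUE)
  keep <- which(eg$values > 1)
  if (length(keep) == 0L) {
    stop(paste("no eigenvalue exceeds 1 (Kaiser rule retains nothing);",
               "the variable group carries no shared component --",
               "use a variable directly instead of compressing"),
         call. = FALSE)
  }
  V <- eg$vectors[, keep, drop = FALSE]
  # orient: sum of loadings positive (ties at exactly zero left unflipped)
  flip <- colSums(V) < 0
  V[, flip] <- -V[, flip, drop = FALSE]
  list(
    scores = Z %*% V,
    eigenvalues = eg$values,
    loadings = V,
    explained = eg$values / ncol(Z)
  )
}

#' Assemble the 8-variable standardized phenotype table
#'
#' Derives the phenotype domain from raw participant measures:
#' \itemize{
#'   \item \code{Sex}: coded female = 0, male = 1, then z-scored.
#'   \item \code{Age}, \code{Education}: years, z-scored.
#'   \item \code{FHD}: family history density (\code{\link{compute_fhd}}),
#'     z-scored.
#'   \item \code{AUD_Symptoms}: symptom count, z-scored.
#'   \item \code{Drinking}: first principal component of the five
#'     log-transformed, z-scored drinking variables (drinks per drinking
#'     day, drinking days per week, drinks per week, greatest drinks in a
#'     day, lifetime kilograms).
#'   \item \code{Urgency}: first PC of z-scored positive and negative
#'     urgency.
#'   \item \code{AlcoholSeeking}: first PC of the z-scored neutral and
#'     aversive alcohol-preference contrasts.
#' }
#' All eight columns are z-scored (sample SD).
#'
#' @param raw Data frame with one row per subject and columns
#'   \code{subject_id}, \code{sex} (\code{"male"}/\code{"female"}),
#'   \code{age}, \code{education}, \code{aud_symptoms}, \code{tlfb_ddd},
#'   \code{tlfb_ddw}, \code{tlfb_dw}, \code{tlfb_gdd}, \code{ldh_kg},
#'   \code{pur}, \code{nur}, \code{n_cwa}, \code{n_cww}, \code{a_cwa},
#'   \code{a_cww}.
#' @param pedigree Data frame in long format with columns
#'   \code{subject_id}, \code{relationship}, \code{affected}; every subject
#'   must have at least one counted relative.  Alternatively \code{raw} may
#'   carry a precomputed \code{fhd} column, in which case \code{pedigree}
#'   may be \code{NULL}.
#' @return List of class \code{"phenotype_table"} with \code{values} (n x 8
#'   z-scored matrix), \code{subject_ids}, and \code{provenance} (group
#'   eigenvalues, explained-variance fractions and loadings of the three
#'   PCA compressions).
#' @export
assemble_phenotype_table <- function(raw, pedigree = NULL) {
  if (nrow(raw) < 3) stop("need at least 3 subjects", call. = FALSE)
  need <- c("subject_id", "sex", "age", "education", "aud_symptoms",
            "tlfb_ddd", "tlfb_ddw", "tlfb_dw", "tlfb_gdd", "ldh_kg",
            "pur", "nur", "n_cwa", "n_cww", "a_cwa", "a_cww")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing raw phenotype column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(raw$subject_id)) {
    stop("duplicate subject ids", call. = FALSE)
  }

  if ("fhd" %in% names(raw)) {
    fhd <- raw$fhd
  } else {
    if (is.null(pedigree)) {
      stop("either a pedigree table or a precomputed 'fhd' column is needed",
           call. = FALSE)
    }
    fhd <- vapply(raw$subject_id, function(sid) {
      ped <- pedigree[pedigree$subject_id == sid, , drop = FALSE]
      if (nrow(ped) == 0L) {
        stop("no pedigree records for subject ", sid, call. = FALSE)
      }
      compute_fhd(ped$relationship, as.logical(ped$affected))
    }, numeric(1))
  }

  sex_num <- ifelse(tolower(as.character(raw$sex)) == "male", 1, 0)

  drink_raw <- cbind(tlfb_ddd = raw$tlfb_ddd, tlfb_ddw = raw$tlfb_ddw,
                     tlfb_dw = raw$tlfb_dw, tlfb_gdd = raw$tlfb_gdd,
                     ldh_kg = raw$ldh_kg)
  drink_z <- zscore_columns(log_transform_drinking(drink_raw))
  urg_z <- zscore_columns(cbind(pur = raw$pur, nur = raw$nur))
  ap_z <- zscore_columns(cbind(
    neutral_ap = alcohol_preference(raw$n_cwa, raw$n_cww),
    aversive_ap = alcohol_preference(raw$a_cwa, raw$a_cww)))

  pc_drink <- pca_compress(drink_z)
  pc_urg <- pca_compress(urg_z)
  pc_ap <- pca_compress(ap_z)

  cols <- cbind(
    Sex = zscore(sex_num, "Sex"),
    Age = zscore(raw$age, "Age"),
    Education = zscore(raw$education, "Education"),
    FHD = zscore(fhd, "FHD"),
    AUD_Symptoms = zscore(raw$aud_symptoms, "AUD_Symptoms"),
    Drinking = zscore(pc_drink$scores[, 1], "Drinking"),
    Urgency = zscore(pc_urg$scores[, 1], "Urgency"),
    AlcoholSeeking = zscore(pc_ap$scores[, 1], "AlcoholSeeking")
  )
  rownames(cols) <- as.character(raw$subject_id)

  structure(list(
    values = cols,
    subject_ids = as.character(raw$subject_id),
    provenance = list(
      sex_coding = c(female = 0, male = 1),
      log_transform = "log(1 + x)",
      zscore_denominator = "sample (n - 1)",
      Drinking = pc_drink[c("eigenvalues", "explained", "loadings")],
      Urgency = pc_urg[c("eigenvalues", "explained", "loadings")],
      AlcoholSeeking = pc_ap[c("eigenvalues", "explained", "loadings")]
    )
  ), class = "phenotype_table")
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat(sprintf("Phenotype table: %d subjects x %d variables\n",
              nrow(x$values), ncol(x$values)))
  ev <- function(g) round(100 * x$provenance[[g]]$explained[1])
  cat(sprintf("  group PC1 explained variance: Drinking %d%%, Urgency %d%%, AlcoholSeeking %d%%\n",
              ev("Drinking"), ev("Urgency"), ev("AlcoholSeeking")))
  invisible(x)
}
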