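# Leave-one-out stability of rPLS components: refit with each subject held
# out, align signs against the full-cohort reference, and summarize
# coefficient variability.

#' Leave-one-out ensemble of rPLS fits
#'
#' Refits the model once per subject on the remaining n - 1 subjects, with
#' the regularization pair held fixed at the values selected on the full
#' cohort.  Standardization is recomputed within each fold by default
#' (each fold sees only its own subjects).  The solver is deterministic,
#' so every fold is exactly reproducible by an independent fit on the same
#' subset.
#'
#' @param X,Y Full-cohort domain matrices (or \code{Y} a
#'   \code{phenotype_table}).
#' @param n_components Components per fold.
#' @param lambda_c,lambda_p Regularization radii (fixed across folds).
#' @param ... Further arguments passed to \code{\link{fit_rpls}}.
#' @return Object of class \code{"loocv_ensemble"}: \code{runs} (one
#'   \code{"rpls_model"} per held-out subject), \code{reference} (the
#'   full-cohort model), \code{held_out} (subject index per run).
#' @export
loocv_fit <- function(X, Y, n_components = 4,
                      lambda_c = ncol(X), lambda_p = NULL, ...) {
  if (inherits(Y, "phenotype_table")) Y <- Y$values
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (n < 3) stop("leave-one-out needs at least 3 subjects", call. = FALSE)
  reference <- fit_rpls(X, Y, n_components = n_components,
                        lambda_c = lambda_c, lambda_p = lambda_p, ...)
  runs <- lapply(seq_len(n), function(i) {
    fit_rpls(X[-i, , drop = FALSE], Y[-i, , drop = FALSE],
             n_components = n_components,
             lambda_c = lambda_c, lambda_p = lambda_p, ...)
  })
  structure(list(runs = runs, reference = reference,
                 held_out = seq_len(n)),
            class = "loocv_ensemble")
}

#' Sign-align a leave-one-out ensemble against its reference
#'
#' Components are matched by index (deflation order is stable for
#' well-separated factors); each run's component k is sign-flipped when its
#' connectivity weights correlate negatively with the reference's component
#' k.  A diagnostic warning is raised when, for some run, a different
#' reference component correlates more strongly than the index-matched one,
#' which signals component-order instability.
#'
#' @param ensemble A \code{"loocv_ensemble"}.
#' @return The ensemble with flips applied, alignment recorded in
#'   \code{$alignment} (runs x components matrix of \code{+1}/\code{-1}).
#' @export
align_components <- function(ensemble) {
  ref <- ensemble$reference
  K <- length(ref$components)
  ref_u <- vapply(ref$components, `[[`, numeric(ref$p), "u")
  flips <- matrix(1, length(ensemble$runs), K)
  order_warned <- FALSE
  for (r in seq_along(ensemble$runs)) {
    run <- ensemble$runs[[r]]
    for (k in seq_len(K)) {
      u <- run$components[[k]]$u
      if (stats::sd(u) == 0) {
        stop("zero-variance weight vector in run ", r, call. = FALSE)
      }
      cc <- suppressWarnings(
        vapply(seq_len(K),
               function(j) stats::cor(u, ref_u[, j]), numeric(1)))
      cc[is.na(cc)] <- 0
      if (which.max(abs(cc)) != k) order_warned <- TRUE
      if (cc[k] < 0) {
        flips[r, k] <- -1
        cp <- run$components[[k]]
        cp$u <- -cp$u; cp$v <- -cp$v; cp$phi <- -cp$phi; cp$psi <- -cp$psi
        run$components[[k]] <- cp
      }
    }
    ensemble$runs[[r]] <- run
  }
  if (order_warned) {
    warning(paste("some runs correlate more strongly with a different",
                  "reference component than their index match;",
                  "component order may be unstable"), call. = FALSE)
  }
  ensemble$alignment <- flips
  ensemble
}

#' Coefficient variability across an aligned leave-one-out ensemble
#'
#' @param ensemble An aligned \code{"loocv_ensemble"} (see
#'   \code{\link{align_components}}).
#' @return List with, per component: \code{phenotype} (per-variable
#'   min/quartiles/max and mean of the coefficient distribution across
#'   runs, plus the full-cohort reference coefficient) and
#'   \code{edge_sd} (per-edge population standard deviation, n
#'   denominator, across runs).
#' @export
coefficient_variability <- function(ensemble) {
  if (is.null(ensemble$alignment)) {
    stop("align the ensemble first (align_components)", call. = FALSE)
  }
  ref <- ensemble$reference
  K <- length(ref$components)
  nR <- length(ensemble$runs)
  q_names <- ref$phenotype_names
  if (is.null(q_names)) q_names <- paste0("y", seq_len(ref$q))
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  out <- vector("list", K)
  for (k in seq_len(K)) {
    V <- vapply(ensemble$runs,
                function(run) run$components[[k]]$v, numeric(ref$q))
    V <- matrix(V, nrow = ref$q)             # q x runs
    qs <- t(apply(V, 1, stats::quantile,
                  probs = c(0, 0.25, 0.5, 0.75, 1), names = FALSE))
    pheno <- data.frame(variable = q_names,
                        min = qs[, 1], q25 = qs[, 2], median = qs[, 3],
                        q75 = qs[, 4], max = qs[, 5],
                        mean = rowMeans(V),
                        reference = ref$components[[k]]$v,
                        stringsAsFactors = FALSE)
    U <- vapply(ensemble$runs,
                function(run) run$components[[k]]$u, numeric(ref$p))
    U <- matrix(U, nrow = ref$p)             # p x runs
    out[[k]] <- list(phenotype = pheno,
                     edge_sd = apply(U, 1, pop_sd))
  }
  names(out) <- paste0("component_", seq_len(K))
  structure(list(components = out, n_runs = nR),
            class = "loocv_variability")
}
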