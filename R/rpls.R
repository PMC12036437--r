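# Two-domain partial least squares and its sparse (regularized) variant.
#
# Each component maximizes cov(Xu, Yv) over unit-norm weight vectors.  The
# regularized solver additionally constrains each domain's weights to an
# L1 ball of radius lambda_D (1 <= lambda_D <= |D|), realized by
# soft-thresholding the power-iteration update and bisecting on the
# threshold; lambda_D = 1 forces a single nonzero coefficient (maximal
# regularization), lambda_D >= sqrt(|D|) is vacuous.  Deflation projects
# each domain onto the orthocomplement of its own latent scores, so
# within-domain scores are orthogonal across components.  The solver is
# fully deterministic: SVD-based initialization, no random restarts.

soft_threshold <- function(z, delta) sign(z) * pmax(abs(z) - delta, 0)

#' Project onto the intersection of the unit sphere and an L1 ball
#'
#' Returns the unit-Euclidean-norm vector \code{w} maximizing
#' \code{sum(z * w)} subject to \code{sum(abs(w)) <= c}.  The maximizer is
#' \code{S(z, delta) / ||S(z, delta)||_2} with \code{S} elementwise
#' soft-thresholding and \code{delta >= 0} the smallest threshold at which
#' the L1 bound holds (\code{delta = 0} when the rescaled input already
#' satisfies it).  \code{delta} is found by bisection.
#'
#' @param z Nonzero numeric vector.
#' @param c L1 radius, \code{c >= 1}.  \code{c = 1} forces a one-hot
#'   result (ties broken toward the lowest index).
#' @param tol Bisection tolerance on \code{delta}.
#' @return Unit-norm vector with \code{sum(abs(w)) <= c} (to within
#'   \code{1e-8}).
#' @export
project_l1_ball_unit_sphere <- function(z, c, tol = 1e-10) {
  if (all(z == 0)) stop("cannot project the zero vector", call. = FALSE)
  if (c < 1) stop("L1 radius must be at least 1", call. = FALSE)
  l1_of <- function(delta) {
    w <- soft_threshold(z, delta)
    n2 <- sqrt(sum(w^2))
    if (n2 == 0) return(1)          # limit: a single surviving coordinate
    sum(abs(w)) / n2
  }
  if (l1_of(0) <= c) return(z / sqrt(sum(z^2)))

  az <- abs(z)
  top <- max(az)
  # limit as delta -> top: coordinates tied at max(|z|) survive equally,
  # giving L1 norm sqrt(#ties); if even that exceeds c, fall back to the
  # documented one-hot tie rule (lowest index).
  n_ties <- sum(az == top)
  if (sqrt(n_ties) > c + 1e-12 && n_ties > 1) {
    w <- numeric(length(z))
    k <- which(az == top)[1]
    w[k] <- sign(z[k])
    return(w)
  }
  lo <- 0; hi <- top
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    if (l1_of(mid) > c) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  w <- soft_threshold(z, hi)        # upper endpoint guarantees feasibility
  n2 <- sqrt(sum(w^2))
  if (n2 == 0) {                    # degenerate: keep the max coordinate
    k <- which(az == top)[1]
    w <- numeric(length(z)); w[k] <- sign(z[k])
    return(w)
  }
  w / n2
}

# joint sign convention: flip (u, v, phi, psi) so the phenotype-domain
# coefficient of largest magnitude is positive (lowest index on ties)
fix_component_sign <- function(comp) {
  k <- which.max(abs(comp$v))
  if (comp$v[k] < 0) {
    comp$u <- -comp$u; comp$v <- -comp$v
    comp$phi <- -comp$phi; comp$psi <- -comp$psi
  }
  comp
}

#' Leading PLS component by SVD of the cross-covariance
#'
#' The unregularized solution: \code{(u, v)} is the leading singular-vector
#' pair of \code{M = t(X) \%*\% Y}; latent scores are \code{phi = X u} and
#' \code{psi = Y v}; the covariance score is the leading singular value
#' \code{t(u) \%*\% M \%*\% v}.
#'
#' @param X n x p column-centered connectivity-domain matrix.
#' @param Y n x q column-centered phenotype-domain matrix.
#' @return List of class \code{"pls_component"} with \code{u}, \code{v},
#'   \code{phi}, \code{psi}, \code{covariance_score}, \code{converged},
#'   \code{n_iter}.
#' @export
pls_svd_component <- function(X, Y) {
  if (nrow(X) != nrow(Y)) stop("domains must share subjects", call. = FALSE)
  if (nrow(X) < 2) stop("need at least 2 subjects", call. = FALSE)
  M <- crossprod(X, Y)
  if (max(abs(M)) == 0) {
    stop("cross-covariance is identically zero: no association to model",
         call. = FALSE)
  }
  sv <- svd(M, nu = 1, nv = 1)
  comp <- list(u = drop(sv$u), v = drop(sv$v),
               phi = drop(X %*% sv$u), psi = drop(Y %*% sv$v),
               covariance_score = sv$d[1], converged = TRUE, n_iter = 0L)
  class(comp) <- "pls_component"
  fix_component_sign(comp)
}

#' Sparse PLS component by soft-thresholded alternating power iteration
#'
#' Maximizes \code{t(u) \%*\% t(X) \%*\% Y \%*\% v} subject to unit L2
#' norms and per-domain L1 bounds \code{sum(abs(u)) <= lambda_c},
#' \code{sum(abs(v)) <= lambda_p}.  Updates alternate
#' \code{u <- P(M v, lambda_c)}, \code{v <- P(t(M) u, lambda_p)} where
#' \code{P} is \code{\link{project_l1_ball_unit_sphere}}, starting from the
#' leading right singular vector of \code{M} (deterministic warm start).
#'
#' @param X,Y Column-centered domain matrices sharing rows.
#' @param lambda_c,lambda_p L1 radii for the connectivity and phenotype
#'   domains; valid range \code{[1, ncol]} per domain.
#' @param tol Convergence tolerance on the max-norm weight change.
#' @param max_iter Iteration cap; non-convergence is recorded on the
#'   component (\code{converged = FALSE}) and warned about, never silent.
#' @return A \code{"pls_component"} (see \code{\link{pls_svd_component}}).
#' @export
rpls_component <- function(X, Y, lambda_c = ncol(X), lambda_p = ncol(Y),
                           tol = 1e-6, max_iter = 500) {
  p <- ncol(X); q <- ncol(Y)
  if (lambda_c < 1 || lambda_c > p) {
    stop(sprintf("lambda_c must lie in [1, %d]", p), call. = FALSE)
  }
  if (lambda_p < 1 || lambda_p > q) {
    stop(sprintf("lambda_p must lie in [1, %d]", q), call. = FALSE)
  }
  M <- crossprod(X, Y)
  if (max(abs(M)) == 0) {
    stop("cross-covariance is identically zero: no association to model",
         call. = FALSE)
  }
  sv <- svd(M, nu = 1, nv = 1)
  v <- drop(sv$v)
  u <- project_l1_ball_unit_sphere(drop(M %*% v), lambda_c)
  converged <- FALSE; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    v_new <- project_l1_ball_unit_sphere(drop(crossprod(M, u)), lambda_p)
    u_new <- project_l1_ball_unit_sphere(drop(M %*% v_new), lambda_c)
    delta <- max(max(abs(u_new - u)), max(abs(v_new - v)))
    u <- u_new; v <- v_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning(sprintf("rPLS component did not converge in %d iterations",
                    max_iter), call. = FALSE)
  }
  comp <- list(u = u, v = v, phi = drop(X %*% u), psi = drop(Y %*% v),
               covariance_score = drop(crossprod(u, M %*% v)),
               converged = converged, n_iter = it)
  class(comp) <- "pls_component"
  fix_component_sign(comp)
}

#' Deflate both domains by a fitted component
#'
#' Own-score projection deflation: each domain is projected onto the
#' orthocomplement of its own latent score vector, so subsequent
#' components have latent scores orthogonal to all earlier ones within
#' each domain.
#'
#' @param X,Y Domain matrices the component was fitted on.
#' @param comp A fitted \code{"pls_component"}.
#' @return List with residual matrices \code{X} and \code{Y}.
#' @export
deflate <- function(X, Y, comp) {
  phi <- comp$phi; psi <- comp$psi
  if (sum(phi^2) == 0 || sum(psi^2) == 0) {
    stop("cannot deflate by zero-norm latent scores", call. = FALSE)
  }
  Xr <- X - phi %*% (crossprod(phi, X) / sum(phi^2))
  Yr <- Y - psi %*% (crossprod(psi, Y) / sum(psi^2))
  list(X = Xr, Y = Yr)
}

#' Select the phenotype-domain regularization by the feature cap
#'
#' Scans a grid over \code{[1, q]} and returns the largest lambda (weakest
#' constraint, i.e. the smallest amount of regularization) at which the
#' first component's phenotype weight vector has at most
#' \code{max_features} nonzero coefficients.
#'
#' @param X,Y Column-standardized domain matrices.
#' @param max_features Nonzero cap for the first component (default 3).
#' @param step Grid step (default 0.1).
#' @param lambda_c Connectivity-domain radius held fixed during the scan
#'   (default: vacuous).
#' @return The selected lambda, with the grid and per-grid-point nonzero
#'   counts attached as attribute \code{"scan"}.
#' @export
select_lambda_phenotype <- function(X, Y, max_features = 3, step = 0.1,
                                    lambda_c = ncol(X)) {
  q <- ncol(Y)
  grid <- seq(1, q, by = step)
  nnz <- vapply(grid, function(lp) {
    sum(rpls_component(X, Y, lambda_c = lambda_c, lambda_p = lp)$v != 0)
  }, numeric(1))
  ok <- which(nnz <= max_features)
  if (length(ok) == 0L) {
    stop("no grid value satisfies the feature cap", call. = FALSE)
  }
  sel <- grid[max(ok)]
  attr(sel, "scan") <- data.frame(lambda = grid, nnz = nnz)
  sel
}

#' Select the connectivity-domain regularization by target density
#'
#' Scans a log-spaced grid over \code{[1, sqrt(p)]} (radii above
#' \code{sqrt(p)} cannot bind for a unit-norm vector) and returns the
#' lambda whose first-component nonzero fraction is closest to
#' \code{target_density}; ties go to the smaller lambda.
#'
#' @param X,Y Column-standardized domain matrices.
#' @param target_density Desired nonzero fraction of the connectivity
#'   weights (default 0.5, i.e. preserve half of the dense solution).
#' @param n_grid Number of log-spaced grid points (default 100).
#' @param lambda_p Phenotype-domain radius held fixed during the scan
#'   (default: vacuous).
#' @return The selected lambda; attributes \code{"scan"} (grid densities)
#'   and \code{"achieved_density"}.
#' @export
select_lambda_connectivity <- function(X, Y, target_density = 0.5,
                                       n_grid = 100, lambda_p = ncol(Y)) {
  p <- ncol(X)
  grid <- exp(seq(0, log(sqrt(p)), length.out = n_grid))
  dens <- vapply(grid, function(lc) {
    sum(rpls_component(X, Y, lambda_c = lc, lambda_p = lambda_p)$u != 0) / p
  }, numeric(1))
  gap <- abs(dens - target_density)
  sel_i <- which(gap == min(gap))[1]   # ties -> smaller lambda (grid sorted)
  sel <- grid[sel_i]
  attr(sel, "scan") <- data.frame(lambda = grid, density = dens)
  attr(sel, "achieved_density") <- dens[sel_i]
  sel
}

#' Fit a multi-component (regularized) PLS model
#'
#' Standardizes both domains column-wise (optional for the connectivity
#' domain), then alternates component fitting and own-score deflation.  The
#' same regularization pair is used for every component.  Covariance
#' percentages are expressed relative to the first component, which by
#' construction carries the maximum.
#'
#' @param X n x p connectivity-domain matrix (subjects x edges).
#' @param Y n x q phenotype-domain matrix (or a \code{phenotype_table}).
#' @param n_components Number of components (default 4); must not exceed
#'   \code{min(p, q, n - 1)}.
#' @param lambda_c,lambda_p Regularization radii (defaults: vacuous, i.e.
#'   ordinary PLS).
#' @param scale_x,scale_y Standardize columns to unit sample SD (default
#'   \code{TRUE} for both; centering is always applied).
#' @param tol,max_iter Solver controls, see \code{\link{rpls_component}}.
#' @return Object of class \code{"rpls_model"}: list with
#'   \code{components} (each a \code{"pls_component"}),
#'   \code{covariance_percentages}, \code{lambda_c}, \code{lambda_p},
#'   \code{centering} (per-domain center/scale), and dimensions.
#' @export
fit_rpls <- function(X, Y, n_components = 4,
                     lambda_c = ncol(X), lambda_p = NULL,
                     scale_x = TRUE, scale_y = TRUE,
                     tol = 1e-6, max_iter = 500) {
  if (inherits(Y, "phenotype_table")) Y <- Y$values
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("domains must share subjects", call. = FALSE)
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  if (is.null(lambda_p)) lambda_p <- q
  if (n_components > min(p, q, n - 1)) {
    stop(sprintf("cannot extract %d components from n=%d, p=%d, q=%d",
                 n_components, n, p, q), call. = FALSE)
  }
  std <- function(M, scale) {
    mu <- colMeans(M)
    sc <- if (scale) apply(M, 2, stats::sd) else rep(1, ncol(M))
    if (any(sc == 0)) stop("constant column in a domain matrix",
                           call. = FALSE)
    list(Z = sweep(sweep(M, 2, mu), 2, sc, "/"), center = mu, scale = sc)
  }
  sx <- std(X, scale_x); sy <- std(Y, scale_y)
  Xc <- sx$Z; Yc <- sy$Z

  comps <- vector("list", n_components)
  for (k in seq_len(n_components)) {
    comps[[k]] <- rpls_component(Xc, Yc, lambda_c = lambda_c,
                                 lambda_p = lambda_p,
                                 tol = tol, max_iter = max_iter)
    if (k < n_components) {
      res <- deflate(Xc, Yc, comps[[k]])
      Xc <- res$X; Yc <- res$Y
    }
  }
  scores <- vapply(comps, `[[`, numeric(1), "covariance_score")
  model <- list(
    components = comps,
    covariance_scores = scores,
    covariance_percentages = 100 * scores / scores[1],
    lambda_c = lambda_c, lambda_p = lambda_p,
    scale_x = scale_x, scale_y = scale_y,
    centering = list(x = list(center = sx$center, scale = sx$scale),
                     y = list(center = sy$center, scale = sy$scale)),
    n = n, p = p, q = q,
    phenotype_names = colnames(Y),
    subject_ids = rownames(X)
  )
  class(model) <- "rpls_model"
  model
}

#' @export
print.rpls_model <- function(x, ...) {
  cat(sprintf("rPLS model: %d components, n=%d subjects, p=%d edges, q=%d phenotypes\n",
              length(x$components), x$n, x$p, x$q))
  cat(sprintf("  lambda_c=%.3g lambda_p=%.3g\n", x$lambda_c, x$lambda_p))
  cat("  covariance %: ",
      paste(sprintf("%.1f", x$covariance_percentages), collapse = ", "),
      "\n", sep = "")
  nz <- vapply(x$components, function(cp) sum(cp$v != 0), numeric(1))
  cat("  phenotype nonzeros per component: ",
      paste(nz, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Serialize a fitted model to a directory of CSV tables
#'
#' Writes per-component phenotype coefficients, connectivity coefficients
#' (long format when an edge index and region table are supplied), latent
#' scores per subject, and a plain-text metadata file (lambdas, convergence
#' flags, centering parameters).
#'
#' @param model A fitted \code{"rpls_model"}.
#' @param dir Output directory (created if missing).
#' @param edges,regions Optional edge index and region table for
#'   long-format connectivity output.
#' @return \code{dir}, invisibly.
#' @export
write_rpls_model <- function(model, dir, edges = NULL, regions = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  q_names <- model$phenotype_names
  if (is.null(q_names)) q_names <- paste0("y", seq_len(model$q))
  vmat <- vapply(model$components, `[[`, numeric(model$q), "v")
  vdf <- data.frame(variable = q_names, vmat)
  names(vdf)[-1] <- paste0("component_", seq_along(model$components))
  utils::write.csv(vdf, file.path(dir, "phenotype_coefficients.csv"),
                   row.names = FALSE)
  for (k in seq_along(model$components)) {
    u <- model$components[[k]]$u
    if (!is.null(edges) && !is.null(regions)) {
      udf <- edge_long_format(u, edges, regions)
    } else {
      udf <- data.frame(edge = seq_along(u), value = u)
    }
    utils::write.csv(udf,
                     file.path(dir, sprintf("connectivity_coefficients_c%d.csv", k)),
                     row.names = FALSE)
  }
  sc <- data.frame(
    subject_id = if (is.null(model$subject_ids)) seq_len(model$n)
                 else model$subject_ids)
  for (k in seq_along(model$components)) {
    sc[[sprintf("phi_%d", k)]] <- model$components[[k]]$phi
    sc[[sprintf("psi_%d", k)]] <- model$components[[k]]$psi
  }
  utils::write.csv(sc, file.path(dir, "latent_scores.csv"),
                   row.names = FALSE)
  meta <- c(
    sprintf("lambda_c: %.10g", model$lambda_c),
    sprintf("lambda_p: %.10g", model$lambda_p),
    sprintf("scale_x: %s", model$scale_x),
    sprintf("scale_y: %s", model$scale_y),
    sprintf("n: %d", model$n), sprintf("p: %d", model$p),
    sprintf("q: %d", model$q),
    sprintf("covariance_scores: %s",
            paste(sprintf("%.10g", model$covariance_scores), collapse = ",")),
    sprintf("converged: %s",
            paste(vapply(model$components, `[[`, logical(1), "converged"),
                  collapse = ","))
  )
  writeLines(meta, file.path(dir, "model_metadata.txt"))
  invisible(dir)
}
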