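test_that("the L1-ball/unit-sphere projection matches its oracles", {
  # constraint inactive: plain normalization
  z <- c(3, 1, 0.5)
  expect_equal(project_l1_ball_unit_sphere(z, 3), z / sqrt(sum(z^2)))

  # c = 1 forces a one-hot at the max coordinate (lowest index on ties)
  expect_equal(project_l1_ball_unit_sphere(c(0.2, -5, 1), 1), c(0, -1, 0))
  expect_equal(project_l1_ball_unit_sphere(c(2, 2, 1), 1), c(1, 0, 0))

  # grid-search oracle over the soft-threshold path
  z <- c(3, 1, 0.5); cc <- 1.2
  w <- project_l1_ball_unit_sphere(z, cc)
  grid <- seq(0, max(abs(z)), length.out = 200001)
  feas <- sapply(grid, function(d) {
    s <- sign(z) * pmax(abs(z) - d, 0)
    n2 <- sqrt(sum(s^2))
    if (n2 == 0) return(NA) else sum(abs(s)) / n2
  })
  d_star <- grid[which(feas <= cc)[1]]     # smallest feasible threshold
  s <- sign(z) * pmax(abs(z) - d_star, 0)
  expect_equal(w, s / sqrt(sum(s^2)), tolerance = 1e-5)
  expect_lte(sum(abs(w)), cc + 1e-8)
  expect_equal(sum(w^2), 1, tolerance = 1e-10)

  expect_error(project_l1_ball_unit_sphere(c(0, 0), 1.5), "zero")
})

test_that("the projection maximizes the linear objective on the feasible set", {
  # against random feasible candidates and the unconstrained direction
  set.seed(31)
  for (r in 1:20) {
    z <- rnorm(6)
    cc <- runif(1, 1, sqrt(6))
    w <- project_l1_ball_unit_sphere(z, cc)
    obj <- sum(z * w)
    for (k in 1:200) {
      cand <- rnorm(6)
      cand <- cand / sqrt(sum(cand^2))
      if (sum(abs(cand)) <= cc) expect_lte(sum(z * cand), obj + 1e-8)
    }
  }
})

test_that("unregularized component 1 equals the SVD of the cross-covariance", {
  set.seed(7)
  for (r in 1:25) {
    n <- sample(4:20, 1); p <- sample(3:30, 1); q <- sample(2:8, 1)
    d <- random_domains(n, p, q, seed = r)
    cmp <- rpls_component(d$X, d$Y)
    sv <- svd(crossprod(d$X, d$Y), nu = 1, nv = 1)
    expect_gte(abs(sum(cmp$u * sv$u)), 1 - 1e-8)
    expect_gte(abs(sum(cmp$v * sv$v)), 1 - 1e-8)
    expect_lt(abs(cmp$covariance_score - sv$d[1]), 1e-8)
    svd_cmp <- pls_svd_component(d$X, d$Y)
    expect_gte(abs(sum(cmp$u * svd_cmp$u)), 1 - 1e-8)
  }
})

test_that("symmetric two-domain input reduces to an eigenproblem", {
  d <- random_domains(10, 6, 6, seed = 2)
  cmp <- pls_svd_component(d$X, d$X)
  ev <- eigen(crossprod(d$X), symmetric = TRUE)$vectors[, 1]
  expect_gte(abs(sum(cmp$u * ev)), 1 - 1e-10)
  expect_gte(abs(sum(cmp$v * ev)), 1 - 1e-10)
})

test_that("noiseless rank-1 data is recovered exactly", {
  a <- c(0.5, -0.3, 0.8, 0, 0.1); a <- a / sqrt(sum(a^2))
  b <- c(0.9, 0, -0.4);          b <- b / sqrt(sum(b^2))
  d <- rank1_domains(15, a, b)
  cmp <- pls_svd_component(d$X, d$Y)
  expect_gte(abs(sum(cmp$u * a)), 1 - 1e-6)
  expect_gte(abs(sum(cmp$v * b)), 1 - 1e-6)
  # sign convention: largest-|.| phenotype coefficient positive
  expect_gt(cmp$v[which.max(abs(cmp$v))], 0)
})

test_that("2-sparse constrained solution matches exhaustive subset search", {
  # noiseless rank-1 with 2-sparse phenotype loadings
  b <- c(0, 0.8, 0, 0.6, 0); q <- 5
  a <- rep(1 / sqrt(6), 6)
  d <- rank1_domains(20, a, b, seed = 8)
  cmp <- rpls_component(d$X, d$Y, lambda_p = 1.45)
  expect_setequal(which(cmp$v != 0), c(2L, 4L))

  # oracle: best L1-feasible vector on each 2-subset of coordinates
  M <- crossprod(d$X, d$Y)
  best <- -Inf; best_set <- NULL
  for (i in 1:(q - 1)) for (j in (i + 1):q) {
    zz <- drop(crossprod(M, cmp$u))[c(i, j)]
    if (all(zz == 0)) next
    w <- project_l1_ball_unit_sphere(zz, 1.45)
    val <- sum(zz * w)
    if (val > best) { best <- val; best_set <- c(i, j) }
  }
  expect_setequal(which(cmp$v != 0), best_set)
})

test_that("lambda = 1 forces one nonzero; vacuous radii satisfy feasibility", {
  set.seed(17)
  for (r in 1:20) {
    d <- random_domains(10, 12, 5, seed = 100 + r)
    lc <- runif(1, 1, 12); lp <- runif(1, 1, 5)
    cmp <- rpls_component(d$X, d$Y, lambda_c = lc, lambda_p = lp)
    expect_lte(sum(abs(cmp$u)), lc + 1e-8)
    expect_lte(sum(abs(cmp$v)), lp + 1e-8)
    expect_equal(sum(cmp$u^2), 1, tolerance = 1e-10)
    expect_equal(sum(cmp$v^2), 1, tolerance = 1e-10)
  }
  d <- random_domains(10, 12, 5, seed = 3)
  expect_equal(sum(rpls_component(d$X, d$Y, lambda_p = 1)$v != 0), 1L)
  expect_error(rpls_component(d$X, d$Y, lambda_c = 0.5), "lambda_c")
  expect_error(rpls_component(d$X, d$Y, lambda_p = 99), "lambda_p")
})

test_that("phenotype sparsity is monotone in the regularization radius", {
  set.seed(23)
  for (r in 1:20) {
    d <- random_domains(12, 10, 6, seed = 200 + r)
    nnz <- sapply(seq(1, 6, by = 0.1), function(lp)
      sum(rpls_component(d$X, d$Y, lambda_p = lp)$v != 0))
    expect_true(all(diff(nnz) >= 0))
  }
})

test_that("deflation removes the fitted factor and orthogonalizes scores", {
  # rank-1 noiseless: residuals vanish
  a <- rep(0.5, 4); b <- c(0.6, 0.8)
  d <- rank1_domains(10, a, b, seed = 5)
  cmp <- pls_svd_component(d$X, d$Y)
  res <- deflate(d$X, d$Y, cmp)
  expect_lt(sqrt(sum(res$X^2)), 1e-8)
  expect_lt(sqrt(sum(res$Y^2)), 1e-8)

  # generic: residuals orthogonal to own scores, next scores orthogonal
  d2 <- random_domains(12, 8, 4, seed = 6)
  c1 <- rpls_component(d2$X, d2$Y)
  r2 <- deflate(d2$X, d2$Y, c1)
  expect_lt(max(abs(crossprod(r2$X, c1$phi))), 1e-10)
  expect_lt(max(abs(crossprod(r2$Y, c1$psi))), 1e-10)
  c2 <- rpls_component(r2$X, r2$Y)
  expect_lt(abs(sum(c2$phi * c1$phi)), 1e-8)
  expect_lt(abs(sum(c2$psi * c1$psi)), 1e-8)
})

test_that("two planted orthogonal factors are recovered in order", {
  set.seed(41)
  n <- 40
  t1 <- rnorm(n); t2 <- rnorm(n)
  t2 <- residuals(lm(t2 ~ t1))          # orthogonal factors
  t1 <- t1 - mean(t1)
  a1 <- c(1, 0, 0, 0, 0, 0); a2 <- c(0, 1, 0, 0, 0, 0)
  b1 <- c(1, 0, 0); b2 <- c(0, 1, 0)
  X <- 2 * t1 %*% t(a1) + 1 * t2 %*% t(a2)
  Y <- 2 * t1 %*% t(b1) + 1 * t2 %*% t(b2)
  m <- fit_rpls(X, Y, n_components = 2, scale_x = FALSE, scale_y = FALSE)
  expect_gte(abs(cor(m$components[[1]]$phi, t1)), 0.999)
  expect_gte(abs(cor(m$components[[2]]$phi, t2)), 0.999)
  expect_true(all(diff(m$covariance_scores) < 0))
})

test_that("lambda selection rules agree with per-grid recomputation", {
  # phenotype cap: unconstrained solution already 2-sparse -> top of grid
  b <- c(0, 0.8, 0, 0.6, 0)
  d <- rank1_domains(20, rep(1 / sqrt(6), 6), b, seed = 8)
  lp <- select_lambda_phenotype(d$X, d$Y, max_features = 3)
  expect_equal(as.numeric(lp), 5)

  # cap 1 selects lambda 1 when any larger radius admits 2+ features
  d2 <- random_domains(12, 8, 4, seed = 9)
  lp1 <- select_lambda_phenotype(d2$X, d2$Y, max_features = 1)
  scan <- attr(lp1, "scan")
  if (any(scan$nnz[scan$lambda > 1] >= 2)) {
    expect_equal(as.numeric(lp1),
                 max(scan$lambda[scan$nnz <= 1]))
  }
  # selected radius is the largest grid value satisfying the cap
  lp3 <- select_lambda_phenotype(d2$X, d2$Y, max_features = 3)
  scan3 <- attr(lp3, "scan")
  expect_equal(as.numeric(lp3), max(scan3$lambda[scan3$nnz <= 3]))
  nnz_at <- sum(rpls_component(d2$X, d2$Y, lambda_p = as.numeric(lp3))$v != 0)
  expect_lte(nnz_at, 3)

  # density rule: grid point closest to the target, ties to smaller lambda
  lc <- select_lambda_connectivity(d2$X, d2$Y, target_density = 0.5,
                                   n_grid = 25)
  scan_c <- attr(lc, "scan")
  gap <- abs(scan_c$density - 0.5)
  expect_equal(as.numeric(lc), scan_c$lambda[which(gap == min(gap))[1]])
  dens_at <- sum(rpls_component(d2$X, d2$Y,
                                lambda_c = as.numeric(lc))$u != 0) / 8
  expect_equal(dens_at, attr(lc, "achieved_density"))

  # extreme targets: density 1 is achieved and the documented tie rule
  # (smaller lambda) picks the first grid point attaining it
  lc_hi <- select_lambda_connectivity(d2$X, d2$Y, target_density = 1,
                                      n_grid = 25)
  expect_equal(attr(lc_hi, "achieved_density"), 1)
  scan_hi <- attr(lc_hi, "scan")
  expect_equal(as.numeric(lc_hi), min(scan_hi$lambda[scan_hi$density == 1]))
  lc_lo <- select_lambda_connectivity(d2$X, d2$Y, target_density = 1e-6,
                                      n_grid = 25)
  expect_equal(sum(rpls_component(d2$X, d2$Y,
                                  lambda_c = as.numeric(lc_lo))$u != 0), 1L)
})

test_that("fit_rpls reports covariance percentages against component 1", {
  d <- random_domains(15, 10, 5, seed = 12)
  m1 <- fit_rpls(d$X, d$Y, n_components = 1, scale_x = FALSE,
                 scale_y = FALSE)
  expect_equal(m1$covariance_percentages, 100)
  m4 <- fit_rpls(d$X, d$Y, n_components = 4, scale_x = FALSE,
                 scale_y = FALSE)
  expect_equal(m4$covariance_percentages[1], 100)
  expect_true(all(m4$covariance_percentages <= 100))

  # unregularized scores equal singular values of the deflated sequence
  Xc <- scale(d$X, scale = FALSE); Yc <- scale(d$Y, scale = FALSE)
  for (k in 1:4) {
    sv <- svd(crossprod(Xc, Yc), nu = 1, nv = 1)
    expect_lt(abs(m4$covariance_scores[k] - sv$d[1]), 1e-8)
    cmp <- m4$components[[k]]
    res <- deflate(Xc, Yc, cmp)
    Xc <- res$X; Yc <- res$Y
  }
  expect_error(fit_rpls(d$X, d$Y, n_components = 20), "components")
})

test_that("latent scores are pairwise orthogonal within each domain", {
  d <- random_domains(15, 12, 6, seed = 14)
  m <- fit_rpls(d$X, d$Y, n_components = 4, lambda_c = 4, lambda_p = 2,
                scale_x = FALSE, scale_y = FALSE)
  Phi <- sapply(m$components, `[[`, "phi")
  Psi <- sapply(m$components, `[[`, "psi")
  cp <- abs(cor(Phi)); cq <- abs(cor(Psi))
  expect_lt(max(cp[upper.tri(cp)]), 1e-8)
  expect_lt(max(cq[upper.tri(cq)]), 1e-8)
})

test_that("fitting is deterministic and serializes to CSV", {
  co <- small_cohort(seed = 4)
  ph <- assemble_phenotype_table(co$raw, co$pedigree)
  m1 <- fit_rpls(co$X, ph, n_components = 2, lambda_c = 8, lambda_p = 2)
  m2 <- fit_rpls(co$X, ph, n_components = 2, lambda_c = 8, lambda_p = 2)
  expect_identical(m1, m2)

  dir <- tempfile()
  write_rpls_model(m1, dir, co$edges, co$regions)
  expect_true(file.exists(file.path(dir, "phenotype_coefficients.csv")))
  back <- read.csv(file.path(dir, "phenotype_coefficients.csv"))
  expect_equal(back$component_1, unname(m1$components[[1]]$v),
               tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})
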