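# End-to-end orchestration: a single configuration object drives
# simulation (or loading), phenotype derivation, regularization selection,
# model fitting, block inference, strength substrates, LOOCV, and a
# report bundle of CSV tables with full provenance.

#' Pipeline run configuration
#'
#' All defaults equal the analysis settings the pipeline is built around:
#' four components, 50\% connectivity density target, at most three
#' phenotype features in the first component, 1000 permutations at the
#' 99th percentile, top 5\% regions.
#'
#' @param n_components Number of PLS components (default 4).
#' @param target_density Connectivity-domain density target for lambda
#'   selection (default 0.5); set to \code{NULL} to supply
#'   \code{lambda_c} directly.
#' @param max_features Phenotype feature cap for lambda selection (default
#'   3); set to \code{NULL} to supply \code{lambda_p} directly.
#' @param lambda_c,lambda_p Fixed radii used when the corresponding
#'   selection rule is disabled.
#' @param n_perm,percentile Permutation-test settings (defaults 1000, 99).
#' @param top_fraction Top-region fraction (default 0.05).
#' @param scale_x Standardize connectivity columns (default \code{TRUE}).
#' @param run_loocv Run the leave-one-out stability analysis (default
#'   \code{TRUE}).
#' @param seed Seed for the permutation null (mandatory).
#' @return A \code{"run_config"} list.
#' @export
run_config <- function(n_components = 4, target_density = 0.5,
                       max_features = 3, lambda_c = NULL, lambda_p = NULL,
                       n_perm = 1000, percentile = 99,
                       top_fraction = 0.05, scale_x = TRUE,
                       run_loocv = TRUE, seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  structure(list(n_components = n_components,
                 target_density = target_density,
                 max_features = max_features,
                 lambda_c = lambda_c, lambda_p = lambda_p,
                 n_perm = n_perm, percentile = percentile,
                 top_fraction = top_fraction, scale_x = scale_x,
                 run_loocv = run_loocv, seed = seed),
            class = "run_config")
}

# config fingerprint: polynomial rolling hash over the serialized config
# (double arithmetic, kept below 2^53 so it is exact)
config_hash <- function(config) {
  bytes <- as.integer(serialize(config, NULL, version = 2))
  h <- 5381
  for (b in bytes) h <- (h * 257 + b) %% 68719476736  # 2^36
  paste0(format(as.hexmode(h %/% 65536), width = 5),
         format(as.hexmode(h %% 65536), width = 4))
}

#' Run the full analysis pipeline on a cohort
#'
#' Derives the 8-variable phenotype table from the raw records, selects
#' the regularization pair on the full cohort (phenotype feature cap
#' first with the connectivity constraint vacuous, then the connectivity
#' density rule at the selected phenotype radius), fits both the
#' unregularized and regularized models, runs the block permutation test,
#' signed strengths and top regions per component, summarizes the TNM
#' circuit, and (optionally) the leave-one-out stability analysis.
#'
#' @param cohort A \code{"tnm_cohort"} from \code{\link{simulate_cohort}},
#'   or a list with elements \code{raw}, \code{pedigree} (or \code{raw$fhd}),
#'   \code{X} (subjects x edges), \code{edges}, \code{regions}.
#' @param config A \code{\link{run_config}}.
#' @param outdir Optional directory; when given, all report tables are
#'   written there as CSV along with the serialized configuration.
#' @return List of class \code{"tnm_report"}: \code{phenotypes},
#'   \code{lambda_c}, \code{lambda_p}, \code{model} (regularized),
#'   \code{model_unregularized}, \code{block_tests}, \code{strengths},
#'   \code{top_regions}, \code{circuits} (per component),
#'   \code{loocv_variability} (or \code{NULL}), \code{config},
#'   \code{config_hash}.
#' @export
run_pipeline <- function(cohort, config, outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  X <- cohort$X
  edges <- cohort$edges
  regions <- cohort$regions

  pheno <- assemble_phenotype_table(cohort$raw, cohort$pedigree)
  if (!identical(rownames(X), pheno$subject_ids)) {
    mism <- union(setdiff(rownames(X), pheno$subject_ids),
                  setdiff(pheno$subject_ids, rownames(X)))
    if (length(mism) || nrow(X) != nrow(pheno$values)) {
      stop("subject ids misaligned between domains: ",
           paste(utils::head(mism, 10), collapse = ", "), call. = FALSE)
    }
  }
  Y <- pheno$values
  message(sprintf("domains aligned: %d subjects, %d edges, %d phenotypes",
                  nrow(X), ncol(X), ncol(Y)))

  # standardized copies for lambda selection (selection refits internally)
  Zx <- zscore_columns(X); Zy <- zscore_columns(Y)
  if (!config$scale_x) Zx <- scale(X, scale = FALSE)

  lambda_p <- config$lambda_p
  if (!is.null(config$max_features)) {
    lambda_p <- select_lambda_phenotype(Zx, Zy,
                                        max_features = config$max_features)
    message(sprintf("selected lambda_p = %.2f (feature cap %d)",
                    lambda_p, config$max_features))
  }
  if (is.null(lambda_p)) lambda_p <- ncol(Y)
  lambda_c <- config$lambda_c
  if (!is.null(config$target_density)) {
    lambda_c <- select_lambda_connectivity(
      Zx, Zy, target_density = config$target_density,
      lambda_p = as.numeric(lambda_p))
    message(sprintf("selected lambda_c = %.2f (achieved density %.3f)",
                    lambda_c, attr(lambda_c, "achieved_density")))
  }
  if (is.null(lambda_c)) lambda_c <- ncol(X)

  fit0 <- fit_rpls(X, Y, n_components = config$n_components,
                   scale_x = config$scale_x)
  fit1 <- fit_rpls(X, Y, n_components = config$n_components,
                   lambda_c = as.numeric(lambda_c),
                   lambda_p = as.numeric(lambda_p),
                   scale_x = config$scale_x)

  part <- block_partition(edges)
  block_tests <- list(); strengths <- list(); tops <- list()
  circuits <- list()
  for (k in seq_len(config$n_components)) {
    u <- fit1$components[[k]]$u
    bt <- permutation_block_test(u, part, n_perm = config$n_perm,
                                 percentile = config$percentile,
                                 seed = config$seed + k)
    W <- rebuild_matrix(u, edges)
    sp <- signed_strengths(W, regions)
    block_tests[[k]] <- bt
    strengths[[k]] <- sp
    tops[[k]] <- top_regions(sp, config$top_fraction)
    circuits[[k]] <- circuit_summary(bt)
  }

  loocv_var <- NULL
  if (config$run_loocv) {
    ens <- loocv_fit(X, Y, n_components = config$n_components,
                     lambda_c = as.numeric(lambda_c),
                     lambda_p = as.numeric(lambda_p),
                     scale_x = config$scale_x)
    loocv_var <- coefficient_variability(align_components(ens))
  }

  report <- structure(list(
    phenotypes = pheno,
    lambda_c = as.numeric(lambda_c), lambda_p = as.numeric(lambda_p),
    model = fit1, model_unregularized = fit0,
    block_tests = block_tests, strengths = strengths,
    top_regions = tops, circuits = circuits,
    loocv_variability = loocv_var,
    config = config, config_hash = config_hash(config)
  ), class = "tnm_report")

  if (!is.null(outdir)) write_report(report, outdir, edges, regions)
  report
}

#' Write a report bundle to a directory of CSV tables
#'
#' @param report A \code{"tnm_report"}.
#' @param outdir Output directory (created if needed).
#' @param edges,regions Edge index and region table for long-format
#'   connectivity output.
#' @return \code{outdir}, invisibly.
#' @export
write_report <- function(report, outdir, edges = NULL, regions = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- report$config_hash
  stamp <- function(df) { df$config_hash <- hash; df }
  wr <- function(df, f) utils::write.csv(stamp(df), file.path(outdir, f),
                                         row.names = FALSE)
  # phenotype table
  ph <- data.frame(subject_id = report$phenotypes$subject_ids,
                   report$phenotypes$values, check.names = FALSE)
  wr(ph, "phenotype_table.csv")
  # coefficients, regularized and not
  write_rpls_model(report$model, file.path(outdir, "model_regularized"),
                   edges, regions)
  write_rpls_model(report$model_unregularized,
                   file.path(outdir, "model_unregularized"), edges, regions)
  for (k in seq_along(report$block_tests)) {
    wr(report$block_tests[[k]]$table, sprintf("block_test_c%d.csv", k))
    wr(report$strengths[[k]], sprintf("strengths_c%d.csv", k))
    wr(report$top_regions[[k]], sprintf("top_regions_c%d.csv", k))
    wr(report$circuits[[k]], sprintf("circuit_c%d.csv", k))
  }
  if (!is.null(report$loocv_variability)) {
    for (k in seq_along(report$loocv_variability$components)) {
      cv <- report$loocv_variability$components[[k]]
      wr(cv$phenotype, sprintf("loocv_phenotype_c%d.csv", k))
      wr(data.frame(edge = seq_along(cv$edge_sd), sd = cv$edge_sd),
         sprintf("loocv_edge_sd_c%d.csv", k))
    }
  }
  cfg <- report$config
  jsonlite::write_json(
    c(cfg[!vapply(cfg, is.null, logical(1))], list(config_hash = hash)),
    file.path(outdir, "run_config.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.tnm_report <- function(x, ...) {
  cat("TNM rPLS report\n")
  cat(sprintf("  lambda_c = %.3f, lambda_p = %.3f (config %s)\n",
              x$lambda_c, x$lambda_p, x$config_hash))
  cat("  covariance %: ",
      paste(sprintf("%.1f", x$model$covariance_percentages),
            collapse = ", "), "\n", sep = "")
  for (k in seq_along(x$circuits)) {
    sig <- x$circuits[[k]]
    sig <- sig[sig$status != "not-significant", ]
    cat(sprintf("  component %d circuit: %s\n", k,
                if (nrow(sig)) paste(sig$element, sig$status,
                                     collapse = "; ")
                else "(no significant blocks)"))
  }
  invisible(x)
}
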