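# Network-level inference on fitted connectivity coefficients: block
# contributions, a coefficient-shuffle permutation null, signed regional
# strengths, top-region substrates and the schematic TNM circuit summary.

.tnm_blocks <- c("SN-SN", "FPN-FPN", "DMN-DMN", "SN-FPN", "SN-DMN")

# run code under a local, seeded RNG stream without disturbing the caller's
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Partition the edge index into network-pair blocks
#'
#' @param edges Edge index from \code{\link{build_edge_index}}.
#' @param regions Optional TNM-restricted region table; when supplied
#'   together with \code{by_hemisphere = TRUE}, blocks are refined by the
#'   hemisphere pair (e.g. \code{"SN_L-FPN_R"}).
#' @param by_hemisphere Refine blocks by hemisphere (default \code{FALSE}).
#' @return Factor of block labels, one per edge; levels are the five TNM
#'   blocks (or their hemisphere refinement).
#' @export
block_partition <- function(edges, regions = NULL, by_hemisphere = FALSE) {
  if (!by_hemisphere) {
    return(factor(edges$block, levels = .tnm_blocks))
  }
  if (is.null(regions)) {
    stop("hemisphere-refined partition needs the region table",
         call. = FALSE)
  }
  net <- regions$tnm_network; hem <- regions$hemisphere
  a <- paste0(net[edges$i + 1L], "_", hem[edges$i + 1L])
  b <- paste0(net[edges$j + 1L], "_", hem[edges$j + 1L])
  # canonical order inside the label: SN first, then FPN, then DMN; L
  # before R within a network
  rank <- function(x) {
    match(sub("_.*", "", x), c("SN", "FPN", "DMN")) * 10 +
      match(sub(".*_", "", x), c("L", "R", "none"))
  }
  swap <- rank(a) > rank(b)
  lab <- ifelse(swap, paste0(b, "-", a), paste0(a, "-", b))
  factor(lab)
}

#' Per-block contributions of a connectivity weight vector
#'
#' @param u Fitted connectivity coefficients (edge vector).
#' @param partition Block labels from \code{\link{block_partition}}.
#' @return Data frame with one row per block: \code{block},
#'   \code{absolute} (sum of \code{|u|}; these sum to \code{sum(abs(u))}
#'   exactly across blocks), \code{signed} (plain sum), \code{n_edges}.
#' @export
block_contributions <- function(u, partition) {
  if (length(u) != length(partition)) {
    stop("coefficient vector and partition lengths differ", call. = FALSE)
  }
  if (anyNA(partition)) {
    stop("partition does not cover every edge", call. = FALSE)
  }
  abs_s <- tapply(abs(u), partition, sum, default = 0)
  sgn_s <- tapply(u, partition, sum, default = 0)
  cnt <- tapply(rep(1L, length(u)), partition, sum, default = 0L)
  data.frame(block = levels(partition),
             absolute = as.numeric(abs_s),
             signed = as.numeric(sgn_s),
             n_edges = as.integer(cnt),
             stringsAsFactors = FALSE)
}

#' Coefficient-shuffle permutation test of block contributions
#'
#' Builds a null ensemble by randomly reassigning the fitted coefficients
#' to edge positions (block memberships stay fixed, so each block's null
#' respects its size), recomputing each block's absolute contribution per
#' shuffle.  A block is significant when its observed contribution strictly
#' exceeds the chosen percentile (default 99th, linear-interpolation
#' quantile) of its own null ensemble.
#'
#' @param u Fitted connectivity coefficients.
#' @param partition Block labels covering every edge.
#' @param n_perm Number of shuffles (default 1000; fewer than 100 is
#'   refused as the tail percentile becomes unstable).
#' @param percentile Null percentile defining the threshold (default 99).
#' @param seed Integer seed for the shuffle stream (mandatory).
#' @return Object of class \code{"block_test"}: data frame \code{table}
#'   with per-block \code{observed}, \code{null_threshold},
#'   \code{significant}, \code{direction} (sign of the signed sum),
#'   \code{signed}, \code{n_edges}; plus \code{null} (n_perm x n_blocks
#'   matrix), \code{n_perm}, \code{percentile}, \code{seed}.
#' @export
permutation_block_test <- function(u, partition, n_perm = 1000,
                                   percentile = 99, seed) {
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  if (n_perm < 100) {
    stop("n_perm < 100: the tail percentile is unstable", call. = FALSE)
  }
  obs <- block_contributions(u, partition)
  au <- abs(u)
  g <- as.integer(partition)
  nb <- nlevels(partition)
  null_mat <- with_seed(seed, {
    m <- matrix(0, n_perm, nb)
    for (b in seq_len(n_perm)) {
      perm <- sample.int(length(u))
      # coefficients land on shuffled positions; block labels fixed
      m[b, ] <- vapply(seq_len(nb), function(k) sum(au[perm][g == k]),
                       numeric(1))
    }
    m
  })
  colnames(null_mat) <- levels(partition)
  thr <- apply(null_mat, 2, stats::quantile, probs = percentile / 100,
               names = FALSE)                     # type 7: linear interp
  res <- obs
  res$observed <- res$absolute
  res$null_threshold <- thr
  res$significant <- res$observed > thr           # strict: "higher than"
  res$direction <- sign(res$signed)
  res <- res[, c("block", "observed", "null_threshold", "significant",
                 "direction", "signed", "n_edges")]
  structure(list(table = res, null = null_mat, n_perm = n_perm,
                 percentile = percentile, seed = seed),
            class = "block_test")
}

#' @export
print.block_test <- function(x, ...) {
  cat(sprintf("Block permutation test (%d shuffles, %gth percentile, seed %d)\n",
              x$n_perm, x$percentile, x$seed))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Signed regional strengths of a coefficient matrix
#'
#' For each region, the positive strength is the sum of the positive
#' coefficients in its row of the rebuilt symmetric coefficient matrix and
#' the negative strength the sum of the negative ones; net strength is
#' their sum.  Because every edge appears in two rows, net strengths sum to
#' twice the sum of the edge coefficients.
#'
#' @param W Symmetric coefficient matrix with zero diagonal (from
#'   \code{\link{rebuild_matrix}}).
#' @param regions Optional region table supplying names, networks and
#'   hemispheres.
#' @return Data frame with per-region \code{positive}, \code{negative},
#'   \code{net} (and labels when \code{regions} is given).
#' @export
signed_strengths <- function(W, regions = NULL) {
  W <- as.matrix(W)
  if (max(abs(W - t(W))) > 1e-10) {
    stop("coefficient matrix must be symmetric", call. = FALSE)
  }
  pos <- rowSums(W * (W > 0))
  neg <- rowSums(W * (W < 0))
  out <- data.frame(region_id = seq_len(nrow(W)) - 1L,
                    positive = pos, negative = neg, net = pos + neg)
  if (!is.null(regions)) {
    out$name <- regions$name
    out$tnm_network <- regions$tnm_network
    out$hemisphere <- regions$hemisphere
  }
  out
}

#' Top contributing regions by absolute net strength
#'
#' @param profile Strength profile from \code{\link{signed_strengths}}.
#' @param fraction Fraction of regions to keep (default 0.05); the count is
#'   \code{ceiling(fraction * N)}.
#' @return The selected rows ranked by \code{|net|} descending (ties broken
#'   by region index), with attributes \code{"k"} and \code{"threshold"}
#'   (the smallest selected \code{|net|}, the percentile line of the
#'   strength plots).
#' @export
top_regions <- function(profile, fraction = 0.05) {
  if (fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]", call. = FALSE)
  }
  k <- ceiling(fraction * nrow(profile))
  ord <- order(-abs(profile$net), profile$region_id)
  sel <- profile[ord[seq_len(k)], , drop = FALSE]
  rownames(sel) <- NULL
  attr(sel, "k") <- k
  attr(sel, "threshold") <- min(abs(sel$net))
  sel
}

#' Schematic TNM circuit from a block test
#'
#' Translates block-level significance into the triple-network circuit
#' diagram: the SN-FPN and SN-DMN blocks become directed arrows SN to FPN
#' and SN to DMN (direction imposed by the model, in which the salience
#' network drives both), within-network blocks become self-loops.  Each
#' element is labelled \code{"increased"} (significant, positive signed
#' sum), \code{"decreased"} (significant, negative) or
#' \code{"not-significant"}.
#'
#' @param test A \code{"block_test"} computed on the five-block partition.
#' @return Data frame with \code{element} (e.g. \code{"SN->FPN"},
#'   \code{"SN"}), \code{block}, \code{status}, \code{observed},
#'   \code{threshold}.
#' @export
circuit_summary <- function(test) {
  tb <- test$table
  need <- .tnm_blocks
  if (!all(need %in% tb$block)) {
    stop("block test must cover the five TNM blocks", call. = FALSE)
  }
  tb <- tb[match(need, tb$block), ]
  element <- c("SN", "FPN", "DMN", "SN->FPN", "SN->DMN")
  status <- ifelse(!tb$significant, "not-significant",
                   ifelse(tb$direction > 0, "increased", "decreased"))
  data.frame(element = element, block = tb$block, status = status,
             observed = tb$observed, threshold = tb$null_threshold,
             stringsAsFactors = FALSE)
}
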