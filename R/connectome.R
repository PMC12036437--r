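# Connectivity-domain construction: parcellation labels, the triple-network
# (TNM) restriction, Pearson FC, and edge vectorization under the coupling
# mask that removes direct FPN-DMN interactions.

# Yeo-17 subnetworks belonging to each TNM network. Matching is
# case-insensitive and tolerant of the common atlas spelling variants
# ("SalVentAttnA", "Ventral Attention Network A", "VentAttnA").
.tnm_synonyms <- local({
  syn <- list(
    VentAttnA = c("ventattna", "salventattna", "ventral attention network a"),
    VentAttnB = c("ventattnb", "salventattnb", "ventral attention network b"),
    ContA = c("conta", "control a", "cont a"),
    ContB = c("contb", "control b", "cont b"),
    ContC = c("contc", "control c", "cont c"),
    DefaultA = c("defaulta", "default a"),
    DefaultB = c("defaultb", "default b"),
    DefaultC = c("defaultc", "default c")
  )
  net <- c(VentAttnA = "SN", VentAttnB = "SN",
           ContA = "FPN", ContB = "FPN", ContC = "FPN",
           DefaultA = "DMN", DefaultB = "DMN", DefaultC = "DMN")
  list(syn = syn, net = net)
})

# Known Yeo-17 subnetwork names outside the TNM, accepted and mapped to
# "excluded" (spelling per the Schaefer lookup tables).
.yeo17_other <- c(
  "viscent", "visperi", "soma", "sommota", "sommotb", "dorsattna",
  "dorsattnb", "limbica", "limbicb", "temppar", "tempparietal",
  "visual central", "visual peripheral", "somatomotor a", "somatomotor b",
  "dorsal attention network a", "dorsal attention network b",
  "limbic a", "limbic b", "subcortical", "other"
)

#' Map a Yeo-17 subnetwork label to its triple-network membership
#'
#' The triple network model (TNM) groups eight of the seventeen Yeo
#' resting-state subnetworks into three large-scale networks: the salience
#' network (SN; Ventral Attention A and B), the frontoparietal control
#' network (FPN; Control A, B and C) and the default mode network (DMN;
#' Default A, B and C).  All other subnetworks fall outside the model and
#' map to \code{"excluded"}.
#'
#' @param label Character vector of Yeo-17 subnetwork names.  Matching is
#'   case-insensitive and accepts both the compact atlas spellings
#'   (\code{"SalVentAttnA"}, \code{"ContB"}) and the long forms
#'   (\code{"Ventral Attention Network A"}, \code{"Control B"}).
#' @return Character vector with elements in
#'   \code{c("SN", "FPN", "DMN", "excluded")}.
#' @examples
#' map_yeo17_to_tnm(c("ContB", "DefaultC", "VisCent"))
#' @export
map_yeo17_to_tnm <- function(label) {
  stopifnot(is.character(label), length(label) >= 1)
  key <- tolower(trimws(label))
  out <- character(length(key))
  for (i in seq_along(key)) {
    hit <- NA_character_
    for (sub in names(.tnm_synonyms$syn)) {
      if (key[i] %in% .tnm_synonyms$syn[[sub]]) {
        hit <- .tnm_synonyms$net[[sub]]
        break
      }
    }
    if (is.na(hit)) {
      if (!(key[i] %in% .yeo17_other)) {
        stop(sprintf("unrecognized Yeo-17 subnetwork label: '%s'", label[i]),
             call. = FALSE)
      }
      hit <- "excluded"
    }
    out[i] <- hit
  }
  out
}

#' Build a region table from parcellation labels
#'
#' @param name Character vector of region names.
#' @param subnetwork17 Yeo-17 subnetwork label per region.
#' @param hemisphere Optional hemisphere per region (\code{"L"}, \code{"R"}
#'   or \code{"none"}).  When \code{NULL}, the hemisphere is parsed from an
#'   \code{"LH_"}/\code{"RH_"} prefix of \code{name} and defaults to
#'   \code{"none"} otherwise.
#' @param atlas_id Optional original atlas integer id per region, preserved
#'   as metadata.
#' @return A \code{data.frame} with columns \code{region_id} (0-based,
#'   contiguous), \code{name}, \code{subnetwork17}, \code{tnm_network},
#'   \code{hemisphere} and \code{atlas_id}.
#' @export
region_table <- function(name, subnetwork17, hemisphere = NULL,
                         atlas_id = NULL) {
  stopifnot(length(name) == length(subnetwork17))
  if (anyDuplicated(name)) stop("region names must be unique", call. = FALSE)
  if (is.null(hemisphere)) {
    hemisphere <- ifelse(grepl("^lh_", tolower(name)), "L",
                         ifelse(grepl("^rh_", tolower(name)), "R", "none"))
  }
  stopifnot(all(hemisphere %in% c("L", "R", "none")))
  if (is.null(atlas_id)) atlas_id <- seq_along(name)
  data.frame(
    region_id = seq_along(name) - 1L,
    name = as.character(name),
    subnetwork17 = as.character(subnetwork17),
    tnm_network = map_yeo17_to_tnm(as.character(subnetwork17)),
    hemisphere = as.character(hemisphere),
    atlas_id = as.integer(atlas_id),
    stringsAsFactors = FALSE
  )
}

#' Read a parcellation lookup table from CSV
#'
#' Expects columns \code{region_id}, \code{name}, \code{subnetwork17} and
#' optionally \code{hemisphere}.
#'
#' @param path Path to the CSV file.
#' @return A region table (see \code{\link{region_table}}).
#' @export
read_parcellation <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("region_id", "name", "subnetwork17")
  if (!all(need %in% names(df))) {
    stop("parcellation CSV must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  df <- df[order(df$region_id), , drop = FALSE]
  region_table(df$name, df$subnetwork17,
               hemisphere = if ("hemisphere" %in% names(df)) df$hemisphere,
               atlas_id = df$region_id)
}

#' Restrict a region table to the triple-network subset
#'
#' Drops regions whose Yeo-17 subnetwork lies outside the SN/FPN/DMN triple
#' and re-indexes \code{region_id} to be 0-based and contiguous so that the
#' edge ordering downstream is stable.  Original atlas ids are preserved in
#' \code{atlas_id}.
#'
#' @param regions A region table.
#' @return The TNM-restricted region table.
#' @export
restrict_tnm <- function(regions) {
  keep <- regions$tnm_network %in% c("SN", "FPN", "DMN")
  out <- regions[keep, , drop = FALSE]
  if (nrow(out) == 0L) stop("no TNM regions in table", call. = FALSE)
  out$region_id <- seq_len(nrow(out)) - 1L
  rownames(out) <- NULL
  out
}

#' Pearson functional connectivity from regional time series
#'
#' @param ts Numeric T x N matrix of mean regional BOLD time series (rows =
#'   time points, columns = regions).
#' @return N x N symmetric Pearson correlation matrix with unit diagonal.
#' @export
compute_fc <- function(ts) {
  ts <- as.matrix(ts)
  if (!is.numeric(ts)) stop("time series must be numeric", call. = FALSE)
  if (nrow(ts) < 3) stop("need at least 3 time points", call. = FALSE)
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    nm <- if (!is.null(colnames(ts))) colnames(ts)[bad] else as.character(bad)
    stop("zero-variance region(s): ", paste(nm, collapse = ", "),
         call. = FALSE)
  }
  fc <- stats::cor(ts)
  # enforce exact symmetry and unit diagonal against rounding
  fc <- (fc + t(fc)) / 2
  diag(fc) <- 1
  fc
}

#' Enumerate allowed triple-network edges
#'
#' Traverses the strict upper triangle of the TNM-restricted region ordering
#' row-major and keeps every within-SN, within-FPN, within-DMN, SN-FPN and
#' SN-DMN pair.  Direct FPN-DMN couplings are excluded: under the triple
#' network model the salience network mediates communication between the
#' frontoparietal and default-mode networks, so their direct interaction is
#' not modelled.
#'
#' @param regions TNM-restricted region table (every \code{tnm_network} one
#'   of SN, FPN, DMN; each network non-empty).
#' @return A \code{data.frame} of class \code{"edge_index"} with columns
#'   \code{i}, \code{j} (0-based region ids, \code{i < j}) and \code{block}
#'   (one of \code{"SN-SN"}, \code{"FPN-FPN"}, \code{"DMN-DMN"},
#'   \code{"SN-FPN"}, \code{"SN-DMN"}).
#' @export
build_edge_index <- function(regions) {
  net <- regions$tnm_network
  if (!all(net %in% c("SN", "FPN", "DMN"))) {
    stop("region table must be TNM-restricted (use restrict_tnm)",
         call. = FALSE)
  }
  for (w in c("SN", "FPN", "DMN")) {
    if (!any(net == w)) stop("no regions in network ", w, call. = FALSE)
  }
  n <- nrow(regions)
  ii <- jj <- integer(0)
  for (a in seq_len(n - 1L)) {
    ii <- c(ii, rep.int(a, n - a))
    jj <- c(jj, seq.int(a + 1L, n))
  }
  na <- net[ii]; nb <- net[jj]
  excl <- (na == "FPN" & nb == "DMN") | (na == "DMN" & nb == "FPN")
  ii <- ii[!excl]; jj <- jj[!excl]
  na <- net[ii]; nb <- net[jj]
  block <- ifelse(na == nb, paste0(na, "-", na),
                  ifelse((na == "SN" & nb == "FPN") |
                           (na == "FPN" & nb == "SN"), "SN-FPN", "SN-DMN"))
  out <- data.frame(i = ii - 1L, j = jj - 1L, block = block,
                    stringsAsFactors = FALSE)
  class(out) <- c("edge_index", "data.frame")
  attr(out, "n_regions") <- n
  out
}

#' Vectorize a connectivity matrix over the allowed edges
#'
#' @param fc N x N symmetric connectivity (or coefficient) matrix.
#' @param edges Edge index from \code{\link{build_edge_index}}.
#' @return Numeric vector of length \code{nrow(edges)}, ordered as the edge
#'   index.
#' @export
vectorize_fc <- function(fc, edges) {
  fc <- as.matrix(fc)
  n <- attr(edges, "n_regions")
  if (nrow(fc) != n || ncol(fc) != n) {
    stop(sprintf("FC matrix is %dx%d but edge index expects %d regions",
                 nrow(fc), ncol(fc), n), call. = FALSE)
  }
  fc[cbind(edges$i + 1L, edges$j + 1L)]
}

#' Rebuild a symmetric coefficient matrix from an edge vector
#'
#' Inverse of \code{\link{vectorize_fc}}: excluded (FPN-DMN) positions and
#' the diagonal are zero.
#'
#' @param u Numeric edge vector aligned to \code{edges}.
#' @param edges Edge index.
#' @param n_regions Number of regions (defaults to the edge index's).
#' @return N x N symmetric matrix with zero diagonal.
#' @export
rebuild_matrix <- function(u, edges, n_regions = attr(edges, "n_regions")) {
  if (length(u) != nrow(edges)) {
    stop(sprintf("edge vector length %d does not match edge index (%d)",
                 length(u), nrow(edges)), call. = FALSE)
  }
  W <- matrix(0, n_regions, n_regions)
  W[cbind(edges$i + 1L, edges$j + 1L)] <- u
  W[cbind(edges$j + 1L, edges$i + 1L)] <- u
  W
}

#' Stack per-subject connectivity matrices into a cohort edge matrix
#'
#' @param fcs List of N x N connectivity matrices, one per subject.
#' @param edges Edge index.
#' @param subject_ids Unique subject identifiers, one per matrix.
#' @return n_subjects x n_edges numeric matrix with \code{subject_ids} as
#'   row names; the edge index is attached as attribute
#'   \code{"edge_index"}.
#' @export
stack_cohort <- function(fcs, edges, subject_ids = names(fcs)) {
  if (is.null(subject_ids)) subject_ids <- as.character(seq_along(fcs))
  if (length(subject_ids) != length(fcs)) {
    stop("one subject id per connectivity matrix required", call. = FALSE)
  }
  if (anyDuplicated(subject_ids)) {
    stop("duplicate subject ids: ",
         paste(unique(subject_ids[duplicated(subject_ids)]), collapse = ", "),
         call. = FALSE)
  }
  X <- t(vapply(fcs, vectorize_fc, numeric(nrow(edges)), edges = edges))
  rownames(X) <- subject_ids
  attr(X, "edge_index") <- edges
  X
}

#' Export an edge vector as a long-format table
#'
#' @param u Edge vector.
#' @param edges Edge index.
#' @param regions TNM-restricted region table giving region names.
#' @return Data frame with columns \code{region_i}, \code{region_j},
#'   \code{block}, \code{value}.
#' @export
edge_long_format <- function(u, edges, regions) {
  data.frame(
    region_i = regions$name[edges$i + 1L],
    region_j = regions$name[edges$j + 1L],
    block = edges$block,
    value = u,
    stringsAsFactors = FALSE
  )
}
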