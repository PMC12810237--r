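#' @title Mode-of-action fingerprinting against a reference library
#' @description
#' Treatment fingerprints (26-endpoint SSMD profiles) are clustered jointly
#' with a library of reference compounds of known mode of action (MoA).
#' Cluster co-membership and nearest-reference distances generate ranked,
#' purely hypothesis-generating MoA reports; no mechanistic claim is made.
#' @name fingerprinting
NULL

#' Read a reference fingerprint library
#'
#' Expected columns: `compound,concentration,moa_target,moa_class` followed
#' by the 26 endpoint columns in canonical order.
#'
#' @param path CSV file path.
#' @return Data frame; endpoint columns validated against [endpoint_names()].
#' @export
read_reference_library <- function(path) {
  lib <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("compound", "concentration", "moa_target", "moa_class")
  miss <- setdiff(c(req, endpoint_names()), names(lib))
  if (length(miss)) stop("reference library missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(!nzchar(lib$moa_class)))
    stop("reference library has empty moa_class annotations")
  lib
}

fingerprint_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (inherits(x, "vamr_effects")) return(x$fingerprints)
  if (is.data.frame(x)) {
    m <- as.matrix(x[endpoint_names()])
    rn <- if ("group" %in% names(x)) x$group
          else if ("compound" %in% names(x)) make.unique(as.character(x$compound))
          else rownames(x)
    rownames(m) <- rn
    return(m)
  }
  stop("cannot interpret fingerprints: expected matrix, data frame or vamr_effects")
}

#' Cluster query fingerprints with a reference library
#'
#' Joint hierarchical clustering of query (treatment) fingerprints and
#' reference-library rows on their 26 SSMD coordinates. SSMD is already
#' standardized, so no column re-scaling is applied. Missing values must have
#' been imputed upstream ([effect_table()] imputes to 0 and flags).
#'
#' @param queries Fingerprints: a `vamr_effects` object, a group x 26 matrix,
#'   or a data frame with a `group` column and the 26 endpoint columns.
#' @param library Optional reference library ([read_reference_library()]).
#' @param distance `"euclidean"` (default) or `"correlation"`
#'   (1 - Pearson correlation between profiles).
#' @param linkage `"ward.D2"` (default) or `"average"`.
#' @param k,h Flat-cluster cut: number of clusters `k`, or height `h`.
#'   Default: cut at 40% of the maximum merge height.
#' @return A `vamr_clusters` object: `hclust` (with deterministic
#'   smallest-label-first leaf order), `assignment` (named cluster id per
#'   row), `is_query`, `nearest` (per query, references sorted by ascending
#'   distance), `annotations` (library MoA columns), `distance`, `linkage`.
#' @export
cluster_fingerprints <- function(queries, library = NULL,
                                 distance = c("euclidean", "correlation"),
                                 linkage = c("ward.D2", "average"),
                                 k = NULL, h = NULL) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  qm <- fingerprint_matrix(queries)
  if (!is.null(library)) {
    lm <- fingerprint_matrix(library)
    if (ncol(lm) != ncol(qm)) stop("fingerprint dimension mismatch")
    m <- rbind(qm, lm)
    is_query <- c(rep(TRUE, nrow(qm)), rep(FALSE, nrow(lm)))
    ann <- library[c("compound", "concentration", "moa_target", "moa_class")]
  } else {
    m <- qm
    is_query <- rep(TRUE, nrow(qm))
    ann <- NULL
  }
  if (nrow(m) < 2) stop("need at least 2 fingerprints to cluster")
  if (anyNA(m)) stop("fingerprints contain missing values; impute before clustering")
  rownames(m) <- make.unique(rownames(m))
  d <- if (distance == "euclidean") stats::dist(m)
       else stats::as.dist(1 - stats::cor(t(m)))
  hc <- stats::hclust(d, method = linkage)
  hc$order <- deterministic_leaf_order(hc)
  if (is.null(k) && is.null(h)) h <- 0.4 * max(hc$height)
  assignment <- if (!is.null(k)) stats::cutree(hc, k = k)
                else stats::cutree(hc, h = h)
  nearest <- NULL
  if (!is.null(library)) {
    dm <- as.matrix(d)
    nearest <- lapply(rownames(qm), function(q) {
      dd <- dm[q, !is_query]
      ord <- order(dd, names(dd))
      data.frame(reference = names(dd)[ord], distance = unname(dd[ord]),
                 moa_class = ann$moa_class[ord], moa_target = ann$moa_target[ord],
                 stringsAsFactors = FALSE)
    })
    names(nearest) <- rownames(qm)
  }
  structure(list(hclust = hc, assignment = assignment, is_query = is_query,
                 nearest = nearest, annotations = ann,
                 distance = distance, linkage = linkage,
                 cut = if (!is.null(k)) list(k = k) else list(h = h)),
            class = "vamr_clusters")
}

# Recursive smallest-label-first rotation of an hclust tree: at every merge,
# the branch containing the lexicographically smallest label is visited first.
deterministic_leaf_order <- function(hc) {
  n <- length(hc$labels)
  leaves <- function(node) {
    if (node < 0) return(-node)
    l <- hc$merge[node, 1]; r <- hc$merge[node, 2]
    ll <- leaves(l); rr <- leaves(r)
    lmin <- min(hc$labels[ll]); rmin <- min(hc$labels[rr])
    if (lmin <= rmin) c(ll, rr) else c(rr, ll)
  }
  leaves(nrow(hc$merge))
}

#' @export
print.vamr_clusters <- function(x, ...) {
  cat(sprintf("vamr_clusters: %d rows (%d queries, %d references), %s distance, %s linkage\n",
              length(x$assignment), sum(x$is_query), sum(!x$is_query),
              x$distance, x$linkage))
  cat(sprintf("  %d flat clusters\n", length(unique(x$assignment))))
  invisible(x)
}

#' Ranked mode-of-action hypotheses for one query
#'
#' Lists the MoA annotations of references co-clustered with the query,
#' ranked by membership count and then by minimum distance. A query in a
#' singleton cluster (no reference co-members) falls back to its `k` nearest
#' references. The report is descriptive and hypothesis-generating only.
#'
#' @param clusters A `vamr_clusters` object (built with a library).
#' @param query Query row label.
#' @param k Nearest-reference fallback size (default 5).
#' @return A `vamr_moa_report`: list with `query`, `cluster`, `basis`
#'   (`"co-cluster"` or `"nearest"`), `references` (data frame with
#'   distances) and `moa` (ranked data frame `moa_class,n,min_distance`).
#' @export
moa_report <- function(clusters, query, k = 5) {
  if (is.null(clusters$nearest)) stop("clusters were built without a reference library")
  if (!query %in% names(clusters$nearest)) stop("query not found: ", query)
  cl <- clusters$assignment[query]
  members <- names(clusters$assignment)[clusters$assignment == cl &
                                        !clusters$is_query]
  near <- clusters$nearest[[query]]
  if (length(members) > 0) {
    refs <- near[near$reference %in% members, , drop = FALSE]
    basis <- "co-cluster"
  } else {
    refs <- utils::head(near, k)
    basis <- "nearest"
  }
  agg <- stats::aggregate(refs["distance"], by = refs["moa_class"],
                          FUN = min)
  names(agg)[2] <- "min_distance"
  agg$n <- as.integer(table(refs$moa_class)[agg$moa_class])
  agg <- agg[order(-agg$n, agg$min_distance, agg$moa_class), c("moa_class", "n", "min_distance")]
  rownames(agg) <- NULL
  structure(list(query = query, cluster = unname(cl), basis = basis,
                 references = refs, moa = agg),
            class = "vamr_moa_report")
}

#' @export
print.vamr_moa_report <- function(x, ...) {
  cat(sprintf("MoA hypotheses for '%s' (cluster %d, basis: %s)\n",
              x$query, x$cluster, x$basis))
  print(x$moa, row.names = FALSE)
  cat("Hypothesis-generating only; requires pharmacological or genetic follow-up.\n")
  invisible(x)
}

#' Serialize the dendrogram to Newick
#'
#' @param clusters A `vamr_clusters` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(clusters, path) {
  phy <- ape::as.phylo(clusters$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Write flat cluster assignments to CSV
#'
#' @param clusters A `vamr_clusters` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cluster_assignments <- function(clusters, path) {
  df <- data.frame(label = names(clusters$assignment),
                   cluster = unname(clusters$assignment),
                   is_query = clusters$is_query,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
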