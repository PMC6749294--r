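#' Distance matrix between descriptor profiles
#'
#' Treats each selected descriptor column as an object whose coordinates
#' are its values across the compound set, and computes pairwise distances
#' between the columns. Compounds (rows) with a missing value in any
#' selected column are dropped first, with a message.
#'
#' @param table data frame of descriptors (rows = compounds).
#' @param columns character vector (>= 2) of descriptor column names.
#' @param metric `"euclidean"` (the default used throughout) or
#'   `"manhattan"`.
#' @return a [stats::dist] object over the descriptor columns.
#' @export
distance_matrix <- function(table, columns, metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  if (length(columns) < 2)
    stop("need at least 2 descriptor columns", call. = FALSE)
  missing_cols <- setdiff(columns, names(table))
  if (length(missing_cols))
    stop("unknown column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  m <- as.matrix(table[, columns, drop = FALSE])
  keep <- complete.cases(m)
  if (!all(keep))
    message(sprintf("dropped %d compound(s) with missing values in the selected columns",
                    sum(!keep)))
  m <- m[keep, , drop = FALSE]
  if (nrow(m) < 1)
    stop("no complete compounds left for the selected columns", call. = FALSE)
  dist(t(m), method = metric)
}

#' Hierarchical agglomerative clustering of descriptors
#'
#' Standard agglomerative merging over a distance matrix. `"ward"` uses
#' the Ward criterion on (non-squared) Euclidean input distances
#' (`ward.D2`). Ties are resolved deterministically.
#'
#' @param d a [stats::dist] object or symmetric distance matrix with zero
#'   diagonal.
#' @param linkage `"single"` (default), `"complete"`, `"average"` or
#'   `"ward"`.
#' @return object of class `rptlc_dendrogram`: list with `merge` (hclust
#'   merge matrix), `height`, `labels`, `order`, `linkage` and the
#'   underlying `hclust` object.
#' @export
agglomerate <- function(d, linkage = c("single", "complete", "average", "ward")) {
  linkage <- match.arg(linkage)
  if (!inherits(d, "dist")) {
    m <- as.matrix(d)
    if (nrow(m) != ncol(m) || !isTRUE(all.equal(m, t(m), tolerance = 1e-12)))
      stop("distance input must be symmetric", call. = FALSE)
    if (any(diag(m) != 0))
      stop("distance matrix must have a zero diagonal", call. = FALSE)
    d <- as.dist(m)
  }
  method <- if (linkage == "ward") "ward.D2" else linkage
  hc <- hclust(d, method = method)
  structure(
    list(merge = hc$merge, height = hc$height, labels = hc$labels,
         order = hc$order, linkage = linkage, hclust = hc),
    class = "rptlc_dendrogram"
  )
}

#' @export
print.rptlc_dendrogram <- function(x, ...) {
  cat(sprintf("Dendrogram (%s linkage): %d leaves, %d merges\n",
              x$linkage, length(x$labels), length(x$height)))
  fm <- first_merge(x)
  cat(sprintf("  first merge: {%s, %s} at height %.4f\n",
              fm[1], fm[2], x$height[1]))
  invisible(x)
}

#' Labels of the first (lowest) merge
#'
#' The first agglomerative merge joins the nearest pair of objects; for
#' the standard linkages this pair does not depend on the linkage choice,
#' which makes it the robust, settings-free feature of a dendrogram.
#'
#' @param d an `rptlc_dendrogram`.
#' @return character vector of the two leaf labels, in leaf-index order.
#' @export
first_merge <- function(d) {
  stopifnot(inherits(d, "rptlc_dendrogram"))
  pair <- -d$merge[1L, ]
  if (any(pair <= 0))
    stop("first merge is not a leaf pair; malformed dendrogram", call. = FALSE)
  d$labels[sort(pair)]
}

hclust_to_phylo <- function(x) {
  n <- length(x$labels)
  stopifnot(n >= 2)
  # hclust merge j -> ape node id: root (last merge) must be n+1
  node_id <- function(j) n + (n - j)
  edges <- matrix(0L, 2L * (n - 1L), 2L)
  lens <- numeric(2L * (n - 1L))
  k <- 1L
  for (j in seq_len(n - 1L)) {
    for (child in x$merge[j, ]) {
      if (child < 0) {
        edges[k, ] <- c(node_id(j), -child)
        lens[k] <- x$height[j]
      } else {
        edges[k, ] <- c(node_id(j), node_id(child))
        lens[k] <- x$height[j] - x$height[child]
      }
      k <- k + 1L
    }
  }
  structure(list(edge = edges, edge.length = lens,
                 tip.label = x$labels, Nnode = n - 1L),
            class = "phylo")
}

#' Export a dendrogram as JSON or Newick text
#'
#' JSON keeps the merge matrix, heights and labels and round-trips
#' losslessly through [import_dendrogram()]. Newick writes an ultrametric
#' tree in which each node sits at its merge height (so a two-leaf tree at
#' height h is `(A:h,B:h);`).
#'
#' @param d an `rptlc_dendrogram`.
#' @param format `"json"` or `"newick"`.
#' @return a character scalar.
#' @export
export_dendrogram <- function(d, format = c("json", "newick")) {
  stopifnot(inherits(d, "rptlc_dendrogram"))
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::toJSON(
      list(labels = d$labels, merge = d$merge, height = d$height,
           order = d$order, linkage = d$linkage),
      digits = NA, auto_unbox = TRUE
    )
  } else {
    ape::write.tree(hclust_to_phylo(d))
  }
}

#' Rebuild a dendrogram from its JSON export
#'
#' @param txt JSON text produced by [export_dendrogram()].
#' @return an `rptlc_dendrogram`.
#' @export
import_dendrogram <- function(txt) {
  obj <- jsonlite::fromJSON(txt)
  merge <- matrix(as.integer(obj$merge), ncol = 2)
  hc <- structure(
    list(merge = merge, height = as.numeric(obj$height),
         order = as.integer(obj$order), labels = as.character(obj$labels),
         method = obj$linkage, call = NULL, dist.method = NULL),
    class = "hclust"
  )
  structure(
    list(merge = merge, height = hc$height, labels = hc$labels,
         order = hc$order, linkage = obj$linkage, hclust = hc),
    class = "rptlc_dendrogram"
  )
}
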