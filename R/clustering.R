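#' Fold-change matrix across contrasts
#'
#' Assembles the signed fold changes of selected tags across a panel of
#' contrasts. A tag absent from a contrast's universe (not expressed in
#' either library) gets \code{NA} -- never 0, because |FC| >= 1 by
#' construction and 0 would fake a signal.
#'
#' @param results named list of [runContrast()] data.frames (columns used:
#'   \code{tag, fold_change}).
#' @param tags tags to keep as rows; default: tags called UR or DR in at
#'   least one contrast.
#' @return numeric matrix, rows = tags, columns = contrast ids, \code{NA}
#'   for missing.
#' @export
fcMatrix <- function(results, tags = NULL) {
  if (is.null(tags)) {
    tags <- unique(unlist(lapply(results, function(r)
      r$tag[r$call %in% c("UR", "DR")])))
    tags <- sort(tags)
  }
  m <- sapply(results, function(r) r$fold_change[match(tags, r$tag)])
  if (length(tags) == 1L) m <- matrix(m, nrow = 1L,
                                      dimnames = list(tags, names(results)))
  else rownames(m) <- tags
  if (any(colSums(!is.na(m)) == 0L))
    stop("fcMatrix: a contrast column is entirely missing")
  m
}

#' Pairwise-complete distance matrix for clustering
#'
#' Distances are computed over the columns present in both rows
#' (pairwise-complete). For correlation similarities the distance is
#' \code{1 - r}; \code{uncentered_correlation} is the Cluster 3.0 default
#' \code{r = sum(xy) / sqrt(sum(x^2) sum(y^2))}. A row pair sharing no
#' column gets similarity 0 (distance 1) with a warning.
#'
#' @param m numeric matrix (rows are profiles; NA = missing).
#' @param similarity \code{"uncentered_correlation"} (default),
#'   \code{"pearson"}, or \code{"euclidean"}.
#' @return a [stats::dist] object over the rows of \code{m}.
#' @export
profileDistance <- function(m,
    similarity = c("uncentered_correlation", "pearson", "euclidean")) {
  similarity <- match.arg(similarity)
  n <- nrow(m)
  d <- matrix(0, n, n)
  warned <- FALSE
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    shared <- !is.na(m[i, ]) & !is.na(m[j, ])
    if (!any(shared)) {
      if (!warned) {
        warning("row pair(s) with no shared columns: similarity set to 0")
        warned <- TRUE
      }
      d[i, j] <- d[j, i] <- if (similarity == "euclidean") NA else 1
      next
    }
    x <- m[i, shared]; y <- m[j, shared]
    d[i, j] <- d[j, i] <- switch(similarity,
      uncentered_correlation = {
        den <- sqrt(sum(x^2) * sum(y^2))
        1 - if (den == 0) 0 else sum(x * y) / den
      },
      pearson = {
        r <- if (length(x) < 2L || stats::sd(x) == 0 || stats::sd(y) == 0) 0
             else stats::cor(x, y)
        1 - r
      },
      euclidean = sqrt(sum((x - y)^2)))
  }
  rownames(d) <- colnames(d) <- rownames(m)
  stats::as.dist(d)
}

#' Hierarchically cluster fold-change profiles
#'
#' Agglomerative clustering of the rows of a fold-change matrix using
#' pairwise-complete similarities ([profileDistance()]) and the chosen
#' linkage. Defaults (uncentered correlation, average linkage, no
#' normalization of the FC values) match the Cluster 3.0 defaults used in
#' SuperSAGE heat-map workflows.
#'
#' @param m numeric matrix as from [fcMatrix()]; >= 2 rows, each with at
#'   least one present value.
#' @param similarity see [profileDistance()].
#' @param linkage \code{"average"} (default), \code{"complete"},
#'   \code{"single"} or \code{"centroid"}.
#' @return an object of class \code{hclust} (merge tree, heights, leaf
#'   order, labels).
#' @export
clusterRows <- function(m,
    similarity = c("uncentered_correlation", "pearson", "euclidean"),
    linkage = c("average", "complete", "single", "centroid")) {
  similarity <- match.arg(similarity)
  linkage <- match.arg(linkage)
  if (nrow(m) < 2L) stop("need at least 2 rows to cluster")
  if (any(rowSums(!is.na(m)) == 0L))
    stop("every row must have at least one present value")
  d <- profileDistance(m, similarity)
  if (linkage == "centroid") {
    if (similarity != "euclidean")
      stop("centroid linkage requires euclidean similarity")
    stats::hclust(d^2, method = "centroid")
  } else {
    stats::hclust(d, method = linkage)
  }
}

#' Leaf order of a clustering
#' @param tree an \code{hclust} object from [clusterRows()].
#' @return character vector of row labels in dendrogram leaf order.
#' @export
leafOrder <- function(tree) tree$labels[tree$order]

#' Write Cluster 3.0 / TreeView CDT and GTR files
#'
#' Emits the tab-delimited clustered-data-table (.cdt) and gene-tree
#' (.gtr) pair consumed by TreeView-compatible heat-map viewers. The CDT
#' uses the GID/UNIQID/NAME/GWEIGHT header convention with data rows in
#' dendrogram leaf order and missing values as empty fields; the GTR lists
#' the merge tree as (node id, child id, child id, similarity) with
#' similarity = 1 - merge height.
#'
#' @param m fold-change matrix ([fcMatrix()]).
#' @param tree \code{hclust} object over the rows of \code{m}
#'   ([clusterRows()]).
#' @param basename output path prefix; writes \code{<basename>.cdt} and
#'   \code{<basename>.gtr}.
#' @return invisibly, a character vector with the two paths written.
#' @export
writeCdtGtr <- function(m, tree, basename) {
  if (!setequal(tree$labels, rownames(m)))
    stop("dendrogram leaves and matrix rows disagree")
  n <- nrow(m)
  geneId <- function(i) sprintf("GENE%dX", i)   # i = original row index
  nodeId <- function(i) sprintf("NODE%dX", i)
  gtrPath <- paste0(basename, ".gtr")
  cdtPath <- paste0(basename, ".cdt")

  childId <- function(v) if (v < 0) geneId(-v) else nodeId(v)
  gtr <- vapply(seq_len(nrow(tree$merge)), function(k) {
    paste(nodeId(k), childId(tree$merge[k, 1L]), childId(tree$merge[k, 2L]),
          format(1 - tree$height[k], digits = 10), sep = "\t")
  }, character(1))
  writeLines(gtr, gtrPath)

  fmt <- function(v) ifelse(is.na(v), "", format(v, digits = 10,
                                                 trim = TRUE))
  header <- paste(c("GID", "UNIQID", "NAME", "GWEIGHT", colnames(m)),
                  collapse = "\t")
  ord <- tree$order                     # original row indices in leaf order
  rows <- vapply(ord, function(i) {
    lbl <- tree$labels[i]
    paste(c(geneId(i), lbl, lbl, "1", fmt(m[lbl, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), cdtPath)
  invisible(c(cdt = cdtPath, gtr = gtrPath))
}

#' Read a CDT file back into a matrix
#'
#' Inverse of the data part of [writeCdtGtr()]: recovers the fold-change
#' matrix (rows in CDT order, empty fields as NA).
#'
#' @param path a .cdt file.
#' @return numeric matrix with UNIQID rownames.
#' @export
readCdt <- function(path) {
  lines <- readLines(path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  dataCols <- setdiff(seq_along(header),
                      match(c("GID", "UNIQID", "NAME", "GWEIGHT"), header))
  body <- lines[-1L]
  body <- body[!startsWith(body, "EWEIGHT")]
  cells <- strsplit(body, "\t", fixed = TRUE)
  m <- t(vapply(cells, function(r) {
    v <- r[dataCols]  # out-of-range indices (trailing empties) give NA
    suppressWarnings(as.numeric(ifelse(is.na(v) | v == "", NA, v)))
  }, numeric(length(dataCols))))
  rownames(m) <- vapply(cells, `[`, character(1),
                        match("UNIQID", header))
  colnames(m) <- header[dataCols]
  m
}

#' Cut a clustering into flat cluster assignments
#'
#' @param tree \code{hclust} object.
#' @param h cut height, or \code{k} number of clusters (one of the two).
#' @param k see \code{h}.
#' @return named integer vector: row label -> cluster id.
#' @export
cutClusters <- function(tree, h = NULL, k = NULL) {
  stats::cutree(tree, h = h, k = k)
}
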