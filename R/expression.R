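# Expression-profile preprocessing, hierarchical clustering and archetype
# calls for HTR gene families across tissues / developmental stages.

#' Read an expression matrix from TSV
#'
#' First column = gene id, header = tissue labels, values linear scale.
#'
#' @param path TSV path.
#' @return Numeric matrix (genes x tissues).
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (any(is.na(m))) stop("missing values in expression matrix", call. = FALSE)
  m
}

#' Preprocess an expression matrix for clustering
#'
#' Genes with every value below `detection_floor` are flagged not-detected
#' and removed (in real surveys these are candidate pseudogenes — reported,
#' never asserted); remaining values are transformed to `log2(x + 1)` and
#' median-centered per gene.
#'
#' @param matrix Numeric matrix, genes x tissues, non-negative linear scale.
#' @param detection_floor Detection threshold on the linear scale (default 1).
#' @return Processed matrix with attribute `not_detected` (character vector
#'   of removed gene ids).
#' @export
preprocess_expression <- function(matrix, detection_floor = 1.0) {
  stopifnot(is.matrix(matrix), all(matrix >= 0))
  detected <- apply(matrix, 1, function(x) any(x >= detection_floor))
  nd <- rownames(matrix)[!detected]
  m <- matrix[detected, , drop = FALSE]
  if (nrow(m) == 0L) stop("no genes above the detection floor", call. = FALSE)
  m <- log2(m + 1)
  m <- m - apply(m, 1, median)
  attr(m, "not_detected") <- nd
  m
}

#' Hierarchical clustering of expression profiles
#'
#' Distance `1 - Pearson correlation` across tissues, average linkage.
#' Rows with zero variance have undefined correlation and raise an error
#' naming the gene.
#'
#' @param matrix Processed expression matrix (>= 2 genes).
#' @return List of class `htr_cluster`: `hclust` (the stats::hclust object),
#'   `merge`, `height`, `order`, `labels`.
#' @export
hierarchical_cluster <- function(matrix) {
  if (nrow(matrix) < 2L) stop("need at least 2 genes", call. = FALSE)
  v <- apply(matrix, 1, sd)
  if (any(v == 0))
    stop("zero-variance gene row(s): ",
         paste(rownames(matrix)[v == 0], collapse = ", "), call. = FALSE)
  d <- as.dist(1 - cor(t(matrix)))
  hc <- hclust(d, method = "average")
  structure(list(hclust = hc, merge = hc$merge, height = hc$height,
                 order = hc$order, labels = hc$labels),
            class = "htr_cluster")
}

#' Cut a clustering into k groups
#' @param cl `htr_cluster`.
#' @param k Number of clusters.
#' @return Named integer vector of cluster ids.
#' @export
cluster_cut <- function(cl, k) stats::cutree(cl$hclust, k = k)

#' Write the ordered (CDT-like) matrix and merge tree as TSV
#'
#' @param cl `htr_cluster`.
#' @param matrix The clustered matrix.
#' @param path Output TSV path; the merge tree goes to `<path>.tree.tsv`.
#' @export
write_clustered_matrix <- function(cl, matrix, path) {
  m <- matrix[cl$order, , drop = FALSE]
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  tree <- data.frame(join = seq_along(cl$height),
                     left = cl$merge[, 1], right = cl$merge[, 2],
                     height = cl$height)
  write.table(tree, paste0(path, ".tree.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Call the expression archetype of one gene
#'
#' `constitutive` when the coefficient of variation across tissues (linear
#' scale) is below `cv_max`; otherwise `dividing_high` when mean log2
#' expression in dividing-like tissues exceeds differentiated-like tissues
#' by more than `delta`; otherwise `heterogeneous`. This mirrors the
#' archetypes seen in grass HTR families: constitutive H3.3-type profiles
#' versus H3.1-type profiles high in roots, stem, seed and embryo (tissues
#' rich in dividing cells) and low in leaves and endosperm.
#'
#' @param gene_row Named numeric vector, linear-scale expression per tissue.
#' @param tissue_groups Named character vector mapping every tissue to
#'   `"dividing"` or `"differentiated"`.
#' @param cv_max Constitutive CV threshold (default 0.25).
#' @param delta Log2 difference threshold for `dividing_high` (default 1.0).
#' @return One of `"constitutive"`, `"dividing_high"`, `"heterogeneous"`.
#' @export
call_profile_archetype <- function(gene_row, tissue_groups, cv_max = 0.25,
                                   delta = 1.0) {
  tissues <- names(gene_row)
  un <- setdiff(tissues, names(tissue_groups))
  if (length(un))
    stop("tissue(s) not assigned to a group: ", paste(un, collapse = ", "),
         call. = FALSE)
  grp <- tissue_groups[tissues]
  if (!all(grp %in% c("dividing", "differentiated")))
    stop("tissue groups must be 'dividing' or 'differentiated'", call. = FALSE)
  if (mean(gene_row) > 0 && sd(gene_row) / mean(gene_row) < cv_max)
    return("constitutive")
  lr <- log2(gene_row + 1)
  if (mean(lr[grp == "dividing"]) - mean(lr[grp == "differentiated"]) > delta)
    return("dividing_high")
  "heterogeneous"
}
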