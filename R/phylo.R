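#' Pairwise protein distances with pairwise deletion
#'
#' For each sequence pair only the columns gapped in that pair are skipped.
#' `p` is the mismatch fraction over compared columns; the Poisson correction
#' is `d = -ln(1 - p)` and the gamma correction
#' `d = alpha * ((1 - p)^(-1/alpha) - 1)` (gamma rate variation across sites;
#' converges to Poisson as `alpha -> Inf`).
#'
#' @param alignment An `htr_alignment` (>= 2 rows).
#' @param model `"poisson"` or `"gamma"`.
#' @param alpha Gamma shape parameter (default 1).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
protein_distance <- function(alignment, model = c("poisson", "gamma"),
                             alpha = 1.0) {
  model <- match.arg(model)
  m <- as.matrix(alignment)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 rows", call. = FALSE)
  d <- matrix(0, n, n, dimnames = list(alignment$ids, alignment$ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    keep <- m[i, ] != "-" & m[j, ] != "-"
    if (!any(keep))
      stop("zero compared columns for pair ", alignment$ids[i], " / ",
           alignment$ids[j], call. = FALSE)
    p <- mean(m[i, keep] != m[j, keep])
    if (p >= 1 - 1e-12)
      stop("saturated pair ", alignment$ids[i], " / ", alignment$ids[j],
           call. = FALSE)
    d[i, j] <- d[j, i] <- if (model == "poisson") -log(1 - p)
      else alpha * ((1 - p)^(-1 / alpha) - 1)
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining. Join ties are broken by the smallest (i, j)
#' index pair in the current node order; negative branch lengths are clamped
#' to zero with the deficit moved onto the sibling branch, so additive
#' matrices are still recovered exactly. The result is an unrooted `ape`
#' `phylo` with a root trifurcation.
#'
#' @param dm Symmetric distance matrix with ids as dimnames (>= 3 taxa).
#' @return An object of class `phylo`.
#' @export
neighbor_joining <- function(dm) {
  d <- as.matrix(dm)
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  stopifnot(!is.null(rownames(d)), isTRUE(all.equal(d, t(d))))
  fmt <- function(x) sprintf("%.10f", max(x, 0))
  labels <- rownames(d)
  while (nrow(d) > 3L) {
    m <- nrow(d)
    r <- rowSums(d)
    q_best <- Inf; bi <- 1L; bj <- 2L
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      q <- (m - 2) * d[i, j] - r[i] - r[j]
      if (q < q_best - 1e-12) { q_best <- q; bi <- i; bj <- j }
    }
    li <- d[bi, bj] / 2 + (r[bi] - r[bj]) / (2 * (m - 2))
    lj <- d[bi, bj] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_label <- sprintf("(%s:%s,%s:%s)", labels[bi], fmt(li),
                         labels[bj], fmt(lj))
    keep <- setdiff(seq_len(m), c(bi, bj))
    dn <- (d[bi, keep] + d[bj, keep] - d[bi, bj]) / 2
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dn), c(dn, 0))
    labels <- c(labels[keep], new_label)
    dimnames(d2) <- list(NULL, NULL)
    d <- d2
  }
  # resolve the final three nodes as a trifurcation
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", labels[1], fmt(la),
                 labels[2], fmt(lb), labels[3], fmt(lc))
  ape::read.tree(text = nwk)
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Columns are resampled with replacement `n_replicates` times under a seeded
#' RNG; each replicate alignment is run through [protein_distance()] and
#' [neighbor_joining()], and each internal edge of the full-data tree gets
#' `100 * frequency` of its bipartition across replicate trees as support.
#' Replicates whose distances are undefined (saturated or zero-overlap pairs)
#' are skipped and counted; the skip rate is reported as an attribute.
#'
#' @param alignment `htr_alignment` with >= 4 rows.
#' @param n_replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer RNG seed.
#' @param model,alpha Distance model, see [protein_distance()].
#' @return A `phylo` whose `node.label` holds supports in \[0, 100\]
#'   (`NA` on the root node), with attributes `n_replicates_used` and
#'   `skip_rate`.
#' @export
bootstrap_support <- function(alignment, n_replicates = 1000L, seed = 1L,
                              model = "poisson", alpha = 1.0) {
  if (n_replicates < 1L) stop("n_replicates must be >= 1", call. = FALSE)
  if (length(alignment$ids) < 4L)
    stop("bootstrap needs at least 4 sequences", call. = FALSE)
  base <- neighbor_joining(protein_distance(alignment, model, alpha))
  m <- as.matrix(alignment)
  L <- ncol(m)
  boot_trees <- list()
  skipped <- 0L
  with_seed(seed, {
    for (b in seq_len(n_replicates)) {
      cols <- sample.int(L, L, replace = TRUE)
      rep_aln <- htr_alignment(alignment$ids,
                               apply(m[, cols, drop = FALSE], 1, paste,
                                     collapse = ""))
      t <- tryCatch(neighbor_joining(protein_distance(rep_aln, model, alpha)),
                    error = function(e) NULL)
      if (is.null(t)) skipped <- skipped + 1L else
        boot_trees[[length(boot_trees) + 1L]] <- t
    }
  })
  used <- length(boot_trees)
  if (used == 0L) stop("all bootstrap replicates were saturated", call. = FALSE)
  class(boot_trees) <- "multiPhylo"
  counts <- ape::prop.clades(base, boot_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- 100 * counts / used
  support[1L] <- NA_real_  # root pseudo-node: whole-tree bipartition
  base$node.label <- as.character(round(support, 1))
  attr(base, "n_replicates_used") <- used
  attr(base, "skip_rate") <- skipped / n_replicates
  base
}

# tips descended from each internal node, as a list indexed by node number
node_tip_sets <- function(tree) {
  n <- length(tree$tip.label)
  nn <- tree$Nnode
  sets <- vector("list", n + nn)
  for (i in seq_len(n)) sets[[i]] <- tree$tip.label[i]
  # edges in ape trees can be traversed child-first via reverse postorder
  ord <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(ord))) {
    par <- ord[k, 1]; child <- ord[k, 2]
    sets[[par]] <- c(sets[[par]], sets[[child]])
  }
  sets
}

#' Smallest well-supported clade containing a set of anchors
#'
#' Scans every internal bipartition of the tree; a side qualifies when it
#' contains all anchors, is a proper subset of the leaves, and its edge
#' support meets `min_support`. The smallest qualifying leaf set is returned
#' (the anchored CenH3 clade); an empty character vector when none qualifies.
#'
#' @param tree `phylo` with supports in `node.label` (as from
#'   [bootstrap_support()]).
#' @param anchor_ids Leaf names that must all sit inside the clade.
#' @param min_support Minimum bootstrap support (default 70).
#' @return Character vector of leaf names (possibly empty).
#' @export
find_anchored_clade <- function(tree, anchor_ids, min_support = 70) {
  missing <- setdiff(anchor_ids, tree$tip.label)
  if (length(missing))
    stop("anchor(s) missing from tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  n <- length(tree$tip.label)
  root <- n + 1L
  sets <- node_tip_sets(tree)
  supports <- suppressWarnings(as.numeric(tree$node.label))
  best <- NULL
  for (v in (n + 1L):(n + tree$Nnode)) {
    if (v == root) next
    s <- supports[v - n]
    if (is.na(s) || s < min_support) next
    side1 <- sets[[v]]
    side2 <- setdiff(tree$tip.label, side1)
    for (side in list(side1, side2)) {
      if (length(side) == 0L || length(side) == n) next
      if (!all(anchor_ids %in% side)) next
      if (is.null(best) || length(side) < length(best)) best <- side
    }
  }
  if (is.null(best)) character(0) else sort(best)
}
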