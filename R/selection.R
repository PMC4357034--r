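#' Codon alignment container
#'
#' @param ids Sequence ids.
#' @param codons Matrix of codon strings (rows = sequences, `"---"` = gap).
#' @return Object of class `htr_codon_alignment`.
#' @export
htr_codon_alignment <- function(ids, codons) {
  codons <- as.matrix(codons)
  rownames(codons) <- ids
  structure(list(ids = as.character(ids), codons = codons,
                 column_count = ncol(codons)), class = "htr_codon_alignment")
}

#' Back-translate a protein alignment into a codon alignment
#'
#' Every amino-acid column expands to its source codon; protein gaps expand
#' to `"---"`. A terminal stop codon on the CDS is stripped. The CDS must
#' translate exactly to the ungapped protein row, otherwise an error names
#' the sequence and the first mismatching position.
#'
#' @param protein_alignment An `htr_alignment`.
#' @param cds_map Named character vector of CDS nucleotide sequences.
#' @return An `htr_codon_alignment`.
#' @export
backtranslate <- function(protein_alignment, cds_map) {
  ids <- protein_alignment$ids
  missing <- setdiff(ids, names(cds_map))
  if (length(missing))
    stop("no CDS for: ", paste(missing, collapse = ", "), call. = FALSE)
  L <- protein_alignment$column_count
  out <- matrix("---", nrow = length(ids), ncol = L)
  for (r in seq_along(ids)) {
    id <- ids[r]
    prot <- ungap(protein_alignment$rows[[id]])
    naa <- nchar(prot)
    codons <- split_codons(cds_map[[id]])
    if (length(codons) == naa + 1L && is_stop(codons[length(codons)]))
      codons <- codons[-length(codons)]
    if (length(codons) != naa)
      stop("CDS length of ", id, " is not 3 x protein length (+/- stop)",
           call. = FALSE)
    aa <- translate_codons(codons)
    mism <- which(aa != strsplit(prot, "")[[1]])
    if (length(mism))
      stop("translation mismatch for ", id, " at protein position ", mism[1],
           ": CDS gives ", aa[mism[1]], ", protein has ",
           substr(prot, mism[1], mism[1]), call. = FALSE)
    chars <- strsplit(protein_alignment$rows[[id]], "")[[1]]
    out[r, chars != "-"] <- codons
  }
  htr_codon_alignment(ids, out)
}

#' Global dN/dS of a codon alignment group
#'
#' `dN` and `dS` are the means of [ng86_pair()] over all unordered sequence
#' pairs; saturated pairs are skipped with a warning and counted. The ratio
#' is undefined (`NA`) when `dS = 0`.
#'
#' @param ca An `htr_codon_alignment` (>= 2 sequences).
#' @param label Group label carried on the result.
#' @return Object of class `htr_selection` with `dN`, `dS`, `ratio`,
#'   `n_pairs`, `n_saturated`.
#' @export
group_dnds <- function(ca, label = "group") {
  n <- length(ca$ids)
  if (n < 2L) stop("need at least 2 sequences", call. = FALSE)
  prs <- combn(n, 2)
  dns <- c(); dss <- c(); sat <- 0L
  for (k in seq_len(ncol(prs))) {
    res <- tryCatch(ng86_pair(ca$codons[prs[1, k], ], ca$codons[prs[2, k], ]),
                    error = function(e) if (grepl("saturated", conditionMessage(e)))
                      NULL else stop(e))
    if (is.null(res)) sat <- sat + 1L
    else { dns <- c(dns, res$dN); dss <- c(dss, res$dS) }
  }
  if (!length(dns)) stop("all sequence pairs saturated", call. = FALSE)
  if (sat > 0L) warning(sat, " saturated pair(s) skipped", call. = FALSE)
  dN <- mean(dns); dS <- mean(dss)
  structure(list(group = label, dN = dN, dS = dS,
                 ratio = if (dS > 0) dN / dS else NA_real_,
                 n_pairs = ncol(prs), n_saturated = sat, per_site = NULL),
            class = "htr_selection")
}

# binomial tail probabilities extended to fractional counts via the
# regularized incomplete beta; exact for integer counts:
#   P(X >= s) = pbeta(p, s, n - s + 1),  P(X <= s) = 1 - pbeta(p, s+1, n-s)
binom_tail_ge <- function(s, n, p) {
  if (s <= 0) return(1)
  if (p <= 0) return(0)
  if (p >= 1) return(1)
  pbeta(p, s, n - s + 1)
}
binom_tail_le <- function(s, n, p) {
  if (s >= n) return(1)
  if (p >= 1) return(0)
  if (p <= 0) return(1)
  1 - pbeta(p, s + 1, n - s)
}

# generalized Fitch parsimony state sets for one site; ties resolved
# lexicographically in the top-down pass (so reconstruction is reproducible)
fitch_ancestral_codons <- function(tip_states, tree, observed) {
  n <- length(tree$tip.label)
  nn <- tree$Nnode
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  sets <- vector("list", n + nn)
  down <- function(node) {
    if (node <= n) {
      st <- tip_states[[tree$tip.label[node]]]
      sets[[node]] <<- if (is.na(st)) observed else st
      return(invisible())
    }
    ch <- kids[[as.character(node)]]
    for (c in ch) down(c)
    cur <- sets[[ch[1]]]
    for (c in ch[-1]) {
      inter <- intersect(cur, sets[[c]])
      cur <- if (length(inter)) inter else union(cur, sets[[c]])
    }
    sets[[node]] <<- cur
  }
  root <- n + 1L
  down(root)
  assign_state <- rep(NA_character_, n + nn)
  up <- function(node, parent_state) {
    assign_state[node] <<- if (!is.null(parent_state) &&
                               parent_state %in% sets[[node]]) parent_state
      else sort(sets[[node]])[1]
    if (node > n) for (c in kids[[as.character(node)]])
      up(c, assign_state[node])
  }
  up(root, NULL)
  list(states = assign_state, edges = tree$edge)
}

#' SLAC-style per-site selection test
#'
#' Ancestral codons are reconstructed by Fitch parsimony on the tree
#' (deterministic lexicographic tie-break); per site, synonymous and
#' nonsynonymous changes are summed over branches with NG86 pathway
#' averaging. The expected synonymous fraction of a site is the mean
#' `S/(S+N)` of its observed tip codons; two one-sided binomial tests
#' compare the observed synonymous share of changes against it. A site is
#' called `negative` (purifying) when `p_negative < alpha` (synonymous
#' excess) and `positive` when `p_positive < alpha`; invariant sites are
#' `ns` with p = 1. Benjamini-Hochberg q-values are reported alongside; the
#' class call uses the raw p.
#'
#' @param ca An `htr_codon_alignment`.
#' @param tree `phylo` whose tip labels equal the alignment ids.
#' @param alpha Significance level (default 0.05).
#' @param label Group label.
#' @return `htr_selection` whose `per_site` data frame has one row per codon
#'   site: `site`, `Nd`, `Sd`, `expected_syn_fraction`, `p_negative`,
#'   `p_positive`, `q_negative`, `q_positive`, `site_class`.
#' @export
site_selection <- function(ca, tree, alpha = 0.05, label = "group") {
  if (!setequal(tree$tip.label, ca$ids))
    stop("tree leaves and alignment ids differ", call. = FALSE)
  tab <- ng86_tables()
  L <- ca$column_count
  rows <- vector("list", L)
  for (s in seq_len(L)) {
    col <- setNames(ca$codons[, s], ca$ids)
    gap <- setNames(grepl("-", col, fixed = TRUE), ca$ids)
    obs <- unique(col[!gap])
    if (length(obs) == 0L) {
      rows[[s]] <- data.frame(site = s, Nd = 0, Sd = 0,
                              expected_syn_fraction = NA_real_,
                              p_negative = 1, p_positive = 1,
                              site_class = "ns", stringsAsFactors = FALSE)
      next
    }
    f_syn <- mean(tab$S[col[!gap]] / 3)
    if (length(obs) == 1L) {
      rows[[s]] <- data.frame(site = s, Nd = 0, Sd = 0,
                              expected_syn_fraction = f_syn,
                              p_negative = 1, p_positive = 1,
                              site_class = "ns", stringsAsFactors = FALSE)
      next
    }
    tips <- lapply(ca$ids, function(id) if (gap[id]) NA_character_ else col[[id]])
    names(tips) <- ca$ids
    anc <- fitch_ancestral_codons(tips, tree, obs)
    Sd <- 0; Nd <- 0
    for (k in seq_len(nrow(anc$edges))) {
      a <- anc$states[anc$edges[k, 1]]
      b <- anc$states[anc$edges[k, 2]]
      if (a != b) {
        Sd <- Sd + tab$Sd[a, b]
        Nd <- Nd + tab$Nd[a, b]
      }
    }
    m <- Sd + Nd
    p_neg <- if (m > 0) binom_tail_ge(Sd, m, f_syn) else 1
    p_pos <- if (m > 0) binom_tail_le(Sd, m, f_syn) else 1
    cls <- if (m == 0) "ns" else if (p_neg < alpha) "negative"
      else if (p_pos < alpha) "positive" else "ns"
    rows[[s]] <- data.frame(site = s, Nd = Nd, Sd = Sd,
                            expected_syn_fraction = f_syn,
                            p_negative = p_neg, p_positive = p_pos,
                            site_class = cls, stringsAsFactors = FALSE)
  }
  per_site <- do.call(rbind, rows)
  per_site$q_negative <- p.adjust(per_site$p_negative, "BH")
  per_site$q_positive <- p.adjust(per_site$p_positive, "BH")
  per_site <- per_site[, c("site", "Nd", "Sd", "expected_syn_fraction",
                           "p_negative", "p_positive", "q_negative",
                           "q_positive", "site_class")]
  structure(list(group = label, dN = NA_real_, dS = NA_real_,
                 ratio = NA_real_, n_pairs = NA_integer_,
                 n_saturated = NA_integer_, per_site = per_site),
            class = "htr_selection")
}
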