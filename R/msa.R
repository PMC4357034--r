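#' Alignment container
#'
#' A light S3 container: `ids` plus equal-length gapped rows (one string per
#' sequence). Ungapping any row reproduces the input sequence exactly.
#'
#' @param ids Character vector of sequence ids.
#' @param rows Character vector of gapped rows (same length strings).
#' @return Object of class `htr_alignment`.
#' @export
htr_alignment <- function(ids, rows) {
  stopifnot(length(ids) == length(rows), length(rows) >= 1)
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop("alignment rows have unequal lengths", call. = FALSE)
  structure(list(ids = as.character(ids), rows = setNames(as.character(rows), ids),
                 column_count = w), class = "htr_alignment")
}

#' @export
as.matrix.htr_alignment <- function(x, ...) {
  m <- do.call(rbind, strsplit(x$rows, ""))
  rownames(m) <- x$ids
  m
}

#' Remove gaps from a row
#' @param row Gapped string.
#' @return Ungapped sequence.
#' @export
ungap <- function(row) gsub("-", "", row, fixed = TRUE)

#' Optimal global alignment of two protein sequences
#'
#' Needleman-Wunsch with BLOSUM62, affine gaps (open 11 / extend 1) and
#' penalized end gaps.
#'
#' @param a,b Protein sequences.
#' @param ids Ids for the two rows.
#' @param gap_open,gap_extend Affine gap penalties.
#' @return `htr_alignment` with two rows and attribute `score`.
#' @export
global_align_pair <- function(a, b, ids = c("a", "b"),
                              gap_open = 11, gap_extend = 1) {
  a <- assert_protein(a, "first sequence")
  b <- assert_protein(b, "second sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = blosum62(),
    gapOpening = gap_open, gapExtension = gap_extend, type = "global")
  ra <- as.character(Biostrings::alignedPattern(pa))
  rb <- as.character(Biostrings::alignedSubject(pa))
  stopifnot(nchar(ra) == nchar(rb), ungap(ra) == a, ungap(rb) == b)
  aln <- htr_alignment(ids, c(ra, rb))
  attr(aln, "score") <- Biostrings::score(pa)
  aln
}

# p-distance between two gapped rows (pairwise deletion)
row_p_distance <- function(x, y) {
  cx <- strsplit(x, "")[[1]]; cy <- strsplit(y, "")[[1]]
  keep <- cx != "-" & cy != "-"
  if (!any(keep)) return(1)
  mean(cx[keep] != cy[keep])
}

# profile frequency matrix (letters x columns); gaps contribute zero weight,
# columns normalized by the number of sequences
profile_freq <- function(rows) {
  m <- do.call(rbind, strsplit(rows, ""))
  letters <- rownames(blosum62())
  f <- matrix(0, nrow = length(letters), ncol = ncol(m),
              dimnames = list(letters, NULL))
  for (l in letters) f[l, ] <- colSums(m == l)
  f / nrow(m)
}

# Gotoh profile-profile alignment; returns list(cols_a, cols_b): for each
# merged column the source column index in A / B or NA (gap)
align_profiles <- function(rows_a, rows_b, gap_open = 11, gap_extend = 1) {
  fa <- profile_freq(rows_a); fb <- profile_freq(rows_b)
  S <- t(fa) %*% blosum62() %*% fb
  la <- ncol(fa); lb <- ncol(fb)
  NEG <- -1e18
  go <- gap_open + gap_extend
  M <- matrix(NEG, la + 1, lb + 1); X <- M; Y <- M
  M[1, 1] <- 0
  if (la) X[2:(la + 1), 1] <- -(gap_open + gap_extend * seq_len(la))
  if (lb) Y[1, 2:(lb + 1)] <- -(gap_open + gap_extend * seq_len(lb))
  for (i in seq_len(la) + 1L) {
    for (j in seq_len(lb) + 1L) {
      M[i, j] <- S[i - 1L, j - 1L] + max(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                                         Y[i - 1L, j - 1L])
      X[i, j] <- max(M[i - 1L, j] - go, X[i - 1L, j] - gap_extend,
                     Y[i - 1L, j] - go)
      Y[i, j] <- max(M[i, j - 1L] - go, X[i, j - 1L] - go,
                     Y[i, j - 1L] - gap_extend)
    }
  }
  # traceback, tie-break diagonal > up (gap in B) > left (gap in A)
  i <- la + 1L; j <- lb + 1L
  state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
  cols_a <- integer(); cols_b <- integer()
  while (i > 1L || j > 1L) {
    if (state == 1L) {
      cols_a <- c(i - 1L, cols_a); cols_b <- c(j - 1L, cols_b)
      prev <- c(M[i - 1L, j - 1L], X[i - 1L, j - 1L], Y[i - 1L, j - 1L])
      i <- i - 1L; j <- j - 1L
      state <- which.max(prev)
    } else if (state == 2L) {
      cols_a <- c(i - 1L, cols_a); cols_b <- c(NA_integer_, cols_b)
      cand <- c(M[i - 1L, j] - go, X[i - 1L, j] - gap_extend, Y[i - 1L, j] - go)
      i <- i - 1L
      state <- which.max(cand == max(cand)) # first max: M > X > Y
    } else {
      cols_a <- c(NA_integer_, cols_a); cols_b <- c(j - 1L, cols_b)
      cand <- c(M[i, j - 1L] - go, X[i, j - 1L] - go, Y[i, j - 1L] - gap_extend)
      j <- j - 1L
      state <- which.max(cand == max(cand))
    }
    if (i == 1L && state == 2L) state <- 3L
    if (j == 1L && state == 3L && i > 1L) state <- 2L
  }
  list(cols_a = cols_a, cols_b = cols_b)
}

# expand a set of gapped rows along merged column indices
expand_rows <- function(rows, cols) {
  vapply(rows, function(r) {
    ch <- strsplit(r, "")[[1]]
    paste(ifelse(is.na(cols), "-", ch[cols]), collapse = "")
  }, "", USE.NAMES = TRUE)
}

#' Progressive multiple alignment of protein sequences
#'
#' Guide tree: neighbor joining on pairwise p-distances (computed from global
#' pairwise alignments); profile-profile merges in post-order with
#' sum-of-pairs BLOSUM62 scoring and affine gaps. Deterministic.
#'
#' @param seqs Named character vector of protein sequences (>= 2).
#' @param gap_open,gap_extend Affine gap penalties.
#' @return `htr_alignment` whose rows, ungapped, equal the inputs.
#' @export
progressive_msa <- function(seqs, gap_open = 11, gap_extend = 1) {
  if (length(seqs) < 2L) stop("progressive_msa needs at least 2 sequences",
                              call. = FALSE)
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  for (s in seqs) assert_protein(s)
  if (length(seqs) == 2L)
    return(global_align_pair(seqs[[1]], seqs[[2]], ids = names(seqs),
                             gap_open = gap_open, gap_extend = gap_extend))
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    aln <- global_align_pair(seqs[[i]], seqs[[j]], gap_open = gap_open,
                             gap_extend = gap_extend)
    d[i, j] <- d[j, i] <- row_p_distance(aln$rows[[1]], aln$rows[[2]])
  }
  tree <- neighbor_joining(d)
  # post-order merge down the guide tree (rooted at ape's root node)
  merge_node <- function(node) {
    if (node <= n) return(setNames(seqs[tree$tip.label[node]],
                                   tree$tip.label[node]))
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    prof <- merge_node(kids[[1]])
    for (k in kids[-1]) {
      other <- merge_node(k)
      tb <- align_profiles(prof, other, gap_open, gap_extend)
      prof <- c(expand_rows(prof, tb$cols_a), expand_rows(other, tb$cols_b))
    }
    prof
  }
  rows <- merge_node(n + 1L)
  rows <- rows[names(seqs)]  # restore input order
  htr_alignment(names(seqs), rows)
}

#' Map a candidate protein onto canonical mature-H3 numbering
#'
#' Canonical position 1 is the first residue of the mature protein (initiator
#' Met excluded); signature positions 31/41/87/90 and the K4/K9/K27/K36
#' lysines are defined in this frame. The candidate is globally aligned to
#' the reference; each canonical position maps to the aligned candidate
#' residue index (1-based) or `NA` at a gap. Candidate residues aligned
#' before canonical position 1 are counted as N-terminal overhang (the CenH3
#' tail signal). A candidate retaining its initiator Met (residue 1 = M
#' aligned just upstream of canonical 1) has the Met trimmed from the
#' overhang count.
#'
#' @param candidate Candidate protein sequence.
#' @param reference Canonical mature H3 reference sequence.
#' @param candidate_id Id recorded on the map.
#' @return List of class `htr_position_map`: `candidate_id`, `map` (integer
#'   vector over canonical positions), `n_terminal_overhang`, `met_trimmed`.
#' @export
map_to_reference <- function(candidate, reference, candidate_id = "candidate") {
  aln <- global_align_pair(candidate, reference, ids = c("cand", "ref"))
  cc <- strsplit(aln$rows[["cand"]], "")[[1]]
  rc <- strsplit(aln$rows[["ref"]], "")[[1]]
  nref <- nchar(reference)
  map <- rep(NA_integer_, nref)
  ref_pos <- 0L; cand_pos <- 0L; overhang <- 0L
  for (k in seq_along(cc)) {
    if (cc[k] != "-") cand_pos <- cand_pos + 1L
    if (rc[k] != "-") {
      ref_pos <- ref_pos + 1L
      if (cc[k] != "-") map[ref_pos] <- cand_pos
    } else if (ref_pos == 0L && cc[k] != "-") {
      overhang <- overhang + 1L
    }
  }
  if (sum(!is.na(map)) < 20L)
    stop("unmappable: alignment covers fewer than 20 reference positions",
         call. = FALSE)
  # the aligner may absorb a divergent tail against the reference N-terminus
  # instead of leaving it upstream of canonical 1; the candidate-index
  # surplus at the last mapped position measures the same N-terminal excess
  # independently of where the gaps were placed
  p_last <- max(which(!is.na(map)))
  overhang <- max(overhang, map[p_last] - p_last, 0L)
  met_trimmed <- FALSE
  if (overhang == 1L && substr(candidate, 1, 1) == "M" &&
      !is.na(map[1]) && map[1] == 2L) {
    overhang <- 0L
    met_trimmed <- TRUE
  }
  structure(list(candidate_id = candidate_id, map = map,
                 n_terminal_overhang = overhang, met_trimmed = met_trimmed),
            class = "htr_position_map")
}

#' Identity of a candidate to the reference over a canonical span
#'
#' Fraction of canonical positions in `span` where the mapped candidate
#' residue equals the reference residue; gaps count as mismatches. Used for
#' the CenH3 divergent-core test.
#'
#' @param pmap An `htr_position_map`.
#' @param candidate,reference The mapped protein and the reference.
#' @param span Canonical positions, default 45:135 (histone-fold core).
#' @return Fraction in \[0, 1\].
#' @export
core_identity <- function(pmap, candidate, reference, span = 45:135) {
  span <- span[span <= nchar(reference)]
  refc <- strsplit(reference, "")[[1]]
  candc <- strsplit(candidate, "")[[1]]
  hits <- vapply(span, function(p) {
    i <- pmap$map[p]
    !is.na(i) && candc[i] == refc[p]
  }, TRUE)
  mean(hits)
}
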