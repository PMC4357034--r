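#' Configuration for the homology scan
#'
#' Defaults follow gapped-BLAST conventions: BLOSUM62, gap open 11 / extend 1,
#' Karlin-Altschul lambda = 0.267 and K = 0.041. The e-value threshold is the
#' survey's inclusion criterion (hits with E < threshold are HTR candidates).
#' `min_core_coverage` is the fraction of the query's histone-fold span a hit
#' must cover to escape the "incomplete" filter; `core_start` is the first
#' query position counted as histone fold (the N-terminal tail upstream of it
#' is often divergent or absent and is not required).
#'
#' @param evalue_threshold Inclusion threshold on the e-value (default 1e-10).
#' @param gap_open,gap_extend Affine gap penalties (positive integers).
#' @param karlin_lambda,karlin_k Karlin-Altschul parameters for the e-value.
#' @param min_core_coverage Fraction in (0, 1] of the query core that must be
#'   covered by the local alignment (default 0.8).
#' @param core_start First query position of the histone-fold core (default 40).
#' @return A list of class `htr_scan_config`.
#' @export
scan_config <- function(evalue_threshold = 1e-10, gap_open = 11L,
                        gap_extend = 1L, karlin_lambda = 0.267,
                        karlin_k = 0.041, min_core_coverage = 0.8,
                        core_start = 40L) {
  stopifnot(evalue_threshold > 0, gap_open >= gap_extend, gap_extend > 0,
            karlin_lambda > 0, karlin_k > 0,
            min_core_coverage > 0, min_core_coverage <= 1, core_start >= 1)
  structure(list(evalue_threshold = evalue_threshold, gap_open = gap_open,
                 gap_extend = gap_extend, karlin_lambda = karlin_lambda,
                 karlin_k = karlin_k, min_core_coverage = min_core_coverage,
                 core_start = core_start),
            class = "htr_scan_config")
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman with BLOSUM62 and affine gaps (a gap of length L costs
#' `gap_open + L * gap_extend`). The score is clamped at 0 (empty-alignment
#' convention). Alignment spans are reported 0-based half-open.
#'
#' @param query,subject Protein sequences (single strings).
#' @param config A [scan_config()].
#' @param query_id,subject_id Optional ids recorded on the hit.
#' @return A list of class `htr_hit` with `query_id`, `subject_id`,
#'   `sw_score`, `span_query`, `span_subject` (each `c(start, end)` 0-based
#'   half-open) and `evalue` (`NA` until [estimate_evalue()]).
#' @export
smith_waterman <- function(query, subject, config = scan_config(),
                           query_id = "query", subject_id = "subject") {
  query <- assert_protein(query, "query")
  subject <- assert_protein(subject, "subject")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject),
    substitutionMatrix = blosum62(),
    gapOpening = config$gap_open, gapExtension = config$gap_extend,
    type = "local", scoreOnly = FALSE)
  sc <- Biostrings::score(pa)
  if (sc <= 0) {
    hit <- list(query_id = query_id, subject_id = subject_id, sw_score = 0,
                span_query = c(0L, 0L), span_subject = c(0L, 0L),
                evalue = NA_real_)
  } else {
    p <- pa@pattern
    s <- pa@subject
    hit <- list(query_id = query_id, subject_id = subject_id, sw_score = sc,
                span_query = c(Biostrings::start(p) - 1L, Biostrings::end(p)),
                span_subject = c(Biostrings::start(s) - 1L, Biostrings::end(s)),
                evalue = NA_real_)
  }
  structure(hit, class = "htr_hit")
}

#' Karlin-Altschul e-value for a local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)` with m the query length and n the total
#' residue count of the scanned database (per-proteome). Monotone decreasing
#' in the score and linear in both lengths.
#'
#' @param hit An `htr_hit` (or a bare numeric score).
#' @param query_len Query length in residues.
#' @param db_residues Total residues in the scanned proteome.
#' @param config A [scan_config()].
#' @return The e-value (positive real).
#' @export
estimate_evalue <- function(hit, query_len, db_residues,
                            config = scan_config()) {
  score <- if (inherits(hit, "htr_hit")) hit$sw_score else hit
  stopifnot(query_len > 0, db_residues > 0)
  config$karlin_k * query_len * db_residues *
    exp(-config$karlin_lambda * score)
}

# best hit of one subject against a set of queries (named character vector);
# returns an htr_hit with evalue filled in, or NULL when no positive score
best_hit_against <- function(subject, subject_id, queries, db_residues, config) {
  subj <- Biostrings::AAString(subject)
  best <- NULL
  for (qi in seq_along(queries)) {
    h <- smith_waterman(queries[[qi]], subject, config,
                        query_id = names(queries)[qi], subject_id = subject_id)
    h$evalue <- estimate_evalue(h, nchar(queries[[qi]]), db_residues, config)
    if (is.null(best) || h$sw_score > best$sw_score) best <- h
  }
  best
}

#' Iteratively scan a proteome for HTR candidates
#'
#' Every proteome sequence is locally aligned against the query set; hits
#' with e-value below the threshold join the query set and the scan repeats
#' until no new sequence is found (the fixpoint mirrors searching "until no
#' new sequences were found"). The query set is bounded by the proteome, so
#' the loop terminates.
#'
#' @param proteome Named character vector of protein sequences (gene ids).
#' @param queries Named character vector of seed H3 query proteins; must be
#'   non-empty (typically at least one H3.1-, H3.3- and CenH3-type sequence).
#' @param gene_models Named list from [read_gff3_gene_models()] (may be
#'   `NULL`; candidates then have unknown intron counts).
#' @param cds_map Named character vector of CDS sequences keyed by gene id
#'   (may be `NULL`).
#' @param config A [scan_config()].
#' @param max_rounds Maximum search rounds (default `Inf` = iterate to the
#'   fixpoint; `1` disables the iterative expansion).
#' @return List of `htr_candidate` objects (gene_id, protein, cds,
#'   gene_model, best_hit, filter_status = "kept"), ordered by gene id.
#' @export
scan_proteome <- function(proteome, queries, gene_models = NULL,
                          cds_map = NULL, config = scan_config(),
                          max_rounds = Inf) {
  if (length(queries) == 0L) stop("empty query set", call. = FALSE)
  if (length(proteome) == 0L) return(list())
  stopifnot(!is.null(names(proteome)), !is.null(names(queries)))
  db_residues <- sum(nchar(proteome))
  active_queries <- queries
  found <- character()           # proteome ids accepted so far
  best_hits <- list()            # id -> htr_hit
  round <- 0L
  repeat {
    round <- round + 1L
    if (round > max_rounds) break
    todo <- setdiff(names(proteome), found)
    if (!length(todo)) break
    new_found <- character()
    for (sid in todo) {
      h <- best_hit_against(proteome[[sid]], sid, active_queries,
                            db_residues, config)
      if (!is.null(h) && h$evalue < config$evalue_threshold) {
        new_found <- c(new_found, sid)
        best_hits[[sid]] <- h
      }
    }
    if (!length(new_found)) break
    found <- c(found, new_found)
    active_queries <- c(active_queries, proteome[new_found])
  }
  found <- sort(found)
  lapply(found, function(id) {
    structure(list(
      gene_id = id,
      protein = proteome[[id]],
      cds = if (!is.null(cds_map) && id %in% names(cds_map)) cds_map[[id]] else NULL,
      gene_model = if (!is.null(gene_models)) gene_models[[id]] else NULL,
      best_hit = best_hits[[id]],
      filter_status = "kept"), class = "htr_candidate")
  })
}

#' Apply redundancy, isoform and incompleteness filters
#'
#' Reproduces the survey's cleanup: (a) byte-identical CDS nucleotide
#' sequences collapse to one candidate (lexicographically smallest gene id
#' kept, the rest marked `redundant`); (b) multiple candidates on the same
#' gene locus collapse to the locus representative (the rest marked
#' `isoform`); (c) candidates whose best local alignment covers less than
#' `min_core_coverage` of the query's histone-fold core are marked
#' `incomplete`. The function is idempotent on its kept output.
#'
#' @param candidates List of `htr_candidate` from [scan_proteome()].
#' @param config A [scan_config()].
#' @param query_lengths Named lengths of the scan queries (needed to locate
#'   each query's core span); when `NULL` the core is taken from the hit's
#'   own query span heuristically.
#' @return List with elements `kept` (surviving candidates) and `all`
#'   (every candidate with its final `filter_status`).
#' @export
filter_candidates <- function(candidates, config = scan_config(),
                              query_lengths = NULL) {
  if (!length(candidates)) return(list(kept = list(), all = list()))
  status <- setNames(rep("kept", length(candidates)),
                     vapply(candidates, `[[`, "", "gene_id"))

  # (a) redundant CDS
  cds <- vapply(candidates, function(x) if (is.null(x$cds)) NA_character_ else x$cds, "")
  ids <- names(status)
  for (grp in split(ids[!is.na(cds)], cds[!is.na(cds)])) {
    if (length(grp) > 1L) status[setdiff(grp, min(grp))] <- "redundant"
  }

  # (b) isoforms of the same locus: keep longest protein, tie -> smallest id
  locus <- vapply(candidates, function(x)
    if (!is.null(x$gene_model)) x$gene_model$gene_id else x$gene_id, "")
  plen <- vapply(candidates, function(x) nchar(x$protein), 0L)
  for (grp_idx in split(seq_along(candidates), locus)) {
    live <- grp_idx[status[ids[grp_idx]] == "kept"]
    if (length(live) > 1L) {
      best <- live[order(-plen[live], ids[live])][1L]
      status[ids[setdiff(live, best)]] <- "isoform"
    }
  }

  # (c) incomplete: query-core coverage of the best hit
  for (i in seq_along(candidates)) {
    if (status[ids[i]] != "kept") next
    h <- candidates[[i]]$best_hit
    if (is.null(h)) next
    qlen <- if (!is.null(query_lengths) && h$query_id %in% names(query_lengths))
      query_lengths[[h$query_id]] else h$span_query[2]
    core <- c(config$core_start - 1L, qlen)  # 0-based half-open core span
    if (core[2] <= core[1]) next
    ov <- max(0, min(h$span_query[2], core[2]) - max(h$span_query[1], core[1]))
    if (ov / (core[2] - core[1]) < config$min_core_coverage)
      status[ids[i]] <- "incomplete"
  }

  all <- lapply(seq_along(candidates), function(i) {
    x <- candidates[[i]]
    x$filter_status <- status[[ids[i]]]
    x
  })
  list(kept = all[vapply(all, `[[`, "", "filter_status") == "kept"], all = all)
}
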