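# Variant classification: signature residues at canonical 31/41/87/90,
# intron evidence, CenH3 clade/tail evidence, conserved-lysine audit.

SIG_H3_1 <- c("A", "F", "S", "A")
SIG_H3_3 <- c("T", "Y", "H", "L")
SIG_H3_1A_S <- c("A", "Y", "S", "L")
SIG_H3_1A_Q <- c("A", "Y", "Q", "L")

# animal rule set (optional): H3.1 vs H3.3 discriminated at 31/87/89/90
SIG_ANIMAL_H3_1 <- c("A", "S", "V", "M")
SIG_ANIMAL_H3_3 <- c("S", "A", "I", "G")

#' Parameters for CenH3 evidence detection
#'
#' The survey literature gives no quantitative CenH3 cutoffs; these defaults
#' (tail of >= 15 extra N-terminal residues together with < 75% identity over
#' the histone-fold core, clade support >= 70) are package choices and fully
#' configurable.
#'
#' @param min_support Minimum bootstrap support of the anchored clade.
#' @param min_overhang Minimum N-terminal overhang (residues).
#' @param max_core_identity Core identity (canonical 45-135) below which the
#'   tail evidence fires.
#' @return List of class `htr_cenh3_params`.
#' @export
cenh3_params <- function(min_support = 70, min_overhang = 15L,
                         max_core_identity = 0.75) {
  structure(list(min_support = min_support, min_overhang = min_overhang,
                 max_core_identity = max_core_identity),
            class = "htr_cenh3_params")
}

#' Extract the signature profile of a mapped candidate
#'
#' Reads the residues at canonical 31/41/87/90 and the lysine sites
#' 4/9/27/36 through the position map; unmapped positions are recorded as
#' `"-"`. `tail_deleted` is set when 10 or more canonical N-tail positions
#' (1-44) map to gaps — the "absent or degenerate N-terminal part" seen in
#' H3-like proteins.
#'
#' @param pmap `htr_position_map` for this protein.
#' @param protein The candidate protein sequence the map was built from.
#' @return List of class `htr_signature` with `s31`, `s41`, `s87`, `s90`,
#'   `k4`, `k9`, `k27`, `k36`, `n_terminal_overhang`, `tail_deleted`.
#' @export
extract_signature <- function(pmap, protein) {
  chars <- strsplit(protein, "")[[1]]
  at <- function(p) {
    if (p > length(pmap$map)) return("-")
    i <- pmap$map[p]
    if (is.na(i)) "-" else chars[i]
  }
  tail_span <- seq_len(min(44L, length(pmap$map)))
  structure(list(
    s31 = at(31L), s41 = at(41L), s87 = at(87L), s90 = at(90L),
    k4 = at(4L), k9 = at(9L), k27 = at(27L), k36 = at(36L),
    n_terminal_overhang = pmap$n_terminal_overhang,
    tail_deleted = sum(is.na(pmap$map[tail_span])) >= 10L),
    class = "htr_signature")
}

#' Classify one candidate into an H3 variant class
#'
#' Decision order (total and deterministic):
#' 1. any CenH3 evidence flag -> `CENH3` (clade/tail evidence outranks
#'    signatures, which CenH3 proteins can spuriously match through gaps);
#' 2. signature A31 F41 S87 A90 and 0 introns -> `H3_1`;
#' 3. signature T31 Y41 H87 L90 and >= 1 intron -> `H3_3`;
#' 4. signature A31 Y41 (S|Q)87 L90 and 0 introns -> `H3_1A`;
#' 5. anything else -> `H3_LIKE`.
#' A recognized signature whose intron state contradicts its class yields
#' `H3_LIKE` with the `signature_intron_conflict` flag. With unknown intron
#' state rules 2-4 run on the signature alone (`signature_only`, confidence
#' `medium`). Non-lysine residues at 4/9/27/36 are flagged, e.g. `K27M`.
#'
#' @param sig `htr_signature` from [extract_signature()].
#' @param intron_count Integer intron count or `NA` when unknown.
#' @param cenh3_evidence Character vector of flags from [detect_cenh3()].
#' @param gene_id Id recorded on the call.
#' @param ruleset `"plant"` (default) or `"animal"` (signatures at
#'   31/87/89/90; requires `sig` extracted at those positions).
#' @return List of class `htr_variant_call`.
#' @export
classify_variant <- function(sig, intron_count = NA_integer_,
                             cenh3_evidence = character(),
                             gene_id = "gene", ruleset = c("plant", "animal")) {
  ruleset <- match.arg(ruleset)
  flags <- character()
  for (p in c(4, 9, 27, 36)) {
    r <- sig[[paste0("k", p)]]
    if (r != "K" && r != "-") flags <- c(flags, sprintf("K%d%s", p, r))
  }
  if (length(cenh3_evidence)) {
    return(new_call(gene_id, "CENH3", sig, intron_count,
                    c(cenh3_evidence, flags), "high"))
  }
  tuple <- c(sig$s31, sig$s41, sig$s87, sig$s90)
  sig_class <- if (ruleset == "plant") {
    if (identical(tuple, SIG_H3_1)) "H3_1"
    else if (identical(tuple, SIG_H3_3)) "H3_3"
    else if (identical(tuple, SIG_H3_1A_S) ||
             identical(tuple, SIG_H3_1A_Q)) "H3_1A"
    else NA_character_
  } else {
    if (identical(tuple, SIG_ANIMAL_H3_1)) "H3_1"
    else if (identical(tuple, SIG_ANIMAL_H3_3)) "H3_3"
    else NA_character_
  }
  if (is.na(sig_class))
    return(new_call(gene_id, "H3_LIKE", sig, intron_count, flags, "low"))
  if (is.na(intron_count)) {
    return(new_call(gene_id, sig_class, sig, intron_count,
                    c("signature_match", "signature_only", flags), "medium"))
  }
  intron_ok <- switch(sig_class,
                      H3_1 = intron_count == 0L,
                      H3_1A = intron_count == 0L,
                      H3_3 = intron_count >= 1L)
  if (intron_ok)
    new_call(gene_id, sig_class, sig, intron_count,
             c("signature_match", "intron_match", flags), "high")
  else
    new_call(gene_id, "H3_LIKE", sig, intron_count,
             c("signature_intron_conflict", flags), "low")
}

new_call <- function(gene_id, class, sig, intron_count, evidence, confidence) {
  structure(list(gene_id = gene_id, variant_class = class, signature = sig,
                 intron_count = as.integer(intron_count),
                 evidence = unique(evidence), confidence = confidence),
            class = "htr_variant_call")
}

#' Collect CenH3 evidence for a candidate
#'
#' Two independent lines of evidence: `cenh3_clade` when the candidate sits
#' inside the smallest well-supported bipartition containing all CenH3
#' anchors (and that clade excludes every listed known H3.1/H3.3 gene);
#' `cenh3_tail` when the candidate carries a long extra N-terminal tail
#' (`n_terminal_overhang >= min_overhang`) over a divergent histone-fold
#' core (identity to the reference below `max_core_identity` over canonical
#' 45-135). With no tree and no anchors the tail heuristic alone is used and
#' a warning is logged.
#'
#' @param candidate Protein sequence.
#' @param pmap Its `htr_position_map`.
#' @param reference Canonical reference protein.
#' @param tree Optional `phylo` with bootstrap supports.
#' @param anchors Character vector of known CenH3 leaf ids in the tree.
#' @param known_h3 Character vector of known H3.1/H3.3 leaf ids that a CenH3
#'   clade must exclude.
#' @param params [cenh3_params()].
#' @param candidate_id Leaf id of the candidate in the tree.
#' @return Character vector, subset of `c("cenh3_clade", "cenh3_tail")`.
#' @export
detect_cenh3 <- function(candidate, pmap, reference, tree = NULL,
                         anchors = character(), known_h3 = character(),
                         params = cenh3_params(),
                         candidate_id = pmap$candidate_id) {
  flags <- character()
  if (pmap$n_terminal_overhang >= params$min_overhang &&
      core_identity(pmap, candidate, reference) < params$max_core_identity)
    flags <- c(flags, "cenh3_tail")
  if (!is.null(tree) && length(anchors)) {
    clade <- find_anchored_clade(tree, anchors, params$min_support)
    if (length(clade) && candidate_id %in% clade &&
        !any(known_h3 %in% clade))
      flags <- c(flags, "cenh3_clade")
  } else if (is.null(tree) && !length(anchors)) {
    warning("no tree and no anchors: CenH3 detection is tail-heuristic only",
            call. = FALSE)
  }
  flags
}

#' Audit the conserved lysines across classified calls
#'
#' Per variant class: the fraction of genes retaining K at canonical 4, 9,
#' 27 and 36, plus the list of observed substitutions (e.g. `geneX:K27M`).
#'
#' @param calls List of `htr_variant_call` (or flat call table).
#' @return data.frame with one row per class (empty for empty input).
#' @export
audit_lysines <- function(calls) {
  empty <- data.frame(class = character(), n = integer(),
                      frac_k4 = numeric(), frac_k9 = numeric(),
                      frac_k27 = numeric(), frac_k36 = numeric(),
                      substitutions = character(), stringsAsFactors = FALSE)
  if (!length(calls)) return(empty)
  df <- as_call_table(calls)
  out <- lapply(split(df, df$class), function(g) {
    subs <- character()
    for (p in c(4, 9, 27, 36)) {
      st <- g[[paste0("k", p, "_state")]]
      bad <- st != "K" & st != "-"
      if (any(bad))
        subs <- c(subs, sprintf("%s:K%d%s", g$gene_id[bad], p, st[bad]))
    }
    data.frame(class = g$class[1], n = nrow(g),
               frac_k4 = mean(g$k4_state == "K"),
               frac_k9 = mean(g$k9_state == "K"),
               frac_k27 = mean(g$k27_state == "K"),
               frac_k36 = mean(g$k36_state == "K"),
               substitutions = paste(sort(subs), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$class), , drop = FALSE]
}
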