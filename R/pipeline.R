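# End-to-end orchestration: scan -> filter -> map -> classify -> phylo ->
# selection -> expression, reproducible per (config, seed).

#' Pipeline configuration
#'
#' @param proteome,cds,gff,queries,reference Input file paths (`gff`,
#'   `expression` optional). `queries` is a FASTA of seed H3 proteins whose
#'   ids mark their type: ids containing `cenh3` (case-insensitive) are CenH3
#'   anchors, the rest known H3.1/H3.3.
#' @param expression Optional expression TSV (genes x tissues).
#' @param tissue_groups Named character vector tissue -> group (required when
#'   `expression` is given).
#' @param outdir Output directory.
#' @param seed Integer seed driving all randomness (bootstrap).
#' @param scan A [scan_config()].
#' @param cenh3 A [cenh3_params()].
#' @param n_bootstrap Bootstrap replicates for the candidate tree.
#' @param alpha Per-site selection significance level.
#' @return List of class `htr_run_config`.
#' @export
run_config <- function(proteome, cds = NULL, gff = NULL, queries,
                       reference = NULL, expression = NULL,
                       tissue_groups = NULL, outdir = tempfile("htrscan_run_"),
                       seed = 1L, scan = scan_config(),
                       cenh3 = cenh3_params(), n_bootstrap = 100L,
                       alpha = 0.05) {
  structure(list(proteome = proteome, cds = cds, gff = gff,
                 queries = queries, reference = reference,
                 expression = expression, tissue_groups = tissue_groups,
                 outdir = outdir, seed = seed, scan = scan, cenh3 = cenh3,
                 n_bootstrap = n_bootstrap, alpha = alpha),
            class = "htr_run_config")
}

#' Path of the bundled synthetic canonical reference
#' @return File path of the packaged reference FASTA (a synthetic stand-in
#'   for the canonical mature H3, see [make_reference()]).
#' @export
default_reference_path <- function()
  system.file("extdata", "synthetic_h3_reference.faa", package = "htrscan",
              mustWork = TRUE)

#' Classify a set of kept candidates
#'
#' Maps each candidate onto the reference, extracts signatures, builds a
#' bootstrap NJ tree over candidates plus queries for anchored CenH3
#' detection, and applies the decision rules. Candidates whose alignment to
#' the reference is unmappable are called `H3_LIKE` with an `unmappable`
#' flag.
#'
#' @param candidates List of kept `htr_candidate`.
#' @param reference Canonical reference protein sequence.
#' @param queries Named character vector of seed query proteins.
#' @param anchors Ids within `queries` that are CenH3 anchors.
#' @param cenh3 [cenh3_params()].
#' @param seed Seed for the bootstrap.
#' @param n_bootstrap Bootstrap replicates (0 disables the tree).
#' @return List of `htr_variant_call`, plus attributes `tree` and `pmaps`.
#' @export
classify_candidates <- function(candidates, reference, queries = character(),
                                anchors = character(),
                                cenh3 = cenh3_params(), seed = 1L,
                                n_bootstrap = 100L) {
  if (!length(candidates)) return(list())
  prots <- setNames(vapply(candidates, `[[`, "", "protein"),
                    vapply(candidates, `[[`, "", "gene_id"))
  tree <- NULL
  if (n_bootstrap > 0L && length(prots) + length(queries) >= 4L) {
    aln <- progressive_msa(c(prots, queries))
    tree <- tryCatch(bootstrap_support(aln, n_bootstrap, seed = seed),
                     error = function(e) NULL)
  }
  known_h3 <- setdiff(names(queries), anchors)
  pmaps <- list()
  calls <- lapply(candidates, function(cand) {
    pmap <- tryCatch(map_to_reference(cand$protein, reference, cand$gene_id),
                     error = function(e) NULL)
    if (is.null(pmap)) {
      sig <- structure(list(s31 = "-", s41 = "-", s87 = "-", s90 = "-",
                            k4 = "-", k9 = "-", k27 = "-", k36 = "-",
                            n_terminal_overhang = 0L, tail_deleted = TRUE),
                       class = "htr_signature")
      return(new_call(cand$gene_id, "H3_LIKE", sig,
                      NA_integer_, "unmappable", "low"))
    }
    pmaps[[cand$gene_id]] <<- pmap
    sig <- extract_signature(pmap, cand$protein)
    intron <- if (!is.null(cand$gene_model) && cand$gene_model$intron_known)
      cand$gene_model$intron_count else NA_integer_
    ev <- suppressWarnings(
      detect_cenh3(cand$protein, pmap, reference, tree = tree,
                   anchors = anchors, known_h3 = known_h3, params = cenh3,
                   candidate_id = cand$gene_id))
    classify_variant(sig, intron, ev, gene_id = cand$gene_id)
  })
  attr(calls, "tree") <- tree
  attr(calls, "pmaps") <- pmaps
  calls
}

#' Per-species, per-class count table
#'
#' @param calls Variant calls (list or flat table).
#' @param species Optional named character vector gene_id -> species
#'   (default: one synthetic species).
#' @return data.frame species x class counts with a `total` column and a
#'   final `total` row; empty input gives an empty table with a header.
#' @export
summarize_counts <- function(calls, species = NULL) {
  classes <- c("CENH3", "H3_1", "H3_1A", "H3_3", "H3_LIKE")
  if (!length(calls) || (is.data.frame(calls) && nrow(calls) == 0L)) {
    out <- data.frame(species = character(), stringsAsFactors = FALSE)
    for (cl in classes) out[[cl]] <- integer()
    out$total <- integer()
    return(out)
  }
  df <- as_call_table(calls)
  sp <- if (is.null(species)) rep("synthetic", nrow(df))
    else unname(species[df$gene_id])
  tab <- table(factor(sp), factor(df$class, levels = classes))
  out <- data.frame(species = rownames(tab), stringsAsFactors = FALSE)
  for (cl in classes) out[[cl]] <- as.integer(tab[, cl])
  out$total <- as.integer(rowSums(tab))
  out <- out[order(out$species), , drop = FALSE]
  total_row <- data.frame(species = "total", stringsAsFactors = FALSE)
  for (cl in classes) total_row[[cl]] <- sum(out[[cl]])
  total_row$total <- sum(out$total)
  rbind(out, total_row)
}

#' Run the full HTR survey pipeline
#'
#' Reads the inputs, scans the proteome, filters candidates, classifies every
#' kept candidate, tabulates per-class counts, runs group dN/dS per class
#' (classes with at least two members with CDS), and clusters expression
#' profiles when a matrix is supplied. All outputs are written under
#' `config$outdir`; identical config + seed gives identical outputs. On a
#' stage error the run aborts naming the stage and removes partial outputs.
#'
#' @param config A [run_config()].
#' @return Invisible list: `calls`, `counts`, `candidates`, `selection`,
#'   `expression`, `tree`, `outdir`.
#' @export
run_full_pipeline <- function(config) {
  outdir <- config$outdir
  created <- !dir.exists(outdir)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- "setup"
  log_con <- file(file.path(outdir, "run.log"), open = "wb")
  logmsg <- function(...) {
    writeLines(paste0("[", stage, "] ", ...), log_con, sep = "\n")
    message("[", stage, "] ", ...)
  }
  ok <- FALSE
  on.exit({
    close(log_con)
    if (!ok) {
      unlink(list.files(outdir, full.names = TRUE))
      if (created) unlink(outdir, recursive = TRUE)
    }
  })
  res <- tryCatch({
    stage <- "read"
    proteome <- read_fasta(config$proteome, "protein")
    cds <- if (!is.null(config$cds)) read_fasta(config$cds, "dna") else NULL
    models <- if (!is.null(config$gff)) read_gff3_gene_models(config$gff)
      else NULL
    queries <- read_fasta(config$queries, "protein")
    ref_path <- if (is.null(config$reference)) default_reference_path()
      else config$reference
    reference <- read_fasta(ref_path, "protein")[[1]]
    logmsg(length(proteome), " proteins, ", length(queries), " queries")

    stage <- "scan"
    cands <- scan_proteome(proteome, queries, models, cds, config$scan)
    logmsg(length(cands), " candidates pass e-value < ",
           config$scan$evalue_threshold)

    stage <- "filter"
    filt <- filter_candidates(cands, config$scan,
                              query_lengths = nchar(queries))
    logmsg(length(filt$kept), " kept of ", length(cands))

    stage <- "classify"
    anchors <- names(queries)[grepl("cenh3", names(queries),
                                    ignore.case = TRUE)]
    calls <- classify_candidates(filt$kept, reference, queries, anchors,
                                 cenh3 = config$cenh3, seed = config$seed,
                                 n_bootstrap = config$n_bootstrap)
    counts <- summarize_counts(calls)
    if (length(calls)) {
      write_variant_report(calls, file.path(outdir, "report.tsv"))
      write.table(audit_lysines(calls), file.path(outdir, "lysine_audit.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write.table(counts, file.path(outdir, "class_counts.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    logmsg("classes: ", paste(counts[nrow(counts), -1], collapse = "/"))

    stage <- "selection"
    selection <- list()
    if (!is.null(cds) && length(calls)) {
      df <- as_call_table(calls)
      for (cl in unique(df$class)) {
        ids <- df$gene_id[df$class == cl]
        ids <- ids[ids %in% names(cds)]
        if (length(ids) < 2L) next
        prots <- setNames(vapply(filt$kept, `[[`, "", "protein"),
                          vapply(filt$kept, `[[`, "", "gene_id"))[ids]
        aln <- progressive_msa(prots)
        ca <- backtranslate(aln, cds)
        selection[[cl]] <- tryCatch(group_dnds(ca, label = cl),
                                    error = function(e) {
                                      logmsg("dN/dS for ", cl, " failed: ",
                                             conditionMessage(e))
                                      NULL
                                    })
      }
      sel_rows <- do.call(rbind, lapply(selection, function(s)
        data.frame(group = s$group, dN = s$dN, dS = s$dS, ratio = s$ratio,
                   n_pairs = s$n_pairs, n_saturated = s$n_saturated)))
      if (!is.null(sel_rows))
        write.table(sel_rows, file.path(outdir, "selection.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
    }

    stage <- "expression"
    expr <- NULL
    if (!is.null(config$expression)) {
      m <- read_expression_tsv(config$expression)
      pm <- preprocess_expression(m)
      cl <- hierarchical_cluster(pm)
      write_clustered_matrix(cl, pm, file.path(outdir, "clustered.tsv"))
      arch <- if (!is.null(config$tissue_groups))
        vapply(rownames(pm), function(g)
          call_profile_archetype(m[g, ], config$tissue_groups), "")
        else NULL
      expr <- list(matrix = pm, cluster = cl, archetypes = arch,
                   not_detected = attr(pm, "not_detected"))
    }

    list(calls = calls, counts = counts, candidates = filt,
         selection = selection, expression = expr,
         tree = attr(calls, "tree"), outdir = outdir)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  ok <- TRUE
  invisible(res)
}
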