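#' Read a FASTA file into a named character vector
#'
#' One element per record, named by the first whitespace-delimited token of
#' the header. Sequences are uppercased. Duplicate IDs and empty files are
#' errors, so downstream gene-id keyed joins are safe.
#'
#' @param path Path to a FASTA file.
#' @param moltype `"protein"`, `"dna"` or `"auto"` (guess from residues).
#' @return Named character vector of sequences with attribute `moltype`.
#' @export
read_fasta <- function(path, moltype = c("auto", "protein", "dna")) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate FASTA ID(s): ", paste(dup, collapse = ", "), call. = FALSE)
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  if (any(!nzchar(seqs))) stop("empty sequence record in ", path, call. = FALSE)
  if (moltype == "auto") {
    letters <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
    moltype <- if (all(letters %in% c("A", "C", "G", "T", "U", "N"))) "dna" else "protein"
  }
  attr(seqs, "moltype") <- moltype
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path; UTF-8, LF line endings, 60-column wrap.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(length(seqs) > 0, !is.null(names(seqs)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    chunks <- substring(seqs[[i]],
                        seq(1L, nchar(seqs[[i]]), 60L),
                        pmin(seq(1L, nchar(seqs[[i]]), 60L) + 59L, nchar(seqs[[i]])))
    writeLines(c(paste0(">", names(seqs)[i]), chunks), con, sep = "\n")
  }
  invisible(path)
}

# parse the attribute column of one GFF3 line into a named character vector
parse_gff3_attrs <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- vapply(kv, function(x) if (length(x) >= 2) x[[2]] else "", "")
  names(vals) <- vapply(kv, `[[`, "", 1L)
  vals
}

#' Read gene models from GFF3
#'
#' Parses gene/mRNA/CDS features and derives, for every gene, the
#' representative transcript (longest total CDS; ties broken by
#' lexicographically smallest transcript id) and its intron count within the
#' CDS (number of CDS segments minus one). Genes with no CDS feature get
#' `intron_known = FALSE`: some annotations ship without gene structure, and
#' classification then falls back to signature-only rules.
#'
#' Coordinates are 1-based inclusive on disk (GFF3 convention) and stored
#' 0-based half-open on the returned objects; this function is the only
#' conversion point.
#'
#' @param path Path to a GFF3 file.
#' @return Named list of gene models; each is a list with `gene_id`,
#'   `transcript_id` (representative), `transcript_ids`, `strand`,
#'   `cds` (matrix with columns `start`, `end`, 0-based half-open, ordered
#'   5'->3'), `intron_count` and `intron_known`.
#' @export
read_gff3_gene_models <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  genes <- list()        # gene_id -> strand
  mrna_parent <- list()  # mRNA id -> gene id
  cds_by_tx <- list()    # tx id -> list of c(start, end) 1-based
  strand_by_tx <- list()

  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (!nzchar(line) || startsWith(line, "#")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L)
      stop("malformed GFF3 line ", ln, ": expected 9 tab-separated fields, got ",
           length(f), call. = FALSE)
    type <- f[[3]]
    if (!type %in% c("gene", "mRNA", "CDS")) next
    start <- suppressWarnings(as.integer(f[[4]]))
    end <- suppressWarnings(as.integer(f[[5]]))
    if (is.na(start) || is.na(end) || start < 1L || end < start)
      stop("malformed GFF3 line ", ln, ": bad coordinates '", f[[4]], "..",
           f[[5]], "'", call. = FALSE)
    at <- parse_gff3_attrs(f[[9]])
    if (type == "gene") {
      id <- at[["ID"]]
      if (is.null(id) || is.na(id)) stop("malformed GFF3 line ", ln,
                                         ": gene without ID", call. = FALSE)
      genes[[id]] <- f[[7]]
    } else if (type == "mRNA") {
      id <- at[["ID"]]
      par <- at[["Parent"]]
      if (is.null(id) || is.na(id)) stop("malformed GFF3 line ", ln,
                                         ": mRNA without ID", call. = FALSE)
      mrna_parent[[id]] <- if (!is.null(par) && !is.na(par)) par else NA_character_
      strand_by_tx[[id]] <- f[[7]]
    } else { # CDS
      par <- at[["Parent"]]
      par <- if (!is.null(par) && !is.na(par)) strsplit(par, ",", fixed = TRUE)[[1]] else character()
      par <- par[par %in% names(mrna_parent)]
      if (!length(par)) {
        warning("GFF3 line ", ln, ": CDS without known mRNA parent, skipped",
                call. = FALSE)
        next
      }
      for (p in par)
        cds_by_tx[[p]] <- c(cds_by_tx[[p]], list(c(start, end)))
    }
  }

  models <- list()
  for (gid in names(genes)) {
    txs <- names(mrna_parent)[vapply(mrna_parent, identical, TRUE, gid)]
    tx_len <- vapply(txs, function(tx) {
      segs <- cds_by_tx[[tx]]
      if (is.null(segs)) 0L else sum(vapply(segs, function(s) s[2] - s[1] + 1L, 0L))
    }, 0L)
    with_cds <- txs[tx_len > 0L]
    if (length(with_cds)) {
      best_len <- max(tx_len[with_cds])
      rep_tx <- sort(with_cds[tx_len[with_cds] == best_len])[1L]
      segs <- do.call(rbind, cds_by_tx[[rep_tx]])
      segs <- segs[order(segs[, 1]), , drop = FALSE]
      if (nrow(segs) > 1 && any(segs[-1, 1] <= segs[-nrow(segs), 2]))
        stop("overlapping CDS segments in transcript ", rep_tx, call. = FALSE)
      strand <- genes[[gid]]
      # 1-based inclusive -> 0-based half-open; order 5'->3'
      segs0 <- cbind(start = segs[, 1] - 1L, end = segs[, 2])
      if (strand == "-") segs0 <- segs0[rev(seq_len(nrow(segs0))), , drop = FALSE]
      models[[gid]] <- list(gene_id = gid, transcript_id = rep_tx,
                            transcript_ids = sort(txs), strand = strand,
                            cds = segs0,
                            intron_count = nrow(segs0) - 1L,
                            intron_known = TRUE)
    } else {
      models[[gid]] <- list(gene_id = gid, transcript_id = NA_character_,
                            transcript_ids = sort(txs), strand = genes[[gid]],
                            cds = NULL, intron_count = NA_integer_,
                            intron_known = FALSE)
    }
  }
  models
}

#' Write gene models as GFF3
#'
#' Inverse of [read_gff3_gene_models()] for the representative transcript
#' (0-based half-open back to 1-based inclusive).
#'
#' @param models Named list of gene models.
#' @param path Output path.
#' @param seqid Chromosome/contig name used in column 1.
#' @export
write_gff3 <- function(models, path, seqid = "chr1") {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("##gff-version 3", con, sep = "\n")
  for (m in models) {
    if (is.null(m$cds)) {
      writeLines(paste(seqid, "htrscan", "gene", 1, 1, ".", m$strand, ".",
                       paste0("ID=", m$gene_id), sep = "\t"), con, sep = "\n")
      next
    }
    segs <- m$cds
    if (m$strand == "-") segs <- segs[rev(seq_len(nrow(segs))), , drop = FALSE]
    g1 <- min(segs[, "start"]) + 1L
    g2 <- max(segs[, "end"])
    tx <- if (is.na(m$transcript_id)) paste0(m$gene_id, ".t1") else m$transcript_id
    writeLines(paste(seqid, "htrscan", "gene", g1, g2, ".", m$strand, ".",
                     paste0("ID=", m$gene_id), sep = "\t"), con, sep = "\n")
    writeLines(paste(seqid, "htrscan", "mRNA", g1, g2, ".", m$strand, ".",
                     paste0("ID=", tx, ";Parent=", m$gene_id), sep = "\t"),
               con, sep = "\n")
    for (i in seq_len(nrow(segs)))
      writeLines(paste(seqid, "htrscan", "CDS", segs[i, "start"] + 1L,
                       segs[i, "end"], ".", m$strand, "0",
                       paste0("ID=", tx, ".cds", i, ";Parent=", tx), sep = "\t"),
                 con, sep = "\n")
  }
  invisible(path)
}

#' Write the variant-call report as TSV
#'
#' One row per gene, ordered lexicographically by gene id so identical inputs
#' give byte-identical files. Columns: gene_id, class, signature (residues at
#' canonical 31/41/87/90), intron_count (`NA` when unknown), evidence flags,
#' lysine states at K4/K9/K27/K36, conflicts and confidence.
#'
#' @param calls A variant-call data frame as returned by [classify_candidates()]
#'   or a list of single calls from [classify_variant()].
#' @param path Output path.
#' @export
write_variant_report <- function(calls, path) {
  df <- as_call_table(calls)
  if (nrow(df) == 0L) stop("no variant calls to write", call. = FALSE)
  df <- df[order(df$gene_id), , drop = FALSE]
  con <- try(file(path, open = "wb"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write to ", path, call. = FALSE)
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = "\t"), con, sep = "\n")
  for (i in seq_len(nrow(df)))
    writeLines(paste(vapply(df[i, ], as.character, ""), collapse = "\t"),
               con, sep = "\n")
  invisible(path)
}

#' Flatten variant calls into a data frame
#'
#' @param calls List of `htr_variant_call` objects or an already-flat data
#'   frame (returned unchanged).
#' @return data.frame with one row per call.
#' @export
as_call_table <- function(calls) {
  if (is.data.frame(calls)) return(calls)
  rows <- lapply(calls, function(x) {
    sig <- x$signature
    data.frame(
      gene_id = x$gene_id,
      class = x$variant_class,
      signature = paste0(sig$s31, sig$s41, sig$s87, sig$s90),
      intron_count = if (is.na(x$intron_count)) NA_integer_ else x$intron_count,
      evidence = paste(sort(x$evidence), collapse = ";"),
      k4_state = sig$k4, k9_state = sig$k9, k27_state = sig$k27,
      k36_state = sig$k36,
      conflicts = if ("signature_intron_conflict" %in% x$evidence)
        "signature_intron_conflict" else "",
      confidence = x$confidence,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
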