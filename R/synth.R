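# Synthetic-data generators: labelled genomes (proteome + CDS + GFF3 + truth
# labels), codon sequences evolved at a known dN/dS, and expression matrices
# with planted archetypes. Every generator is deterministic per seed.

PROTECTED_POSITIONS <- c(4L, 9L, 27L, 31L, 36L, 41L, 87L, 90L)

#' Synthetic canonical H3 reference protein
#'
#' A random protein in mature-H3 numbering with K fixed at 4/9/27/36 and the
#' H3.3 signature (T, Y, H, L) at 31/41/87/90, so no biological sequence is
#' hard-coded as ground truth while the coordinate frame behaves like the
#' canonical reference.
#'
#' @param seed RNG seed.
#' @param length Protein length (>= 100, default 135).
#' @return Single protein string.
#' @export
make_reference <- function(seed, length = 135L) {
  if (length < 100L) stop("reference length must be >= 100", call. = FALSE)
  with_seed(seed, {
    aa <- sample(AA20, length, replace = TRUE)
    aa[c(4, 9, 27, 36)] <- "K"
    aa[c(31, 41, 87, 90)] <- SIG_H3_3
    paste(aa, collapse = "")
  })
}

#' Specification for a synthetic genome
#'
#' Defaults encode the study conditions used throughout the test suite:
#' 4 genes per variant class plus 20 non-histone decoys, 2% background
#' mutation rate outside the protected positions (4/9/27/31/36/41/87/90),
#' CenH3 with a 25-residue extra N-tail over a 40%-diverged core.
#'
#' @param seed RNG seed.
#' @param n_h3_1,n_h3_3,n_h3_1a,n_cenh3,n_h3_like,n_decoys Class counts.
#' @param mutation_rate Per-residue substitution probability outside
#'   protected positions.
#' @param cenh3_tail_length Extra N-terminal residues on CenH3 (> 0).
#' @param cenh3_core_divergence Per-residue substitution probability in the
#'   CenH3 core.
#' @param ref_length Reference protein length.
#' @return List of class `htr_synthesis_spec`.
#' @export
synthesis_spec <- function(seed = 42L, n_h3_1 = 4L, n_h3_3 = 4L,
                           n_h3_1a = 4L, n_cenh3 = 4L, n_h3_like = 4L,
                           n_decoys = 20L, mutation_rate = 0.02,
                           cenh3_tail_length = 25L,
                           cenh3_core_divergence = 0.4, ref_length = 135L) {
  stopifnot(n_h3_1 >= 0, n_h3_3 >= 0, n_h3_1a >= 0, n_cenh3 >= 0,
            n_h3_like >= 0, n_decoys >= 0, mutation_rate >= 0,
            mutation_rate <= 1)
  if (n_cenh3 > 0 && cenh3_tail_length < 1L)
    stop("inconsistent spec: CenH3 requested with tail length 0", call. = FALSE)
  structure(list(seed = seed, n_h3_1 = n_h3_1, n_h3_3 = n_h3_3,
                 n_h3_1a = n_h3_1a, n_cenh3 = n_cenh3,
                 n_h3_like = n_h3_like, n_decoys = n_decoys,
                 mutation_rate = mutation_rate,
                 cenh3_tail_length = cenh3_tail_length,
                 cenh3_core_divergence = cenh3_core_divergence,
                 ref_length = ref_length),
            class = "htr_synthesis_spec")
}

mutate_protein <- function(aa, rate, protected = PROTECTED_POSITIONS) {
  hit <- runif(length(aa)) < rate
  hit[protected[protected <= length(aa)]] <- FALSE
  for (i in which(hit)) aa[i] <- sample(setdiff(AA20, aa[i]), 1)
  aa
}

# uniformly random synonymous back-translation, terminal stop appended;
# when a template codon vector is given (shared within-genome CDS ancestry,
# the way real paralogs descend from one coding sequence), template codons
# are kept at unchanged amino acids except for a synonymous churn rate --
# fully independent codon draws would make every paralog pair NG86-saturated
random_cds <- function(protein, template = NULL, syn_churn = 0.1) {
  gc <- genetic_code()
  by_aa <- split(names(gc), gc)
  aa <- strsplit(protein, "")[[1]]
  draw <- function(a) { opts <- by_aa[[a]]; opts[sample.int(length(opts), 1)] }
  codons <- vapply(seq_along(aa), function(i) {
    if (!is.null(template) && i <= length(template) &&
        gc[[template[i]]] == aa[i] && runif(1) >= syn_churn)
      template[i]
    else draw(aa[i])
  }, "")
  paste(c(codons, by_aa[["*"]][sample.int(3, 1)]), collapse = "")
}

# gene model with the requested intron count; cds_len in nt, 0-based
# half-open genomic coordinates starting at `offset`
random_gene_model <- function(gene_id, cds_len, introns, strand, offset) {
  if (introns > 0L) {
    cuts <- sort(sample(seq(3L, cds_len - 3L, by = 3L), introns))
  } else cuts <- integer()
  lens <- diff(c(0L, cuts, cds_len))
  segs <- matrix(0L, nrow = length(lens), ncol = 2,
                 dimnames = list(NULL, c("start", "end")))
  pos <- offset
  for (i in seq_along(lens)) {
    segs[i, ] <- c(pos, pos + lens[i])
    pos <- pos + lens[i] + 80L  # 80 bp synthetic introns
  }
  if (strand == "-") segs <- segs[rev(seq_len(nrow(segs))), , drop = FALSE]
  list(gene_id = gene_id, transcript_id = paste0(gene_id, ".t1"),
       transcript_ids = paste0(gene_id, ".t1"), strand = strand,
       cds = segs, intron_count = introns, intron_known = TRUE)
}

#' Generate a labelled synthetic genome
#'
#' Builds, per class, proteins derived from the synthetic reference with the
#' class signature planted at canonical 31/41/87/90 and the class intron
#' plan in the gene models (H3.1 and H3.1A intronless; H3.3 with 1-2
#' introns; CenH3 with an extended N-tail over an elevated-divergence core;
#' H3-like with at least one signature residue outside both consensuses
#' and/or a degenerate N-tail), plus unrelated random decoy proteins that
#' fail the homology threshold. CDSs are uniform random synonymous
#' back-translations with a terminal stop.
#'
#' @param spec A [synthesis_spec()].
#' @param outdir Optional directory: writes `proteome.faa`, `cds.fna`,
#'   `genes.gff3`, `truth.tsv`.
#' @return List with `proteome`, `cds` (named vectors), `gene_models`,
#'   `truth` (data.frame gene_id/class/signature/intron_count), `reference`.
#' @export
synth_genome <- function(spec, outdir = NULL) {
  ref <- make_reference(spec$seed, spec$ref_length)
  with_seed(spec$seed + 1L, {
    proteome <- character(); cds <- character()
    models <- list(); truth <- list()
    offset <- 0L
    idx <- 0L
    add_gene <- function(class, aa, introns, sig = "", template = NULL) {
      idx <<- idx + 1L
      id <- sprintf("synt_g%03d", idx)
      prot <- paste(aa, collapse = "")
      proteome[id] <<- prot
      cds[id] <<- random_cds(prot, template)
      models[[id]] <<- random_gene_model(id, nchar(cds[id]), introns,
                                         if (idx %% 2) "+" else "-", offset)
      offset <<- offset + nchar(cds[id]) + 80L * (introns + 1L) + 500L
      truth[[id]] <<- data.frame(gene_id = id, class = class, signature = sig,
                                 intron_count = introns,
                                 stringsAsFactors = FALSE)
    }
    refaa <- strsplit(ref, "")[[1]]
    # genome-wide reference CDS: the shared codon ancestry of the family
    ref_codons <- vapply(refaa, function(a) {
      opts <- names(genetic_code())[genetic_code() == a]
      opts[sample.int(length(opts), 1)]
    }, "")
    plant <- function(sig) { aa <- refaa; aa[c(31, 41, 87, 90)] <- sig; aa }

    for (i in seq_len(spec$n_h3_1))
      add_gene("H3_1", mutate_protein(plant(SIG_H3_1), spec$mutation_rate),
               0L, paste(SIG_H3_1, collapse = ""), ref_codons)
    for (i in seq_len(spec$n_h3_3))
      add_gene("H3_3", mutate_protein(plant(SIG_H3_3), spec$mutation_rate),
               sample(1:2, 1), paste(SIG_H3_3, collapse = ""), ref_codons)
    for (i in seq_len(spec$n_h3_1a)) {
      sig <- if (runif(1) < 0.5) SIG_H3_1A_S else SIG_H3_1A_Q
      add_gene("H3_1A", mutate_protein(plant(sig), spec$mutation_rate), 0L,
               paste(sig, collapse = ""), ref_codons)
    }
    # CenH3 genes descend from one diverged ancestor (tail + core), the way
    # real CenH3s share ancestry and form a recoverable clade
    cenh3_core_anc <- mutate_protein(refaa, spec$cenh3_core_divergence,
                                     protected = integer())
    cenh3_tail_anc <- sample(AA20, spec$cenh3_tail_length, replace = TRUE)
    # stop-codon placeholders in the tail region never match an amino acid,
    # so tail codons are drawn fresh while the core keeps shared ancestry
    cenh3_template <- c(rep("TAA", spec$cenh3_tail_length), ref_codons)
    for (i in seq_len(spec$n_cenh3)) {
      core <- mutate_protein(cenh3_core_anc, spec$mutation_rate,
                             protected = integer())
      tail <- mutate_protein(cenh3_tail_anc, spec$mutation_rate,
                             protected = integer())
      add_gene("CENH3", c(tail, core), sample(1:2, 1),
               paste(core[c(31, 41, 87, 90)], collapse = ""), cenh3_template)
    }
    for (i in seq_len(spec$n_h3_like)) {
      aa <- refaa
      npos <- sample(1:4, 1)
      pos <- sample(c(31, 41, 87, 90), npos)
      for (p in pos) {
        k <- match(p, c(31, 41, 87, 90))
        banned <- c(SIG_H3_1[k], SIG_H3_3[k], SIG_H3_1A_S[k], SIG_H3_1A_Q[k])
        aa[p] <- sample(setdiff(AA20, banned), 1)
      }
      aa <- mutate_protein(aa, spec$mutation_rate)
      sig <- paste(aa[c(31, 41, 87, 90)], collapse = "")
      tmpl <- ref_codons
      if (runif(1) < 0.5) {      # degenerate N-tail
        aa <- aa[-seq_len(20)]
        tmpl <- tmpl[-seq_len(20)]
      }
      add_gene("H3_LIKE", aa, sample(0:2, 1), sig, tmpl)
    }
    for (i in seq_len(spec$n_decoys))
      add_gene("NONE", sample(AA20, sample(110:160, 1), replace = TRUE),
               sample(0:3, 1))

    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL
    out <- list(proteome = proteome, cds = cds, gene_models = models,
                truth = truth, reference = ref,
                cenh3_ancestor = if (spec$n_cenh3 > 0)
                  paste(c(cenh3_tail_anc, cenh3_core_anc), collapse = "")
                else NULL)
    if (!is.null(outdir)) {
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      write_fasta(proteome, file.path(outdir, "proteome.faa"))
      write_fasta(cds, file.path(outdir, "cds.fna"))
      write_gff3(models, file.path(outdir, "genes.gff3"))
      write.table(truth, file.path(outdir, "truth.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    out
  })
}

#' Seed query set matched to a synthetic genome
#'
#' Builds the three seed queries the scan needs (one H3.1-type, one
#' H3.3-type, one CenH3-type) from the genome's own reference and CenH3
#' ancestor — the synthetic analogue of using curated H3.1/H3.3/CenH3
#' proteins as search queries.
#'
#' @param genome Result of [synth_genome()].
#' @return Named character vector of three protein queries; the CenH3 anchor
#'   id contains `"cenh3"` so the pipeline recognizes it.
#' @export
synth_queries <- function(genome) {
  refaa <- strsplit(genome$reference, "")[[1]]
  h31 <- refaa; h31[c(31, 41, 87, 90)] <- SIG_H3_1
  q <- c(query_h3_1 = paste(h31, collapse = ""),
         query_h3_3 = genome$reference)
  if (!is.null(genome$cenh3_ancestor))
    q["query_cenh3"] <- genome$cenh3_ancestor
  q
}

# single-nucleotide mutational neighborhoods of every sense codon:
# targets, transition flag, synonymous flag (static, cached)
codon_mutation_table <- function() {
  if (!is.null(.htr_cache$mut)) return(.htr_cache$mut)
  gc <- genetic_code()
  transitions <- c(A = "G", G = "A", C = "T", T = "C")
  tab <- lapply(sense_codons(), function(codon) {
    nts <- strsplit(codon, "")[[1]]
    targets <- character(); ts <- logical(); syn <- logical()
    for (pos in 1:3) for (alt in setdiff(NUC, nts[pos])) {
      mut <- nts; mut[pos] <- alt
      mcod <- paste(mut, collapse = "")
      if (gc[mcod] == "*") next
      targets <- c(targets, mcod)
      ts <- c(ts, transitions[nts[pos]] == alt)
      syn <- c(syn, gc[mcod] == gc[codon])
    }
    list(targets = targets, ts = unname(ts), syn = syn)
  })
  names(tab) <- sense_codons()
  .htr_cache$mut <- tab
  tab
}

codon_rates <- function(codon, omega, kappa, mut = codon_mutation_table()) {
  e <- mut[[codon]]
  r <- ifelse(e$ts, kappa, 1) * ifelse(e$syn, 1, omega)
  names(r) <- e$targets
  r
}

#' Evolve codon sequences under a known dN/dS
#'
#' Continuous-time (Gillespie) simulation of single-nucleotide codon
#' substitutions: transitions weighted `kappa`, transversions 1,
#' nonsynonymous changes multiplied by `omega`, changes into stop codons
#' forbidden. The rate matrix is normalized so that one unit of branch
#' length equals one expected substitution per codon site at the ancestor's
#' composition.
#'
#' @param ancestor_codons Character vector of sense codons.
#' @param tree_or_divergence Either a `phylo` with branch lengths (leaves
#'   receive the evolved sequences) or a single number: total pairwise
#'   divergence for a two-leaf simulation (each lineage runs half).
#' @param omega dN/dS of the simulation (>= 0).
#' @param kappa Transition/transversion rate ratio (default 2).
#' @param seed RNG seed.
#' @return Named list of codon vectors, one per leaf.
#' @export
evolve_codons <- function(ancestor_codons, tree_or_divergence, omega,
                          kappa = 2, seed = 1L) {
  if (omega < 0) stop("omega must be >= 0", call. = FALSE)
  bad <- setdiff(unique(ancestor_codons), sense_codons())
  if (length(bad)) stop("ancestor contains non-sense codon(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  mut <- codon_mutation_table()
  rho <- mean(vapply(ancestor_codons,
                     function(c) sum(codon_rates(c, omega, kappa, mut)), 0))
  if (rho <= 0) rho <- 1  # omega 0 on an all-nondegenerate ancestor
  sim_branch <- function(codons, t) {
    if (t <= 0) return(codons)
    r <- vapply(codons, function(c) sum(codon_rates(c, omega, kappa, mut)), 0)
    time <- 0
    repeat {
      R <- sum(r) / rho
      if (R <= 0) break
      time <- time + rexp(1, R)
      if (time > t) break
      i <- sample.int(length(codons), 1, prob = r)
      rates_i <- codon_rates(codons[i], omega, kappa, mut)
      codons[i] <- names(rates_i)[sample.int(length(rates_i), 1,
                                             prob = rates_i)]
      r[i] <- sum(codon_rates(codons[i], omega, kappa, mut))
    }
    codons
  }
  with_seed(seed, {
    if (is.numeric(tree_or_divergence)) {
      t1 <- sim_branch(ancestor_codons, tree_or_divergence / 2)
      t2 <- sim_branch(ancestor_codons, tree_or_divergence / 2)
      list(t1 = unname(t1), t2 = unname(t2))
    } else {
      tree <- tree_or_divergence
      n <- length(tree$tip.label)
      kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
      leaves <- list()
      walk <- function(node, codons) {
        for (k in kids[[as.character(node)]]) {
          child <- tree$edge[k, 2]
          evolved <- sim_branch(codons, tree$edge.length[k])
          if (child <= n) leaves[[tree$tip.label[child]]] <<- unname(evolved)
          else walk(child, evolved)
        }
      }
      walk(n + 1L, ancestor_codons)
      leaves[tree$tip.label]
    }
  })
}

#' Random ancestor codon sequence
#' @param n_codons Number of codons.
#' @param seed RNG seed.
#' @return Character vector of sense codons.
#' @export
random_codons <- function(n_codons, seed = 1L) {
  with_seed(seed, sample(sense_codons(), n_codons, replace = TRUE))
}

#' Specification for a synthetic expression matrix
#'
#' Default tissue panel mirrors a grass developmental series: dividing-like
#' tissues (root, stem, seed, embryo) versus differentiated-like tissues
#' (young leaf, mature leaf, endosperm, flower). The planted
#' `dividing_high` effect is +2 log2 units, matching the contrast reported
#' for replication-dependent H3.1-type profiles.
#'
#' @param seed RNG seed.
#' @param n_constitutive,n_dividing_high,n_differentiated_high,
#'   n_heterogeneous,n_not_detected Genes per planted archetype
#'   (`differentiated_high` is the mirror profile, +delta in differentiated
#'   tissues — the seed/embryo/endosperm-high pattern).
#' @param delta Log2 effect of the dividing_high archetype (default 2).
#' @param noise_sd Gaussian noise sd on the log2 scale (default 0.2).
#' @param baseline_log2 Baseline expression, log2 scale (default 6).
#' @param detection_floor Linear floor under which genes are not detected.
#' @param tissue_groups Named character vector tissue -> group.
#' @return List of class `htr_expression_spec`.
#' @export
expression_spec <- function(seed = 3L, n_constitutive = 5L,
                            n_dividing_high = 5L, n_differentiated_high = 0L,
                            n_heterogeneous = 3L,
                            n_not_detected = 2L, delta = 2.0, noise_sd = 0.2,
                            baseline_log2 = 6.0, detection_floor = 1.0,
                            tissue_groups = c(
                              root = "dividing", stem = "dividing",
                              seed = "dividing", embryo = "dividing",
                              leaf_young = "differentiated",
                              leaf_mature = "differentiated",
                              endosperm = "differentiated",
                              flower = "differentiated")) {
  if (length(unique(tissue_groups)) < 2L)
    stop("need at least 2 tissue groups", call. = FALSE)
  structure(list(seed = seed, n_constitutive = n_constitutive,
                 n_dividing_high = n_dividing_high,
                 n_differentiated_high = n_differentiated_high,
                 n_heterogeneous = n_heterogeneous,
                 n_not_detected = n_not_detected, delta = delta,
                 noise_sd = noise_sd, baseline_log2 = baseline_log2,
                 detection_floor = detection_floor,
                 tissue_groups = tissue_groups),
            class = "htr_expression_spec")
}

#' Generate an expression matrix with planted archetypes
#'
#' @param spec An [expression_spec()].
#' @return List with `matrix` (linear scale, genes x tissues), `truth`
#'   (data.frame gene_id/archetype), `tissue_groups`.
#' @export
synth_expression <- function(spec) {
  tg <- spec$tissue_groups
  tissues <- names(tg)
  with_seed(spec$seed, {
    rows <- list(); truth <- list(); idx <- 0L
    add <- function(archetype, log2row) {
      idx <<- idx + 1L
      id <- sprintf("expr_g%03d", idx)
      rows[[id]] <<- if (is.null(log2row)) runif(length(tissues), 0,
                                                 spec$detection_floor / 2)
        else 2^log2row
      truth[[id]] <<- data.frame(gene_id = id, archetype = archetype,
                                 stringsAsFactors = FALSE)
    }
    noise <- function() rnorm(length(tissues), 0, spec$noise_sd)
    for (i in seq_len(spec$n_constitutive))
      add("constitutive", spec$baseline_log2 + noise())
    for (i in seq_len(spec$n_dividing_high))
      add("dividing_high", spec$baseline_log2 +
            spec$delta * (tg == "dividing") - spec$delta / 2 + noise())
    for (i in seq_len(spec$n_differentiated_high))
      add("differentiated_high", spec$baseline_log2 +
            spec$delta * (tg == "differentiated") - spec$delta / 2 + noise())
    for (i in seq_len(spec$n_heterogeneous))
      add("heterogeneous", spec$baseline_log2 +
            runif(length(tissues), -3, 3) + noise())
    for (i in seq_len(spec$n_not_detected))
      add("not_detected", NULL)
    m <- do.call(rbind, rows)
    dimnames(m) <- list(names(rows), tissues)
    list(matrix = m, truth = do.call(rbind, c(truth, make.row.names = FALSE)),
         tissue_groups = tg)
  })
}
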