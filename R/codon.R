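# Codon-level utilities shared by the selection module and the simulator.
# The genetic code table comes from Biostrings (standard code, T alphabet).

genetic_code <- function() Biostrings::GENETIC_CODE

NUC <- c("A", "C", "G", "T")

sense_codons <- function() {
  gc <- genetic_code()
  names(gc)[gc != "*"]
}

is_stop <- function(codon) genetic_code()[codon] == "*"

#' Translate a vector of codons to amino acids
#' @param codons Character vector of 3-letter codons (DNA alphabet).
#' @return Character vector of amino acids (`*` for stops).
#' @export
translate_codons <- function(codons) {
  aa <- genetic_code()[codons]
  if (anyNA(aa)) stop("invalid codon(s): ",
                      paste(unique(codons[is.na(aa)]), collapse = ", "),
                      call. = FALSE)
  unname(aa)
}

#' Split a CDS string into codons
#' @param cds Nucleotide string, length divisible by 3.
#' @return Character vector of codons.
#' @export
split_codons <- function(cds) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0)
    stop("CDS length not divisible by 3", call. = FALSE)
  substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
}

# Nei-Gojobori synonymous site count of one codon: at each of the 3
# positions, the fraction of non-stop single-nucleotide changes that are
# synonymous (stop targets excluded, weights renormalized so every position
# contributes exactly 1 site; hence S + N = 3 per codon).
ng86_syn_sites <- function(codon) {
  gc <- genetic_code()
  aa <- gc[codon]
  nts <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    syn <- 0L; valid <- 0L
    for (alt in setdiff(NUC, nts[pos])) {
      mut <- nts; mut[pos] <- alt
      mcod <- paste(mut, collapse = "")
      if (gc[mcod] == "*") next
      valid <- valid + 1L
      if (gc[mcod] == aa) syn <- syn + 1L
    }
    if (valid > 0L) s <- s + syn / valid
  }
  s
}

# lazily built lookup tables over the 61 sense codons:
#   $S  named numeric: synonymous sites per codon
#   $Sd, $Nd  61 x 61 pathway-averaged difference counts
ng86_tables <- function() {
  if (!is.null(.htr_cache$ng86)) return(.htr_cache$ng86)
  sc <- sense_codons()
  S <- vapply(sc, ng86_syn_sites, 0)
  nS <- length(sc)
  Sd <- matrix(0, nS, nS, dimnames = list(sc, sc))
  Nd <- Sd
  for (i in seq_len(nS)) for (j in seq_len(nS)) {
    if (i >= j) next
    cnt <- codon_path_counts(sc[i], sc[j])
    Sd[i, j] <- Sd[j, i] <- cnt[1]
    Nd[i, j] <- Nd[j, i] <- cnt[2]
  }
  .htr_cache$ng86 <- list(S = S, Sd = Sd, Nd = Nd)
  .htr_cache$ng86
}

# average synonymous / nonsynonymous step counts over all substitution
# pathways between two sense codons; pathways passing through a stop codon
# are excluded and the weights renormalized over the remaining ones (if every
# pathway is blocked, all are used, stop-involving steps counted as
# nonsynonymous -- degenerate but deterministic)
codon_path_counts <- function(a, b) {
  gc <- genetic_code()
  na_ <- strsplit(a, "")[[1]]; nb <- strsplit(b, "")[[1]]
  diff_pos <- which(na_ != nb)
  k <- length(diff_pos)
  if (k == 0L) return(c(0, 0))
  perms <- permutations_of(diff_pos)
  tally <- function(skip_stop) {
    tot_s <- 0; tot_n <- 0; used <- 0L
    for (ord in perms) {
      cur <- na_
      s <- 0L; n <- 0L; blocked <- FALSE
      for (step in seq_along(ord)) {
        aa_from <- gc[paste(cur, collapse = "")]
        cur[ord[step]] <- nb[ord[step]]
        to <- paste(cur, collapse = "")
        if (skip_stop && gc[to] == "*" && step < length(ord)) {
          blocked <- TRUE; break
        }
        if (gc[to] == aa_from && gc[to] != "*") s <- s + 1L else n <- n + 1L
      }
      if (!blocked) { tot_s <- tot_s + s; tot_n <- tot_n + n; used <- used + 1L }
    }
    if (used == 0L) NULL else c(tot_s / used, tot_n / used)
  }
  res <- tally(TRUE)
  if (is.null(res)) res <- tally(FALSE)
  res
}

permutations_of <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in permutations_of(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  out
}

#' Nei-Gojobori (1986) pairwise dN/dS counting
#'
#' Codon columns gapped in either sequence are dropped. Synonymous and
#' nonsynonymous site counts are averaged over the two sequences; observed
#' differences are averaged over all substitution pathways between each codon
#' pair (pathways through stop codons excluded with weight renormalization).
#' Proportions are Jukes-Cantor corrected:
#' `d = -(3/4) ln(1 - (4/3) p)`.
#'
#' @param codons_a,codons_b Equal-length character vectors of codons
#'   (`"---"` marks an alignment gap).
#' @param on_saturation `"error"` (default) raises a "saturated" error when a
#'   corrected proportion reaches 3/4; `"na"` returns the counts with the
#'   affected distance set to `NA` (the raw counts are always well defined).
#' @return List with `Sd`, `Nd`, `S_sites`, `N_sites`, `dS`, `dN`,
#'   `codons_compared`.
#' @export
ng86_pair <- function(codons_a, codons_b,
                      on_saturation = c("error", "na")) {
  on_saturation <- match.arg(on_saturation)
  stopifnot(length(codons_a) == length(codons_b))
  gap <- grepl("-", codons_a, fixed = TRUE) | grepl("-", codons_b, fixed = TRUE)
  ca <- toupper(codons_a[!gap]); cb <- toupper(codons_b[!gap])
  if (!length(ca)) stop("empty overlap: no shared ungapped codons", call. = FALSE)
  tab <- ng86_tables()
  bad <- setdiff(unique(c(ca, cb)), names(tab$S))
  if (length(bad))
    stop("non-sense codon(s) in input: ", paste(bad, collapse = ", "),
         call. = FALSE)
  S_sites <- sum((tab$S[ca] + tab$S[cb]) / 2)
  N_sites <- 3 * length(ca) - S_sites
  Sd <- sum(tab$Sd[cbind(ca, cb)])
  Nd <- sum(tab$Nd[cbind(ca, cb)])
  jc <- function(p) {
    if (p < 1e-15) return(0)
    if (p >= 0.75) {
      if (on_saturation == "error")
        stop("saturated: proportion of differences >= 3/4", call. = FALSE)
      return(NA_real_)
    }
    -0.75 * log(1 - 4 * p / 3)
  }
  dS <- if (S_sites > 0) jc(Sd / S_sites) else NA_real_
  dN <- if (N_sites > 0) jc(Nd / N_sites) else NA_real_
  list(Sd = Sd, Nd = Nd, S_sites = S_sites, N_sites = N_sites,
       dS = dS, dN = dN, codons_compared = length(ca))
}
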