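# Independent oracles used against the package implementations. These are
# deliberately written as plain, unoptimized re-derivations: they share no
# code with the package.

b62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

AAS <- c("A","R","N","D","C","Q","E","G","H","I",
         "L","K","M","F","P","S","T","W","Y","V")

random_protein <- function(n) paste(sample(AAS, n, replace = TRUE),
                                    collapse = "")

# --- local alignment oracle: three-matrix DP written from the recurrences,
# gap of length L costs open + L * ext, score clamped at 0
oracle_local_score <- function(a, b, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)  # gap in b (consumes a)
  Y <- matrix(-Inf, n + 1, m + 1)  # gap in a (consumes b)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
    Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
    M[i, j] <- max(0, b62[A[i - 1], B[j - 1]] +
                     max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]))
    best <- max(best, M[i, j])
  }
  best
}

# --- global alignment oracle: memoized recursion over (i, j, previous move)
# with penalized end gaps
oracle_global_score <- function(a, b, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  memo <- new.env(hash = TRUE)
  rec <- function(i, j, prev) {
    key <- paste(i, j, prev)
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- if (i > length(A) && j > length(B)) 0
    else {
      cand <- -Inf
      if (i <= length(A) && j <= length(B))
        cand <- max(cand, b62[A[i], B[j]] + rec(i + 1, j + 1, "M"))
      if (i <= length(A))
        cand <- max(cand, -(if (prev == "X") ext else open + ext) +
                      rec(i + 1, j, "X"))
      if (j <= length(B))
        cand <- max(cand, -(if (prev == "Y") ext else open + ext) +
                      rec(i, j + 1, "Y"))
      cand
    }
    memo[[key]] <- res
    res
  }
  rec(1, 1, "M")
}

# --- NG86 oracle: explicit pathway enumeration, written independently
GC <- Biostrings::GENETIC_CODE
oracle_ng86 <- function(codons_a, codons_b) {
  all_perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(all_perms(v[-i]), function(p) c(v[i], p))))
  }
  syn_sites_one <- function(codon) {
    total <- 0
    for (pos in 1:3) {
      targets <- character()
      for (nt in c("A", "C", "G", "T")) {
        if (substr(codon, pos, pos) == nt) next
        mut <- codon; substr(mut, pos, pos) <- nt
        if (GC[[mut]] != "*") targets <- c(targets, mut)
      }
      if (length(targets))
        total <- total + mean(vapply(targets, function(m)
          GC[[m]] == GC[[codon]], TRUE))
    }
    total
  }
  Sd <- 0; Nd <- 0; S <- 0; N <- 0
  for (k in seq_along(codons_a)) {
    ca <- codons_a[k]; cb <- codons_b[k]
    S <- S + (syn_sites_one(ca) + syn_sites_one(cb)) / 2
    N <- N + 3 - (syn_sites_one(ca) + syn_sites_one(cb)) / 2
    pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
    if (!length(pos)) next
    path_s <- c(); path_n <- c()
    for (ordv in all_perms(pos)) {
      cur <- ca; s <- 0; n <- 0; through_stop <- FALSE
      for (step in seq_along(ordv)) {
        p <- ordv[step]
        nxt <- cur; substr(nxt, p, p) <- substr(cb, p, p)
        if (GC[[nxt]] == "*" && step < length(ordv)) through_stop <- TRUE
        if (GC[[nxt]] == GC[[cur]] && GC[[nxt]] != "*") s <- s + 1 else n <- n + 1
        cur <- nxt
      }
      if (!through_stop) { path_s <- c(path_s, s); path_n <- c(path_n, n) }
    }
    Sd <- Sd + mean(path_s); Nd <- Nd + mean(path_n)
  }
  c(Sd = Sd, Nd = Nd, S_sites = S, N_sites = N)
}

SENSE <- names(GC)[GC != "*"]

# random pair of codon vectors with at most `max_diff` differing positions
# inside each codon, avoiding all-pathways-blocked codon pairs
random_codon_pair <- function(n_codons) {
  a <- sample(SENSE, n_codons, replace = TRUE)
  b <- vapply(a, function(c0) {
    k <- sample(0:3, 1, prob = c(0.3, 0.4, 0.2, 0.1))
    cur <- c0
    for (i in seq_len(k)) {
      repeat {
        p <- sample(1:3, 1)
        nt <- sample(setdiff(c("A", "C", "G", "T"), substr(cur, p, p)), 1)
        cand <- cur; substr(cand, p, p) <- nt
        if (GC[[cand]] != "*") { cur <- cand; break }
      }
    }
    cur
  }, "")
  list(a = unname(a), b = unname(b))
}

# support of the bipartition separating `leaves` from the rest, NA if absent
clade_support <- function(tree, leaves) {
  n <- length(tree$tip.label)
  sets <- htrscan:::node_tip_sets(tree)
  sup <- suppressWarnings(as.numeric(tree$node.label))
  for (v in (n + 1):(n + tree$Nnode)) {
    side <- sets[[v]]
    if (setequal(side, leaves) ||
        setequal(setdiff(tree$tip.label, side), leaves)) return(sup[v - n])
  }
  NA_real_
}

# --- small fixture writers
write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# two-clade protein alignment with `n_diag` diagnostic columns separating a
# CenH3-like clade from the background clade
two_clade_alignment <- function(seed = 77, n_diag = 20, n_a = 5, n_b = 7,
                                len = 60) {
  set.seed(seed)
  base <- sample(AAS, len, replace = TRUE)
  cladeA <- base
  cladeA[seq_len(n_diag)] <- vapply(base[seq_len(n_diag)], function(x)
    sample(setdiff(AAS, x), 1), "")
  mk <- function(v, nmut = 3) {
    i <- sample((n_diag + 1):len, nmut)
    v[i] <- sample(AAS, nmut, replace = TRUE)
    paste(v, collapse = "")
  }
  seqs <- c(setNames(vapply(1:n_a, function(i) mk(cladeA), ""),
                     paste0("cen", 1:n_a)),
            setNames(vapply(1:n_b, function(i) mk(base), ""),
                     paste0("h3_", 1:n_b)))
  htr_alignment(names(seqs), seqs)
}
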