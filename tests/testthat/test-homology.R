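test_that("smith_waterman matches the self-alignment closed form", {
  set.seed(7)
  s <- random_protein(50)
  h <- smith_waterman(s, s)
  expected <- sum(diag(b62[strsplit(s, "")[[1]], strsplit(s, "")[[1]]]))
  expect_equal(h$sw_score, expected)
  expect_equal(h$span_subject, c(0L, 50L))
})

test_that("smith_waterman equals the independent DP oracle on random pairs", {
  set.seed(42)
  for (i in 1:100) {
    a <- random_protein(8); b <- random_protein(8)
    expect_equal(smith_waterman(a, b)$sw_score, oracle_local_score(a, b),
                 info = paste(a, b))
  }
  # unrelated low-complexity pair: best single-residue match or empty
  expect_equal(smith_waterman("KKKK", "PPPPWPPP")$sw_score,
               oracle_local_score("KKKK", "PPPPWPPP"))
})

test_that("smith_waterman score is symmetric and validates its alphabet", {
  set.seed(8)
  for (i in 1:20) {
    a <- random_protein(12); b <- random_protein(15)
    expect_equal(smith_waterman(a, b)$sw_score, smith_waterman(b, a)$sw_score)
  }
  expect_error(smith_waterman("AR1K", "ARTK"), "non-protein")
})

test_that("Karlin-Altschul e-value: closed form, linearity, monotonicity", {
  cfg <- scan_config()
  expect_equal(estimate_evalue(0, 100, 1e5, cfg), cfg$karlin_k * 100 * 1e5)
  expect_equal(estimate_evalue(50, 100, 2e5, cfg),
               2 * estimate_evalue(50, 100, 1e5, cfg))
  expect_lt(estimate_evalue(60, 100, 1e5, cfg),
            estimate_evalue(50, 100, 1e5, cfg))
})

test_that("scan recovers exactly the planted H3 genes among decoys", {
  g <- synth_genome(synthesis_spec(seed = 7L, n_h3_1 = 1L, n_h3_3 = 1L,
                                   n_h3_1a = 1L, n_cenh3 = 1L,
                                   n_h3_like = 0L, n_decoys = 20L))
  cands <- scan_proteome(g$proteome, synth_queries(g), g$gene_models, g$cds)
  found <- vapply(cands, `[[`, "", "gene_id")
  planted <- g$truth$gene_id[g$truth$class != "NONE"]
  expect_setequal(found, planted)
  # decoys must sit above the e-value threshold
  expect_false(any(g$truth$gene_id[g$truth$class == "NONE"] %in% found))
})

test_that("iterative expansion reaches homologs invisible to the seed query", {
  set.seed(30)
  q <- random_protein(100)
  linker <- random_protein(100)
  b <- paste0(substr(q, 1, 50), substr(linker, 1, 50))     # half shared with q
  c_ <- paste0(random_protein(50), substr(linker, 1, 50))  # shared with b only
  proteome <- c(geneB = b, geneC = c_)
  hits2 <- scan_proteome(proteome, c(seed_q = q))
  expect_setequal(vapply(hits2, `[[`, "", "gene_id"), c("geneB", "geneC"))
  hits1 <- scan_proteome(proteome, c(seed_q = q), max_rounds = 1)
  expect_setequal(vapply(hits1, `[[`, "", "gene_id"), "geneB")
})

test_that("scan output is independent of proteome record order; empty cases", {
  g <- synth_genome(synthesis_spec(seed = 9L, n_decoys = 5L))
  q <- synth_queries(g)
  a <- scan_proteome(g$proteome, q, g$gene_models, g$cds)
  b <- scan_proteome(rev(g$proteome), q, g$gene_models, g$cds)
  expect_setequal(vapply(a, `[[`, "", "gene_id"),
                  vapply(b, `[[`, "", "gene_id"))
  expect_equal(scan_proteome(character(), q), list())
  expect_error(scan_proteome(g$proteome, character()), "empty query")
})

test_that("filters: redundant CDS collapse, incompleteness, idempotence", {
  g <- synth_genome(synthesis_spec(seed = 11L, n_decoys = 0L))
  q <- synth_queries(g)
  cands <- scan_proteome(g$proteome, q, g$gene_models, g$cds)
  # plant an exact CDS duplicate of the lexicographically smallest gene
  dup <- cands[[1]]
  dup$gene_id <- "zzz_dup"
  dup$gene_model <- NULL
  filt <- filter_candidates(c(cands, list(dup)), query_lengths = nchar(q))
  status <- setNames(vapply(filt$all, `[[`, "", "filter_status"),
                     vapply(filt$all, `[[`, "", "gene_id"))
  expect_equal(unname(status["zzz_dup"]), "redundant")
  expect_true(all(status[names(status) != "zzz_dup"] == "kept"))
  # idempotence: refiltering the kept set changes nothing
  again <- filter_candidates(filt$kept, query_lengths = nchar(q))
  expect_equal(length(again$kept), length(filt$kept))

  # truncated candidate covering too little of the query core
  tr <- cands[[2]]
  tr$gene_id <- "trunc"
  tr$protein <- substr(tr$protein, 1, 60)
  tr$cds <- NULL
  tr$best_hit <- smith_waterman(q[[1]], tr$protein, query_id = names(q)[1],
                                subject_id = "trunc")
  f2 <- filter_candidates(list(tr), query_lengths = nchar(q))
  expect_equal(f2$all[[1]]$filter_status, "incomplete")
})
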