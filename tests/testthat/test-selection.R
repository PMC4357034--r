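test_that("backtranslation expands codons and validates translation", {
  cds <- c(a = "ATGGCTAAGTAA", b = "ATGGCTAAGTAA")  # M A K + stop
  aln <- htr_alignment(c("a", "b"), c("MAK", "MAK"))
  ca <- backtranslate(aln, cds)
  expect_equal(unname(ca$codons[1, ]), c("ATG", "GCT", "AAG"))
  expect_equal(ca$codons[1, ], ca$codons[2, ])

  gapped <- htr_alignment(c("a", "b"), c("MAK", "M-K"))
  cds2 <- c(a = "ATGGCTAAGTAA", b = "ATGAAGTAA")
  ca2 <- backtranslate(gapped, cds2)
  expect_equal(unname(ca2$codons[2, ]), c("ATG", "---", "AAG"))

  badlen <- c(a = "ATGGCTAAGTAA", b = "ATGGCTAAGCCCTAA")
  expect_error(backtranslate(aln, badlen), "3 x protein length")
  mism <- c(a = "ATGGCTAAGTAA", b = "ATGGGTAAGTAA")  # b codon 2 -> G, not A
  expect_error(backtranslate(aln, mism), "position 2")
})

test_that("NG86 counting: trivial cases and symmetry", {
  same <- ng86_pair(c("ATG", "GCT"), c("ATG", "GCT"))
  expect_equal(same$Sd, 0); expect_equal(same$Nd, 0)
  expect_equal(same$dS, 0); expect_equal(same$dN, 0)

  phe <- ng86_pair("TTT", "TTC", on_saturation = "na")
  expect_equal(phe$Sd, 1); expect_equal(phe$Nd, 0)

  set.seed(60)
  for (i in 1:20) {
    p <- random_codon_pair(10)
    f <- ng86_pair(p$a, p$b, on_saturation = "na")
    r <- ng86_pair(p$b, p$a, on_saturation = "na")
    expect_equal(f[c("Sd", "Nd", "S_sites", "N_sites")],
                 r[c("Sd", "Nd", "S_sites", "N_sites")])
  }
  expect_error(ng86_pair(c("---"), c("---")), "empty overlap")
})

test_that("site counts always sum to 3 per compared codon", {
  set.seed(61)
  for (i in 1:30) {
    p <- random_codon_pair(15)
    f <- ng86_pair(p$a, p$b, on_saturation = "na")
    expect_equal(f$S_sites + f$N_sites, 3 * f$codons_compared,
                 tolerance = 1e-9)
  }
})

test_that("NG86 counts equal the pathway-enumeration oracle", {
  set.seed(62)
  for (i in 1:100) {
    p <- random_codon_pair(8)
    f <- ng86_pair(p$a, p$b, on_saturation = "na")
    o <- oracle_ng86(p$a, p$b)
    expect_equal(f$Sd, unname(o["Sd"]), tolerance = 1e-9)
    expect_equal(f$Nd, unname(o["Nd"]), tolerance = 1e-9)
    expect_equal(f$S_sites, unname(o["S_sites"]), tolerance = 1e-9)
  }
})

test_that("group dN/dS recovers simulated omega and handles degenerate input", {
  ident <- htr_codon_alignment(c("a", "b"),
                               rbind(c("ATG", "GCT"), c("ATG", "GCT")))
  r0 <- group_dnds(ident)
  expect_equal(r0$dN, 0); expect_equal(r0$dS, 0)
  expect_true(is.na(r0$ratio))

  ratio_at <- function(omega, seeds) {
    mean(vapply(seeds, function(s) {
      anc <- random_codons(200, seed = 5)
      p <- evolve_codons(anc, 0.3, omega = omega, kappa = 2, seed = s)
      group_dnds(htr_codon_alignment(c("t1", "t2"),
                                     rbind(p$t1, p$t2)))$ratio
    }, 0))
  }
  r02 <- ratio_at(0.2, 1:10)
  expect_gt(r02, 0.12); expect_lt(r02, 0.28)
  r10 <- ratio_at(1.0, 11:20)
  expect_gt(r10, 0.8); expect_lt(r10, 1.25)
})

test_that("fractional binomial tails reduce to the exact integer binomial", {
  for (n in c(3, 6, 10)) for (s in 0:n) for (p in c(0.1, 0.25, 0.5, 0.8)) {
    expect_equal(htrscan:::binom_tail_ge(s, n, p),
                 sum(dbinom(s:n, n, p)), tolerance = 1e-9)
    expect_equal(htrscan:::binom_tail_le(s, n, p),
                 sum(dbinom(0:s, n, p)), tolerance = 1e-9)
  }
})

test_that("per-site test: invariant sites, four-fold synonymous site", {
  # star-like quartet over two sites: site 1 invariant, site 2 is Gly with
  # all four third-position codons (3 inferred changes, all synonymous)
  tree <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  ca <- htr_codon_alignment(
    c("a", "b", "c", "d"),
    rbind(c("ATG", "GGT"), c("ATG", "GGC"), c("ATG", "GGA"), c("ATG", "GGG")))
  res <- site_selection(ca, tree, alpha = 0.05)
  ps <- res$per_site
  expect_equal(ps$site_class[1], "ns")
  expect_equal(ps$p_negative[1], 1)
  expect_equal(ps$Sd[2], 3)
  expect_equal(ps$Nd[2], 0)
  expect_equal(ps$expected_syn_fraction[2], 1 / 3)
  # P(X >= 3 | n = 3, p = 1/3) = (1/3)^3
  expect_equal(ps$p_negative[2], (1 / 3)^3, tolerance = 1e-12)
  expect_equal(ps$site_class[2], "negative")

  bad <- htr_codon_alignment(c("a", "b", "c", "x"), ca$codons)
  expect_error(site_selection(bad, tree), "leaves")
})

test_that("purifying simulation yields mostly negative sites; neutral does not", {
  set.seed(13)
  tree <- ape::rtree(6)
  tree$edge.length <- tree$edge.length / sum(tree$edge.length) * 5
  anc <- random_codons(80, seed = 2)
  frac_neg <- vapply(c(0.05, 1), function(om) {
    leaves <- evolve_codons(anc, tree, omega = om, kappa = 2, seed = 11)
    ca <- htr_codon_alignment(names(leaves), do.call(rbind, leaves))
    ps <- site_selection(ca, tree, alpha = 0.05)$per_site
    variable <- ps$Nd + ps$Sd > 0
    mean(ps$site_class[variable] == "negative")
  }, 0)
  expect_gt(frac_neg[1], frac_neg[2])
  expect_lte(frac_neg[2], 0.10)
})
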