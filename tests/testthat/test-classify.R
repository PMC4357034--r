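mk_sig <- function(tuple, k27 = "K", overhang = 0L, tail_deleted = FALSE) {
  structure(list(s31 = tuple[1], s41 = tuple[2], s87 = tuple[3],
                 s90 = tuple[4], k4 = "K", k9 = "K", k27 = k27, k36 = "K",
                 n_terminal_overhang = overhang, tail_deleted = tail_deleted),
            class = "htr_signature")
}

test_that("signature extraction reads planted residues and lysine states", {
  ref <- make_reference(20L)
  aa <- strsplit(ref, "")[[1]]
  aa[c(31, 41, 87, 90)] <- c("A", "F", "S", "A")
  h31 <- paste(aa, collapse = "")
  sig <- extract_signature(map_to_reference(h31, ref), h31)
  expect_equal(c(sig$s31, sig$s41, sig$s87, sig$s90), c("A", "F", "S", "A"))
  expect_equal(c(sig$k4, sig$k9, sig$k27, sig$k36), rep("K", 4))

  aa27 <- strsplit(ref, "")[[1]]; aa27[27] <- "M"
  gm <- paste(aa27, collapse = "")
  sig27 <- extract_signature(map_to_reference(gm, ref), gm)
  expect_equal(sig27$k27, "M")

  trunc <- substr(ref, 45, 135)
  sigt <- extract_signature(map_to_reference(trunc, ref), trunc)
  expect_true(sigt$tail_deleted)
  expect_equal(c(sigt$k4, sigt$k9, sigt$k27), rep("-", 3))
})

test_that("decision rules: canonical classes, conflicts, unknown introns", {
  expect_equal(classify_variant(mk_sig(c("T","Y","H","L")), 1L)$variant_class,
               "H3_3")
  expect_equal(classify_variant(mk_sig(c("T","Y","H","L")), 1L)$confidence,
               "high")
  expect_equal(classify_variant(mk_sig(c("A","F","S","A")), 0L)$variant_class,
               "H3_1")
  expect_equal(classify_variant(mk_sig(c("A","Y","Q","L")), 0L)$variant_class,
               "H3_1A")
  expect_equal(classify_variant(mk_sig(c("A","Y","S","L")), 0L)$variant_class,
               "H3_1A")
  conflict <- classify_variant(mk_sig(c("T","Y","H","L")), 0L)
  expect_equal(conflict$variant_class, "H3_LIKE")
  expect_true("signature_intron_conflict" %in% conflict$evidence)

  unk <- classify_variant(mk_sig(c("A","F","S","A")), NA_integer_)
  expect_equal(unk$variant_class, "H3_1")
  expect_true("signature_only" %in% unk$evidence)
  expect_equal(unk$confidence, "medium")

  cen <- classify_variant(mk_sig(c("T","Y","H","L")), 1L, "cenh3_tail")
  expect_equal(cen$variant_class, "CENH3")

  k27m <- classify_variant(mk_sig(c("G","G","G","G"), k27 = "M"), 0L)
  expect_true("K27M" %in% k27m$evidence)
  expect_equal(k27m$variant_class, "H3_LIKE")
})

test_that("decision table is total and deterministic over the rule domain", {
  set.seed(55)
  known <- list(c("A","F","S","A"), c("T","Y","H","L"),
                c("A","Y","S","L"), c("A","Y","Q","L"))
  perturbed <- replicate(20, {
    t <- known[[sample(4, 1)]]
    i <- sample(4, 1)
    t[i] <- sample(setdiff(AAS, c("A","F","S","T","Y","H","L","Q")), 1)
    t
  }, simplify = FALSE)
  classes <- c("CENH3", "H3_1", "H3_1A", "H3_3", "H3_LIKE")
  for (tuple in c(known, perturbed)) {
    for (introns in list(0L, 1L, NA_integer_)) {
      for (ev in list(character(), "cenh3_tail", "cenh3_clade")) {
        call <- classify_variant(mk_sig(tuple), introns, ev)
        expect_length(call$variant_class, 1L)
        expect_true(call$variant_class %in% classes)
        if (length(ev)) expect_equal(call$variant_class, "CENH3")
        if ("signature_intron_conflict" %in% call$evidence)
          expect_equal(call$variant_class, "H3_LIKE")
        # determinism
        again <- classify_variant(mk_sig(tuple), introns, ev)
        expect_equal(again$variant_class, call$variant_class)
      }
    }
  }
})

test_that("animal rule set discriminates at 31/87/89/90", {
  expect_equal(classify_variant(mk_sig(c("A","S","V","M")), 0L,
                                ruleset = "animal")$variant_class, "H3_1")
  expect_equal(classify_variant(mk_sig(c("S","A","I","G")), 1L,
                                ruleset = "animal")$variant_class, "H3_3")
  expect_equal(classify_variant(mk_sig(c("A","F","S","A")), 0L,
                                ruleset = "animal")$variant_class, "H3_LIKE")
})

test_that("CenH3 evidence: tail construction, clade membership, clean H3.3", {
  ref <- make_reference(20L)
  refaa <- strsplit(ref, "")[[1]]
  set.seed(5)
  core <- refaa
  pos <- sample(135, 54)  # 60% core identity
  for (p in pos) core[p] <- sample(setdiff(AAS, core[p]), 1)
  cand <- paste(c(sample(AAS, 25, replace = TRUE), core), collapse = "")
  pm <- map_to_reference(cand, ref, "cand")
  expect_setequal(detect_cenh3(cand, pm, ref, tree = NULL, anchors = "a"),
                  "cenh3_tail")

  # clade evidence from a supported anchored bipartition
  aln <- two_clade_alignment(seed = 77)
  tr <- bootstrap_support(aln, 100, seed = 7)
  flags <- detect_cenh3(cand, pm, ref, tree = tr, anchors = "cen1",
                        known_h3 = paste0("h3_", 1:7), candidate_id = "cen2")
  expect_true("cenh3_clade" %in% flags)

  pm_ref <- map_to_reference(ref, ref, "ref")
  expect_length(detect_cenh3(ref, pm_ref, ref, tree = tr, anchors = "cen1",
                             candidate_id = "h3_1"), 0L)
})

test_that("lysine audit: conserved fractions and substitution listing", {
  clean <- list(
    htrscan:::new_call("a", "H3_1", mk_sig(c("A","F","S","A")), 0L,
                       "signature_match", "high"),
    htrscan:::new_call("b", "H3_3", mk_sig(c("T","Y","H","L")), 1L,
                       "signature_match", "high"))
  tab <- audit_lysines(clean)
  expect_equal(tab$frac_k4, c(1, 1))
  expect_equal(tab$frac_k27, c(1, 1))

  withm <- c(clean, list(
    htrscan:::new_call("c", "H3_LIKE", mk_sig(c("G","G","G","G"), k27 = "M"),
                       0L, "K27M", "low")))
  tab2 <- audit_lysines(withm)
  expect_match(tab2$substitutions[tab2$class == "H3_LIKE"], "c:K27M")
  expect_equal(tab2$frac_k27[tab2$class == "H3_LIKE"], 0)

  expect_equal(nrow(audit_lysines(list())), 0L)
})
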