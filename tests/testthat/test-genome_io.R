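test_that("read_fasta parses records, uppercases, and rejects bad input", {
  f <- write_lines_tmp(c(">g1 some description", "artkqt", "arks",
                         ">g2", "MVKKPH"), ".faa")
  seqs <- read_fasta(f)
  expect_length(seqs, 2L)
  expect_named(seqs, c("g1", "g2"))
  expect_equal(unname(seqs["g1"]), "ARTKQTARKS")

  dup <- write_lines_tmp(c(">g1", "ARTK", ">g1", "MVKK"), ".faa")
  expect_error(read_fasta(dup), "g1")
  empty <- write_lines_tmp(character(), ".faa")
  expect_error(read_fasta(empty), "empty")
})

test_that("FASTA write/read round-trip preserves ids and sequences", {
  set.seed(101)
  seqs <- setNames(vapply(1:5, function(i) random_protein(sample(50:200, 1)), ""),
                   paste0("gene_", 1:5))
  f <- tempfile(fileext = ".faa")
  write_fasta(seqs, f)
  back <- read_fasta(f)
  expect_equal(as.character(back), as.character(seqs))
  expect_equal(names(back), names(seqs))
})

gff_fixture <- function() c(
  "##gff-version 3",
  "chr1\tsrc\tgene\t100\t400\t.\t+\t.\tID=gA",
  "chr1\tsrc\tmRNA\t100\t400\t.\t+\t.\tID=gA.t1;Parent=gA",
  "chr1\tsrc\tCDS\t100\t400\t.\t+\t0\tID=gA.c1;Parent=gA.t1",
  "chr1\tsrc\tgene\t1000\t2000\t.\t-\t.\tID=gB",
  "chr1\tsrc\tmRNA\t1000\t2000\t.\t-\t.\tID=gB.t1;Parent=gB",
  "chr1\tsrc\tCDS\t1000\t1100\t.\t-\t0\tID=gB.c1;Parent=gB.t1",
  "chr1\tsrc\tCDS\t1300\t1500\t.\t-\t0\tID=gB.c2;Parent=gB.t1",
  "chr1\tsrc\tCDS\t1800\t2000\t.\t-\t0\tID=gB.c3;Parent=gB.t1",
  "chr1\tsrc\tgene\t3000\t3500\t.\t+\t.\tID=gC")

test_that("GFF3 gene models: intron counts, strand ordering, missing CDS", {
  f <- write_lines_tmp(gff_fixture(), ".gff3")
  m <- read_gff3_gene_models(f)
  expect_equal(m$gA$intron_count, 0L)
  expect_true(m$gA$intron_known)
  expect_equal(m$gB$intron_count, 2L)
  # minus strand: segments ordered 5'->3', i.e. descending genomic start
  expect_equal(m$gB$cds[, "start"], c(1799L, 1299L, 999L))
  expect_false(m$gC$intron_known)
  expect_true(is.na(m$gC$intron_count))
})

test_that("GFF3 intron counts are strand-invariant under mirroring", {
  plus <- c("##gff-version 3",
            "chr1\ts\tgene\t10\t100\t.\t+\t.\tID=g",
            "chr1\ts\tmRNA\t10\t100\t.\t+\t.\tID=g.t;Parent=g",
            "chr1\ts\tCDS\t10\t30\t.\t+\t0\tID=c1;Parent=g.t",
            "chr1\ts\tCDS\t50\t70\t.\t+\t0\tID=c2;Parent=g.t",
            "chr1\ts\tCDS\t90\t100\t.\t+\t0\tID=c3;Parent=g.t")
  minus <- sub("\t\\+\t", "\t-\t", plus)
  mp <- read_gff3_gene_models(write_lines_tmp(plus, ".gff3"))
  mm <- read_gff3_gene_models(write_lines_tmp(minus, ".gff3"))
  expect_equal(mp$g$intron_count, mm$g$intron_count)
})

test_that("GFF3 errors carry line numbers; orphan CDS is skipped with warning", {
  bad <- write_lines_tmp(c("##gff-version 3",
                           "chr1\tsrc\tgene\t1\t10\t.\t+\t.", ""), ".gff3")
  expect_error(read_gff3_gene_models(bad), "line 2")
  orphan <- write_lines_tmp(c(
    "chr1\ts\tgene\t1\t10\t.\t+\t.\tID=g1",
    "chr1\ts\tCDS\t1\t9\t.\t+\t0\tID=c;Parent=nonexistent"), ".gff3")
  expect_warning(m <- read_gff3_gene_models(orphan), "skipped")
  expect_false(m$g1$intron_known)
})

test_that("representative transcript is the longest CDS, ties lexicographic", {
  lines <- c("chr1\ts\tgene\t1\t300\t.\t+\t.\tID=g",
             "chr1\ts\tmRNA\t1\t300\t.\t+\t.\tID=g.t2;Parent=g",
             "chr1\ts\tCDS\t1\t90\t.\t+\t0\tID=a;Parent=g.t2",
             "chr1\ts\tmRNA\t1\t300\t.\t+\t.\tID=g.t1;Parent=g",
             "chr1\ts\tCDS\t1\t150\t.\t+\t0\tID=b;Parent=g.t1")
  m <- read_gff3_gene_models(write_lines_tmp(lines, ".gff3"))
  expect_equal(m$g$transcript_id, "g.t1")
  # tie on CDS length -> lexicographically smallest transcript id
  tie <- sub("\t1\t150\t", "\t1\t90\t", lines)
  m2 <- read_gff3_gene_models(write_lines_tmp(tie, ".gff3"))
  expect_equal(m2$g$transcript_id, "g.t1")
})

test_that("gene-model GFF3 round trip preserves structure", {
  g <- synth_genome(synthesis_spec(seed = 5L, n_decoys = 2L))
  f <- tempfile(fileext = ".gff3")
  write_gff3(g$gene_models, f)
  back <- read_gff3_gene_models(f)
  for (id in names(g$gene_models)) {
    expect_equal(back[[id]]$intron_count, g$gene_models[[id]]$intron_count,
                 info = id)
    expect_equal(back[[id]]$strand, g$gene_models[[id]]$strand)
    expect_equal(unname(back[[id]]$cds), unname(g$gene_models[[id]]$cds))
  }
})

test_that("variant report is deterministic TSV with lysine-state columns", {
  sig <- function(k27 = "K") structure(
    list(s31 = "A", s41 = "F", s87 = "S", s90 = "A", k4 = "K", k9 = "K",
         k27 = k27, k36 = "K", n_terminal_overhang = 0L,
         tail_deleted = FALSE), class = "htr_signature")
  calls <- list(
    htrscan:::new_call("g2", "H3_1", sig(), 0L, "signature_match", "high"),
    htrscan:::new_call("g1", "H3_LIKE", sig(k27 = "M"), 1L, "K27M", "low"),
    htrscan:::new_call("g3", "H3_3", sig(), 1L, "intron_match", "high"))
  f1 <- tempfile(); f2 <- tempfile()
  write_variant_report(calls, f1)
  lines <- readLines(f1)
  expect_length(lines, 4L)  # header + 3 rows, gene_id sorted
  expect_match(lines[1], "^gene_id\t")
  expect_equal(sub("\t.*", "", lines[-1]), c("g1", "g2", "g3"))
  k27_col <- which(strsplit(lines[1], "\t")[[1]] == "k27_state")
  expect_equal(strsplit(lines[2], "\t")[[1]][k27_col], "M")
  write_variant_report(calls, f2)
  expect_identical(readLines(f1), readLines(f2))
  suppressWarnings(
    expect_error(write_variant_report(calls, file.path(tempfile(), "x", "y"))))
})
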