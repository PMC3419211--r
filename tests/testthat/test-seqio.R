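test_that("FASTA CDS reading normalizes sequences and labels UNKNOWN", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">g1 some description", "atgaaa", ">g2", "ATGCCU"), f)
  b <- read_cds_fasta(f)
  expect_s3_class(b, "genome_bundle")
  expect_equal(b$genes$id, c("g1", "g2"))
  expect_equal(b$genes$seq, c("ATGAAA", "ATGCCT"))   # uppercased, U -> T
  expect_true(all(b$genes$label == "UNKNOWN"))
})

test_that("FASTA reader rejects duplicate ids and empty files", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">g1", "ATG", ">g1", "CCC"), f)
  expect_error(read_cds_fasta(f), "g1")
  writeLines(character(0), f)
  expect_error(read_cds_fasta(f))
})

test_that("ambiguity codes map to N and are excluded from counts", {
  expect_message(b <- genome_bundle("g1", "ATGRWS"), "ambiguous")
  expect_equal(b$genes$seq, "ATGNNN")
  bc <- build_composition(genome_bundle("g1", "ATGNAA"))
  # fw ATGNAA + rc TTNCAT; N-containing mono/dinucleotides excluded
  expect_equal(sum(bc$kmer_counts[[1]]), 10)
  expect_equal(sum(bc$kmer_counts[[2]]), 6)
})

test_that("GenBank CDS extraction handles strand, join and id fallback", {
  gb <- write_mini_genbank(withr::local_tempfile(fileext = ".gb"))
  b <- read_genbank_cds(gb)
  expect_equal(b$genes$id, c("geneA", "prot_B", "CDS_0003"))
  # origin = ATGAAATTTCCCGGGTTTAAA
  expect_equal(b$genes$seq[1], "ATGAAA")                 # forward == substring
  expect_equal(b$genes$seq[2], "GGGAAA")                 # revcomp of TTTCCC
  expect_equal(b$genes$seq[3], "ATGTTT")                 # join(1..3,7..9)
})

test_that("GenBank reader errors without CDS and skips bad locations", {
  gb <- write_mini_genbank(withr::local_tempfile(fileext = ".gb"),
                           features = character(0))
  expect_error(read_genbank_cds(gb), "no CDS")
  gb2 <- write_mini_genbank(withr::local_tempfile(fileext = ".gb"),
                            features = c("     CDS             1..6",
                                         "     CDS             5..999"))
  expect_warning(b <- read_genbank_cds(gb2), "skipping")
  expect_equal(nrow(b$genes), 1)
})

test_that("attach_labels relabels listed genes and validates ids", {
  b <- genome_bundle(c("g1", "g2", "g3"), c("ATGAAA", "ATGCCC", "ATGGGG"))
  expect_message(b2 <- attach_labels(b, c(g1 = "HGT")), "HGT=1")
  expect_equal(as.integer(table(b2$genes$label)[c("HGT", "UNKNOWN")]),
               c(1L, 2L))
  expect_error(attach_labels(b, c(gX = "HGT")), "gX")
  expect_warning(b3 <- attach_labels(b, setNames(c("HGT", "NATIVE"), c("g1", "g1"))),
                 "last entry wins")
  expect_equal(b3$genes$label[1], "NATIVE")
})

test_that("feature tables round-trip through TSV", {
  d <- make_planted(3, n = 5)
  ds <- hgt_dataset(d$x, ids = sprintf("g%d", 1:5), label = d$label)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(ds, f)
  back <- read_feature_table(f)
  expect_equal(back$x, ds$x, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(back$ids, ds$ids)
  expect_equal(back$label, ds$label)
})

test_that("feature table reader names missing columns; empty table round-trips", {
  d <- make_planted(3, n = 5)
  ds <- hgt_dataset(d$x, ids = sprintf("g%d", 1:5), label = d$label)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(ds, f)
  tab <- read.delim(f, check.names = FALSE)
  tab[["JS-DN"]] <- NULL
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_feature_table(f), "JS-DN")

  empty <- hgt_dataset(matrix(numeric(0), 0, 15,
                              dimnames = list(NULL, hgt_feature_names())),
                       ids = character(0), label = character(0))
  write_feature_table(empty, f)
  back <- read_feature_table(f)
  expect_equal(nrow(back$x), 0)
  expect_equal(colnames(back$x), hgt_feature_names())
})
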