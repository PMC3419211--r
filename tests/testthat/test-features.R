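test_that("background composition counts match hand counts", {
  bc <- build_composition(genome_bundle("g1", "ATG"))
  # ATG + revcomp CAT
  expect_equal(bc$kmer_counts[[1]][c("A", "C", "G", "T")],
               c(A = 2, C = 1, G = 1, T = 2))
  expect_equal(sum(bc$kmer_counts[[2]]), 4)   # AT,TG + CA,AT
  expect_equal(unname(bc$codon_counts["ATG"]), 1)

  # frequencies are invariant to duplicating the gene set
  b1 <- random_bundle(5, 30, seed = 2)
  b2 <- genome_bundle(c(sprintf("a%d", 1:5), sprintf("b%d", 1:5)),
                      rep(b1$genes$seq, 2))
  c1 <- build_composition(b1); c2 <- build_composition(b2)
  for (k in 1:7)
    expect_equal(c2$kmer_counts[[k]] / sum(c2$kmer_counts[[k]]),
                 c1$kmer_counts[[k]] / sum(c1$kmer_counts[[k]]))
  expect_equal(c1$pos_gc, c2$pos_gc)
})

test_that("delta* is zero on self-comparison, symmetric, and matches a 16-term oracle", {
  b <- random_bundle(1, 50, seed = 3)
  bg <- build_composition(b)
  expect_equal(delta_star(b$genes$seq[1], bg), 0)

  sa <- strrep("AATT", 25); sb <- strrep("ACGT", 25)
  bg_a <- build_composition(genome_bundle("a", sa))
  bg_b <- build_composition(genome_bundle("b", sb))
  expect_equal(delta_star(sa, bg_b), delta_star(sb, bg_a))   # |.| symmetry

  ob <- oracle_background(sb)
  expect_equal(delta_star(sa, bg_b),
               unname(oracle_delta_star(oracle_sym_counts(sa, 1),
                                        oracle_sym_counts(sa, 2),
                                        ob$kmer[[1]], ob$kmer[[2]])),
               tolerance = 1e-12)
  expect_gt(delta_star(sa, bg_b), 0)
})

test_that("Karlin codon bias: hand case, zero identity, and L1 bound", {
  # gene AAA AAG (Lys 0.5/0.5) vs background with all-AAA Lys usage
  bg <- build_composition(genome_bundle("bg", "AAAAAA"))
  expect_equal(karlin_codon_bias("AAAAAG", bg), 1.0)
  expect_equal(karlin_codon_bias("AAAAAA", bg), 0)

  bgr <- build_composition(random_bundle(10, 60, seed = 4))
  for (s in 1:20) {
    g <- withr::with_seed(s, random_gene(40))
    expect_lte(karlin_codon_bias(g, bgr), 2)
    expect_gte(karlin_codon_bias(g, bgr), 0)
  }
})

test_that("positional GC matches hand counts and validates length", {
  expect_equal(gc_by_position("ATGGGG"), c(0.5, 0.5, 1.0))
  expect_equal(gc_by_position(strrep("ATTATA", 3)), c(0, 0, 0))
  expect_equal(gc_by_position("GCGCGC"), c(1, 1, 1))
  expect_error(gc_by_position("ATGA"), "divisible")
})

test_that("chi-squared bias is zero at equality and exactly length-stable on codons", {
  b <- random_bundle(1, 60, seed = 5)
  bg <- build_composition(b)
  expect_equal(chi2_bias(b$genes$seq[1], bg, "dinucleotide"), 0)
  expect_equal(chi2_bias(b$genes$seq[1], bg, "codon"), 0)

  g <- withr::with_seed(6, random_gene(50))
  bgr <- build_composition(random_bundle(8, 60, seed = 7))
  # doubling a gene doubles every codon count: the normalized statistic is
  # exactly invariant for the codon unit
  expect_equal(chi2_bias(paste0(g, g), bgr, "codon"),
               chi2_bias(g, bgr, "codon"), tolerance = 1e-12)
  # for dinucleotides only the single junction word differs
  expect_equal(chi2_bias(paste0(g, g), bgr, "dinucleotide"),
               chi2_bias(g, bgr, "dinucleotide"), tolerance = 0.05)
  # unnormalized statistic scales with n instead
  expect_gt(chi2_bias(paste0(g, g), bgr, "codon", normalize = FALSE),
            1.9 * chi2_bias(g, bgr, "codon", normalize = FALSE))
})

test_that("JS divergence: zero at equality, 1 bit on disjoint supports, closed form", {
  b <- random_bundle(1, 60, seed = 8)
  bg <- build_composition(b)
  for (u in c("nucleotide", "dinucleotide", "codon"))
    expect_equal(js_divergence(b$genes$seq[1], bg, u), 0)

  # symmetrized supports {A,T} vs {C,G} are disjoint -> the JS maximum
  bg_c <- build_composition(genome_bundle("c", strrep("C", 30)))
  expect_equal(js_divergence(strrep("A", 30), bg_c, "nucleotide"), 1)

  # closed-form check: symmetrized all-A gene vs uniform background
  bg_u <- build_composition(genome_bundle("u", "ACGT"))
  p <- c(0.5, 0, 0, 0.5); q <- rep(0.25, 4); m <- (p + q) / 2
  H <- function(v) { v <- v[v > 0]; -sum(v * log2(v)) }
  expect_equal(js_divergence(strrep("A", 40), bg_u, "nucleotide"),
               H(m) - 0.5 * H(p) - 0.5 * H(q))
  expect_true(all(vapply(1:10, function(s) {
    g <- withr::with_seed(s, random_gene(30))
    j <- js_divergence(g, bg_u, "dinucleotide")
    j >= 0 && j <= 1
  }, logical(1))))
})

test_that("k-mer deviation: identity, swap symmetry, hand value, length guard", {
  b <- random_bundle(1, 60, seed = 9)
  bg <- build_composition(b)
  for (k in 1:7) expect_equal(kmer_deviation(b$genes$seq[1], bg, k), 0)

  bg_u <- build_composition(genome_bundle("u", "ACGT"))
  expect_equal(kmer_deviation("AAAA", bg_u, 1), 0.25)

  sa <- strrep("AACG", 20); sb <- strrep("TTGC", 20)
  expect_equal(kmer_deviation(sa, build_composition(genome_bundle("b", sb)), 3),
               kmer_deviation(sb, build_composition(genome_bundle("a", sa)), 3))
  expect_error(kmer_deviation("ATG", bg, 5), "k = 5")
})

test_that("feature vectors have the canonical shape and drop ineligible genes", {
  b <- random_bundle(30, 40, seed = 10)
  bg <- build_composition(b)
  for (i in 1:5) {
    v <- feature_vector(b$genes$seq[i], bg)
    expect_length(v, 15)
    expect_true(all(is.finite(v)))
    expect_identical(names(v), hgt_feature_names())
  }
  mixed <- genome_bundle(c("ok", "bad"), c(strrep("ATGAAACCC", 5), strrep("AT", 20)))
  expect_warning(ds <- feature_matrix(mixed), "not codon-eligible")
  expect_equal(ds$ids, "ok")
})

test_that("feature_matrix equals per-gene feature_vector on the same background", {
  b <- random_bundle(10, 50, seed = 11)
  bg <- build_composition(b)
  ds <- feature_matrix(b, bg)
  for (i in c(1, 5, 10))
    expect_equal(ds$x[i, ], feature_vector(b$genes$seq[i], bg), tolerance = 1e-12)
})

test_that("planted transferred genes score stochastically higher on the signal features", {
  b <- generate_genome(synthetic_spec(seed = 31))
  ds <- quiet_features(b)
  for (f in c("Karlin-DN", "JS-DN", "JS-CB")) {
    p <- stats::wilcox.test(ds$x[ds$label == "HGT", f],
                            ds$x[ds$label == "NATIVE", f],
                            alternative = "greater", exact = FALSE)$p.value
    expect_lt(p, 0.01)
  }
})
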