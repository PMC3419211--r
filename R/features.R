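# -- genome background composition and the 15 per-gene atypicality features

# the 61 sense codons (standard genetic code; stops excluded) and their
# amino acids, fixed at load time
GENETIC_CODE_TABLE <- Biostrings::GENETIC_CODE
SENSE_CODONS <- names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE != "*"]
STOP_CODONS <- names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE == "*"]
CODON_AA <- GENETIC_CODE_TABLE[SENSE_CODONS]

#' Canonical feature names
#'
#' The fifteen per-gene atypicality features, in the fixed order used by
#' feature matrices, masks and the GA chromosome: Karlin's dinucleotide
#' relative-abundance difference, Karlin's codon bias, positional GC
#' deviation (GC1-GC3 collapsed to one scalar), chi-squared dinucleotide
#' and codon biases, Jensen-Shannon divergence of the nucleotide,
#' dinucleotide and codon distributions, and the k-mer frequency
#' deviations for k = 1..7.
#'
#' @return Character vector of length 15.
#' @export
hgt_feature_names <- function() {
  c("Karlin-DN", "Karlin-CB", "GC1-GC3", "Chi2-DN", "Chi2-CB",
    "JS-N", "JS-DN", "JS-CB", paste0(1:7, "-mer"))
}

#' Build the genome-wide background composition
#'
#' Accumulates, over all genes of the bundle, strand-symmetrized k-mer
#' counts for k = 1..7 (each gene's sequence plus its reverse complement;
#' words containing N are not counted), sense-codon counts and positional
#' GC fractions (codon counts and positional GC use only genes whose
#' length is a multiple of 3), and per-amino-acid synonymous codon counts.
#'
#' @param bundle a [genome_bundle()].
#' @return An object of class `composition_model`.
#' @export
build_composition <- function(bundle) {
  stopifnot(inherits(bundle, "genome_bundle"))
  ss <- Biostrings::DNAStringSet(bundle$genes$seq)
  rc <- Biostrings::reverseComplement(ss)
  kmer_counts <- lapply(1:7, function(k) {
    colSums(Biostrings::oligonucleotideFrequency(ss, k)) +
      colSums(Biostrings::oligonucleotideFrequency(rc, k))
  })
  codon_ok <- nchar(bundle$genes$seq) %% 3 == 0 & nchar(bundle$genes$seq) >= 3
  if (any(codon_ok)) {
    cs <- ss[codon_ok]
    codon_counts <- colSums(Biostrings::oligonucleotideFrequency(cs, 3, step = 3))
    codon_counts <- codon_counts[SENSE_CODONS]
    pos_gc <- positional_gc(bundle$genes$seq[codon_ok])
  } else {
    codon_counts <- setNames(numeric(length(SENSE_CODONS)), SENSE_CODONS)
    pos_gc <- rep(NA_real_, 3)
  }
  structure(list(kmer_counts = kmer_counts,
                 codon_counts = codon_counts,
                 pos_gc = pos_gc,
                 n_codon_genes = sum(codon_ok),
                 total_len = sum(nchar(bundle$genes$seq))),
            class = "composition_model")
}

#' @export
print.composition_model <- function(x, ...) {
  cat(sprintf("composition_model: %d nt counted, %d codon-eligible genes\n",
              x$total_len, x$n_codon_genes))
  invisible(x)
}

# pooled G+C fraction at codon positions 1..3; N positions excluded from
# numerator and denominator
positional_gc <- function(seqs) {
  gc_num <- numeric(3); denom <- numeric(3)
  for (s in seqs) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    pos <- rep_len(1:3, length(ch))
    keep <- ch != "N"
    for (p in 1:3) {
      sel <- keep & pos == p
      denom[p] <- denom[p] + sum(sel)
      gc_num[p] <- gc_num[p] + sum(ch[sel] %in% c("G", "C"))
    }
  }
  ifelse(denom > 0, gc_num / denom, NA_real_)
}

# frequencies from counts; if positivity is required and any cell is zero,
# add the Jeffreys pseudocount 0.5 to every cell of the vector
safe_freq <- function(counts, need_all_positive = FALSE) {
  if (sum(counts) == 0) stop("no counted units")
  if (need_all_positive && any(counts == 0)) counts <- counts + 0.5
  counts / sum(counts)
}

# per-gene counting: strand-symmetrized k-mer counts for k = 1..7, sense
# codon counts, positional GC
gene_counts <- function(seq) {
  s <- Biostrings::DNAString(seq)
  r <- Biostrings::reverseComplement(s)
  sym <- lapply(1:7, function(k) {
    if (nchar(seq) < k) return(NULL)
    Biostrings::oligonucleotideFrequency(s, k) +
      Biostrings::oligonucleotideFrequency(r, k)
  })
  codon <- if (nchar(seq) %% 3 == 0 && nchar(seq) >= 3)
    Biostrings::oligonucleotideFrequency(s, 3, step = 3)[SENSE_CODONS]
  else NULL
  gcpos <- if (!is.null(codon)) {
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    pos <- rep_len(1:3, length(ch))
    vapply(1:3, function(p) {
      sel <- pos == p & ch != "N"
      if (!sum(sel)) return(NA_real_)
      mean(ch[sel] %in% c("G", "C"))
    }, numeric(1))
  } else NULL
  list(sym = sym, codon = codon, gcpos = gcpos, len = nchar(seq))
}

#' Karlin's dinucleotide relative-abundance difference
#'
#' `delta* = (1/16) * sum_XY | rho*_XY(gene) - rho*_XY(genome) |` where
#' `rho*_XY = f*_XY / (f*_X f*_Y)` and all frequencies are computed on the
#' sequence concatenated with its reverse complement (strand
#' symmetrization, Karlin's convention). Zero mononucleotide frequencies
#' are handled by the 0.5 pseudocount policy.
#'
#' @param seq a gene's nucleotide sequence (length >= 2).
#' @param bg a [build_composition()] model.
#' @return Non-negative scalar; 0 iff the gene's odds-ratio table equals
#'   the genome's.
#' @export
delta_star <- function(seq, bg) {
  gc <- gene_counts(seq)
  if (is.null(gc$sym[[2]])) stop("sequence shorter than 2 nt")
  delta_star_from_counts(gc$sym[[1]], gc$sym[[2]],
                         bg$kmer_counts[[1]], bg$kmer_counts[[2]])
}

delta_star_from_counts <- function(g1, g2, b1, b2) {
  f1 <- safe_freq(g1, need_all_positive = TRUE)
  f2 <- safe_freq(g2)
  h1 <- safe_freq(b1, need_all_positive = TRUE)
  h2 <- safe_freq(b2)
  dn <- names(f2)
  x <- substr(dn, 1, 1); y <- substr(dn, 2, 2)
  rho_f <- f2 / (f1[x] * f1[y])
  rho_g <- h2 / (h1[x] * h1[y])
  mean(abs(rho_f - rho_g))
}

#' Karlin's codon bias
#'
#' `B(gene|genome) = sum_a p_a(gene) * sum_{c in a} | f(c|a) - g(c|a) |`:
#' the amino-acid-frequency-weighted L1 distance between gene and genome
#' synonymous codon usage, conditional on the amino acid. Stop codons are
#' excluded; an amino acid unobserved in the genome falls back to uniform
#' synonymous usage. Bounded above by 2.
#'
#' @inheritParams delta_star
#' @return Scalar in `[0, 2]`.
#' @export
karlin_codon_bias <- function(seq, bg) {
  gc <- gene_counts(seq)
  if (is.null(gc$codon)) stop("gene length must be a multiple of 3")
  karlin_cb_from_counts(gc$codon, bg$codon_counts)
}

karlin_cb_from_counts <- function(cc, bgc) {
  total <- sum(cc)
  if (total == 0) stop("gene has no sense codons")
  B <- 0
  for (a in unique(CODON_AA)) {
    codons_a <- SENSE_CODONS[CODON_AA == a]
    na <- sum(cc[codons_a])
    if (na == 0) next
    f_ca <- cc[codons_a] / na
    bg_tot <- sum(bgc[codons_a])
    g_ca <- if (bg_tot > 0) bgc[codons_a] / bg_tot
            else rep(1 / length(codons_a), length(codons_a))
    B <- B + (na / total) * sum(abs(f_ca - g_ca))
  }
  B
}

#' G+C fraction at the three codon positions
#'
#' @inheritParams delta_star
#' @return `c(gc1, gc2, gc3)`; positions containing N are excluded from
#'   numerator and denominator.
#' @export
gc_by_position <- function(seq) {
  if (nchar(seq) %% 3 != 0) stop("gene length not divisible by 3")
  gene_counts(seq)$gcpos
}

# collapsed positional-GC deviation: mean_i |gc_i(gene) - gc_i(genome)|
gc_dev_from_counts <- function(gcpos, bg) mean(abs(gcpos - bg$pos_gc))

#' Chi-squared compositional bias
#'
#' Pearson statistic `sum_i (O_i - E_i)^2 / E_i` of the gene's observed
#' unit counts against expectations from the genome background
#' (`E_i = n * g_i`), divided by the gene's unit count `n` so the feature
#' is comparable across gene lengths (`normalize = FALSE` gives the raw
#' statistic). Dinucleotide counts are strand-symmetrized; codon counts
#' are not. Background zeros co-occurring with gene observations trigger
#' the 0.5 pseudocount on the background vector; cells with `E_i = 0`
#' (only possible without pseudocount) are skipped.
#'
#' @inheritParams delta_star
#' @param unit `"dinucleotide"` or `"codon"`.
#' @param normalize divide by the gene's unit count (default TRUE).
#' @return Non-negative scalar; 0 iff gene frequencies equal the
#'   background exactly.
#' @export
chi2_bias <- function(seq, bg, unit = c("dinucleotide", "codon"),
                      normalize = TRUE) {
  unit <- match.arg(unit)
  gc <- gene_counts(seq)
  if (unit == "dinucleotide") {
    if (is.null(gc$sym[[2]])) stop("sequence shorter than 2 nt")
    chi2_from_counts(gc$sym[[2]], bg$kmer_counts[[2]], normalize)
  } else {
    if (is.null(gc$codon)) stop("gene length must be a multiple of 3")
    chi2_from_counts(gc$codon, bg$codon_counts, normalize)
  }
}

chi2_from_counts <- function(obs, bgc, normalize = TRUE) {
  n <- sum(obs)
  if (n == 0) stop("gene has no counted units")
  if (any(obs > 0 & bgc == 0)) bgc <- bgc + 0.5
  g <- bgc / sum(bgc)
  e <- n * g
  keep <- e > 0
  stat <- sum((obs[keep] - e[keep])^2 / e[keep])
  if (normalize) stat / n else stat
}

#' Jensen-Shannon divergence between gene and genome composition
#'
#' `JS(P, Q) = H(w1 P + w2 Q) - w1 H(P) - w2 H(Q)` with Shannon entropy
#' `H` in bits and equal weights `w1 = w2 = 1/2`, so the value lies in
#' `[0, 1]` and reaches 1 only on disjoint supports. `P` is the gene's
#' unit distribution, `Q` the genome's; nucleotide and dinucleotide
#' distributions are strand-symmetrized, the codon distribution is not.
#'
#' @inheritParams delta_star
#' @param unit `"nucleotide"`, `"dinucleotide"` or `"codon"`.
#' @param weights `"equal"` (default) or `"length"` (weights proportional
#'   to gene/genome unit totals).
#' @return JS divergence in bits, in `[0, 1]`.
#' @export
js_divergence <- function(seq, bg, unit = c("nucleotide", "dinucleotide", "codon"),
                          weights = c("equal", "length")) {
  unit <- match.arg(unit); weights <- match.arg(weights)
  gc <- gene_counts(seq)
  cnt <- switch(unit,
    nucleotide = list(gc$sym[[1]], bg$kmer_counts[[1]]),
    dinucleotide = list(gc$sym[[2]], bg$kmer_counts[[2]]),
    codon = list(gc$codon, bg$codon_counts))
  if (is.null(cnt[[1]]))
    stop("gene not eligible for unit '", unit, "'")
  w1 <- if (weights == "equal") 0.5 else sum(cnt[[1]]) / (sum(cnt[[1]]) + sum(cnt[[2]]))
  js_from_counts(cnt[[1]], cnt[[2]], w1)
}

shannon_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

js_from_counts <- function(c1, c2, w1 = 0.5) {
  p <- safe_freq(c1); q <- safe_freq(c2)
  m <- w1 * p + (1 - w1) * q
  max(0, shannon_bits(m) - w1 * shannon_bits(p) - (1 - w1) * shannon_bits(q))
}

#' k-mer frequency deviation from the genome background
#'
#' `(1/4^k) * sum_w | f_w(gene) - f_w(genome) |` over all `4^k` words,
#' with strand-symmetrized frequencies on both sides.
#'
#' @inheritParams delta_star
#' @param k word length, 1..7.
#' @return Non-negative scalar; 0 iff the distributions are identical.
#' @export
kmer_deviation <- function(seq, bg, k) {
  stopifnot(k >= 1, k <= 7)
  if (nchar(seq) < k) stop("gene shorter than k = ", k)
  gc <- gene_counts(seq)
  kmer_dev_from_counts(gc$sym[[k]], bg$kmer_counts[[k]], k)
}

kmer_dev_from_counts <- function(gcnt, bcnt, k) {
  mean(abs(safe_freq(gcnt) - safe_freq(bcnt)))
}

# all 15 features from precomputed per-gene counts
features_from_counts <- function(gc, bg) {
  if (is.null(gc$codon) || sum(gc$codon) == 0)
    stop("gene not codon-eligible (length must be a multiple of 3 with >= 1 sense codon)")
  if (gc$len < 7) stop("gene shorter than 7 nt")
  v <- c(
    delta_star_from_counts(gc$sym[[1]], gc$sym[[2]],
                           bg$kmer_counts[[1]], bg$kmer_counts[[2]]),
    karlin_cb_from_counts(gc$codon, bg$codon_counts),
    gc_dev_from_counts(gc$gcpos, bg),
    chi2_from_counts(gc$sym[[2]], bg$kmer_counts[[2]]),
    chi2_from_counts(gc$codon, bg$codon_counts),
    js_from_counts(gc$sym[[1]], bg$kmer_counts[[1]]),
    js_from_counts(gc$sym[[2]], bg$kmer_counts[[2]]),
    js_from_counts(gc$codon, bg$codon_counts),
    vapply(1:7, function(k) kmer_dev_from_counts(gc$sym[[k]], bg$kmer_counts[[k]], k),
           numeric(1)))
  setNames(v, hgt_feature_names())
}

#' Compute the 15-feature vector for one gene
#'
#' Features in canonical [hgt_feature_names()] order. The gene must be
#' codon-eligible: length a multiple of 3, at least 7 nt, and at least one
#' sense codon.
#'
#' @inheritParams delta_star
#' @return Named numeric vector of length 15, all finite.
#' @export
feature_vector <- function(seq, bg) {
  features_from_counts(gene_counts(seq), bg)
}

#' Compute the feature matrix for a whole genome bundle
#'
#' Builds (or reuses) the genome background and scores every
#' codon-eligible gene with the 15 atypicality features. Genes that are
#' not codon-eligible are dropped with a warning.
#'
#' @param bundle a [genome_bundle()].
#' @param bg optional precomputed [build_composition()] model; defaults to
#'   the bundle's own background.
#' @return An [hgt_dataset()] with the raw GC1/GC2/GC3 triple attached as
#'   `gc_raw`.
#' @export
feature_matrix <- function(bundle, bg = NULL) {
  stopifnot(inherits(bundle, "genome_bundle"))
  if (is.null(bg)) bg <- build_composition(bundle)
  len <- nchar(bundle$genes$seq)
  ok <- len %% 3 == 0 & len >= 9
  if (any(!ok))
    warning(sum(!ok), " gene(s) dropped: not codon-eligible")
  genes <- bundle$genes[ok, , drop = FALSE]
  if (!nrow(genes)) stop("no codon-eligible genes")

  ss <- Biostrings::DNAStringSet(genes$seq)
  rc <- Biostrings::reverseComplement(ss)
  sym <- lapply(1:7, function(k) {
    Biostrings::oligonucleotideFrequency(ss, k) +
      Biostrings::oligonucleotideFrequency(rc, k)
  })
  codons <- Biostrings::oligonucleotideFrequency(ss, 3, step = 3)[, SENSE_CODONS, drop = FALSE]

  n <- nrow(genes)
  x <- matrix(NA_real_, n, 15, dimnames = list(genes$id, hgt_feature_names()))
  gc_raw <- matrix(NA_real_, n, 3, dimnames = list(genes$id, c("GC1", "GC2", "GC3")))
  for (i in seq_len(n)) {
    ch <- strsplit(genes$seq[i], "", fixed = TRUE)[[1]]
    pos <- rep_len(1:3, length(ch))
    gcpos <- vapply(1:3, function(p) {
      sel <- pos == p & ch != "N"
      if (!sum(sel)) return(NA_real_)
      mean(ch[sel] %in% c("G", "C"))
    }, numeric(1))
    gc <- list(sym = lapply(sym, function(m) m[i, ]),
               codon = codons[i, ], gcpos = gcpos, len = nchar(genes$seq[i]))
    x[i, ] <- features_from_counts(gc, bg)
    gc_raw[i, ] <- gcpos
  }
  hgt_dataset(x = x, ids = genes$id, label = genes$label, gc_raw = gc_raw)
}
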