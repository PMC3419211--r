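# independent, naively-written recomputation of the 15 features, used as
# the oracle for the feature-equivalence checks; shares no code with the
# package (its own reverse complement, codon table and counting loops)

ORACLE_CODE <- local({
  b <- c("T", "C", "A", "G")
  codons <- paste0(rep(b, each = 16), rep(rep(b, each = 4), 4), rep(b, 16))
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  stats::setNames(aa, codons)
})
ORACLE_SENSE <- names(ORACLE_CODE)[ORACLE_CODE != "*"]

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# all 4^k words in a fixed order
oracle_words <- function(k) {
  w <- c("A", "C", "G", "T")
  for (i in seq_len(k - 1)[k > 1])
    w <- as.vector(outer(w, c("A", "C", "G", "T"), paste0))
  sort(w)
}

# sliding-window k-mer counts of one strand; windows containing N skipped
# (tabulated via factor levels -- no shared code with the package's path)
oracle_count_one <- function(s, k) {
  lv <- oracle_words(k)
  if (nchar(s) < k)
    return(stats::setNames(numeric(length(lv)), lv))
  w <- substring(s, 1:(nchar(s) - k + 1), k:nchar(s))
  w <- w[!grepl("N", w, fixed = TRUE)]
  out <- table(factor(w, levels = lv))
  stats::setNames(as.numeric(out), lv)
}

oracle_sym_counts <- function(s, k) {
  oracle_count_one(s, k) + oracle_count_one(oracle_revcomp(s), k)
}

oracle_codon_counts <- function(s) {
  out <- stats::setNames(numeric(length(ORACLE_SENSE)), ORACLE_SENSE)
  for (i in seq(1, nchar(s) - 2, by = 3)) {
    w <- substr(s, i, i + 2)
    if (w %in% ORACLE_SENSE) out[w] <- out[w] + 1
  }
  out
}

oracle_gc_pos <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  sapply(1:3, function(p) {
    sel <- seq_along(ch)[(seq_along(ch) - 1) %% 3 + 1 == p]
    sel <- sel[ch[sel] != "N"]
    mean(ch[sel] %in% c("G", "C"))
  })
}

# background accumulated over bundle sequences, mirroring the documented
# conventions: symmetrized k-mers over all genes; codons and positional GC
# over genes with length a multiple of 3
oracle_background <- function(seqs) {
  km <- lapply(1:7, function(k) Reduce(`+`, lapply(seqs, oracle_sym_counts, k)))
  cod_ok <- seqs[nchar(seqs) %% 3 == 0]
  cod <- Reduce(`+`, lapply(cod_ok, oracle_codon_counts))
  num <- numeric(3); den <- numeric(3)
  for (s in cod_ok) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    pos <- (seq_along(ch) - 1) %% 3 + 1
    for (p in 1:3) {
      sel <- pos == p & ch != "N"
      den[p] <- den[p] + sum(sel)
      num[p] <- num[p] + sum(ch[sel] %in% c("G", "C"))
    }
  }
  list(kmer = km, codon = cod, pos_gc = num / den)
}

oracle_freq <- function(counts, pseudo_if_zero = FALSE) {
  if (pseudo_if_zero && any(counts == 0)) counts <- counts + 0.5
  counts / sum(counts)
}

oracle_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

oracle_js <- function(c1, c2) {
  p <- oracle_freq(c1); q <- oracle_freq(c2)
  m <- (p + q) / 2
  max(0, oracle_entropy(m) - 0.5 * oracle_entropy(p) - 0.5 * oracle_entropy(q))
}

oracle_chi2 <- function(obs, bgc) {
  n <- sum(obs)
  if (any(obs > 0 & bgc == 0)) bgc <- bgc + 0.5
  e <- n * bgc / sum(bgc)
  sum(((obs - e)^2 / e)[e > 0]) / n
}

oracle_delta_star <- function(g1, g2, b1, b2) {
  f1 <- oracle_freq(g1, TRUE); f2 <- oracle_freq(g2)
  h1 <- oracle_freq(b1, TRUE); h2 <- oracle_freq(b2)
  total <- 0
  for (x in c("A", "C", "G", "T")) for (y in c("A", "C", "G", "T")) {
    xy <- paste0(x, y)
    total <- total + abs(f2[xy] / (f1[x] * f1[y]) - h2[xy] / (h1[x] * h1[y]))
  }
  total / 16
}

oracle_karlin_cb <- function(cc, bgc) {
  total <- sum(cc)
  B <- 0
  for (a in unique(ORACLE_CODE[ORACLE_CODE != "*"])) {
    ca <- ORACLE_SENSE[ORACLE_CODE[ORACLE_SENSE] == a]
    na <- sum(cc[ca])
    if (na == 0) next
    g <- if (sum(bgc[ca]) > 0) bgc[ca] / sum(bgc[ca]) else rep(1 / length(ca), length(ca))
    B <- B + (na / total) * sum(abs(cc[ca] / na - g))
  }
  B
}

# all 15 features of one gene against an oracle_background()
oracle_features <- function(s, obg) {
  sym <- lapply(1:7, function(k) oracle_sym_counts(s, k))
  cod <- oracle_codon_counts(s)
  c(oracle_delta_star(sym[[1]], sym[[2]], obg$kmer[[1]], obg$kmer[[2]]),
    oracle_karlin_cb(cod, obg$codon),
    mean(abs(oracle_gc_pos(s) - obg$pos_gc)),
    oracle_chi2(sym[[2]], obg$kmer[[2]]),
    oracle_chi2(cod, obg$codon),
    oracle_js(sym[[1]], obg$kmer[[1]]),
    oracle_js(sym[[2]], obg$kmer[[2]]),
    oracle_js(cod, obg$codon),
    sapply(1:7, function(k) mean(abs(oracle_freq(sym[[k]]) - oracle_freq(obg$kmer[[k]])))))
}
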