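# -- synthetic genomes with planted horizontally transferred genes

AA_ALPHABET <- sort(unique(unname(CODON_AA)))   # 20 standard amino acids

# number of G/C bases in each codon
codon_gc_count <- function(codons) {
  vapply(strsplit(codons, "", fixed = TRUE),
         function(ch) sum(ch %in% c("G", "C")), numeric(1))
}

# a codon-level composition model: per-amino-acid synonymous codon
# preferences plus stop-codon preferences. `epsilon` reweights synonymous
# usage with a seed-deterministic N(0,1) pattern; `delta_gc` shifts the
# expected G+C fraction away from the unperturbed uniform-synonymous
# model by exponential tilting of codon weights (lambda solved so the
# expectation matches exactly).
codon_model <- function(delta_gc = 0, epsilon = 0, seed = 1) {
  base <- setNames(rep(1, length(SENSE_CODONS)), SENSE_CODONS)
  if (epsilon > 0) {
    z <- with_seed(derive_seed(seed, 101),
                   setNames(rnorm(length(SENSE_CODONS)), SENSE_CODONS))
    base <- exp(epsilon * z)
  }
  stop_pref <- setNames(rep(1, length(STOP_CODONS)), STOP_CODONS)

  norm_by_aa <- function(w) {
    for (a in AA_ALPHABET) {
      sel <- SENSE_CODONS[CODON_AA == a]
      w[sel] <- w[sel] / sum(w[sel])
    }
    w
  }
  pref <- norm_by_aa(base)
  gc_codon <- codon_gc_count(SENSE_CODONS)
  p_aa <- setNames(rep(1 / length(AA_ALPHABET), length(AA_ALPHABET)), AA_ALPHABET)

  expected_gc <- function(w) {
    e <- 0
    for (a in AA_ALPHABET) {
      sel <- CODON_AA == a
      e <- e + p_aa[a] * sum(w[SENSE_CODONS[sel]] * gc_codon[sel])
    }
    unname(e / 3)
  }

  # reference point: the unperturbed uniform-synonymous model
  g0 <- expected_gc(norm_by_aa(setNames(rep(1, length(SENSE_CODONS)), SENSE_CODONS)))
  target <- g0 + delta_gc
  lo <- expected_gc(norm_by_aa(pref * exp(-30 * gc_codon)))
  hi <- expected_gc(norm_by_aa(pref * exp(30 * gc_codon)))
  if (target <= lo || target >= hi)
    stop("infeasible delta_gc = ", delta_gc, ": attainable GC range is (",
         round(lo, 3), ", ", round(hi, 3), ")")
  lambda <- uniroot(function(l) expected_gc(norm_by_aa(pref * exp(l * gc_codon))) - target,
                    c(-30, 30), tol = 1e-10)$root
  pref <- norm_by_aa(pref * exp(lambda * gc_codon))
  stop_pref <- stop_pref * exp(lambda * codon_gc_count(STOP_CODONS))
  stop_pref <- stop_pref / sum(stop_pref)

  list(pref = pref, stop_pref = stop_pref, expected_gc = target,
       delta_gc = delta_gc, epsilon = epsilon)
}

#' Specification of a synthetic genome with planted transferred genes
#'
#' The generated genome emulates a recipient of `n_genes` coding
#' sequences drawn from one background codon-usage model, with a minority
#' fraction of planted horizontally transferred genes drawn from a
#' compositionally divergent donor model. Donor divergence is controlled
#' by `delta_gc` (shift of expected G+C fraction) and `epsilon`
#' (perturbation strength of synonymous codon usage); both zero makes
#' donor and recipient identical (the null case). Every gene starts with
#' ATG, ends with a stop codon, and contains no internal stop.
#'
#' @param n_genes number of genes (default 200).
#' @param hgt_fraction planted-HGT fraction in (0, 0.5); default 0.10,
#'   imbalanced as in real genomes.
#' @param gene_len_range gene length range in codons, excluding the stop
#'   (default 100-400).
#' @param delta_gc donor-vs-recipient expected GC shift (default 0.15).
#' @param epsilon donor synonymous-usage perturbation (default 0.8).
#' @param seed integer seed; generation is fully deterministic given it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 200, hgt_fraction = 0.10,
                           gene_len_range = c(100, 400),
                           delta_gc = 0.15, epsilon = 0.8, seed = 1) {
  stopifnot(n_genes >= 2, hgt_fraction > 0, hgt_fraction < 0.5,
            length(gene_len_range) == 2, gene_len_range[1] >= 2,
            gene_len_range[2] >= gene_len_range[1],
            delta_gc >= -0.5, delta_gc <= 0.5, epsilon >= 0)
  if (round(n_genes * hgt_fraction) < 1)
    stop("spec yields no minority genes")
  structure(list(n_genes = as.integer(n_genes), hgt_fraction = hgt_fraction,
                 gene_len_range = as.integer(gene_len_range),
                 delta_gc = delta_gc, epsilon = epsilon, seed = seed),
            class = "synthetic_spec")
}

#' Generate a labelled synthetic genome
#'
#' Amino-acid sequences are sampled uniformly over the 20 standard amino
#' acids (Met start enforced), codons per amino acid from the
#' recipient/donor codon-preference tables, and a stop codon appended.
#' `round(n_genes * hgt_fraction)` genes are labelled HGT and drawn from
#' the donor model; the rest are NATIVE from the recipient model. Gene
#' order is shuffled. Byte-identical output for equal seeds.
#'
#' @param spec a [synthetic_spec()].
#' @return A labelled [genome_bundle()] with attribute `"spec"`.
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  recipient <- codon_model(0, 0, spec$seed)
  donor <- if (spec$delta_gc == 0 && spec$epsilon == 0) recipient
           else codon_model(spec$delta_gc, spec$epsilon, spec$seed)
  n_hgt <- round(spec$n_genes * spec$hgt_fraction)

  with_seed(spec$seed, {
    label <- sample(c(rep("HGT", n_hgt), rep("NATIVE", spec$n_genes - n_hgt)))
    lens <- sample(seq(spec$gene_len_range[1], spec$gene_len_range[2]),
                   spec$n_genes, replace = TRUE)
    seqs <- vapply(seq_len(spec$n_genes), function(i) {
      m <- if (label[i] == "HGT") donor else recipient
      aa <- c("M", sample(AA_ALPHABET, lens[i] - 1, replace = TRUE))
      codons <- character(lens[i])
      for (a in unique(aa)) {
        sel <- SENSE_CODONS[CODON_AA == a]
        codons[aa == a] <- sample(sel, sum(aa == a), replace = TRUE,
                                  prob = m$pref[sel])
      }
      stopc <- sample(STOP_CODONS, 1, prob = m$stop_pref)
      paste(c(codons, stopc), collapse = "")
    }, character(1))
    bundle <- genome_bundle(id = sprintf("gene_%04d", seq_len(spec$n_genes)),
                            seq = seqs, label = label,
                            genome_id = sprintf("synthetic_seed%s", spec$seed))
    attr(bundle, "spec") <- spec
    bundle
  })
}

#' Benchmark suite of synthetic genomes at graded difficulty
#'
#' Three fixed specifications sharing `n_genes = 200`, 10% planted HGT
#' and 100-400 codon genes, with decreasing donor divergence:
#' easy (`delta_gc = 0.15`, `epsilon = 0.8`), medium (0.08, 0.4) and
#' hard (0.03, 0.15).
#'
#' @param seed integer seed (per-difficulty seeds are derived from it).
#' @return Named list of [synthetic_spec()] objects.
#' @export
benchmark_suite <- function(seed = 1) {
  list(easy = synthetic_spec(delta_gc = 0.15, epsilon = 0.8,
                             seed = derive_seed(seed, 1)),
       medium = synthetic_spec(delta_gc = 0.08, epsilon = 0.4,
                               seed = derive_seed(seed, 2)),
       hard = synthetic_spec(delta_gc = 0.03, epsilon = 0.15,
                             seed = derive_seed(seed, 3)))
}

#' Write a genome bundle as FASTA (+ optional label TSV)
#'
#' @param bundle a [genome_bundle()].
#' @param fasta_path output FASTA path.
#' @param labels_path optional path for a two-column (id, label) TSV of
#'   the HGT/NATIVE genes.
#' @return `fasta_path`, invisibly.
#' @export
write_genome_fasta <- function(bundle, fasta_path, labels_path = NULL) {
  stopifnot(inherits(bundle, "genome_bundle"))
  ss <- Biostrings::DNAStringSet(setNames(bundle$genes$seq, bundle$genes$id))
  Biostrings::writeXStringSet(ss, fasta_path)
  if (!is.null(labels_path)) {
    known <- bundle$genes$label != "UNKNOWN"
    write.table(bundle$genes[known, c("id", "label")], labels_path,
                sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(fasta_path)
}
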