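#' Gene and genome containers
#'
#' A `genome_bundle` holds the annotated coding sequences (CDS) of one
#' genome: a data frame with columns `id` (unique, non-empty), `seq`
#' (coding-strand, frame-0 nucleotide string over A/C/G/T/N) and `label`
#' (one of `"HGT"`, `"NATIVE"`, `"UNKNOWN"`). All sequences are stored
#' uppercased with U mapped to T and any other ambiguity code mapped to N;
#' minus-strand CDS must already be reverse-complemented to the sense
#' strand (the GenBank reader does this).
#'
#' @param id character vector of unique gene identifiers.
#' @param seq character vector of nucleotide sequences (same length as `id`).
#' @param label gene labels, recycled; default `"UNKNOWN"`.
#' @param genome_id single string naming the genome.
#' @return An object of class `genome_bundle`.
#' @export
genome_bundle <- function(id, seq, label = "UNKNOWN", genome_id = "genome") {
  stopifnot(length(id) == length(seq), is.character(id), is.character(seq))
  if (any(!nzchar(id))) stop("gene ids must be non-empty")
  dup <- unique(id[duplicated(id)])
  if (length(dup)) stop("duplicate gene id(s): ", paste(dup, collapse = ", "))
  label <- rep_len(as.character(label), length(id))
  if (!all(label %in% c("HGT", "NATIVE", "UNKNOWN")))
    stop("labels must be HGT, NATIVE or UNKNOWN")
  seq <- normalize_seq(seq)
  structure(list(genome_id = genome_id,
                 genes = data.frame(id = id, seq = seq, label = label,
                                    stringsAsFactors = FALSE)),
            class = "genome_bundle")
}

#' @export
print.genome_bundle <- function(x, ...) {
  cat(sprintf("genome_bundle '%s': %d genes (%s)\n", x$genome_id,
              nrow(x$genes),
              paste(sprintf("%s=%d", names(table(x$genes$label)),
                            as.integer(table(x$genes$label))), collapse = ", ")))
  invisible(x)
}

# uppercase, U->T, non-ACGTN -> N (count reported once per call)
normalize_seq <- function(seq) {
  seq <- toupper(seq)
  seq <- gsub("U", "T", seq, fixed = TRUE)
  bad <- vapply(gregexpr("[^ACGTN]", seq), function(m) sum(m > 0L), integer(1))
  if (sum(bad) > 0) {
    message(sum(bad), " ambiguous base(s) mapped to N")
    seq <- gsub("[^ACGTN]", "N", seq)
  }
  seq
}

#' Read coding sequences from a multi-FASTA file
#'
#' The first whitespace-delimited token of each header is taken as the gene
#' id. All genes are labelled `UNKNOWN`; use [attach_labels()] to add
#' known HGT/NATIVE calls.
#'
#' @param path path to a multi-FASTA file of in-frame CDS.
#' @param genome_id genome name; defaults to the file name.
#' @return A [genome_bundle()].
#' @export
read_cds_fasta <- function(path, genome_id = basename(path)) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(ss), "[ \t]+"), `[`, character(1), 1L)
  genome_bundle(id = ids, seq = as.character(ss), genome_id = genome_id)
}

#' Read coding sequences from a GenBank flat file
#'
#' Extracts every CDS feature from a GenBank record: locations (including
#' `complement(...)` and `join(...)`) are resolved against the ORIGIN
#' sequence, minus-strand CDS are reverse-complemented so every stored
#' sequence is the sense/coding strand. Ids are taken from `locus_tag`,
#' falling back to `protein_id`, then a positional `CDS_<n>` tag. A CDS
#' whose location cannot be resolved is skipped with a warning.
#'
#' @param path path to a GenBank flat file containing one record.
#' @return A [genome_bundle()].
#' @export
read_genbank_cds <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  genome_id <- if (length(locus)) strsplit(locus[1], "[ \t]+")[[1]][2] else basename(path)

  ori <- grep("^ORIGIN", lines)
  if (!length(ori)) stop("no ORIGIN sequence in ", path)
  seq_lines <- lines[(ori[1] + 1):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  genome_seq <- normalize_seq(paste(gsub("[^A-Za-z]", "", seq_lines), collapse = ""))

  cds_idx <- grep("^ {5}CDS {2,}", lines)
  if (!length(cds_idx)) stop("no CDS features in ", path)
  feat_idx <- grep("^ {5}\\S", lines)           # any feature key line

  ids <- character(0); seqs <- character(0)
  for (n in seq_along(cds_idx)) {
    i <- cds_idx[n]
    nxt <- feat_idx[feat_idx > i]
    end <- if (length(nxt)) min(c(nxt, ori[1])) - 1 else ori[1] - 1
    block <- lines[i:end]
    # location may continue over lines until the first qualifier ("/")
    qual_start <- grep("^ +/", block)
    loc_end <- if (length(qual_start)) qual_start[1] - 1 else length(block)
    loc <- paste(gsub("^ {5}CDS +| ", "", block[1:loc_end]), collapse = "")
    quals <- if (length(qual_start)) block[qual_start[1]:length(block)] else character(0)

    id <- gb_qualifier(quals, "locus_tag")
    if (is.na(id)) id <- gb_qualifier(quals, "protein_id")
    if (is.na(id)) id <- sprintf("CDS_%04d", n)

    cds_seq <- tryCatch(gb_extract(loc, genome_seq), error = function(e) {
      warning("skipping CDS '", id, "': ", conditionMessage(e)); NA_character_
    })
    if (is.na(cds_seq)) next
    ids <- c(ids, id); seqs <- c(seqs, cds_seq)
  }
  if (!length(ids)) stop("no CDS features could be resolved in ", path)
  genome_bundle(id = ids, seq = seqs, genome_id = genome_id)
}

gb_qualifier <- function(quals, key) {
  pat <- paste0("^ +/", key, "=\"([^\"]*)\"")
  hit <- grep(pat, quals, value = TRUE)
  if (!length(hit)) return(NA_character_)
  sub(pat, "\\1", hit[1])
}

# resolve a GenBank location string against the full genome sequence;
# coordinates are 1-based inclusive
gb_extract <- function(loc, genome_seq) {
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    inner <- sub("^complement\\((.*)\\)$", "\\1", loc)
    return(revcomp(gb_extract(inner, genome_seq)))
  }
  if (grepl("^(join|order)\\(", loc)) {
    inner <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
    parts <- split_toplevel(inner)
    return(paste(vapply(parts, gb_extract, character(1), genome_seq), collapse = ""))
  }
  if (grepl("^[0-9]+\\.\\.[0-9]+$", loc)) {
    ab <- as.integer(strsplit(loc, "..", fixed = TRUE)[[1]])
  } else if (grepl("^[0-9]+$", loc)) {
    ab <- c(as.integer(loc), as.integer(loc))
  } else stop("unresolvable location '", loc, "'")
  if (ab[1] < 1 || ab[2] > nchar(genome_seq) || ab[1] > ab[2])
    stop("location '", loc, "' outside sequence")
  substr(genome_seq, ab[1], ab[2])
}

# split on commas not nested inside parentheses
split_toplevel <- function(s) {
  chars <- strsplit(s, "")[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  cuts <- which(chars == "," & depth == 0)
  starts <- c(1, cuts + 1); ends <- c(cuts - 1, length(chars))
  mapply(function(a, b) paste(chars[a:b], collapse = ""), starts, ends)
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Attach HGT/NATIVE labels to a genome bundle
#'
#' @param bundle a [genome_bundle()].
#' @param labels named character vector (`id -> "HGT"|"NATIVE"`) or a
#'   two-column data frame `(id, label)`. If an id appears twice the last
#'   entry wins (with a warning). Unlisted genes keep `UNKNOWN`.
#' @return The relabelled bundle; per-label counts are reported via
#'   `message()` and available from `table(bundle$genes$label)`.
#' @export
attach_labels <- function(bundle, labels) {
  stopifnot(inherits(bundle, "genome_bundle"))
  if (is.data.frame(labels)) labels <- setNames(as.character(labels[[2]]), labels[[1]])
  if (is.null(names(labels)) || any(!nzchar(names(labels))))
    stop("labels must be named by gene id")
  if (anyDuplicated(names(labels))) {
    warning("duplicate ids in label mapping; last entry wins")
    labels <- labels[!duplicated(names(labels), fromLast = TRUE)]
  }
  if (!all(labels %in% c("HGT", "NATIVE")))
    stop("labels must be HGT or NATIVE")
  missing_ids <- setdiff(names(labels), bundle$genes$id)
  if (length(missing_ids))
    stop("label id(s) not in bundle: ", paste(missing_ids, collapse = ", "))
  idx <- match(names(labels), bundle$genes$id)
  bundle$genes$label[idx] <- unname(labels)
  counts <- table(bundle$genes$label)
  message(paste(sprintf("%s=%d", names(counts), as.integer(counts)), collapse = " "))
  bundle
}

#' Read a two-column label TSV (id, HGT|NATIVE)
#' @param path path to a headerless two-column TSV file.
#' @return Named character vector suitable for [attach_labels()].
#' @export
read_labels_tsv <- function(path) {
  d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  setNames(as.character(d[[2]]), as.character(d[[1]]))
}

#' Write / read a per-gene feature table
#'
#' Tab-separated with header `id`, the 15 canonical feature names (see
#' [hgt_feature_names()]) and `label`; numeric values at 10 significant
#' digits so that a write/read round trip is identity to 1e-9.
#'
#' @param dataset an `hgt_dataset` as returned by [feature_matrix()].
#' @param path output (or input) file path.
#' @return `read_feature_table()` returns an `hgt_dataset`.
#' @export
write_feature_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "hgt_dataset"))
  df <- data.frame(id = dataset$ids, check.names = FALSE, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(dataset$x)))
    df[[colnames(dataset$x)[j]]] <- sprintf("%.10g", dataset$x[, j])
  df$label <- dataset$label
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  want <- c("id", hgt_feature_names(), "label")
  miss <- setdiff(want, names(df))
  if (length(miss))
    stop("feature table is missing column(s): ", paste(miss, collapse = ", "))
  x <- as.matrix(as.data.frame(lapply(df[hgt_feature_names()], as.numeric)))
  colnames(x) <- hgt_feature_names()
  rownames(x) <- df$id
  hgt_dataset(x = x, ids = df$id, label = df$label)
}

#' Construct a labelled feature dataset
#'
#' @param x numeric matrix, one row per gene, 15 canonical feature columns.
#' @param ids gene ids (rownames of `x` if missing).
#' @param label per-gene labels.
#' @param synthetic logical flag marking SMOTE-generated rows.
#' @param gc_raw optional n x 3 matrix of raw GC1/GC2/GC3 values.
#' @return An object of class `hgt_dataset`.
#' @export
hgt_dataset <- function(x, ids = rownames(x), label, synthetic = NULL,
                        gc_raw = NULL) {
  x <- as.matrix(x)
  if (is.null(ids)) ids <- sprintf("row_%d", seq_len(nrow(x)))
  stopifnot(length(ids) == nrow(x), length(label) == nrow(x))
  if (is.null(synthetic)) synthetic <- rep(FALSE, nrow(x))
  structure(list(x = x, ids = as.character(ids), label = as.character(label),
                 synthetic = synthetic, gc_raw = gc_raw),
            class = "hgt_dataset")
}

#' @export
print.hgt_dataset <- function(x, ...) {
  cat(sprintf("hgt_dataset: %d genes x %d features (%s)\n", nrow(x$x), ncol(x$x),
              paste(sprintf("%s=%d", names(table(x$label)),
                            as.integer(table(x$label))), collapse = ", ")))
  invisible(x)
}
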