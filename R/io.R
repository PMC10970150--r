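#' Construct an alignment object
#'
#' An alignment holds equal-length haploid sequences for one non-recombining
#' locus (e.g. a chloroplast intergenic spacer). Sequences are stored as an
#' uppercase character matrix over the alphabet A, C, G, T, `-`, N; any IUPAC
#' ambiguity code other than N is recoded to N, and U is mapped to T.
#'
#' @param sequences character vector of equal-length sequence strings.
#' @param sample_ids character vector of unique sample identifiers.
#' @param locus_name name of the locus the alignment covers.
#' @return An object of class `cp_alignment` with elements `locus_name`,
#'   `sample_ids`, `seq` (samples x sites character matrix) and `length`.
#' @export
new_alignment <- function(sequences, sample_ids, locus_name = "locus") {
  if (length(sequences) == 0L) {
    stop("alignment must contain at least one sequence", call. = FALSE)
  }
  if (length(sample_ids) != length(sequences)) {
    stop("sample_ids and sequences differ in length", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  nc <- nchar(sequences)
  if (length(unique(nc)) != 1L) {
    stop("ragged alignment: sequence lengths ", paste(sort(unique(nc)), collapse = ", "),
         call. = FALSE)
  }
  if (nc[1] == 0L) stop("alignment has zero sites", call. = FALSE)
  m <- do.call(rbind, strsplit(toupper(sequences), "", fixed = TRUE))
  m[m == "U"] <- "T"
  m[!(m %in% c("A", "C", "G", "T", "-"))] <- "N"
  rownames(m) <- sample_ids
  structure(
    list(locus_name = locus_name, sample_ids = as.character(sample_ids),
         seq = m, length = ncol(m)),
    class = "cp_alignment"
  )
}

#' @export
print.cp_alignment <- function(x, ...) {
  cat("Alignment of locus '", x$locus_name, "': ", length(x$sample_ids),
      " sequences x ", x$length, " sites\n", sep = "")
  invisible(x)
}

#' Number of sequences in an alignment
#' @param a a `cp_alignment`.
#' @return integer count of sequences.
#' @export
n_sequences <- function(a) length(a$sample_ids)

# sequences as plain strings, in row order
alignment_strings <- function(a) {
  apply(a$seq, 1L, paste, collapse = "")
}

#' Read a FASTA alignment
#'
#' Reads a pre-aligned FASTA file. Records must all have the same length;
#' case is normalised to uppercase, U is mapped to T, and ambiguity codes
#' other than N become N. Record order is preserved.
#'
#' @param path path to a FASTA file.
#' @param locus_name locus label stored in the returned alignment; defaults
#'   to the file name without extension.
#' @return A [new_alignment()] object.
#' @export
read_alignment <- function(path, locus_name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(locus_name)) {
    locus_name <- sub("\\.[^.]*$", "", basename(path))
  }
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(x))
  new_alignment(as.character(x), ids, locus_name)
}

#' Write an alignment to FASTA
#'
#' @param a a `cp_alignment`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(a, path) {
  lines <- character(2L * length(a$sample_ids))
  lines[c(TRUE, FALSE)] <- paste0(">", a$sample_ids)
  lines[c(FALSE, TRUE)] <- alignment_strings(a)
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample metadata table
#'
#' The table is a TSV with header columns `sample_id`, `population`,
#' `longitude`, `latitude`, `elevation` (degrees East, degrees North, metres).
#' Population codes are kept verbatim.
#'
#' @param path path to the TSV file.
#' @return A data frame with one row per sample.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  s <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_sample_table(s)
}

#' Validate a sample metadata table
#'
#' @param s a data frame with columns `sample_id`, `population`, `longitude`,
#'   `latitude`, `elevation`.
#' @return `s`, with `sample_id` and `population` coerced to character.
#' @export
validate_sample_table <- function(s) {
  needed <- c("sample_id", "population", "longitude", "latitude", "elevation")
  missing_cols <- setdiff(needed, names(s))
  if (length(missing_cols)) {
    stop("sample table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  s$sample_id <- as.character(s$sample_id)
  s$population <- as.character(s$population)
  if (anyDuplicated(s$sample_id)) {
    stop("duplicate sample_id in sample table", call. = FALSE)
  }
  if (any(is.na(s$population) | s$population == "")) {
    stop("empty population code in sample table", call. = FALSE)
  }
  if (any(is.finite(s$elevation) & s$elevation < 0)) {
    stop("negative elevation in sample table", call. = FALSE)
  }
  s
}

#' Mask alignment sites containing gaps or ambiguities
#'
#' With the default `"complete"` policy every site (column) that carries a
#' `-` or N in any sequence is removed, so all downstream statistics (the
#' haplotype partition, diversity, difference counts) describe the same fully
#' resolved sites. The `"pairwise"` policy keeps all sites and leaves
#' per-statistic handling to the caller.
#'
#' @param a a `cp_alignment`.
#' @param policy `"complete"` (complete deletion, default) or `"pairwise"`.
#' @return A `cp_alignment` with the same samples.
#' @export
clean_alignment <- function(a, policy = c("complete", "pairwise")) {
  policy <- match.arg(policy)
  if (policy == "pairwise") return(a)
  keep <- apply(a$seq, 2L, function(col) all(col %in% c("A", "C", "G", "T")))
  if (!any(keep)) {
    stop("complete deletion removed every site of locus '", a$locus_name, "'",
         call. = FALSE)
  }
  m <- a$seq[, keep, drop = FALSE]
  structure(
    list(locus_name = a$locus_name, sample_ids = a$sample_ids,
         seq = m, length = ncol(m)),
    class = "cp_alignment"
  )
}

#' Concatenate two single-locus alignments
#'
#' Joins per-sample sequences in (a, b) order. Both alignments must cover the
#' same sample set; samples are returned in `a`'s order.
#'
#' @param a,b `cp_alignment` objects over identical sample sets.
#' @param locus_name label for the concatenated locus.
#' @return A `cp_alignment` of length `a$length + b$length`.
#' @export
concat_alignments <- function(a, b,
                              locus_name = paste(a$locus_name, b$locus_name,
                                                 sep = "+")) {
  missing_in_b <- setdiff(a$sample_ids, b$sample_ids)
  missing_in_a <- setdiff(b$sample_ids, a$sample_ids)
  if (length(missing_in_b) || length(missing_in_a)) {
    stop("sample sets differ; missing in second alignment: ",
         paste(missing_in_b, collapse = ", "),
         "; missing in first: ", paste(missing_in_a, collapse = ", "),
         call. = FALSE)
  }
  m <- cbind(a$seq, b$seq[a$sample_ids, , drop = FALSE])
  rownames(m) <- a$sample_ids
  structure(
    list(locus_name = locus_name, sample_ids = a$sample_ids,
         seq = m, length = ncol(m)),
    class = "cp_alignment"
  )
}

#' Collapse aligned sequences into haplotypes
#'
#' Two samples share a haplotype iff their cleaned sequences are identical at
#' all retained sites (complete deletion of gap/ambiguity sites is applied
#' first). Haplotypes are labelled H1..Hk by descending overall abundance,
#' ties broken by first occurrence in input order, so labelling is
#' deterministic.
#'
#' @param a a `cp_alignment`.
#' @param s a sample table covering every sample in `a` (see
#'   [read_sample_table()]).
#' @return An object of class `haplotype_table`: list with `haplotype_ids`,
#'   `haplotype_seqs` (named character vector), `counts` (population x
#'   haplotype integer matrix) and `locus_name`.
#' @export
collapse_haplotypes <- function(a, s) {
  s <- validate_sample_table(s)
  missing <- setdiff(a$sample_ids, s$sample_id)
  if (length(missing)) {
    stop("samples absent from sample table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  a <- clean_alignment(a)
  seqs <- alignment_strings(a)
  first_seen <- !duplicated(seqs)
  uniq <- seqs[first_seen]
  idx <- match(seqs, uniq)
  abundance <- tabulate(idx, nbins = length(uniq))
  ord <- order(-abundance, seq_along(uniq)) # ties: first occurrence wins
  uniq <- uniq[ord]
  idx <- match(seqs, uniq)
  k <- length(uniq)
  hap_ids <- paste0("H", seq_len(k))
  names(uniq) <- hap_ids
  pop <- s$population[match(a$sample_ids, s$sample_id)]
  pops <- unique(pop)
  counts <- matrix(0L, nrow = length(pops), ncol = k,
                   dimnames = list(pops, hap_ids))
  tab <- table(factor(pop, levels = pops), factor(idx, levels = seq_len(k)))
  counts[] <- as.integer(tab)
  structure(
    list(haplotype_ids = hap_ids, haplotype_seqs = uniq, counts = counts,
         locus_name = a$locus_name),
    class = "haplotype_table"
  )
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("Haplotype table for locus '", x$locus_name, "': ",
      length(x$haplotype_ids), " haplotypes in ", nrow(x$counts),
      " populations (", sum(x$counts), " samples)\n", sep = "")
  invisible(x)
}

#' Per-population haplotype frequencies
#'
#' @param h a `haplotype_table`.
#' @return Matrix of per-population relative frequencies; rows of populations
#'   with at least one sample sum to 1.
#' @export
haplotype_frequencies <- function(h) {
  n <- rowSums(h$counts)
  f <- sweep(h$counts, 1L, pmax(n, 1L), "/")
  f[n == 0L, ] <- NA_real_
  f
}

#' Write a haplotype table to FASTA and TSV
#'
#' Writes the distinct haplotype sequences as FASTA and the population x
#' haplotype count matrix as a TSV (first column `population`). The pair of
#' files round-trips losslessly through [read_haplotypes()].
#'
#' @param h a `haplotype_table`.
#' @param fasta_path,counts_path output paths.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_haplotypes <- function(h, fasta_path, counts_path) {
  if (length(h$haplotype_ids) == 0L) stop("empty haplotype table", call. = FALSE)
  lines <- character(2L * length(h$haplotype_ids))
  lines[c(TRUE, FALSE)] <- paste0(">", h$haplotype_ids)
  lines[c(FALSE, TRUE)] <- unname(h$haplotype_seqs)
  writeLines(lines, fasta_path)
  df <- data.frame(population = rownames(h$counts), h$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta = fasta_path, counts = counts_path))
}

#' Read a haplotype table written by [write_haplotypes()]
#'
#' @param fasta_path,counts_path paths written by [write_haplotypes()].
#' @param locus_name locus label for the restored table.
#' @return A `haplotype_table`.
#' @export
read_haplotypes <- function(fasta_path, counts_path, locus_name = "locus") {
  a <- read_alignment(fasta_path, locus_name)
  df <- utils::read.delim(counts_path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df$population
  hap_ids <- a$sample_ids
  if (!identical(sort(colnames(counts)), sort(hap_ids))) {
    stop("haplotype FASTA and count table disagree on haplotype ids",
         call. = FALSE)
  }
  counts <- counts[, hap_ids, drop = FALSE]
  seqs <- alignment_strings(a)
  names(seqs) <- hap_ids
  structure(
    list(haplotype_ids = hap_ids, haplotype_seqs = seqs, counts = counts,
         locus_name = locus_name),
    class = "haplotype_table"
  )
}

# subset an alignment to a set of sample ids (kept in alignment order)
subset_alignment <- function(a, ids) {
  keep <- a$sample_ids %in% ids
  structure(
    list(locus_name = a$locus_name, sample_ids = a$sample_ids[keep],
         seq = a$seq[keep, , drop = FALSE], length = a$length),
    class = "cp_alignment"
  )
}
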