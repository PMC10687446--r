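# Parent-specific k-mer (hap-mer) extraction and trio-binning of long
# reads.  K-mers are counted canonically (lexicographic min of the k-mer
# and its reverse complement over A<C<G<T) with 2-bit packing, so k is
# restricted to odd values in [3, 31]; odd k rules out reverse-complement
# palindromes, which would be ambiguous under canonicalization.

#' Count canonical k-mers in a set of reads
#'
#' Streams the reads once, counting each k-length window by its canonical
#' form. Windows containing any non-ACGT base are skipped (an ambiguity
#' base invalidates every k-mer that spans it).
#'
#' @param reads Sequences: named or unnamed character vector,
#'   `DNAStringSet`, or path(s) to FASTA/FASTQ file(s) (gzip ok).
#' @param k Odd k-mer size in `[3, 31]`; default 21, the standard
#'   trio-binning choice.
#' @param min_count_keep Drop k-mers seen fewer than this many times
#'   (default 1 = keep all).
#' @param parent_id Label attached to the resulting set.
#' @return A `kmer_set` object: list with `parent_id`, `k`, `codes`
#'   (packed canonical k-mers) and `counts`.
#' @examples
#' ks <- count_kmers("ACGT", k = 3)
#' as.data.frame(ks)  # ACG seen twice (CGT is its reverse complement)
#' @export
count_kmers <- function(reads, k = 21L, min_count_keep = 1L, parent_id = "parent") {
  k <- check_k(k)
  reads <- as_reads(reads)
  res <- cpp_count_kmers(unname(reads), k, as.integer(min_count_keep))
  if (length(res$counts) == 0 && length(reads) >= 0) {
    if (length(reads) == 0 || all(nchar(reads) < k)) {
      warning("no k-mers counted (empty input or all reads shorter than k)")
    }
  }
  structure(list(parent_id = parent_id, k = k, codes = res$codes,
                 counts = res$counts),
            class = "kmer_set")
}

check_k <- function(k) {
  k <- as.integer(k)
  if (length(k) != 1 || is.na(k)) stop("k must be a single integer")
  if (k %% 2 == 0) {
    stop("k must be odd (even k admits reverse-complement palindromes, ",
         "which have no unambiguous canonical form)")
  }
  if (k < 3 || k > 31) stop("k must be in [3, 31]")
  k
}

# reads argument: character vector (sequences), DNAStringSet, or file path(s)
as_reads <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    return(stats::setNames(as.character(x), sub("\\s.*$", "", names(x))))
  }
  if (is.character(x)) {
    if (length(x) >= 1 && is.null(names(x)) && all(file.exists(x))) {
      seqs <- unlist(lapply(x, function(p) {
        s <- read_seqs(p)
        attributes(s) <- list(names = names(s))
        s
      }))
      return(seqs)
    }
    return(x)
  }
  stop("expected reads as character vector, DNAStringSet or file path(s)")
}

#' @export
length.kmer_set <- function(x) length(x$counts)

#' @export
print.kmer_set <- function(x, ...) {
  cat("kmer_set:", x$parent_id, "\n")
  cat("  k =", x$k, "| distinct canonical k-mers:", length(x$counts),
      "| total count:", sum(as.numeric(x$counts)), "\n")
  invisible(x)
}

#' @export
as.data.frame.kmer_set <- function(x, ...) {
  data.frame(kmer = cpp_decode_kmers(x$codes, x$k),
             count = x$counts, stringsAsFactors = FALSE)
}

#' Extract parent-specific k-mers (hap-mers)
#'
#' A k-mer is specific to parent A when its count in A passes the noise
#' floor (`>= min_count`), is at most `max_count` when a repeat ceiling is
#' set, and its count in parent B is below the noise floor (absent or
#' error-level); symmetrically for B. The two specific sets are disjoint
#' by construction.
#'
#' @param kset_a,kset_b `kmer_set` objects for the two parents; must share k.
#' @param min_count Noise floor (default 5: at typical 45x parental
#'   coverage, k-mers seen fewer than 5 times are treated as sequencing
#'   error).
#' @param max_count Optional repeat ceiling applied to the own-parent count.
#' @return A `hapmer_sets` object.
#' @export
extract_hapmers <- function(kset_a, kset_b, min_count = 5L, max_count = NULL) {
  stopifnot(inherits(kset_a, "kmer_set"), inherits(kset_b, "kmer_set"))
  if (kset_a$k != kset_b$k) stop("parental k-mer sets have different k (",
                                 kset_a$k, " vs ", kset_b$k, ")")
  mc <- as.integer(min_count)
  xc <- if (is.null(max_count)) -1L else as.integer(max_count)
  res <- cpp_extract_hapmers(kset_a$codes, kset_a$counts,
                             kset_b$codes, kset_b$counts, mc, xc)
  structure(list(k = kset_a$k,
                 specific_a = res$specific_a, specific_b = res$specific_b,
                 min_count = mc, max_count = max_count,
                 parent_a = kset_a$parent_id, parent_b = kset_b$parent_id),
            class = "hapmer_sets")
}

#' @export
print.hapmer_sets <- function(x, ...) {
  cat("hapmer_sets (k =", x$k, ")\n")
  cat("  specific to", x$parent_a, "(A):", length(x$specific_a) / 8, "k-mers\n")
  cat("  specific to", x$parent_b, "(B):", length(x$specific_b) / 8, "k-mers\n")
  cat("  noise floor:", x$min_count,
      if (!is.null(x$max_count)) paste("| repeat ceiling:", x$max_count) else "",
      "\n")
  invisible(x)
}

n_hapmers <- function(h) c(a = length(h$specific_a) / 8, b = length(h$specific_b) / 8)

#' Decode hap-mer sets to k-mer strings
#' @param hapmers A `hapmer_sets` object.
#' @return list with character vectors `specific_a` and `specific_b`.
#' @export
hapmer_strings <- function(hapmers) {
  list(specific_a = cpp_decode_kmers(hapmers$specific_a, hapmers$k),
       specific_b = cpp_decode_kmers(hapmers$specific_b, hapmers$k))
}

#' Partition long reads into parental bins
#'
#' Each read is scored by the number of its canonical k-mers found in the
#' A-specific and B-specific hap-mer sets; the bin is the argmax of the
#' two scores, with ties (including 0-0) going to `unknown`. With
#' `normalize = TRUE` scores are divided by the respective hap-mer set
#' sizes before comparison (exact integer cross-multiplication), which
#' corrects for asymmetric set sizes.
#'
#' @param reads Long reads: named character vector, `DNAStringSet` or
#'   FASTA/FASTQ path.
#' @param hapmers A `hapmer_sets` object.
#' @param normalize Normalize scores by hap-mer set size (default FALSE).
#' @return list with `assignments` (data.frame read_id, length, score_a,
#'   score_b, bin) and `summary` (a `binning_summary`).
#' @export
bin_reads <- function(reads, hapmers, normalize = FALSE) {
  stopifnot(inherits(hapmers, "hapmer_sets"))
  reads <- as_reads(reads)
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  sc <- cpp_score_reads(unname(reads), hapmers$k,
                        hapmers$specific_a, hapmers$specific_b)
  na <- n_hapmers(hapmers)["a"]
  nb <- n_hapmers(hapmers)["b"]
  if (normalize && na > 0 && nb > 0) {
    eff_a <- as.numeric(sc$score_a) * nb
    eff_b <- as.numeric(sc$score_b) * na
  } else {
    eff_a <- as.numeric(sc$score_a)
    eff_b <- as.numeric(sc$score_b)
  }
  bin <- ifelse(eff_a > eff_b, "A", ifelse(eff_b > eff_a, "B", "unknown"))
  assignments <- data.frame(read_id = names(reads), length = nchar(unname(reads)),
                            score_a = sc$score_a, score_b = sc$score_b,
                            bin = bin, stringsAsFactors = FALSE)
  list(assignments = assignments, summary = summarize_binning(assignments))
}

#' Summarize a read binning
#' @param assignments data.frame with a `bin` column (A, B, unknown).
#' @return A `binning_summary`: counts and percentages per bin.
#' @export
summarize_binning <- function(assignments) {
  if (is.null(assignments$bin) || nrow(assignments) == 0) {
    stop("assignments must be a non-empty data.frame with a 'bin' column")
  }
  n_total <- nrow(assignments)
  n_a <- sum(assignments$bin == "A")
  n_b <- sum(assignments$bin == "B")
  n_unknown <- sum(assignments$bin == "unknown")
  stopifnot(n_a + n_b + n_unknown == n_total)
  structure(list(n_total = n_total, n_a = n_a, n_b = n_b, n_unknown = n_unknown,
                 frac_a = 100 * n_a / n_total, frac_b = 100 * n_b / n_total,
                 frac_unknown = 100 * n_unknown / n_total),
            class = "binning_summary")
}

#' @export
print.binning_summary <- function(x, ...) {
  cat("read binning summary\n")
  cat(sprintf("  total reads : %d\n", x$n_total))
  cat(sprintf("  bin A       : %d (%.1f%%)\n", x$n_a, x$frac_a))
  cat(sprintf("  bin B       : %d (%.1f%%)\n", x$n_b, x$frac_b))
  cat(sprintf("  unknown     : %d (%.1f%%)\n", x$n_unknown, x$frac_unknown))
  invisible(x)
}

#' @export
as.data.frame.binning_summary <- function(x, ...) {
  data.frame(bin = c("A", "B", "unknown"),
             n_reads = c(x$n_a, x$n_b, x$n_unknown),
             fraction_pct = round(c(x$frac_a, x$frac_b, x$frac_unknown), 1),
             stringsAsFactors = FALSE)
}

#' Write binned reads to per-bin sequence files
#'
#' Each read is written to exactly one of the three bin files
#' (`<prefix>.haplotype-A`, `-B`, `-unknown`); files for empty bins are
#' still created. For downstream per-parent assembly the convention is to
#' supply a parent bin together with the unknown bin.
#'
#' @param assignments data.frame from [bin_reads()].
#' @param reads The same reads that were binned (named character,
#'   `DNAStringSet` or file path).
#' @param out_prefix Output path prefix.
#' @param format "fasta" or "fastq" (default follows the input when it was
#'   read from file, otherwise fasta).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_bins <- function(assignments, reads, out_prefix, format = NULL) {
  reads <- as_reads(reads)
  if (is.null(format)) format <- attr(reads, "format") %||% "fasta"
  missing <- setdiff(assignments$read_id, names(reads))
  if (length(missing) > 0) {
    stop("read(s) in assignments missing from the sequence stream: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  ext <- if (format == "fastq") "fastq" else "fasta"
  paths <- c(A = paste0(out_prefix, ".haplotype-A.", ext),
             B = paste0(out_prefix, ".haplotype-B.", ext),
             unknown = paste0(out_prefix, ".haplotype-unknown.", ext))
  quals <- attr(reads, "qualities")
  for (b in names(paths)) {
    ids <- assignments$read_id[assignments$bin == b]
    sub <- reads[ids]
    attributes(sub) <- list(names = ids)
    if (length(ids) == 0) sub <- stats::setNames(character(0), character(0))
    write_seqs(sub, paths[[b]], format = format,
               qualities = if (!is.null(quals)) quals[ids] else NULL)
  }
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a k-mer count table (TSV with columns kmer, count)
#' @param kset A `kmer_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kmer_set <- function(kset, path) {
  df <- as.data.frame(kset)
  con <- file(path, "wt")
  writeLines(sprintf("# k=%d parent=%s", kset$k, kset$parent_id), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_kmer_set
#' @export
read_kmer_set <- function(path) {
  hdr <- readLines(path, n = 1)
  k <- as.integer(sub(".*k=(\\d+).*", "\\1", hdr))
  pid <- sub(".*parent=(\\S+).*", "\\1", hdr)
  df <- read.delim(path, skip = 1, stringsAsFactors = FALSE)
  structure(list(parent_id = pid, k = k,
                 codes = cpp_encode_canonical(df$kmer, k),
                 counts = as.integer(df$count)),
            class = "kmer_set")
}
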