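# Assembly statistics, gap discovery, telomere repeat exploration and
# search, heterozygosity estimation and dotplot track export.

#' N-statistics from a multiset of sequence lengths
#'
#' `N50` is the length of the shortest sequence in the minimal set of
#' longest sequences whose lengths sum to at least 50% of the total;
#' `L50` is the size of that set. `N90`/`L90` are the 90% analogues.
#'
#' @param lengths Numeric vector of sequence lengths.
#' @return list with total, longest, n50, l50, n90, l90.
#' @export
nstats <- function(lengths) {
  stopifnot(length(lengths) > 0, all(lengths > 0))
  s <- sort(unname(lengths), decreasing = TRUE)
  cs <- cumsum(s)
  total <- cs[length(cs)]
  i50 <- which(cs >= 0.5 * total)[1]
  i90 <- which(cs >= 0.9 * total)[1]
  list(total = total, longest = s[1],
       n50 = s[i50], l50 = i50, n90 = s[i90], l90 = i90)
}

#' Assembly contiguity statistics
#'
#' Scaffold statistics are computed on the sequences as given; contig
#' statistics after splitting scaffolds at N-runs of at least
#' `contig_split_n` bases.
#'
#' @param x Sequences (named character, `DNAStringSet` or FASTA path).
#' @param contig_split_n Minimum N-run length that separates contigs
#'   within a scaffold (default 10).
#' @return An `assembly_stats` object.
#' @export
assembly_stats <- function(x, contig_split_n = 10) {
  seqs <- as_seqchar(x)
  if (length(seqs) == 0) stop("empty assembly: no sequences")
  stopifnot(contig_split_n >= 1)
  sc_len <- nchar(seqs)
  contig_len <- unlist(lapply(names(seqs), function(cn) {
    contig_lengths_one(seqs[[cn]], contig_split_n)
  }), use.names = FALSE)
  if (length(contig_len) == 0) stop("assembly contains no non-N sequence")
  sc <- nstats(sc_len)
  ct <- nstats(contig_len)
  structure(list(n_scaffolds = length(sc_len), n_contigs = length(contig_len),
                 total_size = sc$total, longest = sc$longest,
                 scaffold_n50 = sc$n50, scaffold_l50 = sc$l50,
                 scaffold_n90 = sc$n90, scaffold_l90 = sc$l90,
                 contig_total = ct$total, contig_longest = ct$longest,
                 contig_n50 = ct$n50, contig_l50 = ct$l50,
                 contig_n90 = ct$n90, contig_l90 = ct$l90,
                 contig_split_n = contig_split_n),
            class = "assembly_stats")
}

# lengths of contig pieces of one scaffold after splitting at N-runs >= n
contig_lengths_one <- function(seq, n) {
  gaps <- n_runs(seq)
  gaps <- gaps[gaps$length >= n, , drop = FALSE]
  bounds <- c(0, as.vector(rbind(gaps$start, gaps$end)), nchar(seq))
  starts <- bounds[seq(1, length(bounds), by = 2)]
  ends <- bounds[seq(2, length(bounds), by = 2)]
  len <- ends - starts
  len[len > 0]
}

#' @export
print.assembly_stats <- function(x, ...) {
  mb <- function(v) sprintf("%.3f Mb", v / 1e6)
  cat("assembly statistics\n")
  cat(sprintf("  scaffolds: %d | contigs: %d (split at N-runs >= %d)\n",
              x$n_scaffolds, x$n_contigs, x$contig_split_n))
  cat(sprintf("  total size: %s | longest scaffold: %s\n",
              mb(x$total_size), mb(x$longest)))
  cat(sprintf("  scaffold N50/L50: %s / %d | N90/L90: %s / %d\n",
              mb(x$scaffold_n50), x$scaffold_l50, mb(x$scaffold_n90),
              x$scaffold_l90))
  cat(sprintf("  contig   N50/L50: %s / %d | N90/L90: %s / %d\n",
              mb(x$contig_n50), x$contig_l50, mb(x$contig_n90), x$contig_l90))
  invisible(x)
}

#' @export
as.data.frame.assembly_stats <- function(x, ...) {
  as.data.frame(unclass(x)[setdiff(names(unclass(x)), character(0))],
                stringsAsFactors = FALSE)
}

# maximal N-runs of one sequence, 0-based half-open
n_runs <- function(seq) {
  m <- gregexpr("[Nn]+", seq, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(data.frame(start = numeric(0), end = numeric(0), length = numeric(0)))
  }
  start <- as.numeric(m) - 1
  len <- as.numeric(attr(m, "match.length"))
  data.frame(start = start, end = start + len, length = len)
}

#' Find assembly gaps (maximal N-runs)
#'
#' @param x Sequences (named character, `DNAStringSet` or FASTA path).
#' @param min_run Minimum run length to report (default 1).
#' @return data.frame contig, start, end, length (0-based half-open,
#'   BED-compatible).
#' @export
find_gaps <- function(x, min_run = 1) {
  seqs <- as_seqchar(x)
  stopifnot(min_run >= 1)
  out <- do.call(rbind, lapply(names(seqs), function(cn) {
    g <- n_runs(seqs[[cn]])
    g <- g[g$length >= min_run, , drop = FALSE]
    if (nrow(g) == 0) return(NULL)
    cbind(data.frame(contig = cn, stringsAsFactors = FALSE), g)
  }))
  if (is.null(out)) {
    out <- data.frame(contig = character(), start = numeric(), end = numeric(),
                      length = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Explore candidate telomere repeat units at sequence ends
#'
#' Counts tandem-repeated units (at least two consecutive exact copies)
#' of every length in `[min_len, max_len]` within the terminal
#' `terminal_bp` of each sequence end. Units are pooled over rotations
#' and strand (canonical rotation: lexicographic minimum over all
#' rotations of the unit and of its reverse complement); non-primitive
#' units (those that are themselves a smaller repeat) are skipped.
#'
#' @param x Sequences (named character, `DNAStringSet` or FASTA path).
#' @param min_len,max_len Unit length bounds (defaults 5 and 12).
#' @param terminal_bp Length of each sequence end to scan (default 50000).
#' @return data.frame unit (canonical rotation), unit_length, count,
#'   ranked by descending count.
#' @export
telomere_explore <- function(x, min_len = 5, max_len = 12, terminal_bp = 50000) {
  seqs <- as_seqchar(x)
  stopifnot(terminal_bp > 0, min_len >= 2, max_len >= min_len)
  ends <- unlist(lapply(unname(seqs), function(s) {
    n <- nchar(s)
    if (n <= 2 * terminal_bp) return(s)
    c(substr(s, 1, terminal_bp), substr(s, n - terminal_bp + 1, n))
  }))
  cpp_tandem_explore(ends, as.integer(min_len), as.integer(max_len))
}

#' Canonical rotation class of a repeat unit
#'
#' Lexicographic minimum over all rotations of the unit and of its
#' reverse complement; telomere repeats are circular-phase and strand
#' ambiguous, so this is the natural class representative.
#'
#' @param unit Character vector of repeat units.
#' @return Character vector of canonical rotations.
#' @export
canonical_rotation <- function(unit) {
  cpp_canonical_rotation(toupper(unit))
}

#' Per-window telomere repeat counts
#'
#' Counts occurrences (overlapping matches included) of `unit` and of its
#' reverse complement in fixed windows along each sequence.
#'
#' @param x Sequences (named character, `DNAStringSet` or FASTA path).
#' @param unit Repeat unit to search (e.g. "TTAGGG").
#' @param window Window width in bp (default 1000).
#' @return data.frame contig, start, end, forward, reverse.
#' @export
telomere_search <- function(x, unit, window = 1000) {
  seqs <- as_seqchar(x)
  stopifnot(nzchar(unit))
  unit <- toupper(unit)
  rc <- rc_chr(unit)
  count_starts <- function(seq, u) {
    m <- gregexpr(paste0("(?=", u, ")"), seq, perl = TRUE)[[1]]
    if (m[1] == -1) numeric(0) else as.numeric(m) - 1
  }
  out <- do.call(rbind, lapply(names(seqs), function(cn) {
    s <- seqs[[cn]]
    w <- make_windows(stats::setNames(nchar(s), cn), width = window)
    fwd <- count_starts(s, unit)
    rev <- count_starts(s, rc)
    w$forward <- as.numeric(table(factor(findInterval(fwd, w$start),
                                         levels = seq_len(nrow(w)))))
    w$reverse <- as.numeric(table(factor(findInterval(rev, w$start),
                                         levels = seq_len(nrow(w)))))
    w
  }))
  rownames(out) <- NULL
  out
}

#' Heterozygosity from alignment differences
#'
#' The estimate counts SNP positions plus insertion/deletion positions
#' (an indel counts as a single position regardless of its length) from
#' unique-alignment records, divided by either the total aligned length
#' (default) or a supplied genome size.
#'
#' @param x Either a data.frame (or TSV path) with columns n_snp,
#'   n_indel, aligned_len - one row per unique alignment block - or a
#'   PAF data.frame/path whose records carry `cs:Z:` difference tags (see
#'   [het_from_paf()]).
#' @param denominator_mode "aligned" (sum of aligned lengths) or
#'   "genome" (requires `genome_size`).
#' @param genome_size Genome size in bp for `denominator_mode = "genome"`.
#' @return A `het_estimate` object with n_snp, n_indel_positions,
#'   denominator and rate (percent).
#' @export
heterozygosity <- function(x, denominator_mode = c("aligned", "genome"),
                           genome_size = NULL) {
  denominator_mode <- match.arg(denominator_mode)
  if (is.character(x) && length(x) == 1) x <- read_tsv(x)
  if (is.data.frame(x) && all(paf_cols %in% names(x))) x <- het_from_paf(x)
  stopifnot(all(c("n_snp", "n_indel", "aligned_len") %in% names(x)))
  n_snp <- sum(x$n_snp)
  n_indel <- sum(x$n_indel)
  denom <- if (denominator_mode == "aligned") sum(x$aligned_len)
           else genome_size
  if (is.null(denom) || is.na(denom) || denom == 0) {
    stop("heterozygosity denominator is zero or missing")
  }
  structure(list(n_snp = n_snp, n_indel_positions = n_indel,
                 denominator = denom, denominator_mode = denominator_mode,
                 rate = 100 * (n_snp + n_indel) / denom),
            class = "het_estimate")
}

#' @export
print.het_estimate <- function(x, ...) {
  cat("heterozygosity estimate\n")
  cat(sprintf("  SNP positions:   %d\n", as.integer(x$n_snp)))
  cat(sprintf("  indel positions: %d\n", as.integer(x$n_indel_positions)))
  cat(sprintf("  denominator:     %s bp (%s)\n",
              format(x$denominator, big.mark = ",", scientific = FALSE),
              x$denominator_mode))
  cat(sprintf("  rate:            %.4f%%\n", x$rate))
  invisible(x)
}

#' Variant counts per PAF record from cs difference tags
#'
#' Parses minimap2-style `cs:Z:` short-form tags: `:N` exact match run,
#' `*ab` substitution, `+seq` insertion, `-seq` deletion. Each
#' substitution is one SNP position; each insertion or deletion event is
#' one indel position. Aligned length is the target-consumed length.
#'
#' @param paf PAF data.frame (from [read_paf()]) or path; records must
#'   carry `cs:Z:` tags.
#' @return data.frame qname, tname, n_snp, n_indel, aligned_len.
#' @export
het_from_paf <- function(paf) {
  paf <- as_paf(paf)
  cs <- regmatches(paf$tags, regexpr("cs:Z:[^\t]*", paf$tags))
  if (length(cs) != nrow(paf)) {
    stop("PAF records without cs:Z: tags; supply counts directly instead")
  }
  cs <- sub("^cs:Z:", "", cs)
  parse_one <- function(s) {
    ops <- regmatches(s, gregexpr("[:=*+-][A-Za-z0-9]+", s))[[1]]
    kind <- substr(ops, 1, 1)
    val <- substr(ops, 2, nchar(ops))
    n_snp <- sum(kind == "*")
    n_indel <- sum(kind %in% c("+", "-"))
    aligned <- sum(as.numeric(val[kind == ":"])) +
      sum(nchar(val[kind == "="])) + n_snp + sum(nchar(val[kind == "-"]))
    c(n_snp = n_snp, n_indel = n_indel, aligned_len = aligned)
  }
  counts <- t(vapply(cs, parse_one, c(n_snp = 0, n_indel = 0, aligned_len = 0)))
  data.frame(qname = paf$qname, tname = paf$tname,
             n_snp = counts[, "n_snp"], n_indel = counts[, "n_indel"],
             aligned_len = counts[, "aligned_len"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Dotplot segment track from PAF alignments
#'
#' One row per alignment record of at least `min_len` block length, with
#' identity = residue matches / block length - plot-ready for dotplots
#' coloured by percent identity.
#'
#' @param paf PAF data.frame or path.
#' @param min_len Minimum block length (default 0).
#' @return data.frame qname, tname, qstart, qend, tstart, tend, strand,
#'   identity.
#' @export
dotplot_data <- function(paf, min_len = 0) {
  paf <- as_paf(paf)
  paf <- paf[paf$block_len >= min_len, , drop = FALSE]
  data.frame(qname = paf$qname, tname = paf$tname,
             qstart = paf$qstart, qend = paf$qend,
             tstart = paf$tstart, tend = paf$tend, strand = paf$strand,
             identity = ifelse(paf$block_len > 0,
                               paf$n_matches / paf$block_len, NA_real_),
             stringsAsFactors = FALSE)
}
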