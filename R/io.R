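# Shared readers/writers: FASTA/FASTQ (via Biostrings), PAF, AGP 2.1,
# BED and headered TSV.  Internal coordinate convention is 0-based
# half-open everywhere except AGP, which is 1-based inclusive per the
# standard; writers state the convention where the format allows comments.

#' Read sequences from a FASTA or FASTQ file
#'
#' Format is auto-detected from the first record character (`>` FASTA,
#' `@` FASTQ); gzipped input is handled transparently. Record ids are the
#' first whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA or FASTQ file, optionally gzipped.
#' @return Named character vector of sequences with attributes `format`
#'   ("fasta" or "fastq") and, for FASTQ, `qualities` (named character).
#' @export
read_seqs <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  con <- gzfile(path, "rb")
  first <- rawToChar(readBin(con, "raw", 1L))
  close(con)
  if (length(first) == 0 || !nzchar(first)) {
    out <- stats::setNames(character(0), character(0))
    attr(out, "format") <- "fasta"
    return(out)
  }
  if (identical(first, ">")) {
    x <- Biostrings::readDNAStringSet(path, format = "fasta")
    quals <- NULL
    fmt <- "fasta"
  } else if (identical(first, "@")) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
    quals <- as.character(S4Vectors::mcols(x)$qualities)
    fmt <- "fastq"
  } else {
    stop("cannot detect sequence format of ", path,
         " (first character ", deparse(first), ")")
  }
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) stop("duplicate record ids in ", path)
  out <- stats::setNames(as.character(x), ids)
  attr(out, "format") <- fmt
  if (!is.null(quals)) attr(out, "qualities") <- stats::setNames(quals, ids)
  out
}

#' Write sequences to FASTA or FASTQ
#'
#' @param seqs Named character vector or `DNAStringSet`.
#' @param path Output path (a `.gz` suffix triggers gzip compression).
#' @param format "fasta" or "fastq". FASTQ records without supplied
#'   qualities get a constant high quality ("I").
#' @param qualities Optional named character vector of quality strings.
#' @return `path`, invisibly.
#' @export
write_seqs <- function(seqs, path, format = c("fasta", "fastq"), qualities = NULL) {
  format <- match.arg(format)
  if (is.character(seqs) && is.null(qualities)) qualities <- attr(seqs, "qualities")
  x <- as_dss(seqs)
  gz <- grepl("\\.gz$", path)
  if (format == "fasta") {
    Biostrings::writeXStringSet(x, path, format = "fasta", compress = gz)
  } else {
    if (is.null(qualities)) {
      q <- Biostrings::BStringSet(vapply(Biostrings::width(x), function(w)
        strrep("I", w), character(1)))
    } else {
      q <- Biostrings::BStringSet(unname(qualities[names(x)]))
    }
    Biostrings::writeXStringSet(x, path, format = "fastq", compress = gz, qualities = q)
  }
  invisible(path)
}

# coerce named character / DNAStringSet to DNAStringSet
as_dss <- function(seqs) {
  if (methods::is(seqs, "DNAStringSet")) return(seqs)
  if (is.character(seqs)) {
    if (is.null(names(seqs))) stop("sequences must be named")
    return(Biostrings::DNAStringSet(seqs))
  }
  stop("unsupported sequence container: ", class(seqs)[1])
}

# coerce seqs argument (vector, DNAStringSet, or file path) to named character
as_seqchar <- function(x) {
  if (is.character(x) && length(x) == 1 && is.null(names(x)) && file.exists(x))
    return(read_seqs(x))
  if (methods::is(x, "DNAStringSet"))
    return(stats::setNames(as.character(x), sub("\\s.*$", "", names(x))))
  if (is.character(x)) {
    if (is.null(names(x))) stop("character sequences must be named")
    return(x)
  }
  stop("expected sequences (named character / DNAStringSet) or a file path")
}

rc_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

paf_cols <- c("qname", "qlen", "qstart", "qend", "strand", "tname", "tlen",
              "tstart", "tend", "n_matches", "block_len", "mapq")

#' Read a PAF alignment file
#'
#' Parses the 12 mandatory PAF columns into typed fields; any additional
#' tag columns are preserved verbatim in a single `tags` string column.
#' Coordinates are 0-based half-open as in the PAF standard.
#'
#' @param path Path to a PAF file (optionally gzipped).
#' @return data.frame with columns qname, qlen, qstart, qend, strand,
#'   tname, tlen, tstart, tend, n_matches, block_len, mapq, tags.
#' @export
read_paf <- function(path) {
  if (!file.exists(path)) stop("PAF file not found: ", path)
  lines <- readLines(gzfile(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_paf())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 12)) {
    stop("malformed PAF line ", which(nf < 12)[1], ": fewer than 12 columns")
  }
  get <- function(i) vapply(parts, `[[`, character(1), i)
  int_col <- function(i, what) {
    v <- suppressWarnings(as.numeric(get(i)))
    if (anyNA(v)) stop("malformed PAF line ", which(is.na(v))[1],
                       ": non-numeric ", what)
    v
  }
  df <- data.frame(
    qname = get(1), qlen = int_col(2, "query length"),
    qstart = int_col(3, "query start"), qend = int_col(4, "query end"),
    strand = get(5), tname = get(6), tlen = int_col(7, "target length"),
    tstart = int_col(8, "target start"), tend = int_col(9, "target end"),
    n_matches = int_col(10, "match count"), block_len = int_col(11, "block length"),
    mapq = int_col(12, "mapq"),
    tags = vapply(parts, function(p)
      if (length(p) > 12) paste(p[-(1:12)], collapse = "\t") else "", character(1)),
    stringsAsFactors = FALSE)
  df
}

empty_paf <- function() {
  df <- data.frame(qname = character(), qlen = numeric(), qstart = numeric(),
                   qend = numeric(), strand = character(), tname = character(),
                   tlen = numeric(), tstart = numeric(), tend = numeric(),
                   n_matches = numeric(), block_len = numeric(), mapq = numeric(),
                   tags = character(), stringsAsFactors = FALSE)
  df
}

#' Write alignments in PAF format
#' @param paf data.frame as produced by [read_paf()] (the `tags` column is
#'   optional).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(paf, path) {
  stopifnot(all(paf_cols %in% names(paf)))
  body <- do.call(paste, c(lapply(paf_cols, function(cn) {
    v <- paf[[cn]]
    if (is.numeric(v)) format(v, scientific = FALSE, trim = TRUE) else as.character(v)
  }), sep = "\t"))
  if (!is.null(paf$tags)) {
    has <- nzchar(paf$tags)
    body[has] <- paste(body[has], paf$tags[has], sep = "\t")
  }
  writeLines(body, path)
  invisible(path)
}

# coerce a PAF argument (data.frame or path) to data.frame
as_paf <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(paf_cols %in% names(x)))
    return(x)
  }
  if (is.character(x) && length(x) == 1) return(read_paf(x))
  stop("expected a PAF data.frame or file path")
}

agp_plan_cols <- c("object", "object_beg", "object_end", "part_number",
                   "component_type", "component_id", "component_beg",
                   "component_end", "orientation", "gap_length", "gap_type",
                   "linkage", "linkage_evidence")

#' Write a scaffold plan as AGP v2.1
#'
#' @param plan A `scaffold_plan` data.frame (see [build_scaffolds()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_agp <- function(plan, path) {
  stopifnot(all(agp_plan_cols %in% names(plan)))
  rows <- vapply(seq_len(nrow(plan)), function(i) {
    r <- plan[i, ]
    if (r$component_type == "N" || r$component_type == "U") {
      paste(r$object, r$object_beg, r$object_end, r$part_number,
            r$component_type, r$gap_length, r$gap_type, r$linkage,
            r$linkage_evidence, sep = "\t")
    } else {
      paste(r$object, r$object_beg, r$object_end, r$part_number,
            r$component_type, r$component_id, r$component_beg,
            r$component_end, r$orientation, sep = "\t")
    }
  }, character(1))
  writeLines(c("##agp-version\t2.1", rows), path)
  invisible(path)
}

#' Read an AGP v2.1 file into a scaffold plan
#'
#' Validates that component coordinates within each object are contiguous
#' and non-overlapping.
#'
#' @param path Path to an AGP file.
#' @return A `scaffold_plan` data.frame (1-based inclusive object and
#'   component coordinates, as in the AGP standard).
#' @export
read_agp <- function(path) {
  if (!file.exists(path)) stop("AGP file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 9)) {
    stop("malformed AGP line ", which(lengths(parts) != 9)[1], ": expected 9 columns")
  }
  get <- function(i) vapply(parts, `[[`, character(1), i)
  type <- get(5)
  is_gap <- type %in% c("N", "U")
  plan <- data.frame(
    object = get(1), object_beg = as.numeric(get(2)),
    object_end = as.numeric(get(3)), part_number = as.integer(get(4)),
    component_type = type,
    component_id = ifelse(is_gap, NA_character_, get(6)),
    component_beg = ifelse(is_gap, NA, suppressWarnings(as.numeric(get(7)))),
    component_end = ifelse(is_gap, NA, suppressWarnings(as.numeric(get(8)))),
    orientation = ifelse(is_gap, NA_character_, get(9)),
    gap_length = ifelse(is_gap, suppressWarnings(as.numeric(get(6))), NA),
    gap_type = ifelse(is_gap, get(7), NA_character_),
    linkage = ifelse(is_gap, get(8), NA_character_),
    linkage_evidence = ifelse(is_gap, get(9), NA_character_),
    stringsAsFactors = FALSE)
  validate_scaffold_plan(plan)
  class(plan) <- c("scaffold_plan", "data.frame")
  plan
}

validate_scaffold_plan <- function(plan) {
  for (obj in unique(plan$object)) {
    p <- plan[plan$object == obj, ]
    p <- p[order(p$part_number), ]
    expected_beg <- c(1, p$object_end[-nrow(p)] + 1)
    if (any(p$object_beg != expected_beg)) {
      stop("AGP object ", obj, ": components not contiguous (overlap or gap in ",
           "object coordinates)")
    }
    span <- p$object_end - p$object_beg + 1
    comp_span <- ifelse(p$component_type %in% c("N", "U"),
                        p$gap_length, p$component_end - p$component_beg + 1)
    if (any(span != comp_span)) {
      stop("AGP object ", obj, ": object span does not match component span")
    }
  }
  invisible(TRUE)
}

#' Reconstruct scaffold sequences from an AGP plan and component sequences
#'
#' @param plan A `scaffold_plan` data.frame.
#' @param components Component (contig) sequences: named character,
#'   `DNAStringSet` or FASTA path.
#' @return Named character vector of scaffold sequences.
#' @export
agp_to_fasta <- function(plan, components) {
  comp <- as_seqchar(components)
  objs <- unique(plan$object)
  out <- vapply(objs, function(obj) {
    p <- plan[plan$object == obj, ]
    p <- p[order(p$part_number), ]
    pieces <- vapply(seq_len(nrow(p)), function(i) {
      r <- p[i, ]
      if (r$component_type %in% c("N", "U")) return(strrep("N", r$gap_length))
      if (!r$component_id %in% names(comp)) {
        stop("AGP component ", r$component_id, " missing from component sequences")
      }
      s <- substr(comp[[r$component_id]], r$component_beg, r$component_end)
      if (identical(r$orientation, "-")) s <- rc_chr(s)
      s
    }, character(1))
    paste(pieces, collapse = "")
  }, character(1))
  stats::setNames(out, objs)
}

#' Write a BED file (0-based half-open)
#' @param df data.frame whose first three columns are contig, start, end;
#'   further columns are written as additional BED fields.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED file (0-based half-open)
#' @param path Input path.
#' @param col_names Names for the columns present (defaults cover BED3-6).
#' @return data.frame with typed start/end columns.
#' @export
read_bed <- function(path, col_names = c("contig", "start", "end", "name",
                                         "score", "strand")) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(contig = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- unique(lengths(parts))
  if (length(nc) != 1 || nc < 3 || nc > length(col_names)) {
    stop("malformed BED: expected a constant 3-", length(col_names),
         " columns")
  }
  df <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(df) <- col_names[seq_len(nc)]
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  if (!is.null(df$score)) df$score <- suppressWarnings(as.numeric(df$score))
  df
}

#' Write a TSV file with a header row
#' @param df data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read a headered TSV file
#' @param path Input path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}
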