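# Haplotype-switch detection: per-window percent-coverage difference of
# binned-read placements, window classification, concordance and
# switch-block intervals.  All coordinates 0-based half-open.

#' Tile contigs with fixed-width windows
#'
#' @param contig_lengths Named numeric vector of contig lengths (bp).
#' @param width Window width in bp (default 1 Mb). The final window of
#'   each contig is truncated to the contig end rather than discarded.
#' @return data.frame with columns contig, start, end (0-based half-open).
#' @export
make_windows <- function(contig_lengths, width = 1e6) {
  stopifnot(width >= 1, all(contig_lengths >= 1), !is.null(names(contig_lengths)))
  out <- lapply(names(contig_lengths), function(cn) {
    len <- contig_lengths[[cn]]
    starts <- seq(0, len - 1, by = width)
    data.frame(contig = cn, start = starts, end = pmin(starts + width, len),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Select one primary placement per binned read from PAF alignments
#'
#' Retains, per read, the alignment record with the greatest number of
#' residue matches (PAF column 10), ties broken by earliest record.
#' Reads labelled `unknown` are excluded (only the two parental bins are
#' informative for phasing); aligned reads without a bin label are
#' skipped and tallied.
#'
#' @param paf PAF alignments (data.frame from [read_paf()] or a path).
#' @param assignments data.frame with columns read_id and bin (from
#'   [bin_reads()]).
#' @param min_mapq Optional minimum mapping quality (default 0 = keep all).
#' @return data.frame read_id, bin, contig, start, end with attributes
#'   `n_unplaced` (A/B-labelled reads with no alignment),
#'   `n_unknown_excluded` and `n_unlabeled`.
#' @export
read_placements <- function(paf, assignments, min_mapq = 0) {
  paf <- as_paf(paf)
  stopifnot(all(c("read_id", "bin") %in% names(assignments)))
  paf <- paf[paf$mapq >= min_mapq, , drop = FALSE]
  bin <- assignments$bin[match(paf$qname, assignments$read_id)]
  n_unlabeled <- length(unique(paf$qname[is.na(bin)]))
  n_unknown_excluded <- length(unique(paf$qname[!is.na(bin) & bin == "unknown"]))
  keep <- !is.na(bin) & bin %in% c("A", "B")
  paf <- paf[keep, , drop = FALSE]
  bin <- bin[keep]
  ord <- order(-paf$n_matches, seq_len(nrow(paf)))  # stable: ties -> earliest
  paf <- paf[ord, , drop = FALSE]
  bin <- bin[ord]
  first <- !duplicated(paf$qname)
  pl <- data.frame(read_id = paf$qname[first], bin = bin[first],
                   contig = paf$tname[first], start = paf$tstart[first],
                   end = paf$tend[first], stringsAsFactors = FALSE)
  labelled <- assignments$read_id[assignments$bin %in% c("A", "B")]
  attr(pl, "n_unplaced") <- sum(!labelled %in% pl$read_id)
  attr(pl, "n_unknown_excluded") <- n_unknown_excluded
  attr(pl, "n_unlabeled") <- n_unlabeled
  pl
}

#' Per-window coverage of each parental bin
#'
#' Percent coverage is breadth: the percentage of window bases covered by
#' the union of that bin's placement intervals (overlap does not count
#' twice and can never exceed 100). A depth mode (mean per-base depth per
#' window, differences in the same units) is available behind `mode`.
#'
#' @param placements data.frame from [read_placements()].
#' @param windows data.frame from [make_windows()].
#' @param mode "breadth" (default; percent of bases covered) or "depth"
#'   (mean per-base depth).
#' @return data.frame contig, start, end, pct_a, pct_b, diff
#'   (`pct_a - pct_b`, signed).
#' @export
window_coverage <- function(placements, windows, mode = c("breadth", "depth")) {
  mode <- match.arg(mode)
  unknown_contig <- setdiff(unique(placements$contig), unique(windows$contig))
  if (length(unknown_contig) > 0) {
    stop("placement(s) on contig(s) absent from the window set: ",
         paste(utils::head(unknown_contig, 5), collapse = ", "))
  }
  win <- windows
  win$pct_a <- 0
  win$pct_b <- 0
  for (cn in unique(win$contig)) {
    wi <- which(win$contig == cn)
    win_ir <- IRanges::IRanges(start = win$start[wi] + 1L, end = win$end[wi])
    for (b in c("A", "B")) {
      pl <- placements[placements$contig == cn & placements$bin == b, , drop = FALSE]
      if (nrow(pl) == 0) next
      ir <- IRanges::IRanges(start = pl$start + 1L, end = pl$end)
      if (mode == "breadth") ir <- IRanges::reduce(ir)
      ov <- IRanges::findOverlaps(win_ir, ir)
      if (length(ov) == 0) next
      inter <- IRanges::pintersect(win_ir[S4Vectors::queryHits(ov)],
                                   ir[S4Vectors::subjectHits(ov)])
      covered <- tapply(IRanges::width(inter), S4Vectors::queryHits(ov), sum)
      idx <- as.integer(names(covered))
      wwidth <- win$end[wi][idx] - win$start[wi][idx]
      val <- if (mode == "breadth") 100 * as.numeric(covered) / wwidth
             else as.numeric(covered) / wwidth
      if (b == "A") win$pct_a[wi[idx]] <- val else win$pct_b[wi[idx]] <- val
    }
  }
  win$diff <- win$pct_a - win$pct_b
  win
}

#' Classify windows and score phasing concordance
#'
#' A window is classified A when `diff > min_abs_diff`, B when
#' `diff < -min_abs_diff`, otherwise tie. Concordance is the percentage
#' of non-tie windows classified to the expected parent (ties are
#' excluded from the denominator). Switch blocks are maximal runs of
#' consecutive windows classified to the unexpected parent, reported at
#' window resolution.
#'
#' @param coverages data.frame from [window_coverage()].
#' @param expected_parent "A", "B", or NULL for a non-binned assembly
#'   (alternation statistics only; concordance is NA).
#' @param min_abs_diff Dead zone in percentage points around zero
#'   (default 0: any signed difference classifies a window).
#' @return A `switch_report` object.
#' @export
classify_and_score <- function(coverages, expected_parent = NULL, min_abs_diff = 0) {
  if (!is.null(expected_parent)) {
    expected_parent <- match.arg(expected_parent, c("A", "B"))
  }
  cov <- coverages
  cov$class <- ifelse(cov$diff > min_abs_diff, "A",
                      ifelse(cov$diff < -min_abs_diff, "B", "tie"))
  n_windows <- nrow(cov)
  n_tie <- sum(cov$class == "tie")
  non_tie <- cov$class != "tie"
  concordance <- NA_real_
  if (!is.null(expected_parent)) {
    if (any(non_tie)) {
      concordance <- 100 * sum(cov$class[non_tie] == expected_parent) /
        sum(non_tie)
    }
  }
  block_classes <- if (is.null(expected_parent)) c("A", "B")
                   else setdiff(c("A", "B"), expected_parent)
  blocks <- do.call(rbind, lapply(unique(cov$contig), function(cn) {
    cc <- cov[cov$contig == cn, , drop = FALSE]
    cc <- cc[order(cc$start), , drop = FALSE]
    r <- rle(cc$class)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values %in% block_classes
    if (!any(keep)) return(NULL)
    data.frame(contig = cn,
               start = cc$start[starts[keep]],
               end = cc$end[ends[keep]],
               n_windows = r$lengths[keep],
               observed_parent = r$values[keep],
               stringsAsFactors = FALSE)
  }))
  if (is.null(blocks)) {
    blocks <- data.frame(contig = character(), start = numeric(), end = numeric(),
                         n_windows = integer(), observed_parent = character(),
                         stringsAsFactors = FALSE)
  }
  n_transitions <- sum(vapply(unique(cov$contig), function(cn) {
    cl <- cov$class[cov$contig == cn][order(cov$start[cov$contig == cn])]
    cl <- cl[cl != "tie"]
    if (length(cl) < 2) 0L else sum(cl[-1] != cl[-length(cl)])
  }, integer(1)))
  structure(list(windows = cov, expected_parent = expected_parent,
                 min_abs_diff = min_abs_diff, n_windows = n_windows,
                 n_tie = n_tie, concordance_pct = concordance,
                 n_transitions = n_transitions, switch_blocks = blocks),
            class = "switch_report")
}

#' @export
print.switch_report <- function(x, ...) {
  cat("haplotype switch report\n")
  cat(sprintf("  windows: %d (%d tie)\n", x$n_windows, x$n_tie))
  if (!is.null(x$expected_parent)) {
    cat(sprintf("  expected parent: %s\n", x$expected_parent))
    cat(sprintf("  concordance: %s\n",
                if (is.na(x$concordance_pct)) "NA (no non-tie windows)"
                else sprintf("%.1f%%", x$concordance_pct)))
    cat(sprintf("  switch blocks (unexpected parent): %d\n", nrow(x$switch_blocks)))
  } else {
    cat("  expected parent: none (alternation statistics only)\n")
    cat(sprintf("  haplotype transitions between non-tie windows: %d\n",
                x$n_transitions))
  }
  invisible(x)
}

#' Export plot-ready switch-analysis tracks
#'
#' Writes a per-window TSV (`<prefix>.windows.tsv`: contig, start, end,
#' pct_a, pct_b, diff, class; BED-style 0-based half-open coordinates), a
#' switch-block BED (`<prefix>.switch_blocks.bed`) and a one-row summary
#' TSV (`<prefix>.summary.tsv`).
#'
#' @param report A `switch_report` from [classify_and_score()].
#' @param out_prefix Output path prefix.
#' @param assembly Optional assembly label for the summary row.
#' @return Named character vector of paths, invisibly.
#' @export
export_tracks <- function(report, out_prefix, assembly = "assembly") {
  stopifnot(inherits(report, "switch_report"))
  paths <- c(windows = paste0(out_prefix, ".windows.tsv"),
             blocks = paste0(out_prefix, ".switch_blocks.bed"),
             summary = paste0(out_prefix, ".summary.tsv"))
  write_tsv(report$windows, paths[["windows"]])
  bed <- report$switch_blocks[, c("contig", "start", "end", "observed_parent")]
  write_bed(bed, paths[["blocks"]])
  write_tsv(data.frame(assembly = assembly,
                       expected_parent = report$expected_parent %||% "NA",
                       n_windows = report$n_windows, n_tie = report$n_tie,
                       concordance_pct = report$concordance_pct,
                       n_switch_blocks = nrow(report$switch_blocks),
                       stringsAsFactors = FALSE),
            paths[["summary"]])
  invisible(paths)
}
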