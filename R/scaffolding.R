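# Reference-guided scaffolding: whole-contig placement (no breaking, to
# retain contig integrity), AGP 2.1 scaffold construction, donor-based
# gap patching and the iterative multi-step workflow driver.

#' Filter PAF alignments by block length and mapping quality
#'
#' @param paf PAF data.frame or path.
#' @param min_len Minimum alignment block length in bp (default 1000).
#' @param min_mapq Minimum mapping quality (default 10).
#' @return Filtered PAF data.frame.
#' @export
filter_alignments <- function(paf, min_len = 1000, min_mapq = 10) {
  paf <- as_paf(paf)
  paf[paf$block_len >= min_len & paf$mapq >= min_mapq, , drop = FALSE]
}

#' Place contigs on a reference from filtered alignments
#'
#' Per contig, the assigned chromosome is the one with the largest merged
#' query-interval coverage; `location_confidence` is that coverage over
#' the total across chromosomes. Orientation is the sign of the
#' match-weighted strand sum over winning-chromosome records, with
#' `orientation_confidence` the winning strand mass over the total (a
#' zero net strand sum yields "+" at confidence 0.5, flagged
#' low-confidence). The ordering key is the coverage-weighted mean of
#' target starts of winning-chromosome records. Contigs are placed whole;
#' there is no contig breaking on conflict.
#'
#' @param paf Filtered PAF alignments (data.frame or path).
#' @param contigs Optional character vector of all contig names, used to
#'   report contigs with no surviving alignment in the `unplaced`
#'   attribute.
#' @return data.frame contig, chrom, orientation, order_key,
#'   location_confidence, orientation_confidence, low_confidence; with
#'   attribute `unplaced`.
#' @export
place_contigs <- function(paf, contigs = NULL) {
  paf <- as_paf(paf)
  res <- lapply(split(paf, paf$qname), function(p) {
    cov_by_chrom <- vapply(split(p, p$tname), function(pp) {
      sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(pp$qstart + 1L, pp$qend))))
    }, numeric(1))
    best_cov <- max(cov_by_chrom)
    winners <- names(cov_by_chrom)[cov_by_chrom == best_cov]
    tie <- length(winners) > 1
    chrom <- sort(winners)[1]  # lexicographic tie-break
    total_cov <- sum(cov_by_chrom)
    pw <- p[p$tname == chrom, , drop = FALSE]
    mass_plus <- sum(pw$n_matches[pw$strand == "+"])
    mass_minus <- sum(pw$n_matches[pw$strand == "-"])
    net <- mass_plus - mass_minus
    orientation <- if (net >= 0) "+" else "-"
    ocf <- if (mass_plus + mass_minus == 0) 0.5
           else max(mass_plus, mass_minus) / (mass_plus + mass_minus)
    if (net == 0) ocf <- 0.5
    wts <- pw$qend - pw$qstart
    data.frame(contig = p$qname[1], chrom = chrom, orientation = orientation,
               order_key = stats::weighted.mean(pw$tstart, wts),
               location_confidence = best_cov / total_cov,
               orientation_confidence = ocf,
               low_confidence = tie || net == 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (is.null(out)) {
    out <- data.frame(contig = character(), chrom = character(),
                      orientation = character(), order_key = numeric(),
                      location_confidence = numeric(),
                      orientation_confidence = numeric(),
                      low_confidence = logical(), stringsAsFactors = FALSE)
  }
  attr(out, "unplaced") <-
    if (is.null(contigs)) character(0) else setdiff(contigs, out$contig)
  out
}

#' Build scaffolds from contig placements
#'
#' Per chromosome, contigs are sorted by their ordering key (ties by
#' contig name), joined with fixed-length N gaps; minus-orientation
#' components are reverse-complemented. Scaffolds adopt the reference
#' chromosome names. Unplaced contigs are emitted unchanged as their own
#' single-component objects. Gap records carry gap_type "scaffold",
#' linkage "yes" and evidence "align_genus".
#'
#' @param placements data.frame from [place_contigs()].
#' @param contigs Contig sequences (named character, `DNAStringSet` or
#'   FASTA path).
#' @param gap_len Gap length between joined contigs in bp (default 100).
#' @return list with `plan` (a `scaffold_plan` data.frame, AGP 2.1
#'   semantics), `scaffolds` (named character), and `unplaced` (names).
#' @export
build_scaffolds <- function(placements, contigs, gap_len = 100) {
  contigs <- as_seqchar(contigs)
  if (anyDuplicated(placements$contig)) {
    stop("duplicate contig placement: ",
         placements$contig[duplicated(placements$contig)][1])
  }
  missing <- setdiff(placements$contig, names(contigs))
  if (length(missing) > 0) {
    stop("placed contig(s) missing from sequences: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  plan_rows <- list()
  scaffolds <- character(0)
  for (chrom in sort(unique(placements$chrom))) {
    pc <- placements[placements$chrom == chrom, , drop = FALSE]
    pc <- pc[order(pc$order_key, pc$contig), , drop = FALSE]
    pos <- 0
    part <- 0L
    pieces <- character(0)
    for (i in seq_len(nrow(pc))) {
      if (i > 1 && gap_len > 0) {
        part <- part + 1L
        plan_rows[[length(plan_rows) + 1]] <- data.frame(
          object = chrom, object_beg = pos + 1, object_end = pos + gap_len,
          part_number = part, component_type = "N",
          component_id = NA_character_, component_beg = NA, component_end = NA,
          orientation = NA_character_, gap_length = gap_len,
          gap_type = "scaffold", linkage = "yes",
          linkage_evidence = "align_genus", stringsAsFactors = FALSE)
        pos <- pos + gap_len
        pieces <- c(pieces, strrep("N", gap_len))
      }
      s <- contigs[[pc$contig[i]]]
      len <- nchar(s)
      part <- part + 1L
      plan_rows[[length(plan_rows) + 1]] <- data.frame(
        object = chrom, object_beg = pos + 1, object_end = pos + len,
        part_number = part, component_type = "W",
        component_id = pc$contig[i], component_beg = 1, component_end = len,
        orientation = pc$orientation[i], gap_length = NA,
        gap_type = NA_character_, linkage = NA_character_,
        linkage_evidence = NA_character_, stringsAsFactors = FALSE)
      pos <- pos + len
      pieces <- c(pieces, if (pc$orientation[i] == "-") rc_chr(s) else s)
    }
    scaffolds[[chrom]] <- paste(pieces, collapse = "")
  }
  unplaced <- setdiff(names(contigs), placements$contig)
  for (cn in unplaced) {
    len <- nchar(contigs[[cn]])
    plan_rows[[length(plan_rows) + 1]] <- data.frame(
      object = cn, object_beg = 1, object_end = len, part_number = 1L,
      component_type = "W", component_id = cn, component_beg = 1,
      component_end = len, orientation = "+", gap_length = NA,
      gap_type = NA_character_, linkage = NA_character_,
      linkage_evidence = NA_character_, stringsAsFactors = FALSE)
    scaffolds[[cn]] <- contigs[[cn]]
  }
  plan <- do.call(rbind, plan_rows)
  class(plan) <- c("scaffold_plan", "data.frame")
  validate_scaffold_plan(plan)
  list(plan = plan, scaffolds = scaffolds, unplaced = unplaced)
}

# linear map of a target coordinate through a (gapless) PAF record
map_to_query <- function(rec, tpos) {
  if (rec$strand == "+") rec$qstart + (tpos - rec$tstart)
  else rec$qend - (tpos - rec$tstart)
}

#' Patch assembly gaps with donor sequence
#'
#' A gap (maximal N-run in the target) is filled when one donor sequence
#' aligns to both flanks within `flank` bp in consistent orientation and
#' collinear order. Anchors are chosen as the longest flank alignments;
#' the gap (plus any flank overlap implied by the anchor coordinates) is
#' replaced by the donor sequence spanning between the anchor ends.
#' Conflicting donors leave the gap unpatched and are logged in the plan.
#'
#' @param target Target sequences (named character, `DNAStringSet` or
#'   FASTA path).
#' @param donor_paf Donor-to-target alignments (PAF data.frame or path;
#'   query = donor, target = target).
#' @param donor Donor sequences.
#' @param flank Maximum distance from a gap edge to its anchor alignment
#'   (default 50000 bp).
#' @return list with `patched` (named character) and `plan` (data.frame
#'   contig, gap_start, gap_end, status, donor, donor_start, donor_end,
#'   strand).
#' @export
patch_gaps <- function(target, donor_paf, donor, flank = 50000) {
  target <- as_seqchar(target)
  donor <- as_seqchar(donor)
  paf <- as_paf(donor_paf)
  gaps <- find_gaps(target, min_run = 1)
  plan <- list()
  patched <- target
  if (nrow(gaps) == 0) {
    return(list(patched = patched,
                plan = data.frame(contig = character(), gap_start = numeric(),
                                  gap_end = numeric(), status = character(),
                                  donor = character(), donor_start = numeric(),
                                  donor_end = numeric(), strand = character(),
                                  stringsAsFactors = FALSE)))
  }
  # apply right-to-left within each contig so earlier coordinates stay valid
  gaps <- gaps[order(gaps$contig, -gaps$start), , drop = FALSE]
  for (i in seq_len(nrow(gaps))) {
    g <- gaps[i, ]
    p <- paf[paf$tname == g$contig, , drop = FALSE]
    left <- p[p$tstart < g$start & p$tend >= g$start - flank, , drop = FALSE]
    right <- p[p$tend > g$end & p$tstart <= g$end + flank, , drop = FALSE]
    rec <- function(d) if (nrow(d) == 0) NULL else d[which.max(d$block_len), ]
    L <- rec(left)
    R <- rec(right)
    entry <- data.frame(contig = g$contig, gap_start = g$start, gap_end = g$end,
                        status = "unpatched", donor = NA_character_,
                        donor_start = NA, donor_end = NA,
                        strand = NA_character_, stringsAsFactors = FALSE)
    if (!is.null(L) && !is.null(R)) {
      if (L$qname != R$qname || L$strand != R$strand) {
        entry$status <- "conflict"
      } else {
        tL <- min(g$start, L$tend)
        tR <- max(g$end, R$tstart)
        dL <- map_to_query(L, tL)
        dR <- map_to_query(R, tR)
        ok <- if (L$strand == "+") dR > dL else dL > dR
        if (!ok) {
          entry$status <- "conflict"
        } else {
          dseq <- donor[[L$qname]]
          seg <- if (L$strand == "+") substr(dseq, dL + 1, dR)
                 else rc_chr(substr(dseq, dR + 1, dL))
          s <- patched[[g$contig]]
          patched[[g$contig]] <- paste0(substr(s, 1, tL), seg,
                                        substr(s, tR + 1, nchar(s)))
          entry$status <- "patched"
          entry$donor <- L$qname
          entry$donor_start <- min(dL, dR)
          entry$donor_end <- max(dL, dR)
          entry$strand <- L$strand
        }
      }
    }
    plan[[length(plan) + 1]] <- entry
  }
  plan <- do.call(rbind, plan)
  plan <- plan[order(plan$contig, plan$gap_start), , drop = FALSE]
  rownames(plan) <- NULL
  list(patched = patched, plan = plan)
}

#' Run an iterative scaffolding / patching workflow
#'
#' Executes an ordered list of steps, each either a `scaffold` action
#' (query contigs ordered and oriented against a reference) or a `patch`
#' action (gaps in the query filled from a donor). Any step's reference
#' may be an externally produced assembly (e.g. an optical-map hybrid).
#' After each step contig/scaffold statistics are recorded.
#'
#' @param steps List of steps; each a list with elements `name`, `action`
#'   ("scaffold" or "patch"), `query` (FASTA path or sequences),
#'   `reference` (scaffold) or `donor` (patch), and `alignments` (PAF
#'   path or data.frame of query/donor vs reference/target). May also be
#'   a YAML config path with a top-level `steps` list.
#' @param out_dir Optional directory: per-step FASTA (and AGP for
#'   scaffold steps) are written there.
#' @param min_len,min_mapq Alignment filters (defaults 1000 bp, mapq 10).
#' @param gap_len Scaffold join gap length (default 100).
#' @param flank Patch anchor distance (default 50000).
#' @return list with `assemblies` (named list of per-step sequences) and
#'   `stats` (data.frame, one row per step).
#' @export
run_workflow <- function(steps, out_dir = NULL, min_len = 1000, min_mapq = 10,
                         gap_len = 100, flank = 50000) {
  if (is.character(steps) && length(steps) == 1) {
    if (!file.exists(steps)) stop("workflow config not found: ", steps)
    steps <- yaml::read_yaml(steps)$steps
  }
  stats_rows <- list()
  assemblies <- list()
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  for (i in seq_along(steps)) {
    st <- steps[[i]]
    nm <- st$name %||% paste0("step", i)
    for (f in c("query", "reference", "donor", "alignments")) {
      if (!is.null(st[[f]]) && is.character(st[[f]]) && length(st[[f]]) == 1 &&
          !file.exists(st[[f]])) {
        stop("workflow step '", nm, "': missing input file for '", f, "': ",
             st[[f]])
      }
    }
    query <- as_seqchar(st$query)
    paf <- as_paf(st$alignments)
    if (identical(st$action, "scaffold")) {
      pl <- place_contigs(filter_alignments(paf, min_len, min_mapq),
                          contigs = names(query))
      res <- build_scaffolds(pl, query, gap_len = gap_len)
      out_seqs <- res$scaffolds
      if (!is.null(out_dir)) {
        write_agp(res$plan, file.path(out_dir, paste0(nm, ".agp")))
      }
    } else if (identical(st$action, "patch")) {
      donor <- as_seqchar(st$donor)
      res <- patch_gaps(query, paf, donor, flank = flank)
      out_seqs <- res$patched
      if (!is.null(out_dir)) {
        write_tsv(res$plan, file.path(out_dir, paste0(nm, ".patchplan.tsv")))
      }
    } else {
      stop("workflow step '", nm, "': unknown action '", st$action, "'")
    }
    if (!is.null(out_dir)) {
      write_seqs(out_seqs, file.path(out_dir, paste0(nm, ".fasta")))
    }
    assemblies[[nm]] <- out_seqs
    as_stats <- assembly_stats(out_seqs)
    stats_rows[[length(stats_rows) + 1]] <- data.frame(
      step = i, name = nm, action = st$action,
      n_scaffolds = as_stats$n_scaffolds, n_contigs = as_stats$n_contigs,
      total_size = as_stats$total_size,
      scaffold_n50 = as_stats$scaffold_n50, scaffold_n90 = as_stats$scaffold_n90,
      contig_n50 = as_stats$contig_n50, contig_n90 = as_stats$contig_n90,
      stringsAsFactors = FALSE)
  }
  stats <- if (length(stats_rows) == 0) {
    data.frame(step = integer(), name = character(), action = character(),
               n_scaffolds = integer(), n_contigs = integer(),
               total_size = numeric(), scaffold_n50 = numeric(),
               scaffold_n90 = numeric(), contig_n50 = numeric(),
               contig_n90 = numeric(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, stats_rows)
  }
  if (!is.null(out_dir) && nrow(stats) > 0) {
    write_tsv(stats, file.path(out_dir, "workflow_stats.tsv"))
  }
  list(assemblies = assemblies, stats = stats)
}
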