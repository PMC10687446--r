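# Synthetic trio generator: ancestor genome with telomere arrays,
# double-haploid parental haplotypes at a configurable heterozygosity,
# parental short reads, F1 long reads, mosaic assemblies, shredded
# contigs, planted gaps - all with full ground truth, plus truth PAF
# emulating haplotype-aware alignment so downstream modules are testable
# without an external aligner.

#' Simulator configuration
#'
#' Defaults are the study conditions of a desk-scale pepper-like trio:
#' double-haploid parents sequenced at 45x with 150 bp paired-end short
#' reads, an F1 sequenced at 58x with HiFi-like ~15 kb long reads at
#' 0.1% substitution error, and a genome-wide heterozygosity of 0.1168%
#' split between SNPs and short indels. The genome itself is scaled to
#' 5 Mb (two 2.5 Mb chromosomes) so the full pipeline runs on a desktop.
#'
#' Variant positions are drawn over the ancestor at `snp_rate` /
#' `indel_rate` per bp and each variant is applied to one haplotype
#' chosen at random, so the realized heterozygosity matches
#' `snp_rate + indel_rate` directly.
#'
#' @param seed Integer seed; fixed seed gives byte-identical outputs.
#' @param n_chroms,chrom_len Number and length (bp) of chromosomes.
#' @param gc GC fraction of the ancestor sequence.
#' @param snp_rate,indel_rate Per-bp heterozygous variant rates.
#' @param indel_size_mean Mean indel length (geometric; default 3 bp).
#' @param telomere_unit,telomere_copies Telomere repeat unit (default
#'   TTAGGG) and tandem copies appended to each chromosome end.
#' @param short_read_len,short_insert_mean,short_coverage,short_error
#'   Parental short-read model: 150 bp paired-end, ~400 bp inserts, 45x,
#'   0.1% substitution error.
#' @param long_len_mean,long_coverage,long_error F1 long-read model:
#'   lognormal lengths with 15 kb mean, 58x, 0.1% substitution error.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_chroms = 2L, chrom_len = 2.5e6, gc = 0.35,
                       snp_rate = 0.001, indel_rate = 0.000168,
                       indel_size_mean = 3, telomere_unit = "TTAGGG",
                       telomere_copies = 300L, short_read_len = 150L,
                       short_insert_mean = 400, short_coverage = 45,
                       short_error = 0.001, long_len_mean = 15000,
                       long_coverage = 58, long_error = 0.001) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_len = chrom_len, gc = gc, snp_rate = snp_rate,
              indel_rate = indel_rate, indel_size_mean = indel_size_mean,
              telomere_unit = toupper(telomere_unit),
              telomere_copies = as.integer(telomere_copies),
              short_read_len = as.integer(short_read_len),
              short_insert_mean = short_insert_mean,
              short_coverage = short_coverage, short_error = short_error,
              long_len_mean = long_len_mean, long_coverage = long_coverage,
              long_error = long_error)
  rates <- c(cfg$snp_rate, cfg$indel_rate, cfg$short_error, cfg$long_error)
  stopifnot(all(rates >= 0), all(rates < 1), cfg$gc > 0, cfg$gc < 1,
            cfg$chrom_len >= 1000, cfg$n_chroms >= 1)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a pair of double-haploid parental genomes
#'
#' Draws an i.i.d. ancestor with the configured GC bias, appends telomere
#' arrays to both ends of each chromosome (reverse-complement orientation
#' at the 5' end), then derives haplotypes A and B by applying SNPs and
#' indels at the configured rates, each variant to one haplotype chosen
#' at random. Overlapping indels are resolved left-to-right (a variant
#' falling inside an earlier deletion on the same haplotype is dropped).
#'
#' @param config A [sim_config()].
#' @param seed Seed (default `config$seed`).
#' @return list with `hap_a`, `hap_b` (named character), and `truth`: a
#'   list with `variants` (chrom, pos (0-based, ancestor coords), type,
#'   ref, alt, haplotype), `ancestor_lengths`, and `realized_het`
#'   (percent).
#' @export
simulate_parents <- function(config, seed = config$seed) {
  set.seed(seed)
  tel <- strrep(config$telomere_unit, config$telomere_copies)
  tel5 <- rc_chr(tel)
  chroms <- paste0("chr", seq_len(config$n_chroms))
  anc <- stats::setNames(vapply(chroms, function(cn) {
    paste0(tel5, cpp_random_dna(as.integer(config$chrom_len), config$gc), tel)
  }, character(1)), chroms)
  hap_a <- anc
  hap_b <- anc
  vars <- list()
  for (cn in chroms) {
    L <- nchar(anc[[cn]])
    n_snp <- stats::rbinom(1, L, config$snp_rate)
    n_indel <- stats::rbinom(1, L, config$indel_rate)
    pos <- sort(sample.int(L, n_snp + n_indel))
    if (length(pos) == 0) next
    type <- sample(rep(c("snp", "indel"), c(n_snp, n_indel)))
    hap <- sample(c("A", "B"), length(pos), replace = TRUE)
    ref <- substr_vec(anc[[cn]], pos, pos)
    alt <- character(length(pos))
    ilen <- integer(length(pos))
    is_snp <- type == "snp"
    alt[is_snp] <- vapply(ref[is_snp], other_base, character(1))
    idx_ind <- which(!is_snp)
    if (length(idx_ind) > 0) {
      ilen[idx_ind] <- 1L + stats::rgeom(length(idx_ind),
                                         prob = 1 / config$indel_size_mean)
      ins <- runif(length(idx_ind)) < 0.5
      type[idx_ind] <- ifelse(ins, "ins", "del")
      alt[idx_ind[ins]] <- vapply(ilen[idx_ind[ins]], function(n)
        cpp_random_dna(n, config$gc), character(1))
    }
    v <- data.frame(chrom = cn, pos = pos - 1, type = type, ref = ref,
                    alt = alt, indel_len = ilen, haplotype = hap,
                    stringsAsFactors = FALSE)
    for (h in c("A", "B")) {
      vh <- v[v$haplotype == h, , drop = FALSE]
      applied <- apply_variants(anc[[cn]], vh)
      if (h == "A") hap_a[[cn]] <- applied$seq else hap_b[[cn]] <- applied$seq
      v$applied[v$haplotype == h] <- applied$applied
    }
    vars[[cn]] <- v[v$applied, setdiff(names(v), "applied")]
  }
  variants <- if (length(vars) > 0) do.call(rbind, vars) else
    data.frame(chrom = character(), pos = numeric(), type = character(),
               ref = character(), alt = character(), indel_len = integer(),
               haplotype = character(), stringsAsFactors = FALSE)
  rownames(variants) <- NULL
  anc_len <- nchar(anc)
  list(hap_a = hap_a, hap_b = hap_b,
       truth = list(variants = variants, ancestor_lengths = anc_len,
                    realized_het = 100 * nrow(variants) / sum(anc_len)))
}

substr_vec <- function(s, from, to) {
  substring(s, from, to)
}

other_base <- function(b) {
  sample(setdiff(c("A", "C", "G", "T"), toupper(b)), 1)
}

# apply SNPs/indels (1-based positions in $pos + 1) to one sequence,
# left-to-right; returns the mutated sequence and which variants applied
apply_variants <- function(seq, vars) {
  if (nrow(vars) == 0) return(list(seq = seq, applied = logical(0)))
  vars <- vars[order(vars$pos), , drop = FALSE]
  applied <- rep(TRUE, nrow(vars))
  # drop variants inside an earlier deletion
  del_until <- -1
  for (i in seq_len(nrow(vars))) {
    if (vars$pos[i] <= del_until) { applied[i] <- FALSE; next }
    if (vars$type[i] == "del") del_until <- vars$pos[i] + vars$indel_len[i]
  }
  v <- vars[applied, , drop = FALSE]
  pieces <- character(0)
  cursor <- 1  # 1-based next unconsumed position
  for (i in seq_len(nrow(v))) {
    p1 <- v$pos[i] + 1
    if (v$type[i] == "snp") {
      pieces <- c(pieces, substr(seq, cursor, p1 - 1), v$alt[i])
      cursor <- p1 + 1
    } else if (v$type[i] == "ins") {
      pieces <- c(pieces, substr(seq, cursor, p1), v$alt[i])
      cursor <- p1 + 1
    } else {  # del: remove indel_len bases after the anchor base
      pieces <- c(pieces, substr(seq, cursor, p1))
      cursor <- p1 + 1 + v$indel_len[i]
    }
  }
  pieces <- c(pieces, substr(seq, cursor, nchar(seq)))
  list(seq = paste(pieces, collapse = ""), applied = applied)
}

#' Simulate paired-end short reads from one haplotype
#'
#' Uniform insert start positions, Normal insert sizes
#' (sd = 0.1 x mean), inward (FR) mate orientation, substitution errors
#' at `short_error`. The pair count is
#' `coverage x genome / (2 x read_len)`.
#'
#' @param hap Haplotype sequences (named character).
#' @param config A [sim_config()].
#' @param seed Seed.
#' @param prefix Read-name prefix.
#' @return list with `read1`, `read2` (named character vectors; names
#'   end in /1 and /2) and `truth` (read_id, chrom, insert_start,
#'   insert_end; 0-based half-open).
#' @export
simulate_short_reads <- function(hap, config, seed = config$seed + 1L,
                                 prefix = "sr") {
  set.seed(seed)
  rl <- config$short_read_len
  lens <- nchar(hap)
  usable <- lens >= 2 * config$short_insert_mean
  if (!all(usable)) {
    warning("chromosome(s) shorter than the insert size skipped: ",
            paste(names(hap)[!usable], collapse = ", "))
    hap <- hap[usable]
    lens <- lens[usable]
  }
  stopifnot(length(hap) > 0, config$short_coverage > 0)
  n_pairs <- round(config$short_coverage * sum(lens) / (2 * rl))
  chrom_idx <- sample.int(length(hap), n_pairs, replace = TRUE,
                          prob = lens / sum(lens))
  insert <- pmax(round(stats::rnorm(n_pairs, config$short_insert_mean,
                                    0.1 * config$short_insert_mean)), rl)
  insert <- pmin(insert, lens[chrom_idx])
  start <- floor(runif(n_pairs) * (lens[chrom_idx] - insert)) + 1  # 1-based
  r1 <- substring(hap[chrom_idx], start, start + rl - 1)
  r2 <- rc_chr(substring(hap[chrom_idx], start + insert - rl, start + insert - 1))
  r1 <- cpp_add_errors(r1, config$short_error)
  r2 <- cpp_add_errors(r2, config$short_error)
  ids <- sprintf("%s%07d", prefix, seq_len(n_pairs))
  names(r1) <- paste0(ids, "/1")
  names(r2) <- paste0(ids, "/2")
  truth <- data.frame(read_id = ids, chrom = names(hap)[chrom_idx],
                      insert_start = start - 1, insert_end = start - 1 + insert,
                      stringsAsFactors = FALSE)
  list(read1 = r1, read2 = r2, truth = truth)
}

#' Simulate F1 long reads from the two haplotypes
#'
#' Reads are drawn from haplotype A or B with equal probability
#' (emulating an F1 diploid), with lognormal lengths
#' (mean `long_len_mean`, sdlog 0.3), random strand, and substitution
#' errors at `long_error`. Read names encode the truth origin; the
#' origin table gives exact source coordinates (of the error-free
#' template) for aligner-free downstream tests.
#'
#' @param hap_a,hap_b Haplotype sequences (named character, same names).
#' @param config A [sim_config()].
#' @param seed Seed.
#' @return list with `reads` (named character) and `origins` (read_id,
#'   haplotype, chrom, start, end, strand; 0-based half-open).
#' @export
simulate_long_reads <- function(hap_a, hap_b, config, seed = config$seed + 3L) {
  set.seed(seed)
  stopifnot(identical(names(hap_a), names(hap_b)), config$long_coverage > 0)
  lens_a <- nchar(hap_a)
  lens_b <- nchar(hap_b)
  n <- round(config$long_coverage * sum(lens_a) / config$long_len_mean)
  hap <- ifelse(runif(n) < 0.5, "A", "B")
  sdlog <- 0.3
  meanlog <- log(config$long_len_mean) - sdlog^2 / 2
  len <- pmax(round(stats::rlnorm(n, meanlog, sdlog)), 500)
  chrom_idx <- sample.int(length(hap_a), n, replace = TRUE,
                          prob = lens_a / sum(lens_a))
  src_len <- ifelse(hap == "A", lens_a[chrom_idx], lens_b[chrom_idx])
  len <- pmin(len, src_len)
  start <- floor(runif(n) * (src_len - len)) + 1  # 1-based
  seqs <- character(n)
  for (h in c("A", "B")) {
    idx <- which(hap == h)
    src <- if (h == "A") hap_a else hap_b
    seqs[idx] <- substring(src[chrom_idx[idx]], start[idx],
                           start[idx] + len[idx] - 1)
  }
  strand <- ifelse(runif(n) < 0.5, "+", "-")
  seqs[strand == "-"] <- rc_chr(seqs[strand == "-"])
  seqs <- cpp_add_errors(seqs, config$long_error)
  chrom <- names(hap_a)[chrom_idx]
  ids <- sprintf("lr%06d_%s_%s_%d_%d", seq_len(n), hap, chrom,
                 start - 1, start - 1 + len)
  names(seqs) <- ids
  origins <- data.frame(read_id = ids, haplotype = hap, chrom = chrom,
                        start = start - 1, end = start - 1 + len,
                        strand = strand, stringsAsFactors = FALSE)
  list(reads = seqs, origins = origins)
}

#' Simulate a haplotype-switching (mosaic) assembly
#'
#' Copies alternating blocks from haplotypes A and B at homologous
#' coordinates (requires indel-free haplotypes so that coordinates
#' agree), starting with A. Emulates the chimeric assemblies produced by
#' naive (non-binned) phasing.
#'
#' @param hap_a,hap_b Haplotype sequences with identical per-chromosome
#'   lengths.
#' @param switch_points Named list (per chromosome) of 0-based switch
#'   positions; chromosomes absent from the list get no switches.
#' @return list with `assembly` (named character) and `blocks`
#'   (contig, start, end, haplotype) tiling each chromosome exactly.
#' @export
simulate_mosaic_assembly <- function(hap_a, hap_b, switch_points = list()) {
  stopifnot(identical(names(hap_a), names(hap_b)))
  if (!all(nchar(hap_a) == nchar(hap_b))) {
    stop("mosaic assembly requires indel-free haplotypes ",
         "(per-chromosome lengths must agree)")
  }
  assembly <- character(0)
  blocks <- list()
  for (cn in names(hap_a)) {
    L <- nchar(hap_a[[cn]])
    pts <- sort(unique(switch_points[[cn]]))
    stopifnot(all(pts > 0), all(pts < L))
    bounds <- c(0, pts, L)
    haps <- rep(c("A", "B"), length.out = length(bounds) - 1)
    pieces <- vapply(seq_len(length(bounds) - 1), function(i) {
      src <- if (haps[i] == "A") hap_a[[cn]] else hap_b[[cn]]
      substr(src, bounds[i] + 1, bounds[i + 1])
    }, character(1))
    assembly[[cn]] <- paste(pieces, collapse = "")
    blocks[[cn]] <- data.frame(contig = cn, start = bounds[-length(bounds)],
                               end = bounds[-1], haplotype = haps,
                               stringsAsFactors = FALSE)
  }
  list(assembly = assembly, blocks = do.call(rbind, blocks))
}

#' Truth PAF of long-read placements on an assembly
#'
#' Emulates idealized haplotype-aware alignment: a read is placed (full
#' length, at its truth coordinates) when the assembly block containing
#' its midpoint derives from the read's own haplotype; reads over blocks
#' of the other haplotype are left unaligned (with a real aligner they
#' attain their primary alignment on the other haplotype's assembly).
#'
#' @param origins Read origin table from [simulate_long_reads()].
#' @param blocks Assembly haplotype blocks (contig, start, end,
#'   haplotype): from [simulate_mosaic_assembly()], or one block per
#'   chromosome for a fully phased assembly.
#' @param contig_lengths Named lengths of the assembly contigs.
#' @return PAF data.frame.
#' @export
truth_alignment_paf <- function(origins, blocks, contig_lengths) {
  mid <- floor((origins$start + origins$end) / 2)
  placed <- vapply(seq_len(nrow(origins)), function(i) {
    b <- blocks[blocks$contig == origins$chrom[i] &
                  blocks$start <= mid[i] & blocks$end > mid[i], , drop = FALSE]
    nrow(b) > 0 && b$haplotype[1] == origins$haplotype[i]
  }, logical(1))
  o <- origins[placed, , drop = FALSE]
  len <- o$end - o$start
  data.frame(qname = o$read_id, qlen = len, qstart = 0, qend = len,
             strand = o$strand, tname = o$chrom,
             tlen = as.numeric(contig_lengths[o$chrom]),
             tstart = o$start, tend = o$end, n_matches = len,
             block_len = len, mapq = 60, tags = "",
             stringsAsFactors = FALSE)
}

#' Shred sequences into fragments
#'
#' Sequential fragments with Normal(frag_mean, frag_sd) sizes (minimum
#' 1 kb), each independently dropped with probability `dropout` and
#' reverse-complemented with probability `flip_prob`; fragment names
#' encode the truth coordinates.
#'
#' @param seqs Sequences (named character, `DNAStringSet` or FASTA path).
#' @param frag_mean,frag_sd Fragment size model (defaults 200 kb, 80 kb).
#' @param dropout Per-fragment drop probability (default 0).
#' @param flip_prob Per-fragment reverse-complement probability
#'   (default 0.5).
#' @param seed Seed.
#' @return list with `fragments` (named character) and `truth` (frag_id,
#'   source, start, end, strand; 0-based half-open, original order).
#' @export
shred <- function(seqs, frag_mean = 2e5, frag_sd = 8e4, dropout = 0,
                  flip_prob = 0.5, seed = 1L) {
  set.seed(seed)
  seqs <- as_seqchar(seqs)
  stopifnot(frag_mean > 0, dropout >= 0, dropout <= 1)
  frags <- character(0)
  truth <- list()
  k <- 0
  for (cn in names(seqs)) {
    L <- nchar(seqs[[cn]])
    pos <- 0
    while (pos < L) {
      size <- max(round(stats::rnorm(1, frag_mean, frag_sd)), 1000)
      end <- min(pos + size, L)
      k <- k + 1
      id <- sprintf("frag%04d_%s_%d_%d", k, cn, pos, end)
      if (runif(1) >= dropout) {
        s <- substr(seqs[[cn]], pos + 1, end)
        strand <- if (runif(1) < flip_prob) "-" else "+"
        if (strand == "-") s <- rc_chr(s)
        frags[[id]] <- s
        truth[[length(truth) + 1]] <- data.frame(
          frag_id = id, source = cn, start = pos, end = end, strand = strand,
          stringsAsFactors = FALSE)
      }
      pos <- end
    }
  }
  truth <- if (length(truth) > 0) do.call(rbind, truth) else
    data.frame(frag_id = character(), source = character(), start = numeric(),
               end = numeric(), strand = character(), stringsAsFactors = FALSE)
  list(fragments = frags, truth = truth)
}

#' Truth PAF of shredded fragments against their source
#'
#' @param truth Fragment truth table from [shred()].
#' @param source_lengths Named lengths of the source sequences.
#' @return PAF data.frame (full-length, perfect-identity records).
#' @export
fragments_paf <- function(truth, source_lengths) {
  len <- truth$end - truth$start
  data.frame(qname = truth$frag_id, qlen = len, qstart = 0, qend = len,
             strand = truth$strand, tname = truth$source,
             tlen = as.numeric(source_lengths[truth$source]),
             tstart = truth$start, tend = truth$end, n_matches = len,
             block_len = len, mapq = 60, tags = "", stringsAsFactors = FALSE)
}

#' Replace random intervals with N-gaps
#'
#' Produces a gapped copy of each sequence for gap-patching fixtures:
#' `n_gaps` non-overlapping intervals of `gap_len` bases, at least
#' `min_flank` from the ends and from each other, are replaced by N.
#'
#' @param seqs Sequences (named character, `DNAStringSet` or FASTA path).
#' @param n_gaps Gaps per sequence (default 3).
#' @param gap_len Gap length in bp (default 5000).
#' @param min_flank Minimum distance between gaps and from sequence ends
#'   (default 20000).
#' @param seed Seed.
#' @return list with `gapped` (named character) and `gaps` (contig,
#'   start, end; 0-based half-open).
#' @export
plant_gaps <- function(seqs, n_gaps = 3, gap_len = 5000, min_flank = 20000,
                       seed = 1L) {
  set.seed(seed)
  seqs <- as_seqchar(seqs)
  gapped <- seqs
  gaps <- list()
  for (cn in names(seqs)) {
    L <- nchar(seqs[[cn]])
    slot <- floor((L - 2 * min_flank) / n_gaps)
    stopifnot(slot > gap_len + min_flank)
    for (j in seq_len(n_gaps)) {
      lo <- min_flank + (j - 1) * slot
      start <- lo + floor(runif(1) * (slot - gap_len - min_flank))
      end <- start + gap_len
      gapped[[cn]] <- paste0(substr(gapped[[cn]], 1, start),
                             strrep("N", gap_len),
                             substr(gapped[[cn]], end + 1, L))
      gaps[[length(gaps) + 1]] <- data.frame(contig = cn, start = start,
                                             end = end, stringsAsFactors = FALSE)
    }
  }
  list(gapped = gapped, gaps = do.call(rbind, gaps))
}

#' Donor-to-target alignments over the non-gap segments
#'
#' For a target produced by [plant_gaps()] (gaps replace equal-length
#' donor sequence, so coordinates agree), emits one perfect PAF record
#' per non-N segment mapping the donor to the target. This is the truth
#' analogue of aligning the donor to the gapped assembly.
#'
#' @param gapped Gapped target sequences.
#' @param donor Ungapped donor sequences with the same names and lengths.
#' @return PAF data.frame (query = donor, target = gapped).
#' @export
segment_alignments <- function(gapped, donor) {
  gapped <- as_seqchar(gapped)
  donor <- as_seqchar(donor)
  stopifnot(identical(sort(names(gapped)), sort(names(donor))))
  out <- list()
  for (cn in names(gapped)) {
    L <- nchar(gapped[[cn]])
    stopifnot(nchar(donor[[cn]]) == L)
    g <- n_runs(gapped[[cn]])
    bounds <- c(0, as.vector(rbind(g$start, g$end)), L)
    starts <- bounds[seq(1, length(bounds), by = 2)]
    ends <- bounds[seq(2, length(bounds), by = 2)]
    keep <- ends > starts
    starts <- starts[keep]
    ends <- ends[keep]
    if (length(starts) == 0) next
    out[[cn]] <- data.frame(
      qname = cn, qlen = L, qstart = starts, qend = ends, strand = "+",
      tname = cn, tlen = L, tstart = starts, tend = ends,
      n_matches = ends - starts, block_len = ends - starts, mapq = 60,
      tags = "", stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(empty_paf())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a full trio: parents, parental short reads and F1 long reads
#'
#' Convenience wrapper chaining [simulate_parents()],
#' [simulate_short_reads()] (per parent) and [simulate_long_reads()],
#' with decorrelated seeds derived from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return list with `parents`, `short_a`, `short_b`, `long`.
#' @export
simulate_trio <- function(config) {
  parents <- simulate_parents(config, seed = config$seed)
  short_a <- simulate_short_reads(parents$hap_a, config,
                                  seed = config$seed + 1L, prefix = "srA")
  short_b <- simulate_short_reads(parents$hap_b, config,
                                  seed = config$seed + 2L, prefix = "srB")
  long <- simulate_long_reads(parents$hap_a, parents$hap_b, config,
                              seed = config$seed + 3L)
  list(parents = parents, short_a = short_a, short_b = short_b, long = long)
}
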