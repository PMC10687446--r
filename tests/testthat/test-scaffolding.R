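# reference-guided placement, AGP scaffolding, gap patching, workflow

paf_row <- function(qname, qlen, qstart, qend, strand, tname, tstart, tend,
                    n_matches = qend - qstart, mapq = 60) {
  data.frame(qname = qname, qlen = qlen, qstart = qstart, qend = qend,
             strand = strand, tname = tname, tlen = 1e6, tstart = tstart,
             tend = tend, n_matches = n_matches,
             block_len = qend - qstart, mapq = mapq, tags = "",
             stringsAsFactors = FALSE)
}

test_that("alignment filtering drops short and low-mapq records", {
  paf <- rbind(paf_row("c1", 5000, 0, 500, "+", "chr1", 0, 500),
               paf_row("c1", 5000, 0, 5000, "+", "chr1", 0, 5000, mapq = 5),
               paf_row("c2", 5000, 0, 5000, "+", "chr1", 0, 5000))
  out <- filter_alignments(paf, min_len = 1000, min_mapq = 10)
  expect_equal(out$qname, "c2")
  expect_equal(nrow(filter_alignments(paf[0, ])), 0L)
  expect_equal(filter_alignments(paf, min_len = 1, min_mapq = 0), paf)
})

test_that("contig placement picks chromosome, orientation and confidences", {
  # single clean record
  p1 <- place_contigs(paf_row("c1", 1000, 0, 1000, "+", "chr1", 5000, 6000))
  expect_equal(p1$chrom, "chr1")
  expect_equal(p1$orientation, "+")
  expect_equal(p1$location_confidence, 1)
  expect_equal(p1$orientation_confidence, 1)
  expect_false(p1$low_confidence)
  # 70/30 coverage split between chromosomes
  p2 <- place_contigs(rbind(
    paf_row("c1", 1000, 0, 700, "+", "chr1", 0, 700),
    paf_row("c1", 1000, 700, 1000, "+", "chr2", 0, 300)))
  expect_equal(p2$chrom, "chr1")
  expect_equal(p2$location_confidence, 0.7)
  # equal coverage -> lexicographically smaller chromosome, flagged
  p3 <- place_contigs(rbind(
    paf_row("c1", 1000, 0, 500, "+", "chrB", 0, 500),
    paf_row("c1", 1000, 500, 1000, "+", "chrA", 0, 500)))
  expect_equal(p3$chrom, "chrA")
  expect_true(p3$low_confidence)
  # orientation by match-weighted strand mass
  p4 <- place_contigs(rbind(
    paf_row("c1", 1000, 0, 400, "+", "chr1", 0, 400, n_matches = 300),
    paf_row("c1", 1000, 400, 1000, "-", "chr1", 400, 1000, n_matches = 500)))
  expect_equal(p4$orientation, "-")
  expect_equal(p4$orientation_confidence, 500 / 800)
  # order key is the coverage-weighted mean of target starts
  p5 <- place_contigs(rbind(
    paf_row("c1", 1000, 0, 600, "+", "chr1", 1000, 1600),
    paf_row("c1", 1000, 600, 1000, "+", "chr1", 4000, 4400)))
  expect_equal(p5$order_key, stats::weighted.mean(c(1000, 4000), c(600, 400)))
  # unplaced reporting
  p6 <- place_contigs(paf_row("c1", 1000, 0, 1000, "+", "chr1", 0, 1000),
                      contigs = c("c1", "c9"))
  expect_equal(attr(p6, "unplaced"), "c9")
})

test_that("scaffold construction joins, orients and round-trips through AGP", {
  set.seed(5)
  c1 <- random_dna(400)
  c2 <- random_dna(300)
  contigs <- c(c1 = c1, c2 = c2, lone = random_dna(120))
  placements <- data.frame(
    contig = c("c1", "c2"), chrom = "chr1", orientation = c("+", "-"),
    order_key = c(0, 2000), location_confidence = 1,
    orientation_confidence = 1, low_confidence = FALSE,
    stringsAsFactors = FALSE)
  res <- build_scaffolds(placements, contigs, gap_len = 100)
  expected <- paste0(c1, strrep("N", 100), oracle_revcomp(c2))
  expect_equal(res$scaffolds[["chr1"]], expected)
  expect_equal(res$unplaced, "lone")
  expect_equal(res$scaffolds[["lone"]], contigs[["lone"]])
  # AGP + components reconstruct the scaffold FASTA byte-identically
  rebuilt <- agp_to_fasta(res$plan, contigs)
  expect_identical(rebuilt[names(res$scaffolds)], res$scaffolds)
  # AGP file round-trip preserves the plan
  agp <- file.path(tempdir(), "plan.agp")
  write_agp(res$plan, agp)
  back <- read_agp(agp)
  expect_equal(as.data.frame(back), as.data.frame(res$plan),
               ignore_attr = TRUE, tolerance = 0)
  expect_identical(agp_to_fasta(back, contigs)[names(res$scaffolds)],
                   res$scaffolds)
  # gap rows carry the documented AGP metadata
  gap <- res$plan[res$plan$component_type == "N", ]
  expect_equal(gap$linkage, "yes")
  expect_equal(gap$gap_type, "scaffold")
  expect_equal(gap$linkage_evidence, "align_genus")
  # single placed contig: scaffold equals the contig, no gap
  res1 <- build_scaffolds(placements[1, ], contigs["c1"], gap_len = 100)
  expect_equal(res1$scaffolds[["chr1"]], c1)
  expect_equal(nrow(res1$plan), 1L)
  # duplicate placement is a hard error
  expect_error(build_scaffolds(rbind(placements, placements[1, ]), contigs),
               "duplicate")
})

test_that("sequence content is conserved by scaffolding (up to revcomp)", {
  fix <- small_trio()
  genome <- fix$trio$parents$hap_a
  sh <- shred(genome, frag_mean = 15000, frag_sd = 4000, seed = 9)
  paf <- fragments_paf(sh$truth, nchar(genome))
  pl <- place_contigs(filter_alignments(paf), contigs = names(sh$fragments))
  res <- build_scaffolds(pl, sh$fragments, gap_len = 100)
  got <- gsub("N", "", paste(res$scaffolds, collapse = ""))
  canon <- function(s) sort(strsplit(s, "")[[1]])
  expect_equal(sum(nchar(got)), sum(nchar(sh$fragments)))
  expect_equal(canon(got), canon(paste(genome, collapse = "")))
})

test_that("shredded genome is recovered in full order and orientation", {
  fix <- small_trio()
  genome <- fix$trio$parents$hap_a
  sh <- shred(genome, frag_mean = 12000, frag_sd = 3000, flip_prob = 0.5,
              seed = 3)
  paf <- fragments_paf(sh$truth, nchar(genome))
  pl <- place_contigs(filter_alignments(paf), contigs = names(sh$fragments))
  res <- build_scaffolds(pl, sh$fragments, gap_len = 0)
  # with no join gaps the reconstruction is exactly the source genome
  expect_identical(res$scaffolds[names(genome)], genome)
  # scaffold N50 is never below the input contig N50
  st_in <- nstats(nchar(sh$fragments))
  st_out <- nstats(nchar(res$scaffolds))
  expect_gte(st_out$n50, st_in$n50)
})

test_that("gap patching fills the toy example and respects conflicts", {
  target <- c(t1 = paste0("AAAAG", strrep("N", 10), "CCCCG"))
  donor <- c(d1 = "AAAAGTTTTCCCCG")
  paf <- rbind(
    data.frame(qname = "d1", qlen = 14, qstart = 0, qend = 5, strand = "+",
               tname = "t1", tlen = 20, tstart = 0, tend = 5, n_matches = 5,
               block_len = 5, mapq = 60, tags = "", stringsAsFactors = FALSE),
    data.frame(qname = "d1", qlen = 14, qstart = 9, qend = 14, strand = "+",
               tname = "t1", tlen = 20, tstart = 15, tend = 20, n_matches = 5,
               block_len = 5, mapq = 60, tags = "", stringsAsFactors = FALSE))
  res <- patch_gaps(target, paf, donor, flank = 10)
  expect_equal(res$patched[["t1"]], "AAAAGTTTTCCCCG")
  expect_equal(res$plan$status, "patched")
  # no donor spanning -> output identical to input
  res2 <- patch_gaps(target, paf[1, ], donor, flank = 10)
  expect_identical(res2$patched, target)
  expect_equal(res2$plan$status, "unpatched")
  # anchors from different donors -> conflict, gap untouched
  paf3 <- paf
  paf3$qname <- c("d1", "d2")
  res3 <- patch_gaps(target, paf3, c(donor, d2 = "GGGGGTTTTGGGGG"), flank = 10)
  expect_equal(res3$plan$status, "conflict")
  expect_identical(res3$patched, target)
})

test_that("patching with the truth genome as donor restores it exactly", {
  fix <- small_trio()
  genome <- fix$trio$parents$hap_a
  pg <- plant_gaps(genome, n_gaps = 2, gap_len = 2000, min_flank = 8000,
                   seed = 13)
  paf <- segment_alignments(pg$gapped, genome)
  res <- patch_gaps(pg$gapped, paf, genome, flank = 50000)
  expect_identical(res$patched, genome)
  expect_true(all(res$plan$status == "patched"))
  # gap count never increases
  expect_lte(nrow(find_gaps(res$patched)), nrow(find_gaps(pg$gapped)))
})

test_that("the workflow driver chains steps and tracks statistics", {
  fix <- small_trio()
  genome <- fix$trio$parents$hap_a
  sh <- shred(genome, frag_mean = 12000, frag_sd = 3000, seed = 21)
  dir <- file.path(tempdir(), "wf")
  frag_fa <- file.path(tempdir(), "frags.fasta")
  ref_fa <- file.path(tempdir(), "ref.fasta")
  paf_file <- file.path(tempdir(), "frags.paf")
  write_seqs(sh$fragments, frag_fa)
  write_seqs(genome, ref_fa)
  write_paf(fragments_paf(sh$truth, nchar(genome)), paf_file)
  steps <- list(list(name = "scaffold_vs_truth", action = "scaffold",
                     query = frag_fa, reference = ref_fa,
                     alignments = paf_file))
  res <- run_workflow(steps, out_dir = dir)
  expect_equal(nrow(res$stats), 1L)
  expect_true(file.exists(file.path(dir, "scaffold_vs_truth.fasta")))
  expect_true(file.exists(file.path(dir, "scaffold_vs_truth.agp")))
  # scaffolding a shredded genome cannot lower N50
  expect_gte(res$stats$scaffold_n50, nstats(nchar(sh$fragments))$n50)
  # empty step list passes through with an empty stats table
  res0 <- run_workflow(list())
  expect_equal(nrow(res0$stats), 0L)
  # missing input file aborts naming the step
  bad <- list(list(name = "broken", action = "scaffold", query = "no-such.fa",
                   reference = ref_fa, alignments = paf_file))
  expect_error(run_workflow(bad), "broken")
})
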