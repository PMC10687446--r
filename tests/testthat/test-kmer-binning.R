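# hap-mer extraction and trio-binning of long reads

test_that("canonical k-mer counting matches the worked examples and rejects bad k", {
  df <- as.data.frame(count_kmers("ACGT", k = 3))
  expect_equal(df$kmer, "ACG")   # CGT is the reverse complement of ACG
  expect_equal(df$count, 2L)
  expect_equal(as.data.frame(count_kmers("AAAA", k = 3)),
               data.frame(kmer = "AAA", count = 2L, stringsAsFactors = FALSE))
  expect_equal(length(count_kmers("ACNGT", k = 3)), 0L)  # N breaks every window
  expect_error(count_kmers("ACGT", k = 4), "odd")
  expect_error(count_kmers("ACGT", k = 33), "\\[3, 31\\]")
  expect_warning(ks <- count_kmers(character(0), k = 3), "empty")
  expect_equal(length(ks), 0L)
})

test_that("counting agrees with a brute-force enumeration oracle", {
  set.seed(7)
  for (k in c(3L, 5L, 21L, 31L)) {
    reads <- replicate(8, random_dna(sample(50:200, 1)))
    reads[3] <- paste0(substr(reads[3], 1, 40), "N", substr(reads[3], 41, 99))
    got <- as.data.frame(count_kmers(reads, k = k))
    want <- oracle_count_kmers(reads, k)
    expect_equal(stats::setNames(got$count, got$kmer)[order(got$kmer)],
                 want[order(names(want))], label = paste("k =", k))
  }
})

test_that("counting a gzipped FASTQ file equals counting in-memory reads", {
  reads <- stats::setNames(replicate(5, random_dna(100)), paste0("r", 1:5))
  path <- file.path(tempdir(), "reads.fastq.gz")
  write_seqs(reads, path, format = "fastq")
  expect_equal(as.data.frame(count_kmers(path, k = 11)),
               as.data.frame(count_kmers(unname(reads), k = 11)))
})

test_that("hap-mer extraction applies the noise floor and set difference", {
  mk <- function(kmers, counts, id) {
    structure(list(parent_id = id, k = 3L,
                   codes = triokit:::cpp_encode_canonical(kmers, 3L),
                   counts = as.integer(counts)), class = "kmer_set")
  }
  a <- mk(c("AAC", "ACG"), c(5, 4), "A")
  b <- mk(c("ACG", "ATG"), c(6, 3), "B")
  hs <- extract_hapmers(a, b, min_count = 2)
  expect_equal(hapmer_strings(hs), list(specific_a = "AAC", specific_b = "ATG"))
  # identical parents -> both specific sets empty
  hs2 <- extract_hapmers(a, a, min_count = 2)
  expect_equal(lengths(hapmer_strings(hs2)), c(specific_a = 0L, specific_b = 0L))
  # below the noise floor nothing is specific
  hs3 <- extract_hapmers(mk("AAC", 1, "A"), mk(character(0), integer(0), "B"),
                         min_count = 2)
  expect_equal(lengths(hapmer_strings(hs3)), c(specific_a = 0L, specific_b = 0L))
  # repeat ceiling removes high-count k-mers
  hs4 <- extract_hapmers(a, b, min_count = 2, max_count = 4)
  expect_equal(hapmer_strings(hs4)$specific_a, character(0))
  b5 <- structure(list(parent_id = "B", k = 5L,
                       codes = triokit:::cpp_encode_canonical("AACGT", 5L),
                       counts = 3L), class = "kmer_set")
  expect_error(extract_hapmers(a, b5), "different k")
})

test_that("read binning follows the argmax rule with ties to unknown", {
  hs <- structure(list(k = 3L,
                       specific_a = triokit:::cpp_encode_canonical("AAC", 3L),
                       specific_b = triokit:::cpp_encode_canonical("ATG", 3L),
                       min_count = 2L, max_count = NULL,
                       parent_a = "A", parent_b = "B"), class = "hapmer_sets")
  reads <- c(r1 = "AACACG",  # one A hap-mer, no B -> bin A
             r2 = "CCCCCC",  # no evidence -> unknown
             r3 = "AACCAT",  # AAC vs CAT (canonical ATG): 1-1 tie -> unknown
             r4 = "AC")      # shorter than k -> zero scores, unknown
  res <- bin_reads(reads, hs)
  a <- res$assignments
  expect_equal(a$score_a, c(1L, 0L, 1L, 0L))
  expect_equal(a$score_b, c(0L, 0L, 1L, 0L))
  expect_equal(a$bin, c("A", "unknown", "unknown", "unknown"))
  expect_equal(res$summary$n_total, 4L)
  # scores equal brute-force sliding-window counts on both sets
  for (i in seq_len(nrow(a))) {
    expect_equal(a$score_a[i], oracle_score(reads[[i]], "AAC", 3))
    expect_equal(a$score_b[i], oracle_score(reads[[i]], "ATG", 3))
  }
})

test_that("binning conserves reads, is parent-symmetric, and honest on identical parents", {
  fix <- small_trio()
  trio <- fix$trio
  ka <- count_kmers(c(trio$short_a$read1, trio$short_a$read2), k = 21,
                    parent_id = "A")
  kb <- count_kmers(c(trio$short_b$read1, trio$short_b$read2), k = 21,
                    parent_id = "B")
  hs <- extract_hapmers(ka, kb, min_count = 5)
  res <- bin_reads(trio$long$reads, hs)
  s <- res$summary
  # conservation
  expect_equal(s$n_a + s$n_b + s$n_unknown, s$n_total)
  expect_equal(s$n_total, length(trio$long$reads))
  expect_equal(s$frac_a + s$frac_b + s$frac_unknown, 100)
  # swapping the parents swaps bins A and B, unknown unchanged
  hs_swap <- extract_hapmers(kb, ka, min_count = 5)
  res_swap <- bin_reads(trio$long$reads, hs_swap)
  expect_equal(res_swap$assignments$bin,
               c(A = "B", B = "A", unknown = "unknown")[res$assignments$bin],
               ignore_attr = TRUE)
  # identical parents: no hap-mers, everything unknown
  hs_same <- extract_hapmers(ka, ka, min_count = 5)
  res_same <- bin_reads(trio$long$reads, hs_same)
  expect_equal(res_same$summary$frac_unknown, 100)
  # truth-label accuracy on the error-free fixture
  truth <- trio$long$origins$haplotype[match(res$assignments$read_id,
                                             trio$long$origins$read_id)]
  assigned <- res$assignments$bin %in% c("A", "B")
  acc <- mean(res$assignments$bin[assigned] == truth[assigned])
  expect_gte(acc, 0.99)
})

test_that("binning accuracy is monotone in read length and heterozygosity", {
  base <- sim_config(seed = 11L, n_chroms = 1L, chrom_len = 4e4,
                     telomere_copies = 20L, short_coverage = 20,
                     short_error = 0, long_coverage = 6, long_error = 0,
                     indel_rate = 0)
  run <- function(cfg) {
    trio <- simulate_trio(cfg)
    ka <- count_kmers(c(trio$short_a$read1, trio$short_a$read2), k = 21)
    kb <- count_kmers(c(trio$short_b$read1, trio$short_b$read2), k = 21)
    res <- bin_reads(trio$long$reads, extract_hapmers(ka, kb, min_count = 5))
    truth <- trio$long$origins$haplotype
    ok <- res$assignments$bin %in% c("A", "B")
    if (!any(ok)) return(0)
    mean(res$assignments$bin[ok] == truth[ok]) * mean(ok)
  }
  by_len <- vapply(c(1000, 4000, 12000), function(L) {
    cfg <- base; cfg$long_len_mean <- L; run(cfg)
  }, numeric(1))
  expect_true(all(diff(by_len) >= -0.02))  # non-decreasing up to sampling noise
  by_het <- vapply(c(0.0005, 0.002, 0.008), function(h) {
    cfg <- base; cfg$snp_rate <- h; run(cfg)
  }, numeric(1))
  expect_true(all(diff(by_het) >= -0.02))
})

test_that("summary fractions match the printed convention", {
  s <- summarize_binning(data.frame(bin = c("A", "B", "unknown")))
  expect_equal(round(s$frac_a, 1), 33.3)
  # counts at the published scale reproduce the printed percentage
  big <- summarize_binning(data.frame(
    bin = rep(c("A", "B", "unknown"),
              c(4586239, 4505092, 11822010 - 4586239 - 4505092))))
  expect_equal(round(big$frac_a, 1), 38.8)
  expect_equal(round(big$frac_b, 1), 38.1)
  all_unknown <- summarize_binning(data.frame(bin = rep("unknown", 5)))
  expect_equal(all_unknown$frac_unknown, 100)
  expect_error(summarize_binning(data.frame(bin = character(0))), "non-empty")
})

test_that("write_bins partitions reads into three round-trippable files", {
  reads <- c(r1 = "ACGTACGTAC", r2 = "GGGGCCCCGG", r3 = "TTTTAAAATT")
  asn <- data.frame(read_id = names(reads), bin = c("A", "B", "unknown"),
                    stringsAsFactors = FALSE)
  prefix <- file.path(tempdir(), "bins")
  paths <- write_bins(asn, reads, prefix)
  expect_true(all(file.exists(paths)))
  back <- do.call(c, unname(lapply(paths, function(p) {
    s <- read_seqs(p); attributes(s) <- list(names = names(s)); s
  })))
  expect_equal(sort(names(back)), sort(names(reads)))
  expect_equal(back[names(reads)], reads, ignore_attr = TRUE)
  # all-unknown still creates (empty) A and B files
  asn2 <- data.frame(read_id = names(reads), bin = "unknown")
  paths2 <- write_bins(asn2, reads, file.path(tempdir(), "bins2"))
  expect_true(all(file.exists(paths2)))
  expect_equal(length(read_seqs(paths2[["A"]])), 0L)
  # a read missing from the stream is a hard error naming it
  expect_error(write_bins(data.frame(read_id = "ghost", bin = "A"), reads,
                          file.path(tempdir(), "bins3")), "ghost")
})
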