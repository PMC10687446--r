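# Independent brute-force oracles and tiny fixture builders.  These stay
# deliberately naive (string enumeration, logical masks, linear scans) so
# they cannot share a defect with the packed/rolling implementations they
# check.

oracle_revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

oracle_canonical <- function(kmer) {
  rc <- oracle_revcomp(kmer)
  if (kmer <= rc) kmer else rc
}

# sliding-window canonical k-mer counts over a set of reads
oracle_count_kmers <- function(reads, k) {
  tab <- new.env()
  for (s in reads) {
    n <- nchar(s)
    if (n < k) next
    for (i in seq_len(n - k + 1)) {
      km <- substr(s, i, i + k - 1)
      if (grepl("[^ACGT]", km)) next
      cn <- oracle_canonical(km)
      tab[[cn]] <- (if (is.null(tab[[cn]])) 0 else tab[[cn]]) + 1
    }
  }
  out <- unlist(as.list(tab))
  if (is.null(out)) return(integer(0))
  out[order(names(out))]
}

# per-read hap-mer score by brute-force enumeration
oracle_score <- function(read, set_kmers, k) {
  n <- nchar(read)
  if (n < k) return(0)
  score <- 0
  for (i in seq_len(n - k + 1)) {
    km <- substr(read, i, i + k - 1)
    if (grepl("[^ACGT]", km)) next
    if (oracle_canonical(km) %in% set_kmers) score <- score + 1
  }
  score
}

# minimal-set N-statistic by direct enumeration over sorted prefixes
oracle_nstat <- function(lengths, frac) {
  s <- sort(lengths, decreasing = TRUE)
  total <- sum(s)
  acc <- 0
  for (i in seq_along(s)) {
    acc <- acc + s[i]
    if (acc >= frac * total) return(list(n = s[i], l = i))
  }
}

# union coverage of a window by a logical base mask
oracle_breadth <- function(intervals, win_start, win_end) {
  mask <- rep(FALSE, win_end - win_start)
  for (i in seq_len(nrow(intervals))) {
    a <- max(intervals$start[i], win_start)
    b <- min(intervals$end[i], win_end)
    if (b > a) mask[(a - win_start + 1):(b - win_start)] <- TRUE
  }
  100 * sum(mask) / length(mask)
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small trio fixture shared across unit tests (cached per session)
small_trio <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 42L, n_chroms = 2L, chrom_len = 6e4,
                        telomere_copies = 50L, short_coverage = 20,
                        short_error = 0, long_coverage = 8, long_error = 0,
                        long_len_mean = 4000, indel_rate = 0)
      cache <<- list(config = cfg, trio = simulate_trio(cfg))
    }
    cache
  }
})
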