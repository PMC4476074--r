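# Independent brute-force oracles: plain base-R scans over reads, used to
# cross-check the interval-tree-based implementations. Deliberately written
# against the read table columns directly, without IRanges.

# unspliced unique reads fully inside [s, e)
oracle_count_intron <- function(reads, s, e) {
  sum(reads$unique & reads$n_blocks == 1 & reads$start >= s & reads$end <= e)
}

# unique reads fully inside the upstream or downstream flanking exon
oracle_count_exon <- function(reads, us, ue, ds, de) {
  inside <- function(a, b) reads$unique & reads$start >= a & reads$end <= b
  sum(inside(us, ue) | inside(ds, de))
}

# spliced unique reads with a gap exactly (s, e) and both anchors >= anchor
oracle_count_junc <- function(reads, s, e, anchor = 4) {
  n <- 0L
  for (i in which(reads$unique & reads$n_blocks >= 2)) {
    bs <- reads$block_starts[[i]]
    be <- reads$block_ends[[i]]
    k <- length(bs)
    for (j in seq_len(k - 1)) {
      if (be[j] == s && bs[j + 1] == e &&
          (be[j] - bs[j]) >= anchor && (be[j + 1] - bs[j + 1]) >= anchor) {
        n <- n + 1L
        break
      }
    }
  }
  n
}

# unspliced unique reads covering position `pos` with >= ov bases each side
oracle_count_ss <- function(reads, pos, ov = 1) {
  sum(reads$unique & reads$n_blocks == 1 &
        reads$start <= pos - ov & reads$end >= pos + ov)
}

# fraction of [s, e) positions under at least one unique-read block
oracle_coverage <- function(reads, s, e) {
  covered <- logical(e - s)
  for (i in which(reads$unique)) {
    bs <- reads$block_starts[[i]]
    be <- reads$block_ends[[i]]
    for (j in seq_along(bs)) {
      a <- max(bs[j], s)
      b <- min(be[j], e)
      if (a < b) covered[(a - s + 1):(b - s)] <- TRUE
    }
  }
  mean(covered)
}

# unique reads whose span overlaps any of the gene's union-exon intervals
oracle_gene_exonic <- function(reads, ivs) {
  n <- 0L
  for (i in which(reads$unique)) {
    hit <- any(reads$start[i] < ivs$end & reads$end[i] > ivs$start)
    if (hit) n <- n + 1L
  }
  n
}

# information gain by direct entropy sums over an explicit contingency table
oracle_gain <- function(bins, labels) {
  ent <- function(v) {
    out <- 0
    for (lv in unique(v)) {
      p <- sum(v == lv) / length(v)
      out <- out - p * log2(p)
    }
    out
  }
  total <- ent(labels)
  cond <- 0
  for (b in unique(bins)) {
    idx <- bins == b
    cond <- cond + sum(idx) / length(bins) * ent(labels[idx])
  }
  total - cond
}

# line-by-line GFF3 re-parse: exon rows only, 1-based inclusive coordinates
oracle_gff_exons <- function(lines) {
  out <- list()
  for (ln in lines) {
    if (startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 9 || f[3] != "exon") next
    parent <- sub(".*Parent=([^;]+).*", "\\1", f[9])
    out[[length(out) + 1]] <- data.frame(
      transcript_id = parent, chrom = f[1],
      start = as.integer(f[4]) - 1L, end = as.integer(f[5]),
      strand = f[7], stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# brute-force per-transcript gap enumeration, deduplicated genome-wide
oracle_intron_count <- function(exons) {
  keys <- character(0)
  for (tx in unique(exons$transcript_id)) {
    e <- exons[exons$transcript_id == tx, ]
    e <- e[order(e$start), ]
    if (nrow(e) < 2) next
    for (j in seq_len(nrow(e) - 1)) {
      keys <- c(keys, paste(e$chrom[j], e$end[j], e$start[j + 1],
                            e$strand[j]))
    }
  }
  length(unique(keys))
}

# a linearly separable 17-feature labeled matrix with a planted mean shift
make_separable_matrix <- function(n = 500, shift = 5, seed = 42,
                                  yes_fraction = 0.3) {
  set.seed(seed)
  n_yes <- round(yes_fraction * n)
  lab <- rep(c("no", "yes"), c(n - n_yes, n_yes))
  x <- as.data.frame(matrix(rnorm(n * 17), n, 17))
  names(x) <- irdetect:::ir_feature_columns()
  for (cc in c("TNintron", "TN5ss", "TN3ss")) {
    x[[cc]] <- x[[cc]] + shift * (lab == "yes")
  }
  dplyr::bind_cols(tibble::tibble(intron_id = sprintf("i%04d", seq_len(n))),
                   x, tibble::tibble(label = lab))
}

# a feature-table row that passes every default removal criterion
passing_record <- function(...) {
  rec <- tibble::tibble(
    intron_id = "i1", chrom = "chr1", start = 100L, end = 200L,
    strand = "+",
    TNintron = 5, TNexon = 5, TNjunc = 1, TN5ss = 10, TN3ss = 10,
    TNcoverage = 0.95, TNexpression = 50,
    CNintron = 0, CNexon = 5, CNjunc = 5, CN5ss = 0, CN3ss = 0,
    CNcoverage = 0, CNexpression = 50)
  repl <- list(...)
  for (nm in names(repl)) rec[[nm]] <- repl[[nm]]
  rec
}

# default-condition simulated dataset, built once per test run
sim_fixture <- local({
  cache <- new.env()
  function(seed = 101) {
    key <- paste0("s", seed)
    if (is.null(cache[[key]])) {
      sim <- simulate_ir_dataset(sim_config(seed = seed))
      sim$features <- build_feature_table(sim$treatment, sim$control,
                                          sim$catalog, sim$exons)
      cache[[key]] <- sim
    }
    cache[[key]]
  }
})
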