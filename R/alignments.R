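#' Read spliced alignments into a read table
#'
#' Loads a coordinate-sorted SAM or BAM file and returns one row per mapped
#' record. Aligned blocks (split at N CIGAR operations, i.e. at splice
#' junctions) are kept as list columns so junction gaps and anchors can be
#' recovered exactly. A read is flagged `unique` if its `NH` tag equals 1;
#' records without an `NH` tag fall back to a mapping-quality threshold.
#'
#' @param path Path to a `.sam` or `.bam` file. SAM input is converted with
#'   [Rsamtools::asBam()] on the fly.
#' @param mapq Mapping-quality threshold used as the uniqueness proxy when the
#'   `NH` tag is absent (default 20).
#' @return A tibble with columns `read_id`, `chrom`, `strand`, `start`, `end`
#'   (the full aligned span, 0-based half-open), `n_blocks`, `block_starts`
#'   and `block_ends` (list columns of 0-based half-open block coordinates)
#'   and `unique` (logical).
#' @export
read_alignments <- function(path, mapq = 20) {
  if (!file.exists(path)) {
    abort(paste0("alignment file not found: ", path))
  }
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "mapq"),
    tag = "NH",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  gal <- GenomicAlignments::readGAlignments(bam, param = param)
  blocks <- GenomicAlignments::grglist(gal)
  bstart <- BiocGenerics::start(blocks)
  bend <- BiocGenerics::end(blocks)
  md <- S4Vectors::mcols(gal)
  nh <- md$NH
  if (is.null(nh)) nh <- rep(NA_integer_, length(gal))
  uniq <- ifelse(!is.na(nh), nh == 1L, !is.na(md$mapq) & md$mapq >= mapq)
  tibble(
    read_id = as.character(md$qname),
    chrom = as.character(GenomeInfoDb::seqnames(gal)),
    strand = as.character(BiocGenerics::strand(gal)),
    start = BiocGenerics::start(gal) - 1L,
    end = BiocGenerics::end(gal),
    n_blocks = GenomicAlignments::njunc(gal) + 1L,
    block_starts = as.list(bstart - 1L),
    block_ends = as.list(bend),
    unique = as.logical(uniq)
  )
}

#' Assemble a read table from block coordinates
#'
#' Constructor used by the simulator and by tests: builds the same table
#' layout as [read_alignments()] from in-memory block coordinates.
#'
#' @param chrom Chromosome name (recycled).
#' @param blocks A list with one element per read; each element is an even
#'   numeric vector or a 2-column matrix of 0-based half-open
#'   (start, end) block pairs, sorted and non-overlapping.
#' @param read_id Read identifiers (default `read_1`, `read_2`, ...).
#' @param strand Strand per read (default `"+"`).
#' @param unique Uniquely-mapped flag per read (default `TRUE`).
#' @return A read tibble (see [read_alignments()]).
#' @export
alignment_table <- function(chrom, blocks, read_id = NULL, strand = "+",
                            unique = TRUE) {
  n <- length(blocks)
  norm <- lapply(blocks, function(b) {
    m <- if (is.matrix(b)) b else matrix(as.numeric(b), ncol = 2, byrow = TRUE)
    if (any(m[, 1] >= m[, 2])) abort("block with start >= end")
    m[order(m[, 1]), , drop = FALSE]
  })
  bs <- lapply(norm, function(m) as.integer(m[, 1]))
  be <- lapply(norm, function(m) as.integer(m[, 2]))
  tibble(
    read_id = read_id %||% sprintf("read_%d", seq_len(n)),
    chrom = rep_len(chrom, n),
    strand = rep_len(strand, n),
    start = map_int(bs, min),
    end = map_int(be, max),
    n_blocks = lengths(bs),
    block_starts = bs,
    block_ends = be,
    unique = rep_len(unique, n)
  )
}

# GRanges over full read spans (1-based internally for IRanges arithmetic)
.span_granges <- function(reads) {
  GenomicRanges::GRanges(reads$chrom,
                         IRanges::IRanges(reads$start + 1L, reads$end))
}

# GRanges over aligned blocks, with the originating row index attached
.block_granges <- function(reads) {
  k <- reads$n_blocks
  GenomicRanges::GRanges(
    rep(reads$chrom, k),
    IRanges::IRanges(unlist(reads$block_starts) + 1L,
                     unlist(reads$block_ends)),
    read = rep(seq_len(nrow(reads)), k)
  )
}
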