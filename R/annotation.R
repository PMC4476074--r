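#' Read a gene annotation into an exon table
#'
#' Parses a GFF3 or GTF annotation and returns one row per exon with its gene
#' and transcript assignment. Coordinates are converted from the 1-based
#' inclusive convention of GFF/GTF to the 0-based half-open convention used
#' throughout the package, so `end - start` is always a length in base pairs
#' and intervals interoperate directly with BED.
#'
#' @param path Path to a GFF3 (`.gff`, `.gff3`) or GTF (`.gtf`) file.
#' @return A tibble with columns `gene_id`, `transcript_id`, `chrom`,
#'   `start`, `end` (0-based half-open) and `strand` (`"+"`, `"-"` or `"."`),
#'   ordered by transcript and start. Exons whose parent transcript cannot be
#'   resolved are skipped with a warning.
#' @seealso [derive_introns()], [gene_models()]
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("annotation file not found: ", path))
  }
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  if (is.null(md$type)) {
    abort("annotation has no feature 'type' column; is this a GFF3/GTF file?")
  }
  type <- tolower(as.character(md$type))
  is_exon <- type == "exon"
  if (!any(is_exon)) {
    abort("annotation contains no exon features")
  }
  ex <- gr[is_exon]
  exd <- S4Vectors::mcols(ex)

  if (!is.null(exd$transcript_id)) {
    # GTF: exon rows carry transcript_id/gene_id attributes directly
    tx <- as.character(exd$transcript_id)
    gene <- if (!is.null(exd$gene_id)) as.character(exd$gene_id) else tx
  } else {
    # GFF3: exon Parent points at a transcript feature whose Parent is a gene
    parent <- exd$Parent
    if (is.null(parent)) {
      abort("GFF3 exon features carry no Parent attribute")
    }
    n_parent <- lengths(parent)
    if (any(n_parent == 0)) {
      warn(sprintf("skipping %d exon(s) with no parent transcript",
                   sum(n_parent == 0)))
      ex <- ex[n_parent > 0]
      parent <- parent[n_parent > 0]
    }
    tx <- vapply(parent, function(p) as.character(p)[1], character(1))
    tx_rows <- type %in% c("mrna", "transcript") & !is_exon
    tx_md <- S4Vectors::mcols(gr)[tx_rows, , drop = FALSE]
    tx_gene <- character(0)
    if (nrow(tx_md) > 0 && !is.null(tx_md$ID)) {
      gp <- vapply(tx_md$Parent, function(p) {
        if (length(p) == 0) NA_character_ else as.character(p)[1]
      }, character(1))
      tx_gene <- setNames(gp, as.character(tx_md$ID))
    }
    gene <- unname(tx_gene[tx])
    gene[is.na(gene)] <- tx[is.na(gene)]
  }

  out <- tibble(
    gene_id = gene,
    transcript_id = tx,
    chrom = as.character(GenomeInfoDb::seqnames(ex)),
    start = BiocGenerics::start(ex) - 1L,
    end = BiocGenerics::end(ex),
    strand = sub("\\*", ".", as.character(BiocGenerics::strand(ex)))
  )
  # preserve transcript first-appearance order, sort exons genomically within
  tx_order <- match(out$transcript_id, unique(out$transcript_id))
  out[order(tx_order, out$start, out$end), , drop = FALSE]
}

#' Summarise an exon table into per-gene models
#'
#' @param exons An exon tibble as returned by [read_annotation()].
#' @return A tibble with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `start`/`end` (the gene span over all exons), `n_transcripts` and
#'   `union_exonic_length`, the number of base pairs in the union of all of
#'   the gene's exons (the exon model length used for RPKM).
#' @export
gene_models <- function(exons) {
  stopifnot(is.data.frame(exons), nrow(exons) > 0)
  exons |>
    group_by(gene_id) |>
    summarise(
      chrom = chrom[1],
      strand = strand[1],
      start = min(start),
      end = max(end),
      n_transcripts = n_distinct(transcript_id),
      union_exonic_length = sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(start + 1L, end)))),
      .groups = "drop"
    )
}

#' Per-gene union-exon intervals
#'
#' Collapses all exons of each gene into a set of non-overlapping intervals.
#' Reads overlapping these intervals are the gene's exonic reads for
#' expression estimation.
#'
#' @inheritParams gene_models
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @export
exon_union <- function(exons) {
  exons |>
    group_by(gene_id) |>
    reframe(
      chrom = chrom[1],
      {
        red <- IRanges::reduce(IRanges::IRanges(start + 1L, end))
        tibble(start = BiocGenerics::start(red) - 1L,
               end = BiocGenerics::end(red))
      }
    )
}

#' Derive the intron catalog from an exon table
#'
#' Introns are the gaps between consecutive exons of each transcript.
#' Identical gaps arising in several transcripts are emitted once; the
#' flanking exons of a shared intron are taken from the first transcript
#' (in annotation order) that contains it. Upstream/downstream exons are in
#' genomic orientation (upstream is the lower-coordinate exon); the 5' and 3'
#' splice-site positions respect strand, so on `-` the 5' splice site sits at
#' the intron's genomic end. Unstranded introns default the 5' splice site to
#' the lower coordinate, with a warning.
#'
#' @inheritParams gene_models
#' @return A tibble with one row per distinct intron: `intron_id`, `chrom`,
#'   `start`, `end`, `strand`, `gene_id`, `transcript_id` (the defining
#'   transcript), flanking-exon coordinates `up_start`, `up_end`,
#'   `down_start`, `down_end`, and splice-site positions `ss5_pos`,
#'   `ss3_pos`. Ordered by chromosome and start.
#' @export
derive_introns <- function(exons) {
  stopifnot(is.data.frame(exons))
  per_tx <- exons |>
    mutate(.tx_order = match(transcript_id, unique(transcript_id))) |>
    group_by(transcript_id) |>
    arrange(start, .by_group = TRUE) |>
    reframe(
      gene_id = gene_id[1],
      chrom = chrom[1],
      strand = strand[1],
      .tx_order = .tx_order[1],
      {
        k <- n()
        if (k < 2) {
          tibble(start = integer(0), end = integer(0),
                 up_start = integer(0), up_end = integer(0),
                 down_start = integer(0), down_end = integer(0))
        } else {
          es <- start
          ee <- end
          tibble(start = ee[-k], end = es[-1],
                 up_start = es[-k], up_end = ee[-k],
                 down_start = es[-1], down_end = ee[-1])
        }
      }
    )
  if (nrow(per_tx) == 0) {
    return(tibble(intron_id = character(0), chrom = character(0),
                  start = integer(0), end = integer(0), strand = character(0),
                  gene_id = character(0), transcript_id = character(0),
                  up_start = integer(0), up_end = integer(0),
                  down_start = integer(0), down_end = integer(0),
                  ss5_pos = integer(0), ss3_pos = integer(0)))
  }
  if (any(per_tx$start >= per_tx$end)) {
    abort("transcript has overlapping or abutting exons; cannot derive introns")
  }
  if (any(per_tx$strand == ".")) {
    warn("unstranded intron(s): defaulting the 5' splice site to the lower coordinate")
  }
  per_tx |>
    arrange(.tx_order) |>
    distinct(chrom, start, end, strand, .keep_all = TRUE) |>
    mutate(
      intron_id = sprintf("%s:%d-%d:%s", chrom, start, end, strand),
      ss5_pos = if_else(strand == "-", end, start),
      ss3_pos = if_else(strand == "-", start, end)
    ) |>
    arrange(chrom, start, end) |>
    select(intron_id, chrom, start, end, strand, gene_id, transcript_id,
           up_start, up_end, down_start, down_end, ss5_pos, ss3_pos)
}

#' Write an intron catalog as 6-column BED
#'
#' @param catalog An intron catalog from [derive_introns()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intron_bed <- function(catalog, path) {
  gr <- GenomicRanges::GRanges(
    catalog$chrom,
    IRanges::IRanges(catalog$start + 1L, catalog$end),
    strand = sub("^\\.$", "*", catalog$strand)
  )
  gr$name <- catalog$intron_id
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a BED interval file
#'
#' @param path Path to a BED file (3+ columns).
#' @return A tibble with `chrom`, `start`, `end` (0-based half-open), `name`
#'   (NA when absent) and `strand`.
#' @export
read_bed_intervals <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  nm <- if (!is.null(gr$name)) as.character(gr$name) else NA_character_
  tibble(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    name = nm,
    strand = sub("\\*", ".", as.character(BiocGenerics::strand(gr)))
  )
}
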