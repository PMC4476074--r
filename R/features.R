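#' Per-intron read-count features
#'
#' The five count features of the method, each computed from uniquely mapped
#' reads only:
#' \describe{
#'   \item{`count_intron_reads()`}{unspliced reads whose full aligned span
#'     lies within the intron.}
#'   \item{`count_flanking_exon_reads()`}{reads whose span lies entirely
#'     within the upstream or the downstream flanking exon.}
#'   \item{`count_junction_reads()`}{spliced reads with a block gap exactly
#'     matching the intron, with at least `min_anchor` aligned bases on each
#'     side of the gap.}
#'   \item{`count_splice_site_reads()`}{unspliced reads straddling the 5' or
#'     3' splice site with at least `min_overhang` bases on both the exonic
#'     and the intronic side.}
#' }
#' Containment (not mere overlap) keeps the features disjoint: a read
#' counted at a splice site is by construction not an intronic read, and a
#' spliced junction read never contributes to the intronic count.
#'
#' @param reads A read tibble from [read_alignments()] or
#'   [alignment_table()].
#' @param intron A single intron: one row of a [derive_introns()] catalog.
#' @param min_anchor Minimum aligned bases on each side of a junction gap
#'   (default 4).
#' @param side Which splice site to count at: `"5ss"` or `"3ss"`.
#' @param min_overhang Minimum bases on each side of the splice-site
#'   boundary (default 1).
#' @return A single count (or coverage fraction for [intron_coverage()]).
#' @name intron_features
NULL

.one_row <- function(intron) {
  x <- as_tibble(as.list(intron)[intersect(names(intron),
        c("intron_id", "chrom", "start", "end", "strand",
          "up_start", "up_end", "down_start", "down_end",
          "ss5_pos", "ss3_pos"))])
  stopifnot(nrow(x) == 1)
  x
}

#' @rdname intron_features
#' @export
count_intron_reads <- function(reads, intron) {
  n_intron_reads(reads, .one_row(intron))[1]
}

#' @rdname intron_features
#' @export
count_flanking_exon_reads <- function(reads, intron) {
  n_flanking_exon_reads(reads, .one_row(intron))[1]
}

#' @rdname intron_features
#' @export
count_junction_reads <- function(reads, intron, min_anchor = 4) {
  n_junction_reads(reads, .one_row(intron), min_anchor = min_anchor)[1]
}

#' @rdname intron_features
#' @export
count_splice_site_reads <- function(reads, intron, side = c("5ss", "3ss"),
                                    min_overhang = 1) {
  if (!is.character(side) || !side[1] %in% c("5ss", "3ss")) {
    abort("`side` must be \"5ss\" or \"3ss\"")
  }
  side <- side[1]
  n_splice_site_reads(reads, .one_row(intron), side = side,
                      min_overhang = min_overhang)[1]
}

#' @rdname intron_features
#' @export
intron_coverage <- function(reads, intron) {
  n_intron_coverage(reads, .one_row(intron))[1]
}

# ---- vectorized engines (one value per catalog row) ------------------------

.catalog_granges <- function(catalog, start_col = "start", end_col = "end") {
  GenomicRanges::GRanges(
    catalog$chrom,
    IRanges::IRanges(catalog[[start_col]] + 1L, catalog[[end_col]])
  )
}

n_intron_reads <- function(reads, catalog) {
  r <- reads[reads$unique & reads$n_blocks == 1L, , drop = FALSE]
  if (nrow(r) == 0) return(integer(nrow(catalog)))
  hits <- GenomicRanges::findOverlaps(.span_granges(r),
                                      .catalog_granges(catalog),
                                      type = "within")
  tabulate(S4Vectors::subjectHits(hits), nbins = nrow(catalog))
}

n_flanking_exon_reads <- function(reads, catalog) {
  r <- reads[reads$unique, , drop = FALSE]
  if (nrow(r) == 0) return(integer(nrow(catalog)))
  spans <- .span_granges(r)
  up <- GenomicRanges::findOverlaps(
    spans, .catalog_granges(catalog, "up_start", "up_end"), type = "within")
  down <- GenomicRanges::findOverlaps(
    spans, .catalog_granges(catalog, "down_start", "down_end"),
    type = "within")
  tabulate(S4Vectors::subjectHits(up), nbins = nrow(catalog)) +
    tabulate(S4Vectors::subjectHits(down), nbins = nrow(catalog))
}

n_junction_reads <- function(reads, catalog, min_anchor = 4) {
  stopifnot(min_anchor >= 1)
  sp <- reads[reads$unique & reads$n_blocks >= 2L, , drop = FALSE]
  if (nrow(sp) == 0) return(integer(nrow(catalog)))
  k <- sp$n_blocks - 1L
  gaps <- tibble(
    chrom = rep(sp$chrom, k),
    read = rep(seq_len(nrow(sp)), k),
    gstart = unlist(lapply(sp$block_ends, function(x) x[-length(x)])),
    gend = unlist(lapply(sp$block_starts, function(x) x[-1])),
    left_anchor = unlist(map2(sp$block_starts, sp$block_ends,
                              function(s, e) (e - s)[-length(s)])),
    right_anchor = unlist(map2(sp$block_starts, sp$block_ends,
                               function(s, e) (e - s)[-1]))
  ) |>
    filter(left_anchor >= min_anchor, right_anchor >= min_anchor)
  key <- tibble(chrom = catalog$chrom, gstart = catalog$start,
                gend = catalog$end, .idx = seq_len(nrow(catalog)))
  matched <- gaps |>
    inner_join(key, by = c("chrom", "gstart", "gend")) |>
    distinct(read, .idx)
  tabulate(matched$.idx, nbins = nrow(catalog))
}

n_splice_site_reads <- function(reads, catalog, side, min_overhang = 1) {
  stopifnot(min_overhang >= 1)
  pos <- if (side == "5ss") catalog$ss5_pos else catalog$ss3_pos
  r <- reads[reads$unique & reads$n_blocks == 1L, , drop = FALSE]
  if (nrow(r) == 0) return(integer(nrow(catalog)))
  win <- GenomicRanges::GRanges(
    catalog$chrom,
    IRanges::IRanges(pos - min_overhang + 1L, pos + min_overhang))
  hits <- GenomicRanges::findOverlaps(win, .span_granges(r), type = "within")
  tabulate(S4Vectors::queryHits(hits), nbins = nrow(catalog))
}

n_intron_coverage <- function(reads, catalog) {
  r <- reads[reads$unique, , drop = FALSE]
  width <- catalog$end - catalog$start
  if (nrow(r) == 0) return(numeric(nrow(catalog)))
  red <- GenomicRanges::reduce(.block_granges(r))
  introns <- .catalog_granges(catalog)
  hits <- GenomicRanges::findOverlaps(introns, red)
  if (length(hits) == 0) return(numeric(nrow(catalog)))
  ov <- IRanges::pintersect(introns[S4Vectors::queryHits(hits)],
                            red[S4Vectors::subjectHits(hits)])
  covered <- tapply(BiocGenerics::width(ov), S4Vectors::queryHits(hits), sum)
  out <- numeric(nrow(catalog))
  out[as.integer(names(covered))] <- as.numeric(covered)
  out / width
}

#' Gene expression in reads per kilobase per million (RPKM)
#'
#' @param exonic_read_count Reads assigned to the gene's exon model.
#' @param total_mapped Total mapped reads in the sample (library size).
#' @param union_exonic_length Length of the gene's union exon model in bp.
#' @return `1e9 * exonic_read_count / (total_mapped * union_exonic_length)`.
#' @export
gene_rpkm <- function(exonic_read_count, total_mapped, union_exonic_length) {
  if (any(total_mapped <= 0)) abort("total_mapped must be > 0")
  if (any(union_exonic_length <= 0)) {
    abort("union_exonic_length must be > 0")
  }
  1e9 * exonic_read_count / (total_mapped * union_exonic_length)
}

# Uniquely mapped reads whose span overlaps a gene's union-exon intervals,
# counted once per gene.
n_gene_exonic_reads <- function(reads, union_tbl) {
  genes <- unique(union_tbl$gene_id)
  r <- reads[reads$unique, , drop = FALSE]
  if (nrow(r) == 0) return(setNames(integer(length(genes)), genes))
  eg <- .catalog_granges(union_tbl)
  hits <- GenomicRanges::findOverlaps(eg, .span_granges(r))
  pairs <- distinct(tibble(
    gene_id = union_tbl$gene_id[S4Vectors::queryHits(hits)],
    read = S4Vectors::subjectHits(hits)))
  counts <- table(factor(pairs$gene_id, levels = genes))
  setNames(as.integer(counts), genes)
}

#' Extract the seven per-sample features for every intron
#'
#' Computes, for one sample, the read count within each intron, within its
#' flanking exons, supporting its splice junction, overlapping its 5' and 3'
#' splice sites, the fraction of intron positions covered by at least one
#' read, and the RPKM of the intron's gene.
#'
#' @inheritParams intron_features
#' @param catalog Intron catalog from [derive_introns()].
#' @param exons Exon table from [read_annotation()] (for gene exon models).
#' @param total_mapped Library size used for RPKM; defaults to the number of
#'   records in `reads`.
#' @return A tibble with one row per catalog intron: `intron_id`, `n_intron`,
#'   `n_exon`, `n_junc`, `n_5ss`, `n_3ss`, `n_coverage`, `n_expression`.
#' @export
extract_sample_features <- function(reads, catalog, exons, min_anchor = 4,
                                    min_overhang = 1, total_mapped = NULL) {
  total_mapped <- total_mapped %||% nrow(reads)
  uni <- exon_union(exons)
  glen <- gene_models(exons)
  exonic <- n_gene_exonic_reads(reads, uni)
  rpkm <- gene_rpkm(as.numeric(exonic[glen$gene_id]), total_mapped,
                    glen$union_exonic_length)
  names(rpkm) <- glen$gene_id
  tibble(
    intron_id = catalog$intron_id,
    n_intron = n_intron_reads(reads, catalog),
    n_exon = n_flanking_exon_reads(reads, catalog),
    n_junc = n_junction_reads(reads, catalog, min_anchor = min_anchor),
    n_5ss = n_splice_site_reads(reads, catalog, "5ss",
                                min_overhang = min_overhang),
    n_3ss = n_splice_site_reads(reads, catalog, "3ss",
                                min_overhang = min_overhang),
    n_coverage = n_intron_coverage(reads, catalog),
    n_expression = unname(rpkm[catalog$gene_id])
  )
}

#' Build the cross-sample normalization plan
#'
#' All samples are rescaled to the standard normalization scale (SNS), the
#' smallest per-sample mapped-read total: a raw count is divided by its
#' sample's total and multiplied by the SNS, i.e. multiplied by
#' `sns / total`.
#'
#' @param sample_totals A named numeric vector of total mapped reads per
#'   sample, or a data frame with columns `sample` and `total`.
#' @return A tibble with columns `sample`, `total`, `sns` and
#'   `scale_factor` (`sns / total`, in (0, 1]).
#' @export
build_normalization_plan <- function(sample_totals) {
  if (is.data.frame(sample_totals)) {
    stopifnot(all(c("sample", "total") %in% names(sample_totals)))
    tbl <- tibble(sample = as.character(sample_totals$sample),
                  total = as.numeric(sample_totals$total))
  } else {
    if (length(sample_totals) == 0) abort("no samples in normalization plan")
    if (is.null(names(sample_totals))) {
      names(sample_totals) <- sprintf("sample_%d", seq_along(sample_totals))
    }
    tbl <- tibble(sample = names(sample_totals),
                  total = as.numeric(sample_totals))
  }
  if (nrow(tbl) == 0) abort("no samples in normalization plan")
  if (any(!is.finite(tbl$total)) || any(tbl$total <= 0)) {
    abort("all sample totals must be positive")
  }
  tbl |>
    mutate(sns = min(total), scale_factor = sns / total)
}

#' Build the per-intron treatment/control feature table
#'
#' For each intron, count features are extracted per replicate, multiplied by
#' the replicate's normalization scale factor, and summed within each
#' condition. Coverage is a fraction, not a count, so it is computed on the
#' pooled (unscaled) reads of the condition's replicates. Expression is the
#' RPKM of the pooled normalized exonic counts against an effective library
#' size of `sns * replicates`.
#'
#' @param treatment,control Named lists of read tibbles, one per replicate.
#' @param catalog Intron catalog from [derive_introns()].
#' @param exons Exon table from [read_annotation()].
#' @param plan Optional normalization plan over all samples of both
#'   conditions; defaults to [build_normalization_plan()] on the per-sample
#'   record totals.
#' @inheritParams intron_features
#' @return A tibble with one row per intron: `intron_id`, `chrom`, `start`,
#'   `end`, `strand`, then `TNintron`, `TNexon`, `TNjunc`, `TN5ss`, `TN3ss`,
#'   `TNcoverage`, `TNexpression` for treatment and the corresponding `CN*`
#'   columns for control.
#' @export
build_feature_table <- function(treatment, control, catalog, exons,
                                plan = NULL, min_anchor = 4,
                                min_overhang = 1) {
  if (length(treatment) < 1 || length(control) < 1) {
    abort("at least one replicate per condition is required")
  }
  if (nrow(catalog) == 0) {
    warn("empty intron catalog: returning an empty feature table")
    return(tibble(intron_id = character(0)))
  }
  name_reps <- function(x, prefix) {
    nm <- names(x) %||% rep("", length(x))
    nm[nm == ""] <- sprintf("%s_%d", prefix, which(nm == ""))
    setNames(x, nm)
  }
  treatment <- name_reps(treatment, "treatment")
  control <- name_reps(control, "control")
  samples <- c(treatment, control)
  if (is.null(plan)) {
    plan <- build_normalization_plan(map_dbl(samples, nrow))
  }
  factors <- setNames(plan$scale_factor, plan$sample)
  missing <- setdiff(names(samples), names(factors))
  if (length(missing) > 0) {
    abort(paste0("normalization plan lacks sample(s): ",
                 paste(missing, collapse = ", ")))
  }
  sns <- plan$sns[1]
  uni <- exon_union(exons)
  glen <- gene_models(exons)

  condition_features <- function(reps) {
    counts <- NULL
    exonic <- setNames(numeric(nrow(glen)), glen$gene_id)
    for (nm in names(reps)) {
      f <- factors[[nm]]
      cnt <- tibble(
        n_intron = n_intron_reads(reps[[nm]], catalog) * f,
        n_exon = n_flanking_exon_reads(reps[[nm]], catalog) * f,
        n_junc = n_junction_reads(reps[[nm]], catalog, min_anchor) * f,
        n_5ss = n_splice_site_reads(reps[[nm]], catalog, "5ss",
                                    min_overhang) * f,
        n_3ss = n_splice_site_reads(reps[[nm]], catalog, "3ss",
                                    min_overhang) * f
      )
      counts <- if (is.null(counts)) cnt else counts + cnt
      ex <- n_gene_exonic_reads(reps[[nm]], uni)
      exonic <- exonic + ex[names(exonic)] * f
    }
    pooled <- bind_rows(reps)
    rpkm <- gene_rpkm(unname(exonic[glen$gene_id]),
                      sns * length(reps), glen$union_exonic_length)
    names(rpkm) <- glen$gene_id
    counts |>
      mutate(n_coverage = n_intron_coverage(pooled, catalog),
             n_expression = unname(rpkm[catalog$gene_id]))
  }

  tfeat <- condition_features(treatment)
  cfeat <- condition_features(control)
  bind_cols(
    catalog |> select(intron_id, chrom, start, end, strand),
    tfeat |> rename_with(~ sub("^n_", "TN", .x)),
    cfeat |> rename_with(~ sub("^n_", "CN", .x))
  )
}
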