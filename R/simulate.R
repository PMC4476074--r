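# run code with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  code
}

#' Simulation configuration
#'
#' Describes the toy genome and the planted retention signal. The defaults
#' define the study conditions used throughout the package's tests: 20
#' four-exon genes (60 introns) on one synthetic chromosome, two replicates
#' per condition, 50 bp single-end uniquely mapped reads, 10% of introns
#' planted as true IR events and 10% each as the three false-positive
#' archetypes — boundary-only pile-ups, a dense interior cluster, and a
#' condition-specific expression shift.
#'
#' @param n_genes Number of genes (default 20).
#' @param exons_per_gene Exons per gene (default 4, i.e. 3 introns).
#' @param exon_length,intron_length Lengths in bp (defaults 200 and 150).
#' @param read_length Read length in bp (default 50).
#' @param base_depth Exonic reads per exon per replicate (default 30).
#' @param ir_fraction Fraction of introns planted as true IR (default 0.1).
#' @param fp_boundary_fraction,fp_cluster_fraction,fp_expression_fraction
#'   Fractions planted as the three false-positive archetypes
#'   (defaults 0.1 each). The expression archetype is planted gene-wise,
#'   since an expression shift affects a whole gene.
#' @param expression_shift Fold change applied to expression-archetype genes
#'   in treatment (default 2, safely outside the (2/3, 3/2) ratio band).
#' @param replicates_per_condition Replicates per condition (default 2).
#' @param seed Integer seed (mandatory).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 20, exons_per_gene = 4, exon_length = 200,
                       intron_length = 150, read_length = 50,
                       base_depth = 30, ir_fraction = 0.1,
                       fp_boundary_fraction = 0.1,
                       fp_cluster_fraction = 0.1,
                       fp_expression_fraction = 0.1,
                       expression_shift = 2,
                       replicates_per_condition = 2, seed) {
  if (missing(seed)) abort("sim_config() requires a seed")
  frac <- c(ir_fraction, fp_boundary_fraction, fp_cluster_fraction,
            fp_expression_fraction)
  if (any(frac < 0) || any(frac > 1) || sum(frac) > 1) {
    abort("class fractions must be in [0,1] and sum to at most 1")
  }
  if (exon_length < 20 || intron_length < 20) {
    abort("exon and intron lengths must be at least 20 bp")
  }
  if (exon_length < read_length || intron_length < read_length + 10) {
    abort("exons/introns are too short for the requested read length")
  }
  if (exons_per_gene < 2) abort("genes need at least 2 exons")
  structure(list(
    n_genes = n_genes, exons_per_gene = exons_per_gene,
    exon_length = exon_length, intron_length = intron_length,
    read_length = read_length, base_depth = base_depth,
    ir_fraction = ir_fraction,
    fp_boundary_fraction = fp_boundary_fraction,
    fp_cluster_fraction = fp_cluster_fraction,
    fp_expression_fraction = fp_expression_fraction,
    expression_shift = expression_shift,
    replicates_per_condition = replicates_per_condition,
    seed = as.integer(seed),
    chrom = "chrS"
  ), class = "sim_config")
}

sim_genome_length <- function(config) {
  gene_len <- config$exons_per_gene * config$exon_length +
    (config$exons_per_gene - 1) * config$intron_length
  1000L + config$n_genes * (gene_len + 500L) + 1000L
}

#' Generate the toy annotation
#'
#' Lays `n_genes` identical multi-exon genes along one synthetic chromosome
#' with alternating strands, and returns both the GFF3 text and the parsed
#' tables. The layout is fully determined by the configuration (no
#' randomness), so the GFF3 is byte-identical across runs.
#'
#' @param config A [sim_config()].
#' @return A list with `gff` (character vector of GFF3 lines), `exons`
#'   (as from [read_annotation()]), `genes` ([gene_models()]) and
#'   `catalog` ([derive_introns()]).
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gene_len <- config$exons_per_gene * config$exon_length +
    (config$exons_per_gene - 1) * config$intron_length
  rows <- vector("list", config$n_genes)
  gff <- c("##gff-version 3",
           sprintf("##sequence-region %s 1 %d", config$chrom,
                   sim_genome_length(config)))
  for (i in seq_len(config$n_genes)) {
    gstart <- 1000L + (i - 1L) * (gene_len + 500L)
    strand <- if (i %% 2 == 1) "+" else "-"
    gid <- sprintf("gene%02d", i)
    tid <- sprintf("%s.1", gid)
    ex_start <- gstart +
      (seq_len(config$exons_per_gene) - 1L) *
      (config$exon_length + config$intron_length)
    ex_end <- ex_start + config$exon_length
    gff <- c(gff,
      sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              config$chrom, gstart + 1L, gstart + gene_len, strand, gid),
      sprintf("%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              config$chrom, gstart + 1L, gstart + gene_len, strand, tid,
              gid),
      sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
              config$chrom, ex_start + 1L, ex_end, strand, tid,
              seq_len(config$exons_per_gene), tid))
    rows[[i]] <- tibble(gene_id = gid, transcript_id = tid,
                        chrom = config$chrom, start = ex_start, end = ex_end,
                        strand = strand)
  }
  exons <- bind_rows(rows)
  list(gff = gff, exons = exons, genes = gene_models(exons),
       catalog = suppressWarnings(derive_introns(exons)))
}

# assign exactly one truth class to every intron; expression-shift genes are
# chosen gene-wise, the remaining classes intron-wise
assign_truth <- function(config, catalog) {
  .with_seed(config$seed, {
    n <- nrow(catalog)
    per_gene <- table(catalog$gene_id)
    n_fpe <- round(config$fp_expression_fraction * n)
    fpe_genes <- character(0)
    if (n_fpe > 0) {
      k <- ceiling(n_fpe / mean(per_gene))
      fpe_genes <- sample(sort(unique(catalog$gene_id)), k)
    }
    truth <- tibble(intron_id = catalog$intron_id,
                    gene_id = catalog$gene_id,
                    class = if_else(catalog$gene_id %in% fpe_genes,
                                    "fp_expression", "clean"))
    pool <- which(truth$class == "clean")
    n_ir <- round(config$ir_fraction * n)
    n_fpb <- round(config$fp_boundary_fraction * n)
    n_fpc <- round(config$fp_cluster_fraction * n)
    picks <- sample(pool, min(n_ir + n_fpb + n_fpc, length(pool)))
    truth$class[picks[seq_len(n_ir)]] <- "true_ir"
    if (n_fpb > 0) truth$class[picks[n_ir + seq_len(n_fpb)]] <- "fp_boundary"
    if (n_fpc > 0) {
      truth$class[picks[n_ir + n_fpb + seq_len(n_fpc)]] <- "fp_cluster"
    }
    truth
  })
}

# one unspliced read of length rl starting at each position in `starts`
.unspliced <- function(chrom, starts, rl, strand) {
  n <- length(starts)
  if (n == 0) return(NULL)
  tibble(chrom = chrom, strand = strand, start = as.integer(starts),
         end = as.integer(starts + rl), n_blocks = 1L,
         block_starts = as.list(as.integer(starts)),
         block_ends = as.list(as.integer(starts + rl)))
}

# junction reads spanning the gap (s, e) with left anchors `anchors`
.junction <- function(chrom, s, e, anchors, rl, strand) {
  n <- length(anchors)
  if (n == 0) return(NULL)
  a <- as.integer(anchors)
  tibble(chrom = chrom, strand = strand, start = as.integer(s - a),
         end = as.integer(e + rl - a), n_blocks = 2L,
         block_starts = map2(s - a, e, ~ as.integer(c(.x, .y))),
         block_ends = map2(s, e + rl - a, ~ as.integer(c(.x, .y))))
}

# uniform draw of n elements from a vector, safe for length-1 vectors
.sample_from <- function(v, n) {
  v[sample.int(length(v), n, replace = TRUE)]
}

# deterministic tiling of [s, e) with overlapping rl-length reads
.tile_starts <- function(s, e, rl) {
  unique(c(seq(s, e - rl, by = rl - 5L), e - rl))
}

#' Simulate per-sample alignments with planted IR signal
#'
#' Generates seeded single-end uniquely mapped reads for each replicate of
#' each condition. All genes receive exonic reads on every exon and spliced
#' junction reads across every intron. On top of that baseline, treatment
#' samples receive the planted signal: true-IR introns get near-complete
#' intronic coverage plus splice-site-straddling reads while their junction
#' support drops; boundary-archetype introns get splice-site reads but a
#' sparse interior; cluster-archetype introns get one dense interior pile-up
#' covering under half the intron; expression-archetype genes get all counts
#' scaled by the expression shift in treatment (in both the intron and its
#' gene), which is the only difference between their conditions.
#'
#' @param config A [sim_config()].
#' @param annotation Output of [generate_annotation()] on the same config.
#' @return A list with `samples` (a named list of read tibbles,
#'   `treatment_1`, ..., `control_1`, ...), `truth` (tibble of `intron_id`,
#'   `gene_id`, `class`) and `conditions` (sample-to-condition map).
#' @export
simulate_alignments <- function(config, annotation) {
  stopifnot(inherits(config, "sim_config"))
  catalog <- annotation$catalog
  if (nrow(catalog) == 0) abort("annotation yields no introns")
  truth <- assign_truth(config, catalog)
  rl <- config$read_length
  j0 <- max(4L, round(config$base_depth / 3))
  fpe_genes <- unique(truth$gene_id[truth$class == "fp_expression"])

  gen_sample <- function(condition, sidx) {
    .with_seed(config$seed + 7919L * sidx, {
      rows <- list()
      add <- function(x) if (!is.null(x)) rows[[length(rows) + 1L]] <<- x
      for (g in unique(annotation$exons$gene_id)) {
        gex <- annotation$exons[annotation$exons$gene_id == g, ]
        strand <- gex$strand[1]
        m <- if (g %in% fpe_genes && condition == "treatment") {
          config$expression_shift
        } else 1
        for (j in seq_len(nrow(gex))) {
          n <- round(config$base_depth * m)
          starts <- .sample_from(seq(gex$start[j], gex$end[j] - rl), n)
          add(.unspliced(config$chrom, starts, rl, strand))
        }
        gint <- catalog[catalog$gene_id == g, ]
        for (j in seq_len(nrow(gint))) {
          s <- gint$start[j]; e <- gint$end[j]
          cls <- truth$class[truth$intron_id == gint$intron_id[j]]
          n_junc <- if (cls == "true_ir" && condition == "treatment") {
            2L
          } else if (cls == "fp_expression") {
            round(j0 * m)
          } else j0
          anchors <- .sample_from(10:(rl - 10), n_junc)
          add(.junction(config$chrom, s, e, anchors, rl, strand))
          if (cls == "true_ir" && condition == "treatment") {
            add(.unspliced(config$chrom, .tile_starts(s, e, rl), rl, strand))
            extra <- .sample_from(seq(s, e - rl),
                                  round(config$base_depth / 2))
            add(.unspliced(config$chrom, extra, rl, strand))
            for (pos in c(s, e)) {
              off <- .sample_from(10:40, 4L)
              add(.unspliced(config$chrom, pos - off, rl, strand))
            }
          } else if (cls == "fp_boundary" && condition == "treatment") {
            for (pos in c(s, e)) {
              off <- .sample_from(10:40, 6L)
              add(.unspliced(config$chrom, pos - off, rl, strand))
            }
            # one fixed centered interior read keeps the pooled coverage
            # union bounded below the 0.9 criterion by construction
            add(.unspliced(config$chrom, s + ((e - s) - rl) %/% 2L, rl,
                           strand))
          } else if (cls == "fp_cluster" && condition == "treatment") {
            w <- max(as.integer(floor((e - s) * 0.4)), rl)
            cs <- s + as.integer(floor(((e - s) - w) / 2))
            cstarts <- .sample_from(seq(cs, cs + w - rl), 15L)
            add(.unspliced(config$chrom, cstarts, rl, strand))
          } else if (cls == "fp_expression") {
            add(.unspliced(config$chrom, .tile_starts(s, e, rl), rl, strand))
            for (pos in c(s, e)) {
              off <- .sample_from(10:40, round(4 * m))
              add(.unspliced(config$chrom, pos - off, rl, strand))
            }
          }
        }
      }
      reads <- bind_rows(rows) |>
        arrange(start, end, n_blocks) |>
        mutate(read_id = sprintf("%s_%s_%06d", condition, sidx,
                                 row_number()),
               unique = TRUE) |>
        select(read_id, chrom, strand, start, end, n_blocks, block_starts,
               block_ends, unique)
      reads
    })
  }

  reps <- config$replicates_per_condition
  samples <- list()
  sidx <- 0L
  for (cond in c("treatment", "control")) {
    for (r in seq_len(reps)) {
      sidx <- sidx + 1L
      samples[[sprintf("%s_%d", cond, r)]] <- gen_sample(cond, sidx)
    }
  }
  conditions <- setNames(rep(c("treatment", "control"), each = reps),
                         names(samples))
  list(samples = samples, truth = select(truth, intron_id, gene_id, class),
       conditions = conditions)
}

#' Simulate a complete offline IR dataset
#'
#' Convenience wrapper: generates the annotation, simulates the alignments
#' and (optionally) writes everything to disk as plain-text GFF3, SAM and a
#' truth TSV.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory; created if missing.
#' @return A list with `config`, `exons`, `genes`, `catalog`, `gff`,
#'   `treatment` and `control` (named lists of read tibbles), `truth`, and
#'   — when `dir` is given — `paths` (annotation, per-sample SAM, truth).
#' @export
simulate_ir_dataset <- function(config, dir = NULL) {
  ann <- generate_annotation(config)
  sim <- simulate_alignments(config, ann)
  is_t <- sim$conditions == "treatment"
  out <- list(config = config, exons = ann$exons, genes = ann$genes,
              catalog = ann$catalog, gff = ann$gff,
              treatment = sim$samples[names(sim$conditions)[is_t]],
              control = sim$samples[names(sim$conditions)[!is_t]],
              truth = sim$truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    gff_path <- file.path(dir, "annotation.gff3")
    writeLines(ann$gff, gff_path)
    sam_paths <- imap_chr_samples(sim$samples, function(reads, nm) {
      p <- file.path(dir, paste0(nm, ".sam"))
      write_sam(reads, p, chrom_lengths = setNames(sim_genome_length(config),
                                                   config$chrom),
                producer = "simulate", params = unclass(config))
      p
    })
    truth_path <- file.path(dir, "truth.tsv")
    write_ir_tsv(sim$truth, truth_path, producer = "simulate",
                 params = unclass(config))
    out$paths <- list(annotation = gff_path, samples = sam_paths,
                      truth = truth_path)
  }
  out
}

imap_chr_samples <- function(x, f) {
  setNames(vapply(names(x), function(nm) f(x[[nm]], nm), character(1)),
           names(x))
}

#' Write a read table as SAM
#'
#' Emits a coordinate-sorted SAM file with an `@SQ` header and one record
#' per read; spliced reads are encoded with M/N CIGAR operations, every
#' record carries `NH:i:1`, and sequences are written as runs of `A` of the
#' aligned length so the file remains convertible with samtools or
#' Rsamtools.
#'
#' @param reads A read tibble.
#' @param path Output path.
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param producer,params Recorded in an `@CO` header comment.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, path, chrom_lengths, producer = "export",
                      params = list()) {
  reads <- arrange(reads, chrom, start, end, read_id)
  cigar <- map2_chr_blocks(reads$block_starts, reads$block_ends)
  qlen <- vapply(seq_len(nrow(reads)), function(i) {
    as.integer(sum(reads$block_ends[[i]] - reads$block_starts[[i]]))
  }, integer(1))
  lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
            as.integer(chrom_lengths)),
    sprintf("@CO\tirdetect %s config=%s", producer, config_hash(params)),
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*\tNH:i:1",
            reads$read_id, ifelse(reads$strand == "-", 16L, 0L),
            reads$chrom, reads$start + 1L, 60L, cigar,
            strrep("A", qlen))
  )
  writeLines(lines, path)
  invisible(path)
}

map2_chr_blocks <- function(bs, be) {
  vapply(seq_along(bs), function(i) {
    w <- be[[i]] - bs[[i]]
    if (length(w) == 1) return(sprintf("%dM", w))
    gaps <- bs[[i]][-1] - be[[i]][-length(w)]
    paste0(paste0(w[-length(w)], "M", gaps, "N", collapse = ""),
           w[length(w)], "M")
  }, character(1))
}
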