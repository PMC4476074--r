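# a catalog row for an intron (1050, 1150) flanked by exons of 100 bp
toy_intron <- tibble::tibble(
  intron_id = "chr1:1050-1150:+", chrom = "chr1", start = 1050L, end = 1150L,
  strand = "+", gene_id = "g1", transcript_id = "t1",
  up_start = 950L, up_end = 1050L, down_start = 1150L, down_end = 1250L,
  ss5_pos = 1050L, ss3_pos = 1150L)

test_that("intronic read counting uses full-span containment of unspliced unique reads", {
  expect_equal(count_intron_reads(alignment_table("chr1", list())[0, ],
                                  toy_intron), 0)
  reads <- alignment_table("chr1", list(
    c(1060, 1110), c(1070, 1120), c(1080, 1130), c(1050, 1100),
    c(1100, 1150),                       # 5 fully inside (incl. boundaries)
    c(1040, 1090), c(1120, 1170),        # straddle a boundary
    c(1000, 1050, 1150, 1200)            # spliced across
  ))
  expect_equal(count_intron_reads(reads, toy_intron), 5)
  # a read exactly equal to the intron interval is contained
  exact <- alignment_table("chr1", list(c(1050, 1150)))
  expect_equal(count_intron_reads(exact, toy_intron), 1)
  # multimappers are ignored
  multi <- alignment_table("chr1", list(c(1060, 1110)), unique = FALSE)
  expect_equal(count_intron_reads(multi, toy_intron), 0)
})

test_that("flanking-exon counts add over the two disjoint exons and require containment", {
  reads <- alignment_table("chr1", list(
    c(950, 1000), c(960, 1010), c(1000, 1050),       # upstream exon
    c(1150, 1200), c(1160, 1210), c(1170, 1220), c(1200, 1250)  # downstream
  ))
  expect_equal(count_flanking_exon_reads(reads, toy_intron), 7)
  straddling <- alignment_table("chr1", list(c(1020, 1070)))
  expect_equal(count_flanking_exon_reads(straddling, toy_intron), 0)
})

test_that("junction counting requires the exact gap and the anchor rule", {
  ok <- alignment_table("chr1", list(c(1040, 1050, 1150, 1160)))
  expect_equal(count_junction_reads(ok, toy_intron), 1)
  short_anchor <- alignment_table("chr1", list(c(1047, 1050, 1150, 1160)))
  expect_equal(count_junction_reads(short_anchor, toy_intron, min_anchor = 4), 0)
  expect_equal(count_junction_reads(short_anchor, toy_intron, min_anchor = 3), 1)
  # planted 12 exact junctions plus 2 off-by-one gaps
  exact <- lapply(1:12, function(i) c(1040 - i, 1050, 1150, 1160 + i))
  off <- list(c(1040, 1051, 1150, 1160), c(1040, 1050, 1149, 1160))
  reads <- alignment_table("chr1", c(exact, off))
  expect_equal(count_junction_reads(reads, toy_intron), 12)
})

test_that("splice-site counting respects overhangs, strand mapping and rejects spliced reads", {
  over <- alignment_table("chr1", list(c(1045, 1055)))
  expect_equal(count_splice_site_reads(over, toy_intron, "5ss"), 1)
  touch <- alignment_table("chr1", list(c(1040, 1050)))
  expect_equal(count_splice_site_reads(touch, toy_intron, "5ss"), 0)
  expect_equal(count_splice_site_reads(over, toy_intron, "5ss",
                                       min_overhang = 5), 1)
  expect_equal(count_splice_site_reads(over, toy_intron, "5ss",
                                       min_overhang = 6), 0)
  spliced <- alignment_table("chr1", list(c(1045, 1055, 1200, 1210)))
  expect_equal(count_splice_site_reads(spliced, toy_intron, "5ss"), 0)
  expect_error(count_splice_site_reads(over, toy_intron, "donor"), "side")
  # the 5' splice site of a minus-strand intron is its genomic end
  minus <- dplyr::mutate(toy_intron, strand = "-",
                         ss5_pos = end, ss3_pos = start)
  at_end <- alignment_table("chr1", list(c(1145, 1155)))
  expect_equal(count_splice_site_reads(at_end, minus, "5ss"), 1)
  expect_equal(count_splice_site_reads(over, minus, "3ss"), 1)
})

test_that("coverage is the fraction of intron positions under a unique read", {
  none <- alignment_table("chr1", list(c(2000, 2050)))
  expect_equal(intron_coverage(none, toy_intron), 0)
  # 95 of 100 positions covered
  reads <- alignment_table("chr1", list(c(1050, 1100), c(1100, 1145)))
  expect_equal(intron_coverage(reads, toy_intron), 0.95)
  whole <- alignment_table("chr1", list(c(1040, 1160)))
  expect_equal(intron_coverage(whole, toy_intron), 1)
  # spliced blocks count as aligned bases, the gap does not
  spliced <- alignment_table("chr1", list(c(1050, 1060, 1140, 1150)))
  expect_equal(intron_coverage(spliced, toy_intron), 0.2)
})

test_that("coverage never decreases as reads are added", {
  base <- alignment_table("chr1", list(c(1050, 1080)))
  cov <- intron_coverage(base, toy_intron)
  for (extra in list(c(1060, 1090), c(1100, 1130), c(1140, 1150))) {
    base <- dplyr::bind_rows(base, alignment_table("chr1", list(extra)))
    cov2 <- intron_coverage(base, toy_intron)
    expect_gte(cov2, cov)
    cov <- cov2
  }
})

test_that("RPKM follows its closed form and rejects degenerate inputs", {
  expect_equal(gene_rpkm(1000, 1e7, 2000), 50)
  expect_equal(gene_rpkm(0, 1e7, 2000), 0)
  expect_equal(gene_rpkm(1000, 2e7, 2000), 25)  # doubling depth halves RPKM
  expect_error(gene_rpkm(10, 0, 2000), "total_mapped")
  expect_error(gene_rpkm(10, 1e7, 0), "union_exonic_length")
})

test_that("every feature matches an independent per-read scan on a large fixture", {
  sim <- sim_fixture()
  reads <- sim$treatment$treatment_1
  expect_gte(nrow(reads), 1000)
  expect_gte(nrow(sim$catalog), 60)
  got <- extract_sample_features(reads, sim$catalog, sim$exons)
  uni <- exon_union(sim$exons)
  gm <- gene_models(sim$exons)
  for (i in seq_len(nrow(sim$catalog))) {
    ci <- sim$catalog[i, ]
    expect_equal(got$n_intron[i], oracle_count_intron(reads, ci$start, ci$end))
    expect_equal(got$n_exon[i],
                 oracle_count_exon(reads, ci$up_start, ci$up_end,
                                   ci$down_start, ci$down_end))
    expect_equal(got$n_junc[i], oracle_count_junc(reads, ci$start, ci$end))
    expect_equal(got$n_5ss[i], oracle_count_ss(reads, ci$ss5_pos))
    expect_equal(got$n_3ss[i], oracle_count_ss(reads, ci$ss3_pos))
    expect_equal(got$n_coverage[i], oracle_coverage(reads, ci$start, ci$end))
    gi <- gm[gm$gene_id == ci$gene_id, ]
    exp_rpkm <- gene_rpkm(
      oracle_gene_exonic(reads, uni[uni$gene_id == ci$gene_id, ]),
      nrow(reads), gi$union_exonic_length)
    expect_equal(got$n_expression[i], exp_rpkm)
  }
})

test_that("spliced reads never leak into intronic or splice-site counts", {
  sim <- sim_fixture()
  reads <- sim$treatment$treatment_1
  spliced_only <- reads[reads$n_blocks > 1, ]
  cat60 <- sim$catalog
  expect_true(all(irdetect:::n_intron_reads(spliced_only, cat60) == 0))
  expect_true(all(irdetect:::n_splice_site_reads(spliced_only, cat60,
                                                 "5ss", 1) == 0))
  expect_true(all(irdetect:::n_splice_site_reads(spliced_only, cat60,
                                                 "3ss", 1) == 0))
})

test_that("condition features add over replicates and reduce to raw counts for identity plans", {
  sim <- sim_fixture()
  one <- sim$treatment["treatment_1"]
  plan_eq <- build_normalization_plan(
    c(treatment_1 = 1000, control_1 = 1000))
  ft <- build_feature_table(one, list(control_1 = sim$control$control_1),
                            sim$catalog, sim$exons,
                            plan = dplyr::mutate(plan_eq, scale_factor = 1,
                                                 sns = nrow(one[[1]])))
  raw <- extract_sample_features(one[[1]], sim$catalog, sim$exons,
                                 total_mapped = nrow(one[[1]]))
  expect_equal(ft$TNintron, as.numeric(raw$n_intron))
  expect_equal(ft$TNjunc, as.numeric(raw$n_junc))
  expect_equal(ft$TNcoverage, raw$n_coverage)
  expect_equal(ft$TNexpression, raw$n_expression)

  # two identical replicates with unit factors double every count feature
  dup <- list(a = one[[1]], b = one[[1]])
  plan2 <- tibble::tibble(sample = c("a", "b", "control_1"),
                          total = 1, sns = nrow(one[[1]]), scale_factor = 1)
  ft2 <- build_feature_table(dup, list(control_1 = sim$control$control_1),
                             sim$catalog, sim$exons, plan = plan2)
  expect_equal(ft2$TNintron, 2 * ft$TNintron)
  expect_equal(ft2$TN5ss, 2 * ft$TN5ss)
  # coverage pools reads and is unchanged by duplication
  expect_equal(ft2$TNcoverage, ft$TNcoverage)
})

test_that("an empty catalog produces an empty table with a warning", {
  sim <- sim_fixture()
  expect_warning(
    out <- build_feature_table(sim$treatment, sim$control,
                               sim$catalog[0, ], sim$exons),
    "empty")
  expect_equal(nrow(out), 0)
})
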