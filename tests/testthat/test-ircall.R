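test_that("each removal criterion is strict at its threshold", {
  cases <- list(
    list(col = "TN5ss", at = 3, above = 3.01, reason = "min_tn5ss"),
    list(col = "TN3ss", at = 3, above = 3.01, reason = "min_tn3ss"),
    list(col = "TNcoverage", at = 0.9, above = 0.91,
         reason = "min_tncoverage"),
    list(col = "TNexon", at = 1, above = 1.01, reason = "min_tnexon"),
    list(col = "TNexpression", at = 10, above = 10.1,
         reason = "min_tnexpression", other = list(CNexpression = 12)),
    list(col = "TNintron", at = 1, above = 1.01, reason = "min_tnintron"),
    list(col = "CNexpression", at = 10, above = 10.1,
         reason = "min_cnexpression", other = list(TNexpression = 12)),
    list(col = "CNjunc", at = 1, above = 1.01, reason = "min_cnjunc"),
    list(col = "CNexon", at = 1, above = 1.01, reason = "min_cnexon")
  )
  for (cs in cases) {
    at <- passing_record()
    at[[cs$col]] <- cs$at
    # keep the expression ratio inside the band while testing a floor
    for (nm in names(cs$other)) at[[nm]] <- cs$other[[nm]]
    flagged <- apply_removal_criteria(at)
    expect_false(flagged$keep, info = cs$col)
    expect_equal(flagged$drop_reason, cs$reason)

    above <- passing_record()
    above[[cs$col]] <- cs$above
    for (nm in names(cs$other)) above[[nm]] <- cs$other[[nm]]
    expect_true(apply_removal_criteria(above)$keep, info = cs$col)
  }
})

test_that("the expression-ratio band is open and strict at its edges", {
  keep <- apply_removal_criteria(passing_record(TNexpression = 50,
                                                CNexpression = 50))
  expect_true(keep$keep)
  fourfold <- apply_removal_criteria(passing_record(TNexpression = 48,
                                                    CNexpression = 12))
  expect_false(fourfold$keep)
  expect_equal(fourfold$drop_reason, "expression_ratio")
  # exactly at log2(3/2): dropped (strict), just inside: kept
  edge <- apply_removal_criteria(passing_record(TNexpression = 18,
                                                CNexpression = 12))
  expect_false(edge$keep)
  inside <- apply_removal_criteria(passing_record(TNexpression = 14.9,
                                                  CNexpression = 12))
  expect_true(inside$keep)
  # the ratio is undefined when control expression is zero
  undef <- apply_removal_criteria(passing_record(CNexpression = 0))
  expect_false(undef$keep)
  expect_equal(undef$drop_reason, "expression-ratio undefined")
})

test_that("raising any threshold never increases the number of kept introns", {
  sim <- sim_fixture()
  feats <- sim$features
  base_kept <- sum(apply_removal_criteria(feats)$keep)
  tighter <- list(
    removal_criteria(min_tn5ss = 5), removal_criteria(min_tncoverage = 0.95),
    removal_criteria(min_tnexpression = 100),
    removal_criteria(min_cnjunc = 10),
    removal_criteria(expression_ratio_band = c(log2(0.9), log2(1.1))))
  for (cr in tighter) {
    expect_lte(sum(apply_removal_criteria(feats, cr)$keep), base_kept)
  }
})

test_that("delta features follow their closed forms and flag non-positive changes as noise", {
  # coverage difference of 0.1 maps to DIC = 0.1 * log2(e)
  rec <- passing_record(TNcoverage = 1, CNcoverage = 0.9)
  d <- compute_deltas(rec)
  expect_equal(d$dic, 0.1 * log2(exp(1)), tolerance = 1e-12)
  expect_equal(d$dic, 0.14427, tolerance = 1e-4)

  # raw-count arithmetic with pseudo-count 0
  rec2 <- passing_record(TNintron = 20, TNexon = 10, CNintron = 5,
                         CNexon = 10)
  d2 <- compute_deltas(rec2, pseudo = 0)
  expect_equal(d2$die, 2)

  # identical conditions carry no signal
  sym <- passing_record(TNintron = 5, CNintron = 5, TNexon = 5, CNexon = 5,
                        TNjunc = 3, CNjunc = 3,
                        TNcoverage = 0.5, CNcoverage = 0.5)
  d3 <- compute_deltas(sym)
  expect_equal(d3$die, 0)
  expect_true(d3$noise)
})

test_that("normalization against candidate maxima fixes the score scale", {
  one <- compute_deltas(passing_record())
  ctx <- build_scoring_context(one)
  scored <- score_candidates(one, ctx)
  expect_equal(scored$ir_score, 1)

  two <- dplyr::bind_rows(
    compute_deltas(passing_record(TNintron = 10)),
    compute_deltas(passing_record(TNintron = 40)))
  ctx2 <- build_scoring_context(two)
  expect_equal(ctx2$max_die, max(two$die))
  sc2 <- score_candidates(two, ctx2)
  expect_equal(sc2$ndie, two$die / max(two$die))

  expect_error(build_scoring_context(one[0, ]), "no surviving")
  expect_error(build_scoring_context(one, weights = c(0.5, 0.5, 0.1)),
               "sum")
})

test_that("the IR score is the weighted mean of the normalized deltas", {
  expect_equal(ir_score(1, 1, 1), 1)
  expect_equal(ir_score(0.6, 0.3, 0.9), 0.6)
  expect_equal(ir_score(0.6, 0.3, 0.9, weights = c(1, 0, 0)), 0.6)
  # monotone in each argument
  expect_gt(ir_score(0.7, 0.3, 0.9), ir_score(0.6, 0.3, 0.9))
  expect_gt(ir_score(0.6, 0.4, 0.9), ir_score(0.6, 0.3, 0.9))
  expect_gt(ir_score(0.6, 0.3, 1.0), ir_score(0.6, 0.3, 0.9))
})

test_that("ranking uses the ceiling rule and deterministic tie-breaks", {
  scored <- dplyr::bind_rows(lapply(1:10, function(i) {
    dplyr::mutate(compute_deltas(passing_record(TNintron = 4 + i)),
                  intron_id = sprintf("i%02d", i))
  }))
  ctx <- build_scoring_context(scored)
  sc <- score_candidates(scored, ctx)
  expect_equal(nrow(rank_and_select(sc, 10)), 1)
  allr <- rank_and_select(sc, 100)
  expect_equal(nrow(allr), 10)
  expect_true(all(diff(allr$ir_score) <= 0))

  ties <- sc[1:2, ]
  ties$ir_score <- 0.5
  ties$dic <- c(0.1, 0.2)
  ranked <- rank_and_select(ties, 100)
  expect_equal(ranked$dic[1], 0.2)
  expect_error(rank_and_select(sc, 0), "n_percent")
})

test_that("the caller's audit partitions the input and recovers a planted event", {
  sim <- sim_fixture()
  res <- run_ircall(sim$features, n_percent = 100)
  expect_equal(sum(res$audit$n), res$n_input)
  kept_plus_dropped <- sum(res$audit$n[res$audit$reason != "candidate"]) +
    nrow(res$candidates)
  expect_equal(kept_plus_dropped, res$n_input)

  truth_ir <- sim$truth$intron_id[sim$truth$class == "true_ir"]
  expect_gt(length(truth_ir), 0)
  expect_equal(res$events$intron_id[1] %in% truth_ir, TRUE)

  # a table where nothing passes gives an empty result that still audits
  hopeless <- dplyr::mutate(sim$features, TN5ss = 0)
  res0 <- run_ircall(hopeless, n_percent = 10)
  expect_equal(nrow(res0$events), 0)
  expect_equal(sum(res0$audit$n), nrow(hopeless))

  g <- glance(res)
  expect_equal(g$n_input, nrow(sim$features))
  expect_s3_class(tidy(res), "tbl_df")
  expect_s3_class(autoplot(res), "ggplot")
})
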