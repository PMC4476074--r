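#' Intron removal criteria
#'
#' Thresholds used to discard low-quality introns before scoring. All
#' comparisons are strict: a value exactly at a threshold is dropped. The
#' expression-ratio band discards introns whose gene expression differs
#' between conditions — the hallmark of false-positive case where counts
#' shift only because the gene as a whole is up- or down-regulated: an
#' intron is kept only when `log2(TNexpression / CNexpression)` lies strictly
#' inside `expression_ratio_band`.
#'
#' @param min_tn5ss,min_tn3ss Minimum treatment splice-site read counts
#'   (default 3).
#' @param min_tncoverage Minimum treatment intron coverage fraction
#'   (default 0.9).
#' @param min_tnexon,min_cnexon Minimum flanking-exon read counts (default 1).
#' @param min_tnexpression,min_cnexpression Minimum RPKM (default 10).
#' @param min_tnintron Minimum treatment intronic read count (default 1).
#' @param min_cnjunc Minimum control junction read count (default 1).
#' @param expression_ratio_band Open interval of admissible
#'   `log2(TNexpression/CNexpression)` values
#'   (default `(log2(2/3), log2(3/2))`).
#' @return A `removal_criteria` list.
#' @export
removal_criteria <- function(min_tn5ss = 3, min_tn3ss = 3,
                             min_tncoverage = 0.9, min_tnexon = 1,
                             min_tnexpression = 10, min_tnintron = 1,
                             min_cnexpression = 10, min_cnjunc = 1,
                             min_cnexon = 1,
                             expression_ratio_band = c(log2(2 / 3),
                                                       log2(3 / 2))) {
  vals <- c(min_tn5ss, min_tn3ss, min_tncoverage, min_tnexon,
            min_tnexpression, min_tnintron, min_cnexpression, min_cnjunc,
            min_cnexon)
  if (any(vals < 0)) abort("removal thresholds must be non-negative")
  if (length(expression_ratio_band) != 2 ||
      expression_ratio_band[1] >= expression_ratio_band[2]) {
    abort("expression_ratio_band must be an increasing pair of bounds")
  }
  structure(list(
    min_tn5ss = min_tn5ss, min_tn3ss = min_tn3ss,
    min_tncoverage = min_tncoverage, min_tnexon = min_tnexon,
    min_tnexpression = min_tnexpression, min_tnintron = min_tnintron,
    min_cnexpression = min_cnexpression, min_cnjunc = min_cnjunc,
    min_cnexon = min_cnexon,
    expression_ratio_band = expression_ratio_band
  ), class = "removal_criteria")
}

#' Apply the intron removal criteria
#'
#' Flags each feature-table row keep/drop. A row is kept only if it passes
#' every criterion; `drop_reason` names the first failed criterion, in the
#' fixed criterion order (treatment splice sites, coverage, exon,
#' expression, intron count, then control expression, junction, exon, then
#' the expression-ratio band).
#'
#' @param features A feature table from [build_feature_table()].
#' @param criteria A [removal_criteria()] object.
#' @return `features` with added logical `keep` and character `drop_reason`
#'   (NA for kept rows).
#' @export
apply_removal_criteria <- function(features, criteria = removal_criteria()) {
  stopifnot(inherits(criteria, "removal_criteria"))
  band <- criteria$expression_ratio_band
  ratio <- ifelse(features$CNexpression > 0,
                  log2(features$TNexpression / features$CNexpression),
                  NA_real_)
  checks <- list(
    min_tn5ss = features$TN5ss > criteria$min_tn5ss,
    min_tn3ss = features$TN3ss > criteria$min_tn3ss,
    min_tncoverage = features$TNcoverage > criteria$min_tncoverage,
    min_tnexon = features$TNexon > criteria$min_tnexon,
    min_tnexpression = features$TNexpression > criteria$min_tnexpression,
    min_tnintron = features$TNintron > criteria$min_tnintron,
    min_cnexpression = features$CNexpression > criteria$min_cnexpression,
    min_cnjunc = features$CNjunc > criteria$min_cnjunc,
    min_cnexon = features$CNexon > criteria$min_cnexon,
    expression_ratio = !is.na(ratio) & ratio > band[1] & ratio < band[2]
  )
  pass <- do.call(cbind, checks)
  first_fail <- apply(pass, 1, function(p) {
    i <- which(!p)
    if (length(i) == 0) NA_character_ else names(checks)[i[1]]
  })
  # a zero control expression with treatment signal makes the ratio
  # undefined; that diagnosis outranks the ordered criteria
  undefined <- features$CNexpression == 0 & features$TNexpression > 0
  first_fail[which(undefined)] <- "expression-ratio undefined"
  features |>
    mutate(keep = is.na(first_fail), drop_reason = first_fail)
}

#' Treatment/control delta features
#'
#' Per condition, three summaries are formed for each intron: the
#' intron-to-exon count ratio `IE`, the intron-to-junction count ratio `IJ`
#' (both pseudo-counted so empty denominators stay finite) and
#' `IC = exp(coverage)`. The deltas are the log2 treatment-over-control
#' ratios `DIE`, `DIJ`, `DIC`; positive values indicate a retention gain in
#' treatment. A candidate with any delta at or below zero (or non-finite)
#' carries no retention signal and is flagged as noise.
#'
#' @inheritParams apply_removal_criteria
#' @param pseudo Pseudo-count added to all counts entering `IE` and `IJ`
#'   (default 1).
#' @return `features` with added columns `ie_t`, `ie_c`, `ij_t`, `ij_c`,
#'   `ic_t`, `ic_c`, `die`, `dij`, `dic` and logical `noise`.
#' @export
compute_deltas <- function(features, pseudo = 1) {
  if (pseudo < 0) abort("pseudo must be >= 0")
  out <- features |>
    mutate(
      ie_t = (TNintron + pseudo) / (TNexon + pseudo),
      ie_c = (CNintron + pseudo) / (CNexon + pseudo),
      ij_t = (TNintron + pseudo) / (TNjunc + pseudo),
      ij_c = (CNintron + pseudo) / (CNjunc + pseudo),
      ic_t = exp(TNcoverage),
      ic_c = exp(CNcoverage),
      die = log2(ie_t / ie_c),
      dij = log2(ij_t / ij_c),
      dic = log2(ic_t / ic_c)
    )
  out |>
    mutate(noise = !is.finite(die) | !is.finite(dij) | !is.finite(dic) |
             die <= 0 | dij <= 0 | dic <= 0)
}

#' Scoring context: candidate-set maxima and weights
#'
#' Deltas are mapped onto a common (0, 1] scale by dividing each by its
#' maximum over the candidate set, so the three aspects contribute
#' comparably to the weighted score.
#'
#' @param candidates Delta-feature rows that survived filtering and the
#'   noise flag (all deltas strictly positive).
#' @param weights Non-negative weights for (NDIE, NDIJ, NDIC); must sum
#'   to 1 (default equal thirds).
#' @return A `scoring_context` list with `max_die`, `max_dij`, `max_dic`
#'   and `weights`.
#' @export
build_scoring_context <- function(candidates, weights = rep(1, 3) / 3) {
  if (nrow(candidates) == 0) {
    abort("no surviving candidates to build a scoring context from")
  }
  check_weights(weights)
  if (any(candidates$die <= 0 | candidates$dij <= 0 | candidates$dic <= 0)) {
    abort("scoring context requires strictly positive deltas")
  }
  structure(list(
    max_die = max(candidates$die),
    max_dij = max(candidates$dij),
    max_dic = max(candidates$dic),
    weights = weights
  ), class = "scoring_context")
}

check_weights <- function(weights) {
  if (length(weights) != 3 || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-6) {
    abort("weights must be three non-negative values summing to 1")
  }
  invisible(weights)
}

#' IR score from normalized deltas
#'
#' The weighted average of the three normalized deltas; with all inputs in
#' (0, 1] and weights summing to 1, the score lies in (0, 1].
#'
#' @param ndie,ndij,ndic Normalized deltas in (0, 1].
#' @param weights See [build_scoring_context()].
#' @return Numeric score(s).
#' @export
ir_score <- function(ndie, ndij, ndic, weights = rep(1, 3) / 3) {
  check_weights(weights)
  weights[1] * ndie + weights[2] * ndij + weights[3] * ndic
}

#' Normalize candidate deltas and score them
#'
#' @param candidates Delta rows that survived filtering and noise removal.
#' @param context A [build_scoring_context()] object.
#' @return `candidates` with added `ndie`, `ndij`, `ndic`, `ir_score`.
#' @export
score_candidates <- function(candidates, context) {
  stopifnot(inherits(context, "scoring_context"))
  candidates |>
    mutate(
      ndie = die / context$max_die,
      ndij = dij / context$max_dij,
      ndic = dic / context$max_dic,
      ir_score = ir_score(ndie, ndij, ndic, context$weights)
    )
}

#' Rank scored candidates and keep the top n percent
#'
#' Candidates are sorted by IR score descending; ties are broken by `dic`
#' descending and then by `intron_id`, so rankings are reproducible. The
#' number returned is `ceiling(n_percent/100 * candidates)`, which is
#' non-empty for any positive `n_percent`.
#'
#' @param scored Output of [score_candidates()].
#' @param n_percent Percentage of candidates to return, in (0, 100].
#' @return The top rows with a 1-based `rank` column.
#' @export
rank_and_select <- function(scored, n_percent = 10) {
  if (!is.numeric(n_percent) || n_percent <= 0 || n_percent > 100) {
    abort("n_percent must be in (0, 100]")
  }
  if (nrow(scored) == 0) return(scored |> mutate(rank = integer(0)))
  scored |>
    arrange(desc(ir_score), desc(dic), intron_id) |>
    slice_head(n = ceiling(n_percent / 100 * nrow(scored))) |>
    mutate(rank = row_number(), .before = 1)
}

#' Call differential intron-retention events
#'
#' The full rank-based caller: the feature table is filtered by the removal
#' criteria, deltas are computed and noise-flagged, the survivors are
#' normalized against their candidate-set maxima, scored, and the top
#' `n_percent` are returned as IR events. The audit accounts for every
#' input intron exactly once (dropped per criterion, flagged as noise, or
#' kept as a candidate).
#'
#' @inheritParams apply_removal_criteria
#' @inheritParams compute_deltas
#' @inheritParams build_scoring_context
#' @inheritParams rank_and_select
#' @return An object of class `ircall` with elements `events` (ranked
#'   tibble), `candidates` (all scored survivors), `audit` (tibble of
#'   `reason`, `n`), `n_input` and `params`.
#' @examples
#' sim <- simulate_ir_dataset(sim_config(seed = 1))
#' feats <- build_feature_table(sim$treatment, sim$control,
#'                              sim$catalog, sim$exons)
#' res <- run_ircall(feats, n_percent = 10)
#' glance(res)
#' @export
run_ircall <- function(features, criteria = removal_criteria(),
                       weights = rep(1, 3) / 3, pseudo = 1, n_percent = 10) {
  if (nrow(features) == 0) abort("feature table is empty")
  check_weights(weights)
  flagged <- apply_removal_criteria(features, criteria)
  kept <- flagged |> filter(keep) |> select(-keep, -drop_reason)
  deltas <- compute_deltas(kept, pseudo = pseudo)
  survivors <- deltas |> filter(!noise)
  audit <- flagged |>
    filter(!keep) |>
    count(drop_reason, name = "n") |>
    rename(reason = drop_reason) |>
    bind_rows(tibble(reason = c("noise", "candidate"),
                     n = c(sum(deltas$noise), nrow(survivors))))
  if (nrow(survivors) == 0) {
    events <- survivors |> mutate(ndie = numeric(0), ndij = numeric(0),
                                  ndic = numeric(0), ir_score = numeric(0),
                                  rank = integer(0))
    scored <- events
  } else {
    context <- build_scoring_context(survivors, weights)
    scored <- score_candidates(survivors, context)
    events <- rank_and_select(scored, n_percent)
  }
  structure(list(
    events = events,
    candidates = scored,
    audit = audit,
    n_input = nrow(features),
    params = list(criteria = criteria, weights = weights, pseudo = pseudo,
                  n_percent = n_percent)
  ), class = "ircall")
}

#' @export
print.ircall <- function(x, ...) {
  cat("IR call result\n")
  cat(sprintf("  introns in: %d\n", x$n_input))
  cat(sprintf("  candidates after filtering: %d\n", nrow(x$candidates)))
  cat(sprintf("  events returned (top %g%%): %d\n",
              x$params$n_percent, nrow(x$events)))
  invisible(x)
}

#' @describeIn run_ircall Ranked events as a tibble.
#' @param x An `ircall` object.
#' @param ... Unused.
#' @export
tidy.ircall <- function(x, ...) {
  as_tibble(x$events)
}

#' @describeIn run_ircall One-row summary of the run.
#' @export
glance.ircall <- function(x, ...) {
  tibble(
    n_input = x$n_input,
    n_dropped = sum(x$audit$n[!x$audit$reason %in% c("candidate", "noise")]),
    n_noise = x$audit$n[x$audit$reason == "noise"],
    n_candidates = nrow(x$candidates),
    n_events = nrow(x$events),
    top_score = if (nrow(x$events) > 0) max(x$events$ir_score) else NA_real_
  )
}

#' @describeIn run_ircall IR score against rank for all candidates, with
#'   the returned events highlighted.
#' @param object An `ircall` object.
#' @export
autoplot.ircall <- function(object, ...) {
  if (nrow(object$candidates) == 0) {
    abort("no candidates to plot")
  }
  all_ranked <- object$candidates |>
    arrange(desc(ir_score), desc(dic), intron_id) |>
    mutate(rank = row_number(),
           selected = intron_id %in% object$events$intron_id)
  ggplot(all_ranked, aes(x = rank, y = ir_score, colour = selected)) +
    geom_point() +
    labs(x = "rank", y = "IR score", colour = "reported event") +
    theme_bw()
}
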