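#' Shannon entropy of a discrete label vector, in bits
#' @noRd
label_entropy <- function(labels) {
  p <- as.numeric(table(labels)) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Information gain of a discretized feature about a binary label
#'
#' `gain = H(label) - sum_b p(b) H(label | b)` over the bins `b`.
#'
#' @param bins A factor (or vector) of bin assignments, one per example.
#' @param labels A binary label vector of the same length.
#' @return Gain in bits; non-negative and at most `H(label)`.
#' @export
information_gain <- function(bins, labels) {
  stopifnot(length(bins) == length(labels))
  h <- label_entropy(labels)
  cond <- tapply(labels, bins, label_entropy)
  w <- as.numeric(table(bins)[names(cond)]) / length(labels)
  h - sum(w * cond, na.rm = TRUE)
}

# equal-frequency discretization; constant features collapse to one bin
equal_frequency_bins <- function(x, n_bins = 10) {
  breaks <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                            names = FALSE, type = 7))
  if (length(breaks) < 2) {
    return(factor(rep("bin1", length(x))))
  }
  cut(x, breaks = breaks, include.lowest = TRUE)
}

#' Rank base features by information gain of their treatment/control ratio
#'
#' For each of the seven base features the per-intron ratio
#' `treatment / (control + pseudo)` is formed — IR events live where
#' treatment and control differ — discretized into equal-frequency bins,
#' and scored by the reduction in label entropy.
#'
#' @param features A feature table from [build_feature_table()].
#' @param labels A tibble with `intron_id` and `label` (binary), or an
#'   `ir_labeling` object.
#' @param n_bins Number of equal-frequency bins (default 10).
#' @param pseudo Pseudo-count in the ratio denominator (default 1).
#' @return An `ir_gain` tibble of `feature` and `gain` (bits), sorted by
#'   gain descending; ties break by feature name.
#' @export
information_gain_ranking <- function(features, labels, n_bins = 10,
                                     pseudo = 1) {
  if (n_bins < 2) abort("n_bins must be at least 2")
  if (inherits(labels, "ir_labeling")) labels <- tidy(labels)
  dat <- inner_join(as_tibble(labels), as_tibble(features),
                    by = "intron_id")
  if (nrow(dat) == 0) abort("no labeled introns found in the feature table")
  if (length(unique(dat$label)) != 2) {
    abort("labels must take exactly two values")
  }
  base <- c("intron", "exon", "junc", "5ss", "3ss", "coverage", "expression")
  gains <- map_dbl(base, function(b) {
    ratio <- dat[[paste0("TN", b)]] / (dat[[paste0("CN", b)]] + pseudo)
    information_gain(equal_frequency_bins(ratio, n_bins), dat$label)
  })
  out <- tibble(feature = base, gain = gains) |>
    arrange(desc(gain), feature)
  class(out) <- c("ir_gain", class(out))
  out
}

#' @describeIn information_gain_ranking Bar chart of per-feature gains.
#' @param object An `ir_gain` tibble.
#' @param ... Unused.
#' @export
autoplot.ir_gain <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(feature = factor(feature, levels = rev(feature)))
  ggplot(df, aes(x = feature, y = gain)) +
    geom_col() +
    coord_flip() +
    labs(x = NULL, y = "information gain (bits)") +
    theme_bw()
}
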