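#' Binned histogram of rod-length measurements
#'
#' Half-open bins `[anchor + k*w, anchor + (k+1)*w)` matching the 2 nm
#' binning used for rod-length frequency distributions.
#'
#' @param lengths Numeric vector of lengths in nm.
#' @param bin_width Bin width in nm (default 2).
#' @param anchor Left edge of the bin lattice in nm (default 40).
#' @return Tibble with `bin_start`, `bin_end`, `count` (counts sum to
#'   `length(lengths)`; empty input gives an empty histogram).
#' @export
length_histogram <- function(lengths, bin_width = 2, anchor = 40) {
  stopifnot(bin_width > 0)
  if (length(lengths) == 0) {
    return(tibble(bin_start = numeric(0), bin_end = numeric(0),
                  count = integer(0)))
  }
  k <- floor((lengths - anchor) / bin_width)
  tab <- table(k)
  ks <- as.numeric(names(tab))
  full <- seq(min(ks), max(ks))
  counts <- as.integer(tab[match(full, ks)])
  counts[is.na(counts)] <- 0L
  tibble(bin_start = anchor + full * bin_width,
         bin_end = anchor + (full + 1) * bin_width,
         count = counts)
}

#' Median and central quantile range
#'
#' The median plus the central `central_mass` interval (5th-95th
#' percentiles for the default 0.9), using linear interpolation between
#' order statistics (quantile type 7).
#'
#' @param lengths Numeric vector (n >= 1).
#' @param central_mass Central probability mass of the interval (default
#'   0.9).
#' @return One-row tibble: `n`, `median`, `low`, `high`.
#' @export
median_and_range <- function(lengths, central_mass = 0.9) {
  stopifnot(length(lengths) >= 1, central_mass > 0, central_mass <= 1)
  alpha <- (1 - central_mass) / 2
  q <- quantile(lengths, c(alpha, 1 - alpha), names = FALSE, type = 7)
  tibble(n = length(lengths), median = median(lengths),
         low = q[1], high = q[2])
}

#' Kruskal-Wallis test across measurement conditions
#'
#' Tie-corrected rank-based H statistic with the chi-square approximation,
#' as used to compare rod-length distributions between buffer conditions.
#'
#' @param data Data frame with a grouping column and a value column.
#' @param condition,length Column names (strings) of group labels and
#'   values (defaults `"condition"`, `"length_nm"`).
#' @return One-row tibble: `H`, `df`, `p_value`, `n`.
#' @export
rod_kruskal <- function(data, condition = "condition", length = "length_nm") {
  data <- as_tibble(data)
  g <- factor(data[[condition]])
  x <- data[[length]]
  if (nlevels(g) < 2) abort("need at least two conditions")
  if (length(unique(x)) == 1) {
    return(tibble(H = 0, df = nlevels(g) - 1L, p_value = 1, n = length(x)))
  }
  kt <- kruskal.test(x, g)
  tibble(H = unname(kt$statistic), df = unname(kt$parameter),
         p_value = kt$p.value, n = length(x))
}

#' Dunn post-hoc tests against a reference condition, Holm-adjusted
#'
#' Tie-corrected Dunn z statistics comparing each group's mean rank with
#' the reference group on the pooled ranking, two-sided normal p-values,
#' and Holm step-down adjustment across the comparison family.
#'
#' @inheritParams rod_kruskal
#' @param reference Label of the reference condition.
#' @return Tibble with one row per non-reference condition: `comparison`,
#'   `z`, `p_value`, `p_adj`.
#' @export
dunn_holm <- function(data, reference, condition = "condition",
                      length = "length_nm") {
  data <- as_tibble(data)
  g <- factor(data[[condition]])
  x <- data[[length]]
  if (!reference %in% levels(g)) {
    abort(sprintf("reference condition '%s' not present", reference))
  }
  n <- base::length(x)
  r <- rank(x)
  mean_rank <- tapply(r, g, mean)
  n_g <- tapply(r, g, base::length)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  var_term <- n * (n + 1) / 12 - tie_term
  others <- setdiff(levels(g), reference)
  z <- vapply(others, function(lvl) {
    se <- sqrt(var_term * (1 / n_g[[lvl]] + 1 / n_g[[reference]]))
    if (se == 0) return(0)
    (mean_rank[[lvl]] - mean_rank[[reference]]) / se
  }, numeric(1))
  p <- unname(2 * pnorm(-abs(z)))
  tibble(comparison = paste(others, "vs", reference), z = unname(z),
         p_value = p, p_adj = p.adjust(p, method = "holm"))
}
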