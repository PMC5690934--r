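# Synthesis stage: correlation of spatial registration error with
# dosimetric error across a benchmark suite, correlation-strength wording,
# and paired significance testing between registration sources.

#' Pearson correlation with benchmark guardrails
#'
#' Standard product-moment correlation, returning `NA` (with a warning)
#' when fewer than 3 complete pairs are available or either input has zero
#' variance — which happens when every registration in a suite is
#' error-free.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Correlation coefficient in `[-1, 1]`, or `NA`.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) {
    warning("pearson: fewer than 3 complete pairs")
    return(NA_real_)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("pearson: zero variance input")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Correlation-strength wording
#'
#' Maps `|r|` onto the conventional adjectives: below 0.2 very weak,
#' 0.2-0.39 weak, 0.4-0.59 moderate, 0.6-0.79 strong, 0.8 and above very
#' strong.
#'
#' @param r Correlation coefficient(s) in `[-1, 1]`.
#' @return Character vector of labels (`NA` input gives `NA`).
#' @export
strength_label <- function(r) {
  stopifnot(all(abs(r) <= 1, na.rm = TRUE))
  cut(abs(r), breaks = c(-Inf, 0.2, 0.4, 0.6, 0.8, Inf), right = FALSE,
      labels = c("very weak", "weak", "moderate", "strong", "very strong")) |>
    as.character()
}

# the five TRE-vs-dose metric pairings of the benchmark correlation table
correlation_pairings <- function() {
  data.frame(tre_metric = c("tre_mean", "tre_mean", "tre_mean", "tre_mean",
                            "tre_max"),
             dose_metric = c("d_mean_pct", "d_mean_gy", "dvh_mean_gy",
                             "d_max_gy", "d_max_gy"))
}

#' Correlation table of spatial versus dosimetric error
#'
#' For each ROI, pools all (phantom x registration source) benchmark records
#' and computes Pearson correlations for the five standard pairings: TREmu
#' against mean-dose difference (% and Gy), mean DVH difference and max-dose
#' difference, and TREmax against max-dose difference. ROIs with fewer than
#' 3 complete records are omitted with a warning.
#'
#' @param records A benchmark record data frame (see [run_suite()]) with
#'   columns `roi`, `tre_mean`, `tre_max`, `d_mean_pct`, `d_mean_gy`,
#'   `dvh_mean_gy`, `d_max_gy`.
#' @return A data frame with columns `roi`, `tre_metric`, `dose_metric`,
#'   `r`, `n`, `strength`.
#' @export
build_correlation_table <- function(records) {
  stopifnot(is.data.frame(records))
  pairings <- correlation_pairings()
  out <- list()
  for (roi in unique(records$roi)) {
    rec <- records[records$roi == roi, , drop = FALSE]
    if (nrow(rec) < 3) {
      warning("correlation table: fewer than 3 records for ROI ", roi,
              "; omitted")
      next
    }
    for (p in seq_len(nrow(pairings))) {
      x <- rec[[pairings$tre_metric[p]]]
      y <- rec[[pairings$dose_metric[p]]]
      n_ok <- sum(is.finite(x) & is.finite(y))
      r <- if (n_ok >= 3) suppressWarnings(pearson(x, y)) else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        roi = roi, tre_metric = pairings$tre_metric[p],
        dose_metric = pairings$dose_metric[p], r = r, n = n_ok)
    }
  }
  if (length(out) == 0) stop("no ROI had enough records for correlation")
  tab <- do.call(rbind, out)
  tab$strength <- strength_label(tab$r)
  rownames(tab) <- NULL
  tab
}

#' Paired comparison of two registration sources
#'
#' Two-sided paired t-test on per-phantom TREmu differences between two
#' registration sources. When the differences have zero variance (e.g. both
#' sources identical) the test is degenerate and reported as missing.
#'
#' @param tre_mu_a,tre_mu_b Per-phantom TREmu values (mm), paired by
#'   phantom; at least 3 pairs.
#' @return A list with `t`, `df`, `p`, `mean_difference` and `degenerate`.
#' @export
compare_sources <- function(tre_mu_a, tre_mu_b) {
  stopifnot(length(tre_mu_a) == length(tre_mu_b), length(tre_mu_a) >= 3)
  d <- tre_mu_a - tre_mu_b
  if (stats::sd(d) == 0) {
    return(list(t = NA_real_, df = length(d) - 1L, p = NA_real_,
                mean_difference = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(tre_mu_a, tre_mu_b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_difference = mean(d), degenerate = FALSE)
}
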