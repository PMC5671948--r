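#' Depth-methylation log-log Pearson correlation
#'
#' The headline artifact statistic: among cytosines with coverage >= 1 and
#' estimated methylation strictly greater than 0, the Pearson correlation
#' between the logarithm of coverage and the logarithm of the methylation
#' percentage. A genuine methylome gives no systematic relationship; the
#' structure artifact produces a tight negative correlation (low-coverage
#' cytosines carry inflated apparent methylation). Pooling samples is
#' concatenating their filtered records before calling this.
#'
#' @param records Cytosine-report data.frame (with `coverage` and
#'   `methylation_percent`; see [add_methylation_percent()]).
#' @param base Logarithm base; the Pearson coefficient is invariant to it.
#' @return A `correlation_result`: list with `r`, `p_value`, `n`, `filter`
#'   and `defined` (FALSE when fewer than 3 points survive the filter).
#' @export
depth_methylation_correlation <- function(records, base = exp(1)) {
  if (!"coverage" %in% names(records))
    records <- add_methylation_percent(records)
  keep <- records$coverage >= 1 & !is.na(records$methylation_percent) &
    records$methylation_percent > 0
  x <- log(records$coverage[keep], base = base)
  y <- log(records$methylation_percent[keep], base = base)
  filter_desc <- "coverage >= 1 and methylation_percent > 0"
  if (sum(keep) < 3) {
    return(structure(list(r = NA_real_, p_value = NA_real_, n = sum(keep),
                          filter = filter_desc, defined = FALSE),
                     class = "correlation_result"))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), p_value = ct$p.value,
                 n = sum(keep), filter = filter_desc, defined = TRUE),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  if (!x$defined) {
    cat("<correlation_result> undefined (", x$n, " points after filter)\n",
        sep = "")
  } else {
    cat(sprintf("<correlation_result> r = %.3f, p = %.3g, n = %d [%s]\n",
                x$r, x$p_value, x$n, x$filter))
  }
  invisible(x)
}

#' Paired sign test with Bonferroni correction
#'
#' Exact two-sided binomial sign test on paired values (same cytosines under
#' two conditions, e.g. undigested vs digested). Ties are excluded. With
#' `n = n_pos + n_neg` informative pairs and `k = min(n_pos, n_neg)`,
#' `p_raw = min(1, 2 * sum_{i<=k} choose(n, i) / 2^n)` and
#' `p_adjusted = min(1, m_tests * p_raw)`.
#'
#' @param a,b Equal-length numeric vectors of paired values; positives are
#'   pairs with `a > b`.
#' @param m_tests Bonferroni family size, default 1.
#' @return A `sign_test_result`: `n_pos`, `n_neg`, `n_ties`, `p_raw`,
#'   `p_adjusted`, `m`, `degenerate` (all ties).
#' @export
sign_test <- function(a, b, m_tests = 1L) {
  stopifnot(length(a) == length(b), m_tests >= 1)
  ok <- !is.na(a) & !is.na(b)
  d <- a[ok] - b[ok]
  n_pos <- sum(d > 0); n_neg <- sum(d < 0); n_ties <- sum(d == 0)
  n <- n_pos + n_neg
  if (n == 0) {
    p_raw <- 1
  } else {
    k <- min(n_pos, n_neg)
    p_raw <- min(1, 2 * stats::pbinom(k, n, 0.5))
  }
  structure(list(n_pos = n_pos, n_neg = n_neg, n_ties = n_ties,
                 p_raw = p_raw, p_adjusted = min(1, m_tests * p_raw),
                 m = m_tests, degenerate = n == 0),
            class = "sign_test_result")
}

#' @export
print.sign_test_result <- function(x, ...) {
  cat(sprintf(
    "<sign_test_result> +%d/-%d (ties %d), p_raw = %.3g, p_adj = %.3g (m = %d)%s\n",
    x$n_pos, x$n_neg, x$n_ties, x$p_raw, x$p_adjusted, x$m,
    if (x$degenerate) " [degenerate: all ties]" else ""))
  invisible(x)
}

#' Min-max methylation summary for a region
#'
#' Summarises covered cytosines inside a region by the minimum and maximum
#' methylation percentage, optionally split by CpG vs non-CpG context.
#' A region with no covered cytosines is "not determined" (ND).
#'
#' @param records Cytosine-report data.frame.
#' @param region A [genomic_interval()]; when it carries a strand, only
#'   cytosines on that strand are summarised (amplicons interrogate one
#'   strand). Wrapped intervals (end beyond genome length) are supported
#'   when `genome_length` is given.
#' @param name Region label; defaults to the interval's name.
#' @param context_split If `TRUE`, one summary row per context class
#'   (CpG / non-CpG) instead of one pooled row.
#' @param strand_specific Restrict to the region's strand (default TRUE).
#' @param genome_length Genome length for wrapped intervals (`NULL` for
#'   unwrapped).
#' @return data.frame with columns `region`, `context`, `n_cytosines`,
#'   `min_percent`, `max_percent`, `determined`.
#' @export
region_summary <- function(records, region, name = region$name,
                           context_split = FALSE, strand_specific = TRUE,
                           genome_length = NULL) {
  if (!"methylation_percent" %in% names(records))
    records <- add_methylation_percent(records)
  pos <- seq.int(region$start, region$end - 1L)
  if (!is.null(genome_length)) pos <- ((pos - 1L) %% genome_length) + 1L
  sel <- records$position %in% pos & records$coverage > 0
  if (strand_specific && !is.null(region$strand))
    sel <- sel & records$strand == region$strand
  sub <- records[sel, , drop = FALSE]
  groups <- if (context_split) {
    split(sub, ifelse(sub$context == "CpG", "CpG", "non-CpG"))
  } else {
    list(all = sub)
  }
  rows <- lapply(names(groups), function(g) {
    s <- groups[[g]]
    if (nrow(s) == 0) {
      data.frame(region = name, context = g, n_cytosines = 0L,
                 min_percent = NA_real_, max_percent = NA_real_,
                 determined = FALSE, stringsAsFactors = FALSE)
    } else {
      data.frame(region = name, context = g, n_cytosines = nrow(s),
                 min_percent = min(s$methylation_percent),
                 max_percent = max(s$methylation_percent),
                 determined = TRUE, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (nrow(out) == 0)
    out <- data.frame(region = name, context = "all", n_cytosines = 0L,
                      min_percent = NA_real_, max_percent = NA_real_,
                      determined = FALSE, stringsAsFactors = FALSE)
  out
}

#' Correlation of NUMT methylation with NUMT features
#'
#' Plain Pearson correlations (no log transform) of per-NUMT methylation
#' against NUMT length and against NUMT alignment score — the contamination
#' null checks. Constant vectors give an undefined (flagged) result.
#'
#' @param per_numt_methylation Numeric vector of per-NUMT methylation.
#' @param numt_lengths,numt_scores Numeric vectors of the same length.
#' @return List of two `correlation_result`s: `length` and `score`.
#' @export
numt_feature_correlation <- function(per_numt_methylation, numt_lengths,
                                     numt_scores) {
  stopifnot(length(per_numt_methylation) == length(numt_lengths),
            length(per_numt_methylation) == length(numt_scores))
  plain <- function(x, y, what) {
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(structure(list(r = NA_real_, p_value = NA_real_, n = length(x),
                            filter = what, defined = FALSE),
                       class = "correlation_result"))
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    structure(list(r = unname(ct$estimate), p_value = ct$p.value,
                   n = length(x), filter = what, defined = TRUE),
              class = "correlation_result")
  }
  list(length = plain(per_numt_methylation, numt_lengths,
                      "methylation vs NUMT length"),
       score = plain(per_numt_methylation, numt_scores,
                     "methylation vs NUMT alignment score"))
}

#' Smoothed per-position coverage and methylation profile
#'
#' Centred circular sliding-window mean over positions, window =
#' `window_fraction` of the number of positions — a transparent stand-in for
#' a generalized-additive smoother at comparable span, adequate for
#' profile-level comparison (figure-level equivalence is not claimed).
#'
#' @param records Cytosine-report data.frame (one reference).
#' @param window_fraction Window size as a fraction of positions, in
#'   `(0, 1]`; default 0.2.
#' @param circular Wrap the window across the profile ends (default TRUE).
#' @return data.frame `position`, `coverage`, `methylation_percent`,
#'   `smoothed_coverage`, `smoothed_methylation` (positions sorted; both
#'   strands pooled by position).
#' @export
smooth_profile <- function(records, window_fraction = 0.2, circular = TRUE) {
  stopifnot(window_fraction > 0, window_fraction <= 1)
  if (!"methylation_percent" %in% names(records))
    records <- add_methylation_percent(records)
  agg <- stats::aggregate(
    cbind(coverage, count_methylated, count_unmethylated) ~ position,
    data = records, FUN = sum)
  agg <- agg[order(agg$position), ]
  cov_tot <- agg$count_methylated + agg$count_unmethylated
  pct <- ifelse(cov_tot > 0, 100 * agg$count_methylated / cov_tot, NA_real_)
  n <- nrow(agg)
  w <- max(1L, as.integer(round(window_fraction * n)))
  if (w %% 2L == 0L) w <- w + 1L       # centred window
  w <- min(w, n)
  run_mean <- function(x) {
    x0 <- ifelse(is.na(x), 0, x)
    present <- as.numeric(!is.na(x))
    kern <- rep(1, w)
    s <- stats::filter(x0, kern, circular = circular, sides = 2)
    m <- stats::filter(present, kern, circular = circular, sides = 2)
    as.numeric(s / pmax(m, 1e-12))
  }
  data.frame(position = agg$position, coverage = agg$coverage,
             methylation_percent = pct,
             smoothed_coverage = run_mean(agg$coverage),
             smoothed_methylation = run_mean(pct))
}

#' Multiplicity-adjusted background envelope for a region maximum
#'
#' Upper bound on the maximum apparent methylation (in percent) expected
#' from conversion failure alone among `n_cytosines` cytosines sequenced at
#' `coverage`, using the binomial `1 - alpha / n_cytosines` quantile at the
#' baseline failure rate — the envelope the digested arm should fall under.
#'
#' @param epsilon0 Baseline conversion-failure probability.
#' @param coverage Per-cytosine coverage (scalar or vector; the minimum
#'   coverage gives the widest envelope, so the vector's minimum is used).
#' @param n_cytosines Number of cytosines the maximum is taken over.
#' @param alpha Family-wise tail probability, default 0.01.
#' @return Envelope in percent.
#' @export
background_envelope <- function(epsilon0, coverage, n_cytosines,
                                alpha = 0.01) {
  cov <- max(1, min(coverage))
  100 * stats::qbinom(1 - alpha / max(1, n_cytosines), cov, epsilon0) / cov
}
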