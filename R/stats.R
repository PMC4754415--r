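#' Summarize one fish's behavioral event stream
#'
#' @param events data frame `time_s`, `behavior` for one fish (time-ordered).
#' @param session_length_s session duration in seconds.
#' @param resolution_time_s the fish's dyad resolution time (`NA` if the
#'   fight never resolved, e.g. mirror-fighters).
#' @return one-row data frame: `latency_first_bite_s` (session length, with
#'   `latency_censored = TRUE`, when no bite occurred), `resolution_time_s`,
#'   and aggressive/submissive counts over the final five minutes.
#' @export
summarize_behavior <- function(events, session_length_s,
                               resolution_time_s = NA_real_) {
  aggr <- c("bite", "chase", "strike")
  subm <- c("freeze", "flee")
  if (nrow(events) && (any(events$time_s < 0) ||
                       any(events$time_s > session_length_s)))
    stop("event times must lie within the session")
  bites <- events$time_s[events$behavior == "bite"]
  censored <- length(bites) == 0
  latency <- if (censored) session_length_s else min(bites)
  last5 <- events[events$time_s > session_length_s - 300, , drop = FALSE]
  data.frame(latency_first_bite_s = latency,
             latency_censored = censored,
             resolution_time_s = resolution_time_s,
             aggressive_freq_last5 = sum(last5$behavior %in% aggr),
             submissive_freq_last5 = sum(last5$behavior %in% subm))
}

#' Pooled-variance two-sample t-test
#'
#' Student's t with the pooled variance estimate and integer
#' `df = n_x + n_y - 2` (the convention under which the reference behavioral
#' comparisons report whole-number degrees of freedom).
#'
#' @param x,y numeric samples, each `n >= 2`.
#' @return list of class `test_result`: `statistic`, `df`, `p`, `method`.
#' @export
two_sample_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("need n >= 2 per group")
  sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  if (sp2 == 0) {
    if (mean(x) == mean(y))
      return(structure(list(statistic = 0, df = length(x) + length(y) - 2,
                            p = 1, method = "pooled t"),
                       class = "test_result"))
    stop("zero pooled variance with unequal means")
  }
  ht <- stats::t.test(x, y, var.equal = TRUE)
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p = ht$p.value,
                 method = "pooled t"), class = "test_result")
}

#' Cohen's d effect sizes
#'
#' Independent samples: \eqn{d_s = (\bar x - \bar y)/s_p} with the pooled SD.
#' Paired samples: \eqn{d_z = \bar{d} / s_d} on the within-pair differences.
#' Magnitudes are labelled with the conventional thresholds on \eqn{|d|}:
#' > 0.8 large, > 0.5 medium, > 0.2 small, otherwise negligible.
#'
#' @param x,y numeric vectors. When `paired = TRUE` they must align as pairs
#'   (use `pair_key` to match and order them).
#' @param paired compute \eqn{d_z} on differences instead of \eqn{d_s}.
#' @param pair_key_x,pair_key_y optional keys used to form complete pairs.
#' @return list: `d`, `d_type` ("d_s" or "d_z"), `magnitude`, `n` (pair count
#'   when paired), `flag` ("zero_denominator" when the SD vanishes).
#' @export
cohens_d <- function(x, y, paired = FALSE,
                     pair_key_x = NULL, pair_key_y = NULL) {
  if (paired) {
    if (!is.null(pair_key_x)) {
      common <- intersect(pair_key_x, pair_key_y)
      x <- x[match(common, pair_key_x)]
      y <- y[match(common, pair_key_y)]
    }
    keep <- stats::complete.cases(x, y)
    x <- x[keep]; y <- y[keep]
    if (length(x) < 2) stop("need at least 2 complete pairs")
    d_raw <- x - y
    s <- stats::sd(d_raw)
    if (s == 0)
      return(list(d = NA_real_, d_type = "d_z", magnitude = NA_character_,
                  n = length(x), flag = "zero_denominator"))
    d <- mean(d_raw) / s
    type <- "d_z"; n <- length(x)
  } else {
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 2 || length(y) < 2) stop("need n >= 2 per group")
    sp <- sqrt(((length(x) - 1) * stats::var(x) +
                  (length(y) - 1) * stats::var(y)) /
                 (length(x) + length(y) - 2))
    if (sp == 0)
      return(list(d = NA_real_, d_type = "d_s", magnitude = NA_character_,
                  n = c(length(x), length(y)), flag = "zero_denominator"))
    d <- (mean(x) - mean(y)) / sp
    type <- "d_s"; n <- c(length(x), length(y))
  }
  list(d = d, d_type = type, magnitude = d_magnitude(d), n = n, flag = "")
}

d_magnitude <- function(d) {
  a <- abs(d)
  if (a > 0.8) "large" else if (a > 0.5) "medium" else
    if (a > 0.2) "small" else "negligible"
}

#' Welch's one-way ANOVA
#'
#' Heteroscedasticity-robust one-way ANOVA (Welch correction) with
#' Welch–Satterthwaite fractional denominator df.
#'
#' @param values numeric vector.
#' @param group factor/character of group labels (>= 2 groups, each n >= 2,
#'   positive within-group variances).
#' @return `test_result` list: `statistic` (F), `df` (length-2: df1, df2 with
#'   fractional df2), `p`, `method`.
#' @export
welch_anova <- function(values, group) {
  group <- factor(group)
  ns <- tapply(values, group, length)
  vs <- tapply(values, group, stats::var)
  if (nlevels(group) < 2) stop("need at least 2 groups")
  if (any(ns < 2)) stop("each group needs n >= 2")
  if (any(vs == 0)) stop("Welch ANOVA undefined with a zero-variance group")
  ht <- stats::oneway.test(values ~ group, var.equal = FALSE)
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p = ht$p.value,
                 method = "Welch ANOVA"), class = "test_result")
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range post-hoc comparisons on a one-way layout.
#'
#' @inheritParams welch_anova
#' @return data frame: `pair`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
tukey_hsd <- function(values, group) {
  group <- factor(group)
  fit <- stats::aov(values ~ group)
  tk <- stats::TukeyHSD(fit)$group
  data.frame(pair = rownames(tk), diff = tk[, "diff"], lwr = tk[, "lwr"],
             upr = tk[, "upr"], p_adj = tk[, "p adj"], row.names = NULL)
}

#' Benjamini–Hochberg step-up adjustment
#'
#' Thin, name-stable wrapper around `p.adjust(method = "BH")`:
#' \eqn{\tilde p_{(i)} = \min_{j \ge i} \min(1, p_{(j)} m / j)}.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Pearson correlation screen with BH adjustment
#'
#' Computes Pearson correlations for a set of variable pairs over complete
#' observation pairs, then applies [bh_adjust()] across the whole set.
#' Pairs with fewer than 3 complete observations are omitted and logged.
#'
#' @param data wide data frame (one row per unit).
#' @param pairs data frame with columns `var1`, `var2` naming columns of
#'   `data`.
#' @return list: `correlations` (var1, var2, n, r, p, p_adj) and `omitted`
#'   (pairs with insufficient data).
#' @export
corr_with_bh <- function(data, pairs) {
  rows <- vector("list", nrow(pairs))
  omitted <- list()
  for (i in seq_len(nrow(pairs))) {
    v1 <- pairs$var1[i]; v2 <- pairs$var2[i]
    x <- data[[v1]]; y <- data[[v2]]
    keep <- stats::complete.cases(x, y)
    n <- sum(keep)
    if (n < 3) {
      omitted[[length(omitted) + 1]] <- data.frame(var1 = v1, var2 = v2,
                                                   n = n)
      next
    }
    ct <- stats::cor.test(x[keep], y[keep], method = "pearson")
    rows[[i]] <- data.frame(var1 = v1, var2 = v2, n = n,
                            r = unname(ct$estimate), p = ct$p.value)
  }
  cor_df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(cor_df))
    cor_df <- data.frame(var1 = character(0), var2 = character(0),
                         n = integer(0), r = numeric(0), p = numeric(0))
  cor_df$p_adj <- if (nrow(cor_df)) bh_adjust(cor_df$p) else numeric(0)
  rownames(cor_df) <- NULL
  list(correlations = cor_df,
       omitted = if (length(omitted)) do.call(rbind, omitted) else
         data.frame(var1 = character(0), var2 = character(0), n = integer(0)))
}
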