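#' Generalized extreme studentized deviate (gESD) outlier test
#'
#' Rosner's sequential procedure for up to `max_outliers` outliers: at each
#' step the value with the largest two-sided studentized deviation
#' \eqn{R_i = \max_j |x_j - \bar x| / s} is removed and compared with the
#' critical value
#' \deqn{\lambda_i = \frac{(n-i)\, t_{p,\,n-i-1}}{\sqrt{(n-i-1+t^2_{p,\,n-i-1})(n-i+1)}},
#'       \quad p = 1 - \frac{\alpha}{2(n-i+1)},}
#' and the declared outlier count is the largest \eqn{i} with
#' \eqn{R_i > \lambda_i}.
#'
#' @param values numeric vector, `n >= 5` finite values.
#' @param alpha two-sided significance level.
#' @param max_outliers maximum number of outliers tested (`>= 1`).
#' @return list of class `esd_result`: `values`, `R_stats`, `lambda_crit`
#'   (both length `max_outliers`, `NA`-padded if iteration stopped early on
#'   zero variance), `n_outliers`, and `outlier_indices` (indices into
#'   `values` in removal order, truncated to the declared outliers).
#' @examples
#' gesd(c(0.1, 0.2, 0.15, 0.18, 0.12, 100), max_outliers = 1)$outlier_indices
#' @export
gesd <- function(values, alpha = 0.05, max_outliers) {
  if (max_outliers < 1) stop("max_outliers must be >= 1")
  if (length(values) < 5 || any(!is.finite(values)))
    stop("gesd requires at least 5 finite values")
  n <- length(values)
  max_outliers <- min(max_outliers, n - 2)
  R <- lambda <- rep(NA_real_, max_outliers)
  removed <- integer(0)
  remaining <- seq_len(n)
  for (i in seq_len(max_outliers)) {
    x <- values[remaining]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) break  # zero variance: stop, no further outliers
    dev <- abs(x - mean(x))
    j <- which.max(dev)
    R[i] <- dev[j] / s
    ni <- n - i + 1  # sample size at this iteration
    p <- 1 - alpha / (2 * ni)
    tq <- stats::qt(p, df = ni - 2)
    lambda[i] <- (ni - 1) * tq / sqrt((ni - 2 + tq^2) * ni)
    removed <- c(removed, remaining[j])
    remaining <- remaining[-j]
  }
  exceeds <- which(!is.na(R) & R > lambda)
  n_out <- if (length(exceeds)) max(exceeds) else 0L
  structure(list(values = values, R_stats = R, lambda_crit = lambda,
                 n_outliers = as.integer(n_out),
                 outlier_indices = removed[seq_len(n_out)]),
            class = "esd_result")
}

#' Screen a long table for outliers condition by condition
#'
#' Applies [gesd()] independently within every condition cell (by default
#' treatment x nucleus x gene), with the per-cell outlier cap set to
#' `floor(max_frac * n_cell)`. Cells with fewer than 5 values are skipped
#' (and logged). Also usable for cortisol by passing
#' `group_cols = "treatment"` and `value_col = "cortisol_ng_ml"`.
#'
#' @param table long data frame.
#' @param alpha gESD significance level.
#' @param max_frac maximum removable fraction of each cell (default 20%).
#' @param value_col name of the numeric column screened.
#' @param group_cols columns defining a condition cell.
#' @param id_col identifier column echoed into the log.
#' @return list with `table` (rows declared outliers removed), `log` (one row
#'   per removed value: condition, id, value, `R`, `lambda`, iteration) and
#'   `skipped` (cells too small to screen).
#' @export
screen_dataset <- function(table, alpha = 0.05, max_frac = 0.2,
                           value_col = "relative_expression",
                           group_cols = c("treatment", "nucleus", "gene"),
                           id_col = "fish_id") {
  stopifnot(all(c(value_col, group_cols, id_col) %in% names(table)))
  key <- interaction(table[group_cols], drop = TRUE, sep = ":")
  drop_rows <- integer(0)
  log_rows <- list()
  skipped <- character(0)
  for (cell in levels(key)) {
    idx <- which(key == cell)
    x <- table[[value_col]][idx]
    if (length(idx) < 5) {
      skipped <- c(skipped, cell)
      next
    }
    cap <- floor(max_frac * length(idx))
    if (cap < 1) {
      skipped <- c(skipped, cell)
      next
    }
    res <- gesd(x, alpha = alpha, max_outliers = cap)
    if (res$n_outliers > 0) {
      out_idx <- res$outlier_indices
      drop_rows <- c(drop_rows, idx[out_idx])
      log_rows[[cell]] <- data.frame(
        condition = cell,
        id = table[[id_col]][idx[out_idx]],
        value = x[out_idx],
        R = res$R_stats[seq_len(res$n_outliers)],
        lambda = res$lambda_crit[seq_len(res$n_outliers)],
        iteration = seq_len(res$n_outliers),
        stringsAsFactors = FALSE)
    }
  }
  log_df <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(condition = character(0), id = character(0),
               value = numeric(0), R = numeric(0), lambda = numeric(0),
               iteration = integer(0))
  rownames(log_df) <- NULL
  if (length(skipped))
    message("screening skipped for ", length(skipped),
            " condition cell(s) with n < 5 (or cap < 1)")
  out <- if (length(drop_rows)) table[-drop_rows, , drop = FALSE] else table
  rownames(out) <- NULL
  list(table = out, log = log_df, skipped = skipped)
}
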