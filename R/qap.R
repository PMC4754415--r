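#' Gene co-expression matrix for one condition
#'
#' Pairwise-complete Pearson correlations between all target-gene pairs for
#' the fish of one (treatment, nucleus) cell, with per-pair two-sided
#' p-values BH-adjusted within the matrix's gene pairs. Genes observed in
#' fewer than 3 fish have their row/column marked missing.
#'
#' @param table screened expression table (`fish_id`, `treatment`, `nucleus`,
#'   `gene`, `relative_expression`).
#' @param treatment,nucleus the condition cell.
#' @param genes gene order (default: order of appearance).
#' @param log_scale correlate log expression (default, consistent with the
#'   mixed-model scale).
#' @return object of class `coexpr_matrix`: `treatment`, `nucleus`, `genes`,
#'   `r` (gene x gene), `n` (per-pair complete counts), `p`, `p_adj`,
#'   `dropped_genes`.
#' @export
coexpression_matrix <- function(table, treatment, nucleus, genes = NULL,
                                log_scale = TRUE) {
  d <- table[table$treatment == treatment & table$nucleus == nucleus, ]
  # gene order taken from the full table so every condition's matrix shares
  # the same ordering regardless of which rows screening removed
  if (is.null(genes)) genes <- unique(table$gene)
  d <- d[d$gene %in% genes, , drop = FALSE]
  g <- length(genes)
  fish <- sort(unique(d$fish_id))
  wide <- matrix(NA_real_, length(fish), g, dimnames = list(fish, genes))
  for (i in seq_len(nrow(d)))
    wide[d$fish_id[i], d$gene[i]] <- d$relative_expression[i]
  if (log_scale) wide <- log(wide)

  obs <- colSums(!is.na(wide))
  dropped <- genes[obs < 3]
  r <- p <- n <- matrix(NA_real_, g, g, dimnames = list(genes, genes))
  diag(r) <- 1
  for (i in seq_len(g - 1)) for (j in (i + 1):g) {
    keep <- stats::complete.cases(wide[, i], wide[, j])
    n[i, j] <- n[j, i] <- sum(keep)
    if (genes[i] %in% dropped || genes[j] %in% dropped || sum(keep) < 3) next
    ct <- stats::cor.test(wide[keep, i], wide[keep, j], method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  up <- upper.tri(p)
  padj <- matrix(NA_real_, g, g, dimnames = list(genes, genes))
  pv <- p[up]
  adj <- rep(NA_real_, length(pv))
  adj[!is.na(pv)] <- bh_adjust(pv[!is.na(pv)])
  padj[up] <- adj
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  if (length(dropped))
    message("genes with < 3 observations in (", treatment, ", ", nucleus,
            "): ", paste(dropped, collapse = ", "))
  structure(list(treatment = treatment, nucleus = nucleus, genes = genes,
                 r = r, n = n, p = p, p_adj = padj,
                 dropped_genes = dropped),
            class = "coexpr_matrix")
}

coexpr_r <- function(x) {
  if (inherits(x, "coexpr_matrix")) x$r else as.matrix(x)
}

# Pearson correlation of rows of M against vector a (both length ncell).
row_cor <- function(M, a) {
  ac <- a - mean(a)
  Mc <- M - rowMeans(M)
  num <- Mc %*% ac
  den <- sqrt(rowSums(Mc^2) * sum(ac^2))
  drop(num / den)
}

qap_stat_setup <- function(A, B) {
  A <- coexpr_r(A); B <- coexpr_r(B)
  g <- nrow(A)
  if (!identical(dim(A), dim(B))) stop("matrices must match in dimension")
  if (!is.null(dimnames(A)) && !is.null(dimnames(B)) &&
      !identical(colnames(A), colnames(B)))
    stop("matrices must share the same gene set and order")
  up <- which(upper.tri(A))
  a <- A[up]; b <- B[up]
  if (anyNA(a) || anyNA(b)) stop("missing cells among compared pairs")
  list(A = A, B = B, g = g, up = up, a = a, b = b,
       rows = row(A)[up], cols = col(A)[up])
}

qap_perm_values <- function(setup, P) {
  # P: n_perm x g matrix of permutations; values of permuted B's upper cells
  li <- P[, setup$rows, drop = FALSE] +
    (P[, setup$cols, drop = FALSE] - 1L) * setup$g
  matrix(setup$B[li], nrow = nrow(P))
}

#' QAP correlation test between two co-expression matrices
#'
#' Observed statistic: Pearson correlation over the \eqn{g(g-1)/2} upper
#' off-diagonal cells. Null distribution: the rows and columns of the second
#' matrix are permuted by a common random gene relabeling and the statistic
#' recomputed. The default alternative is one-tailed positive association
#' ("similar matrices"); the Monte-Carlo p uses the add-one estimator
#' \eqn{p = (1 + \#\{r_{perm} \ge r_{obs}\}) / (1 + n_{perm})} and so never
#' returns 0. Exhaustive mode enumerates all \eqn{g!} relabelings and
#' returns the exact \eqn{p = \#\{r_{perm} \ge r_{obs}\}/g!}; it is selected
#' automatically when \eqn{g! \le n_{perm}}.
#'
#' @param A,B `coexpr_matrix` objects (or plain symmetric matrices) with
#'   identical gene sets and order.
#' @param n_perm number of Monte-Carlo permutations.
#' @param seed integer seed (required in Monte-Carlo mode).
#' @param mode `"auto"`, `"monte_carlo"` or `"exhaustive"`.
#' @param alternative `"greater"` (positive association, default) or
#'   `"two_sided"`.
#' @return object of class `qap_result`: `r_obs`, `p`, `n_perm`, `mode`,
#'   `seed`, `alternative`, `defined`. When either matrix has zero variance
#'   across its off-diagonal cells the association is undefined
#'   (`defined = FALSE`, no p).
#' @export
qap_correlation <- function(A, B, n_perm = 5000, seed = NULL,
                            mode = c("auto", "monte_carlo", "exhaustive"),
                            alternative = c("greater", "two_sided")) {
  mode <- match.arg(mode)
  alternative <- match.arg(alternative)
  setup <- qap_stat_setup(A, B)
  g <- setup$g
  if (mode == "auto")
    mode <- if (g <= 8 && factorial(g) <= n_perm) "exhaustive" else
      "monte_carlo"
  if (stats::sd(setup$a) == 0 || stats::sd(setup$b) == 0) {
    return(structure(list(r_obs = NA_real_, p = NA_real_, n_perm = NA_integer_,
                          mode = mode, seed = seed,
                          alternative = alternative, defined = FALSE),
                     class = "qap_result"))
  }
  r_obs <- stats::cor(setup$a, setup$b)
  tol <- 1e-12
  if (mode == "exhaustive") {
    if (g > 8) stop("exhaustive mode refused for g > 8; use monte_carlo")
    P <- all_permutations(g)
    r_perm <- row_cor(qap_perm_values(setup, P), setup$a)
    hits <- if (alternative == "greater") sum(r_perm >= r_obs - tol) else
      sum(abs(r_perm) >= abs(r_obs) - tol)
    p <- hits / nrow(P)
    n_used <- nrow(P)
  } else {
    if (is.null(seed)) stop("monte_carlo mode requires a seed")
    P <- with_substream(seed, "qap",
                        t(replicate(n_perm, sample.int(g))))
    r_perm <- row_cor(qap_perm_values(setup, P), setup$a)
    hits <- if (alternative == "greater") sum(r_perm >= r_obs - tol) else
      sum(abs(r_perm) >= abs(r_obs) - tol)
    p <- (1 + hits) / (1 + n_perm)
    n_used <- n_perm
  }
  structure(list(r_obs = r_obs, p = p, n_perm = n_used, mode = mode,
                 seed = seed, alternative = alternative, defined = TRUE),
            class = "qap_result")
}

#' Exhaustive QAP test (testing oracle)
#'
#' Convenience wrapper forcing exhaustive enumeration of all \eqn{g!}
#' simultaneous row+column permutations (`g <= 8`).
#'
#' @inheritParams qap_correlation
#' @return a `qap_result` with exact rational p (denominator \eqn{g!}).
#' @export
qap_exhaustive <- function(A, B, alternative = c("greater", "two_sided")) {
  qap_correlation(A, B, mode = "exhaustive",
                  alternative = match.arg(alternative))
}

#' @export
print.qap_result <- function(x, ...) {
  if (!x$defined) {
    cat("QAP correlation: undefined association (zero off-diagonal variance)\n")
    return(invisible(x))
  }
  cat(sprintf("QAP correlation: r_obs = %.3f, p = %.4g (%s, %d permutations)\n",
              x$r_obs, x$p, x$mode, x$n_perm))
  invisible(x)
}

#' Partition conditions into neurogenomic-state classes
#'
#' Runs all pairwise QAP tests among a set of co-expression matrices and
#' groups the units by the decision rule of the source analysis: a
#' significant positive QAP association (`p < alpha`) is read as "same
#' co-expression pattern", and letter classes are the connected components of
#' the resulting similarity graph. Components that are not cliques
#' (intransitive similarity) are reported loudly in `intransitive`. Units
#' involved in an undefined association are flagged and excluded.
#'
#' @param matrices named list of `coexpr_matrix` objects (the units).
#' @param axis `"treatments"` (capital letters) or `"nuclei"` (small
#'   letters); controls labelling only.
#' @param alpha similarity threshold on the QAP p-value.
#' @param n_perm,seed,alternative passed to [qap_correlation()].
#' @return object of class `state_partition`: `labels` (unit -> letter),
#'   `edges` (pairwise QAP results), `intransitive` (within-component
#'   non-edges), `excluded`.
#' @export
partition_states <- function(matrices, axis = c("treatments", "nuclei"),
                             alpha = 0.05, n_perm = 5000, seed = NULL,
                             alternative = "greater") {
  axis <- match.arg(axis)
  units <- names(matrices)
  if (is.null(units) || anyDuplicated(units))
    stop("matrices must be a uniquely named list")
  k <- length(units)
  edges <- list()
  sim <- matrix(FALSE, k, k, dimnames = list(units, units))
  excluded <- character(0)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    pair_seed <- if (is.null(seed)) NULL else
      substream_seed(seed, paste0("qap:", units[i], ":", units[j]))
    q <- qap_correlation(matrices[[i]], matrices[[j]], n_perm = n_perm,
                         seed = pair_seed, alternative = alternative)
    edges[[length(edges) + 1]] <- data.frame(
      unit1 = units[i], unit2 = units[j],
      r_obs = q$r_obs, p = q$p, mode = q$mode,
      n_perm = q$n_perm, defined = q$defined)
    if (!q$defined) {
      excluded <- union(excluded, c(units[i], units[j]))
    } else if (!is.na(q$p) && q$p < alpha) {
      sim[i, j] <- sim[j, i] <- TRUE
    }
  }
  edges <- do.call(rbind, edges)

  active <- setdiff(units, excluded)
  comp <- stats::setNames(rep(NA_integer_, length(active)), active)
  cid <- 0
  for (u in active) {
    if (!is.na(comp[u])) next
    cid <- cid + 1
    frontier <- u
    while (length(frontier)) {
      comp[frontier] <- cid
      nbrs <- unlist(lapply(frontier, function(v)
        active[sim[v, active] & is.na(comp[active])]))
      frontier <- unique(nbrs)
    }
  }
  letters_pool <- if (axis == "treatments") LETTERS else letters
  labels <- stats::setNames(letters_pool[comp], names(comp))

  intransitive <- list()
  for (cc in unique(comp)) {
    members <- names(comp)[comp == cc]
    if (length(members) < 3) next
    for (i in seq_along(members)) for (j in seq_along(members)) {
      if (i < j && !sim[members[i], members[j]])
        intransitive[[length(intransitive) + 1]] <-
          data.frame(unit1 = members[i], unit2 = members[j],
                     component = letters_pool[cc])
    }
  }
  intransitive <- if (length(intransitive)) do.call(rbind, intransitive) else
    data.frame(unit1 = character(0), unit2 = character(0),
               component = character(0))
  if (nrow(intransitive))
    warning("intransitive similarity within component(s): ",
            paste(unique(intransitive$component), collapse = ", "),
            " — letters are connected components, not cliques")
  structure(list(axis = axis, labels = labels, edges = edges,
                 intransitive = intransitive, excluded = excluded,
                 alpha = alpha),
            class = "state_partition")
}

#' @export
print.state_partition <- function(x, ...) {
  cat("Neurogenomic-state partition (", x$axis, ", alpha = ", x$alpha,
      ")\n", sep = "")
  for (u in names(x$labels)) cat("  ", u, ": ", x$labels[[u]], "\n", sep = "")
  if (length(x$excluded))
    cat("  excluded (undefined association):",
        paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}
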