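#' Mann-Whitney U comparison of two samples
#'
#' Two-sided rank-sum comparison as used for between-group endpoint
#' comparisons. The exact null distribution is used when both samples have
#' at most `exact_max` observations and there are no ties; otherwise the
#' normal approximation with tie and continuity corrections is used
#' (delegating to [stats::wilcox.test()]).
#'
#' @param x,y Numeric samples (each n >= 3).
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @param exact_max Largest per-sample size for the exact distribution.
#' @return A `comparison_result`: list with `test = "MWU"`, `statistic` (U),
#'   `p_value`, `significant`, `exact`, `n`.
#' @export
mann_whitney <- function(x, y, alpha = 0.05, exact_max = 8) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) {
    stop("empty sample", call. = FALSE)
  }
  if (length(x) < 3L || length(y) < 3L) {
    warning("sample with fewer than 3 observations; p-value unreliable",
            call. = FALSE)
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- length(x) <= exact_max && length(y) <= exact_max && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE)
  )
  structure(list(test = "MWU",
                 statistic = unname(wt$statistic),
                 p_value = wt$p.value,
                 significant = wt$p.value < alpha,
                 exact = exact,
                 n = c(length(x), length(y)),
                 alpha = alpha),
            class = "comparison_result")
}

#' Kruskal-Wallis comparison of two or more samples
#'
#' Tie-corrected H statistic referred to its chi-square asymptotic
#' distribution (delegating to [stats::kruskal.test()]).
#'
#' @param groups List of numeric samples (>= 2 non-empty groups, each
#'   ideally n >= 3).
#' @param alpha Significance level for the `significant` flag.
#' @return A `comparison_result` with `test = "KW"`, `statistic` (H), `df`,
#'   `p_value`, `significant`.
#' @export
kruskal_wallis <- function(groups, alpha = 0.05) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  groups <- Filter(function(g) length(g) > 0L, groups)
  if (length(groups) < 2L) {
    stop("need at least 2 non-empty groups", call. = FALSE)
  }
  if (any(vapply(groups, length, integer(1)) < 3L)) {
    warning("group with fewer than 3 observations; p-value unreliable",
            call. = FALSE)
  }
  kt <- kruskal.test(groups)
  structure(list(test = "KW",
                 statistic = unname(kt$statistic),
                 df = unname(kt$parameter),
                 p_value = kt$p.value,
                 significant = kt$p.value < alpha,
                 n = vapply(groups, length, integer(1)),
                 alpha = alpha),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<%s> statistic=%.4g  p=%.4g %s(alpha=%.2g)\n",
              x$test, x$statistic, x$p_value,
              if (x$significant) "*significant* " else "", x$alpha))
  invisible(x)
}

#' Group summaries with between-group comparisons
#'
#' Summarizes a tidy feature table as mean +/- SD with n per group within
#' each cell (characteristic, and optionally preload), and attaches a
#' CONT-vs-MCT style nonparametric comparison per cell. Comparisons are
#' skipped (p = NA) when any group in the cell has fewer than 3 muscles; a
#' single-muscle group is summarized with the `sd = 0` convention and a
#' warning. P-values are uncorrected by default, matching the convention of
#' reporting each preload/characteristic separately; `holm = TRUE` applies a
#' Holm adjustment across the cells.
#'
#' @param tbl Data frame with columns `group`, `characteristic`, `value`,
#'   and optionally `preload_pct` and `units`.
#' @param test `"MWU"` (two groups) or `"KW"`.
#' @param alpha Significance level.
#' @param holm Apply Holm correction across cells (default `FALSE`).
#' @return Data frame with one row per group x characteristic (x preload):
#'   `n`, `mean`, `sd`, `units`, plus the per-cell `test`, `statistic`, `p`,
#'   `significant`.
#' @export
summarize_features <- function(tbl, test = c("MWU", "KW"), alpha = 0.05,
                               holm = FALSE) {
  test <- match.arg(test)
  need <- c("group", "characteristic", "value")
  if (!all(need %in% names(tbl))) {
    stop("`tbl` needs columns group, characteristic, value", call. = FALSE)
  }
  if (!"preload_pct" %in% names(tbl)) tbl$preload_pct <- NA_real_
  if (!"units" %in% names(tbl)) tbl$units <- ""
  cells <- unique(tbl[, c("characteristic", "preload_pct")])
  out <- list()
  warned_single <- FALSE
  for (i in seq_len(nrow(cells))) {
    cell <- tbl[tbl$characteristic == cells$characteristic[i] &
                  (is.na(cells$preload_pct[i]) |
                     tbl$preload_pct %in% cells$preload_pct[i]), ]
    samples <- split(cell$value, cell$group)
    ns <- vapply(samples, length, integer(1))
    cmp <- if (length(samples) >= 2L && all(ns >= 3L)) {
      if (test == "MWU" && length(samples) == 2L) {
        mann_whitney(samples[[1L]], samples[[2L]], alpha = alpha)
      } else {
        kruskal_wallis(samples, alpha = alpha)
      }
    } else NULL
    for (g in names(samples)) {
      v <- samples[[g]]
      if (length(v) == 1L) warned_single <- TRUE
      s <- if (length(v) == 1L) 0 else sd(v)
      out[[length(out) + 1L]] <- data.frame(
        characteristic = cells$characteristic[i],
        preload_pct = cells$preload_pct[i],
        group = g, n = length(v), mean = mean(v), sd = s,
        units = cell$units[1L],
        test = if (is.null(cmp)) NA_character_ else cmp$test,
        statistic = if (is.null(cmp)) NA_real_ else cmp$statistic,
        p = if (is.null(cmp)) NA_real_ else cmp$p_value,
        stringsAsFactors = FALSE)
    }
  }
  if (warned_single) {
    warning("single-muscle group summarized with sd = 0", call. = FALSE)
  }
  res <- do.call(rbind, out)
  if (holm) {
    cell_id <- paste(res$characteristic, res$preload_pct)
    first <- !duplicated(cell_id)
    adj <- p.adjust(res$p[first], method = "holm")
    res$p <- adj[match(cell_id, cell_id[first])]
  }
  res$significant <- !is.na(res$p) & res$p < alpha
  res
}
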