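#' Two-way fixed-effects ANOVA with rank-transform fallback
#'
#' Classical two-way ANOVA of a response against two crossed factors
#' (typically treatment and dose) on a balanced design, with an optional
#' rank transform applied when residual normality fails: with
#' `transform = "auto"` the raw-scale model is fitted first and ranks are
#' used instead when a Shapiro-Wilk test of its residuals rejects at 0.05.
#'
#' Only balanced designs are accepted; an unbalanced table would make the
#' sums-of-squares decomposition ambiguous and is rejected explicitly.
#'
#' @param data a `data.frame` containing the response and factor columns.
#' @param response name of the numeric response column (e.g. `"fe"`).
#' @param factors character vector of two factor column names; default
#'   `c("particle", "dose")`.
#' @param transform `"auto"`, `"none"` or `"rank"`.
#' @return an object of class `"anova_result"`: a list with `table`
#'   (`data.frame` of term, df, F, p), `transform` (applied transform),
#'   `shapiro_p` (residual normality p-value of the raw-scale fit) and
#'   `model`.
#' @export
two_way_anova <- function(data, response = "fe",
                          factors = c("particle", "dose"),
                          transform = c("auto", "none", "rank")) {
  transform <- match.arg(transform)
  if (length(factors) != 2L || !all(factors %in% names(data)) ||
      !response %in% names(data)) {
    stop("response and two factor columns must exist in data", call. = FALSE)
  }
  a <- factor(data[[factors[1L]]])
  b <- factor(data[[factors[2L]]])
  y <- data[[response]]
  if (nlevels(a) < 2L || nlevels(b) < 2L) {
    stop("each factor needs >= 2 levels", call. = FALSE)
  }
  counts <- table(a, b)
  if (length(unique(as.vector(counts))) != 1L) {
    stop("unbalanced design: unequal cell counts", call. = FALSE)
  }
  n_cell <- counts[1L]
  if (n_cell < 2L) {
    stop("interaction term needs >= 2 replicates per cell", call. = FALSE)
  }

  fit_tab <- function(yy) {
    terms <- c(factors, paste(factors, collapse = " x "), "Residuals")
    if (sd(yy) == 0) {
      # no variance anywhere: every between- and within-term SS is exactly
      # zero, so every F ratio is reported as 0
      dfs <- c(nlevels(a) - 1L, nlevels(b) - 1L,
               (nlevels(a) - 1L) * (nlevels(b) - 1L),
               length(yy) - nlevels(a) * nlevels(b))
      return(data.frame(term = terms, df = dfs, F = c(0, 0, 0, NA),
                        p = c(1, 1, 1, NA), stringsAsFactors = FALSE))
    }
    fit <- aov(yy ~ a * b)
    tab <- anova(fit)
    data.frame(term = terms, df = tab$Df, F = tab$`F value`,
               p = tab$`Pr(>F)`, stringsAsFactors = FALSE)
  }

  raw_fit <- aov(y ~ a * b)
  res <- residuals(raw_fit)
  shapiro_p <- if (length(res) >= 3L && length(res) <= 5000L && sd(res) > 0) {
    shapiro.test(res)$p.value
  } else {
    NA_real_
  }
  applied <- switch(transform,
    none = "none",
    rank = "rank",
    auto = if (!is.na(shapiro_p) && shapiro_p < 0.05) "rank" else "none")

  yy <- if (applied == "rank") rank(y) else y
  tab <- fit_tab(yy)
  # a no-variance response yields NaN F ratios; report them as 0 since
  # between-group and within-group variation are both exactly zero
  tab$F[is.nan(tab$F)] <- 0
  structure(list(table = tab, transform = applied, shapiro_p = shapiro_p,
                 factors = factors, model = raw_fit),
            class = "anova_result")
}

#' One-way ANOVA across treatment groups
#'
#' Standard one-way F test, used e.g. for particle-treatment effects on the
#' GSH/GSSG oxidative-stress ratio.
#'
#' @param groups a named list of numeric vectors (one per group, each with
#'   at least 2 observations), or a `data.frame` with `value` and `group`
#'   columns.
#' @return an `"anova_result"` object (see [two_way_anova()]).
#' @export
#' @examples
#' one_way_anova(list(a = c(1, 2, 3), b = c(4, 5, 6)))$table$F[1]  # 13.5
one_way_anova <- function(groups) {
  if (is.data.frame(groups)) {
    groups <- split(groups$value, groups$group)
  }
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need >= 2 groups", call. = FALSE)
  }
  sizes <- lengths(groups)
  if (any(sizes < 2L)) {
    stop("every group needs >= 2 observations", call. = FALSE)
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), sizes))
  dfs <- c(length(groups) - 1L, length(y) - length(groups))
  if (sd(y) == 0) {
    out <- data.frame(term = c("group", "Residuals"), df = dfs,
                      F = c(0, NA), p = c(1, NA),
                      stringsAsFactors = FALSE)
    fit <- NULL
  } else {
    fit <- aov(y ~ g)
    tab <- anova(fit)
    out <- data.frame(term = c("group", "Residuals"), df = tab$Df,
                      F = tab$`F value`, p = tab$`Pr(>F)`,
                      stringsAsFactors = FALSE)
    out$F[is.nan(out$F)] <- 0
  }
  structure(list(table = out, transform = "none", shapiro_p = NA_real_,
                 factors = "group", model = fit),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("ANOVA (transform:", x$transform, ")\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Holm-Sidak step-down multiple-comparison adjustment
#'
#' Sorts the raw p-values ascending and adjusts the i-th smallest of m as
#' `1 - (1 - p_(i))^(m - i + 1)`, then enforces monotonicity with a running
#' maximum and caps at 1. Values are returned in the original input order.
#'
#' @param raw_p numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of adjusted p-values, same order as `raw_p`.
#' @export
#' @examples
#' holm_sidak(c(0.01, 0.04))  # 0.0199, 0.04
holm_sidak <- function(raw_p) {
  if (!is.numeric(raw_p) || any(!is.finite(raw_p)) ||
      any(raw_p < 0 | raw_p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(raw_p)
  if (m == 0L) return(numeric(0))
  o <- order(raw_p)
  p_sorted <- raw_p[o]
  adj <- 1 - (1 - p_sorted)^(m - seq_len(m) + 1L)
  adj <- cummax(adj)
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Treatment-versus-control comparisons with Holm-Sidak adjustment
#'
#' Welch t-tests of every treatment group against the control group, with
#' step-down Sidak adjustment across the contrast family. An all-pairs
#' family is available as an option.
#'
#' @param values numeric response vector.
#' @param group group labels, same length as `values`.
#' @param control label of the control group (required for
#'   `family = "vs_control"`).
#' @param family `"vs_control"` (default) or `"all_pairs"`.
#' @return a `data.frame` of contrasts with columns `group1`, `group2`,
#'   `estimate` (mean difference), `raw_p`, `adj_p`, ordered by `raw_p`.
#' @export
adjusted_comparisons <- function(values, group, control = NULL,
                                 family = c("vs_control", "all_pairs")) {
  family <- match.arg(family)
  group <- as.character(group)
  levels <- unique(group)
  pairs <- if (family == "vs_control") {
    if (is.null(control) || !control %in% levels) {
      stop("control group not found in data", call. = FALSE)
    }
    lapply(setdiff(levels, control), function(g) c(g, control))
  } else {
    utils::combn(levels, 2L, simplify = FALSE)
  }
  rows <- lapply(pairs, function(pr) {
    x <- values[group == pr[1L]]; y <- values[group == pr[2L]]
    # degenerate limit: with zero variance in both groups the test
    # collapses to an equality check of the means
    p <- if (sd(x) == 0 && sd(y) == 0) {
      as.numeric(isTRUE(all.equal(mean(x), mean(y))))
    } else {
      t.test(x, y)$p.value
    }
    data.frame(group1 = pr[1L], group2 = pr[2L],
               estimate = mean(x) - mean(y), raw_p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- holm_sidak(out$raw_p)
  out <- out[order(out$raw_p), ]
  rownames(out) <- NULL
  out
}
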