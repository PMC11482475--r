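#' Pearson correlation with listwise deletion
#'
#' Product-moment correlation between two numeric vectors after dropping
#' pairs with a missing value in either. At least three complete pairs and
#' nonzero variance in both vectors are required.
#'
#' @param x,y numeric vectors of equal length.
#' @return a list with `r` (full-precision correlation), `n` (complete
#'   pairs used) and `p` (two-sided test p-value from [stats::cor.test()]).
#' @export
#' @examples
#' pearson_r(c(1, 2, 3), c(1, 2, 3))$r  # 1
pearson_r <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y)) {
    stop("x and y must be numeric vectors of equal length", call. = FALSE)
  }
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) {
    stop("need at least 3 complete pairs after listwise deletion",
         call. = FALSE)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop("degenerate input: zero variance", call. = FALSE)
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), n = n, p = ct$p.value)
}

#' All pairwise descriptor-potency correlations
#'
#' Correlates each numeric descriptor column against the signed potency
#' exponent of each endpoint/cell type, with per-pair listwise deletion of
#' missing descriptor values.
#'
#' @param descriptors a `data.frame` with a `particle` column and numeric
#'   descriptor columns (see [zno_descriptors()]).
#' @param potency a long potency `data.frame` with `particle`, `cell_type`,
#'   `endpoint` and `beta_abs` or `beta_signed` columns.
#' @param particles optional subset of particle labels to use (e.g. the
#'   nanoforms only); default all shared particles.
#' @return a tidy `data.frame` with columns `cell_type`, `endpoint`,
#'   `descriptor`, `r`, `n`, `p`.
#' @export
pairwise_associations <- function(descriptors, potency, particles = NULL) {
  if (!"particle" %in% names(descriptors)) {
    stop("descriptor table needs a particle column", call. = FALSE)
  }
  if (is.null(particles)) {
    particles <- intersect(descriptors$particle, potency$particle)
  }
  desc <- descriptors[match(particles, descriptors$particle), , drop = FALSE]
  num_cols <- names(desc)[vapply(desc, is.numeric, logical(1L))]

  pot <- potency[potency$particle %in% particles, , drop = FALSE]
  if (!"beta_signed" %in% names(pot)) {
    pot$beta_signed <- signed_beta(pot$beta_abs, pot$endpoint)
  }
  combos <- unique(pot[, c("cell_type", "endpoint")])
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    sub <- pot[pot$cell_type == combos$cell_type[i] &
                 pot$endpoint == combos$endpoint[i], ]
    b <- sub$beta_signed[match(particles, sub$particle)]
    for (col in num_cols) {
      res <- tryCatch(pearson_r(desc[[col]], b), error = function(e) NULL)
      if (is.null(res)) next
      rows[[length(rows) + 1L]] <- data.frame(
        cell_type = combos$cell_type[i], endpoint = combos$endpoint[i],
        descriptor = col, r = res$r, n = res$n, p = res$p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Backward stepwise regression by p-value elimination
#'
#' Ordinary least squares with intercept on internally standardized
#' predictors; the predictor with the largest p-value above `alpha_remove`
#' is dropped and the model refitted, until every retained predictor has
#' `p <= alpha_remove`. With small screening panels this is the standard
#' way to search for physicochemical determinants of potency.
#'
#' @param X numeric matrix or data.frame of candidate predictors (columns
#'   named); rows with any missing value are dropped listwise.
#' @param y numeric response vector (e.g. signed potency exponents).
#' @param alpha_remove removal threshold on the per-predictor p-value
#'   (default 0.10). `alpha_remove = 1` retains all predictors;
#'   `alpha_remove = 0` retains none.
#' @return a list of class `"stepwise_fit"`: `retained` (character),
#'   `coefficients` (on the standardized scale, intercept included),
#'   `p_values`, `n`, `dropped` (in drop order), `model` (the final `lm`).
#' @export
backward_stepwise <- function(X, y, alpha_remove = 0.10) {
  X <- as.data.frame(X)
  if (!all(vapply(X, is.numeric, logical(1L)))) {
    stop("all predictors must be numeric", call. = FALSE)
  }
  if (!is.numeric(y) || length(y) != nrow(X)) {
    stop("y must be numeric with one value per row of X", call. = FALSE)
  }
  ok <- complete.cases(X, y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  n <- nrow(X); p <- ncol(X)
  if (n < p + 2L) {
    stop(sprintf(
      "refusing stepwise fit: %d rows for %d predictors (need >= %d); %s",
      n, p, p + 2L, "use pairwise correlation instead"), call. = FALSE)
  }
  const <- vapply(X, function(v) sd(v) == 0, logical(1L))
  if (any(const)) {
    stop("constant predictor(s): ", paste(names(X)[const], collapse = ", "),
         call. = FALSE)
  }
  Xs <- as.data.frame(scale(X))

  keep <- names(Xs)
  dropped <- character(0)
  repeat {
    if (!length(keep)) {
      fit <- lm(y ~ 1)
      pv <- numeric(0)
      break
    }
    dat <- cbind(Xs[, keep, drop = FALSE], .y = y)
    fit <- lm(.y ~ ., data = dat)
    cf <- coef(fit)
    if (anyNA(cf)) {
      stop("collinear design; aliased predictor(s): ",
           paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
    }
    sm <- summary(fit)$coefficients
    rows <- setdiff(rownames(sm), "(Intercept)")
    pv <- sm[rows, 4L]
    # single-row subsetting drops the name; restore it explicitly
    names(pv) <- sub("^`(.*)`$", "\\1", rows)
    worst <- which.max(pv)
    if (length(pv) && pv[worst] > alpha_remove) {
      dropped <- c(dropped, names(pv)[worst])
      keep <- setdiff(keep, names(pv)[worst])
    } else {
      break
    }
  }

  structure(
    list(retained = keep, coefficients = coef(fit), p_values = pv,
         n = n, dropped = dropped, alpha_remove = alpha_remove, model = fit),
    class = "stepwise_fit")
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat("Backward stepwise OLS (alpha_remove =", x$alpha_remove, ")\n")
  if (length(x$retained)) {
    cat("retained:", paste(x$retained, collapse = ", "), "\n")
    print(round(cbind(coef = x$coefficients[x$retained], p = x$p_values), 4))
  } else {
    cat("retained: (intercept only)\n")
  }
  invisible(x)
}
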