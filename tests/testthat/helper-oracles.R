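# Independent oracles used across the suite. Each is a deliberately
# different computational route from the implementation it checks.

# through-origin slope of log(fe) on log(dose + 1); closed form
oracle_loglinear_beta <- function(dose, fe) {
  ld <- log(dose + 1)
  sum(log(fe) * ld) / sum(ld^2)
}

# backward p-value elimination via explicit normal equations (no lm())
oracle_backward_eliminate <- function(X, y, alpha) {
  Xs <- scale(as.matrix(X))
  keep <- colnames(Xs)
  repeat {
    if (!length(keep)) return(character(0))
    M <- cbind(`(Intercept)` = 1, Xs[, keep, drop = FALSE])
    XtXi <- solve(crossprod(M))
    bh <- XtXi %*% crossprod(M, y)
    df <- nrow(M) - ncol(M)
    s2 <- sum((y - M %*% bh)^2) / df
    tval <- bh / sqrt(diag(XtXi) * s2)
    p <- 2 * pt(-abs(tval[-1L]), df)
    names(p) <- keep
    w <- which.max(p)
    if (p[w] > alpha) keep <- keep[-w] else return(keep)
  }
}

# per-predictor p-values of an OLS fit on a given predictor subset,
# again via explicit matrix algebra
oracle_subset_pvalues <- function(X, y, subset) {
  Xs <- scale(as.matrix(X))
  M <- cbind(1, Xs[, subset, drop = FALSE])
  XtXi <- solve(crossprod(M))
  bh <- XtXi %*% crossprod(M, y)
  df <- nrow(M) - ncol(M)
  s2 <- sum((y - M %*% bh)^2) / df
  tval <- bh / sqrt(diag(XtXi) * s2)
  p <- as.numeric(2 * pt(-abs(tval[-1L]), df))
  names(p) <- subset
  p
}

# balanced two-way ANOVA by manual sums-of-squares decomposition
oracle_two_way_ss <- function(y, a, b) {
  a <- factor(a); b <- factor(b)
  g <- mean(y)
  am <- tapply(y, a, mean)
  bm <- tapply(y, b, mean)
  cm <- tapply(y, interaction(a, b), mean)
  n_a <- table(a)[1L]
  n_b <- table(b)[1L]
  n_cell <- table(a, b)[1L]
  ss_a <- sum(n_a * (am - g)^2)
  ss_b <- sum(n_b * (bm - g)^2)
  cell_df <- expand.grid(a = levels(a), b = levels(b))
  cell_means <- cm[paste(cell_df$a, cell_df$b, sep = ".")]
  ss_int <- n_cell * sum((cell_means - am[cell_df$a] - bm[cell_df$b] + g)^2)
  ss_tot <- sum((y - g)^2)
  ss_err <- ss_tot - ss_a - ss_b - ss_int
  df_a <- nlevels(a) - 1L
  df_b <- nlevels(b) - 1L
  df_int <- df_a * df_b
  df_err <- length(y) - nlevels(a) * nlevels(b)
  mse <- ss_err / df_err
  list(F_a = (ss_a / df_a) / mse,
       F_b = (ss_b / df_b) / mse,
       F_int = (ss_int / df_int) / mse,
       df = c(df_a, df_b, df_int, df_err))
}

# one mini-screen (single particle, single endpoint) simulated and fitted;
# returns the fitted signed exponent
recover_beta_once <- function(beta_true, seed, noise_sigma = 0.1,
                              method = "nls") {
  cfg <- sim_config(
    betas = data.frame(particle = "NP", cell_type = "C", endpoint = "ATP",
                       beta_signed = beta_true),
    noise_sigma = noise_sigma, seed = seed)
  fe <- suppressWarnings(compute_fold_effect(simulate_assay(cfg)))
  fit_potency(fe, method = method)$beta_signed[1L]
}
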