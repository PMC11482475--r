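#' Fit the power-law potency model FE = (Dose + 1)^beta
#'
#' The potency exponent beta is the single parameter of the model
#' `FE = (Dose + 1)^beta`: its magnitude measures how steeply the endpoint
#' changes with dose and its sign the direction. Two estimators are
#' available:
#' \describe{
#'   \item{`nls`}{(default) least squares on untransformed fold effects:
#'     beta minimizes `sum((fe - (dose+1)^beta)^2)` over `[-5, 5]`
#'     (bounded 1-D minimization polished by a root solve of the gradient).}
#'   \item{`loglinear`}{closed-form through-origin regression of `log(fe)`
#'     on `log(dose + 1)`.}
#' }
#' On noise-free power-law data the two coincide.
#'
#' @param dose numeric vector of doses (ug/cm2), finite, `>= 0`, with at
#'   least 3 distinct values including 0.
#' @param fe numeric vector of fold effects, finite and `> 0`.
#' @param method `"nls"` or `"loglinear"`.
#' @return an object of class `"potency_fit"`: a list with `beta_signed`,
#'   `beta_abs`, `se_beta`, `rss`, `n_points`, `method`.
#' @export
#' @examples
#' d <- c(0, 10, 30, 100)
#' fit_beta(d, (d + 1)^0.2)$beta_signed  # 0.2
fit_beta <- function(dose, fe, method = c("nls", "loglinear")) {
  method <- match.arg(method)
  if (!is.numeric(dose) || !is.numeric(fe) ||
      any(!is.finite(dose)) || any(!is.finite(fe))) {
    stop("dose and fe must be finite numeric vectors", call. = FALSE)
  }
  if (length(dose) != length(fe)) {
    stop("dose and fe must have equal length", call. = FALSE)
  }
  if (any(dose < 0)) stop("doses must be >= 0", call. = FALSE)
  if (any(fe <= 0)) stop("fold effects must be > 0", call. = FALSE)
  if (length(unique(dose)) < 3L) {
    stop("insufficient design: need >= 3 distinct doses", call. = FALSE)
  }
  if (!any(dose == 0)) {
    stop("insufficient design: a zero dose is required", call. = FALSE)
  }

  ld <- log1p(dose)
  lf <- log(fe)
  beta_ll <- sum(lf * ld) / sum(ld^2)

  if (method == "loglinear") {
    beta <- beta_ll
  } else {
    obj <- function(b) sum((fe - (dose + 1)^b)^2)
    grad <- function(b) -2 * sum((fe - (dose + 1)^b) * (dose + 1)^b * ld)
    opt <- optimize(obj, interval = c(-5, 5), tol = 1e-10)
    beta <- opt$minimum
    # polish: the objective is smooth in one parameter, so a root solve on
    # the gradient around the bracketed optimum sharpens the estimate
    lo <- beta - 1e-4; hi <- beta + 1e-4
    if (is.finite(grad(lo)) && is.finite(grad(hi)) &&
        sign(grad(lo)) != sign(grad(hi))) {
      beta <- uniroot(grad, c(lo, hi), tol = 1e-14)$root
    }
  }

  resid <- fe - (dose + 1)^beta
  rss <- sum(resid^2)
  n <- length(fe)
  g <- (dose + 1)^beta * ld           # d/dbeta of the model curve
  se <- if (n > 1L && sum(g^2) > 0) {
    sqrt((rss / (n - 1L)) / sum(g^2))
  } else {
    NA_real_
  }

  structure(
    list(beta_signed = beta, beta_abs = abs(beta), se_beta = se,
         rss = rss, n_points = n, method = method),
    class = "potency_fit")
}

#' @export
print.potency_fit <- function(x, ...) {
  cat(sprintf("Power-law potency fit (%s): beta = %.4f (se %.4f), n = %d\n",
              x$method, x$beta_signed, x$se_beta, x$n_points))
  invisible(x)
}

#' Fit potency exponents for every particle x cell type x endpoint
#'
#' Duplicate wells are first averaged within each experiment and dose, then
#' the per-(experiment, dose) mean fold effects of all experiments are
#' pooled and fitted jointly with [fit_beta()], each point weighted equally.
#'
#' @param fe_table a fold-effect table from [compute_fold_effect()].
#' @param method fitting method passed to [fit_beta()].
#' @param directions named endpoint-direction map (see
#'   [endpoint_direction()]).
#' @return a `data.frame` with one row per particle/cell type/endpoint and
#'   columns `beta_signed`, `beta_abs`, `se_beta`, `rss`, `n_points`,
#'   `direction`.
#' @export
fit_potency <- function(fe_table, method = c("nls", "loglinear"),
                        directions = .default_directions) {
  method <- match.arg(method)
  needed <- c("experiment_id", "particle", "cell_type", "dose", "endpoint",
              "fe")
  missing <- setdiff(needed, names(fe_table))
  if (length(missing)) {
    stop("fold-effect table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  # average duplicates within experiment x dose
  aggr <- stats::aggregate(
    fe ~ experiment_id + cell_type + particle + endpoint + dose,
    data = fe_table, FUN = mean)

  groups <- split(aggr,
                  interaction(aggr$particle, aggr$cell_type, aggr$endpoint,
                              drop = TRUE))
  rows <- lapply(groups, function(g) {
    fit <- fit_beta(g$dose, g$fe, method = method)
    data.frame(particle = g$particle[1L], cell_type = g$cell_type[1L],
               endpoint = g$endpoint[1L], beta_signed = fit$beta_signed,
               beta_abs = fit$beta_abs, se_beta = fit$se_beta,
               rss = fit$rss, n_points = fit$n_points,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$direction <- endpoint_direction(out$endpoint, directions)
  rownames(out) <- NULL
  out[order(out$cell_type, out$particle, out$endpoint), ]
}

#' Consensus potency across the three cytotoxicity endpoints
#'
#' The consensus average potency is the mean of the absolute potency
#' exponents of the ATP, LDH and CTB endpoints,
#' `beta_avg = (|beta_ATP| + |beta_LDH| + |beta_CTB|) / 3`,
#' computed at full precision.
#'
#' @param beta_atp,beta_ldh,beta_ctb numeric vectors of potency exponents
#'   (signed or absolute; absolute values are taken).
#' @return numeric vector of consensus average potencies.
#' @export
#' @examples
#' consensus_beta(0.120, 0.058, 0.089)  # 0.089
consensus_beta <- function(beta_atp, beta_ldh, beta_ctb) {
  if (!is.numeric(beta_atp) || !is.numeric(beta_ldh) ||
      !is.numeric(beta_ctb)) {
    stop("potency exponents must be numeric", call. = FALSE)
  }
  (abs(beta_atp) + abs(beta_ldh) + abs(beta_ctb)) / 3
}

#' Consensus potency table from per-endpoint estimates
#'
#' Combines a long potency table (one row per particle/cell type/endpoint,
#' endpoints ATP, LDH, CTB) into per particle x cell type consensus average
#' potencies with within-cell-type ranks.
#'
#' @param potency a `data.frame` with columns `particle`, `cell_type`,
#'   `endpoint` and `beta_abs` (or `beta_signed`, whose absolute value is
#'   used), e.g. from [fit_potency()] or [zno_potency()].
#' @return a `data.frame` with columns `particle`, `cell_type`, `beta_avg`,
#'   `rank` (1 = most potent within its cell type).
#' @export
consensus_potency <- function(potency) {
  if (!all(c("particle", "cell_type", "endpoint") %in% names(potency))) {
    stop("potency table needs particle, cell_type and endpoint columns",
         call. = FALSE)
  }
  b <- if ("beta_abs" %in% names(potency)) {
    abs(potency$beta_abs)
  } else if ("beta_signed" %in% names(potency)) {
    abs(potency$beta_signed)
  } else {
    stop("potency table needs a beta_abs or beta_signed column",
         call. = FALSE)
  }
  need <- c("ATP", "LDH", "CTB")
  wide <- lapply(split(data.frame(endpoint = potency$endpoint, b = b,
                                  particle = potency$particle,
                                  cell_type = potency$cell_type,
                                  stringsAsFactors = FALSE),
                       interaction(potency$particle, potency$cell_type,
                                   drop = TRUE)),
                 function(g) {
                   if (!all(need %in% g$endpoint)) {
                     stop("particle ", g$particle[1L], " (", g$cell_type[1L],
                          ") lacks endpoint(s): ",
                          paste(setdiff(need, g$endpoint), collapse = ", "),
                          call. = FALSE)
                   }
                   bb <- setNames(g$b, g$endpoint)
                   data.frame(particle = g$particle[1L],
                              cell_type = g$cell_type[1L],
                              beta_avg = consensus_beta(bb["ATP"], bb["LDH"],
                                                        bb["CTB"]),
                              stringsAsFactors = FALSE)
                 })
  out <- do.call(rbind, wide)
  rownames(out) <- NULL
  parts <- split(out, out$cell_type)
  out <- do.call(rbind, lapply(parts, rank_particles))
  rownames(out) <- NULL
  out
}

#' Rank particles by consensus potency
#'
#' Rank 1 is the most potent (largest consensus average beta). Ranking uses
#' the full-precision consensus values, not their rounded display form;
#' exact ties are broken lexicographically by particle label with a notice.
#'
#' @param consensus a `data.frame` with columns `particle` and `beta_avg`
#'   for a single cell type (one row per particle).
#' @return the input with a `rank` column added (a permutation of
#'   `1..n_particles`).
#' @export
rank_particles <- function(consensus) {
  if (anyDuplicated(consensus$particle)) {
    stop("duplicate particle entries: ",
         paste(consensus$particle[duplicated(consensus$particle)],
               collapse = ", "), call. = FALSE)
  }
  if (length(unique(consensus$cell_type)) > 1L) {
    stop("rank_particles expects a single cell type; use consensus_potency",
         call. = FALSE)
  }
  ord <- order(-consensus$beta_avg, consensus$particle)
  if (anyDuplicated(consensus$beta_avg)) {
    message("tied consensus potencies broken lexicographically by particle")
  }
  consensus$rank <- integer(nrow(consensus))
  consensus$rank[ord] <- seq_len(nrow(consensus))
  consensus
}

#' Recover a signed potency exponent from an absolute value
#'
#' Published potency tables report absolute exponents; associations with
#' descriptors need the sign back. For endpoints that decrease with dose
#' (ATP, CTB) the signed exponent is `-beta_abs`; for increasing endpoints
#' (LDH) it is `+beta_abs`.
#'
#' @param beta_abs numeric vector of absolute exponents.
#' @param endpoint endpoint labels, same length (or length 1).
#' @param directions named endpoint-direction map.
#' @return numeric vector of signed exponents.
#' @export
#' @examples
#' signed_beta(1.233, "ATP")  # -1.233
signed_beta <- function(beta_abs, endpoint,
                        directions = .default_directions) {
  dir <- endpoint_direction(endpoint, directions)
  ifelse(dir == "decreasing", -abs(beta_abs), abs(beta_abs))
}
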