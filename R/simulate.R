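# All generators are pure functions of (config, seed): the RNG state is
# seeded locally and restored on exit, so identical calls are bit-identical
# and callers' random streams are untouched.
.with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Simulation configuration for a study-structured cytotoxicity screen
#'
#' Bundles and validates the design parameters of the synthetic plate-assay
#' generator. The defaults emulate a standard screening design: 8 particles
#' in 2 cell types with 3 endpoints, a 7-point dose grid spanning
#' 0-100 ug/cm2, 3 independent experiments with duplicate wells, and
#' multiplicative log-normal noise with sigma 0.1 (a typical plate-assay
#' CV). The default true exponents are the signed versions of the bundled
#' ZnO case-study potency table, so the simulated screen has a realistic
#' potency spread.
#'
#' @param betas a `data.frame` with columns `particle`, `cell_type`,
#'   `endpoint`, `beta_signed` giving the ground-truth exponents; default
#'   the signed [zno_potency()] table.
#' @param doses numeric dose grid including 0 (ug/cm2); default
#'   `c(0, 5, 10, 20, 40, 80, 100)`.
#' @param n_experiments number of independent experiments (default 3).
#' @param duplicates wells per treatment group per experiment (default 2).
#' @param noise_sigma SD of the log-normal multiplicative well noise
#'   (default 0.1).
#' @param control_signal_mean mean zero-dose instrument signal (default
#'   5e4, arbitrary units).
#' @param control_cv between-experiment CV of the control signal level
#'   (default 0.1).
#' @param blank_frac no-cells interference signal at the top dose, as a
#'   fraction of the control signal (default 0.02; scales linearly with
#'   dose).
#' @param ldh_total_factor total LDH content of lysed controls relative to
#'   the zero-dose released signal (default 5).
#' @param seed integer RNG seed.
#' @return a validated list of class `"sim_config"`.
#' @export
sim_config <- function(betas = NULL, doses = c(0, 5, 10, 20, 40, 80, 100),
                       n_experiments = 3L, duplicates = 2L,
                       noise_sigma = 0.1, control_signal_mean = 5e4,
                       control_cv = 0.1, blank_frac = 0.02,
                       ldh_total_factor = 5, seed = 1L) {
  if (is.null(betas)) {
    betas <- zno_potency()
    betas$beta_signed <- signed_beta(betas$beta_abs, betas$endpoint)
    betas <- betas[, c("particle", "cell_type", "endpoint", "beta_signed")]
  }
  need <- c("particle", "cell_type", "endpoint", "beta_signed")
  if (!all(need %in% names(betas))) {
    stop("betas needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!any(doses == 0)) stop("dose grid must include 0", call. = FALSE)
  if (any(doses < 0) || any(!is.finite(doses))) {
    stop("doses must be finite and >= 0", call. = FALSE)
  }
  if (n_experiments < 1L) stop("n_experiments must be >= 1", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (control_signal_mean <= 0) {
    stop("control_signal_mean must be > 0", call. = FALSE)
  }
  structure(
    list(betas = betas, doses = sort(unique(doses)),
         n_experiments = as.integer(n_experiments),
         duplicates = as.integer(duplicates), noise_sigma = noise_sigma,
         control_signal_mean = control_signal_mean, control_cv = control_cv,
         blank_frac = blank_frac, ldh_total_factor = ldh_total_factor,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' Simulate a raw plate-assay table
#'
#' Generates per-well signals under the power-law dose-response model: each
#' cells-well signal is
#' `control_level_experiment * (dose + 1)^beta_true * exp(eps)` with
#' `eps ~ N(0, noise_sigma^2)`, plus a dose-proportional no-cells
#' interference baseline that is also emitted as matching `no_cells` wells
#' (so blank correction recovers the clean signal). Lysed-control wells are
#' emitted for the LDH endpoint so that %LDH released can be formed.
#'
#' With `noise_sigma = 0`, running [compute_fold_effect()] on the output
#' returns fold effects equal to `(dose + 1)^beta_true` exactly.
#'
#' @param config a [sim_config()] object.
#' @return a raw assay `data.frame` (see [read_assay_table()] for the
#'   column contract).
#' @export
#' @examples
#' cfg <- sim_config(noise_sigma = 0, seed = 7)
#' raw <- simulate_assay(cfg)
#' fe <- compute_fold_effect(raw)
simulate_assay <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, {
    betas <- config$betas
    doses <- config$doses
    max_dose <- max(doses)
    blank_at <- function(d) {
      if (max_dose > 0) {
        config$blank_frac * config$control_signal_mean * d / max_dose
      } else {
        0
      }
    }
    strata <- unique(betas[, c("cell_type", "endpoint")])
    rows <- vector("list", 0L)
    for (s in seq_len(nrow(strata))) {
      ct <- strata$cell_type[s]; ep <- strata$endpoint[s]
      sub <- betas[betas$cell_type == ct & betas$endpoint == ep, ]
      for (e in seq_len(config$n_experiments)) {
        exp_id <- sprintf("E%d", e)
        level <- config$control_signal_mean *
          exp(rnorm(1L, 0, config$control_cv))
        for (i in seq_len(nrow(sub))) {
          part <- sub$particle[i]; b <- sub$beta_signed[i]
          for (d in doses) {
            mu <- level * (d + 1)^b
            eps <- rnorm(config$duplicates, 0, config$noise_sigma)
            rows[[length(rows) + 1L]] <- data.frame(
              experiment_id = exp_id, cell_type = ct, particle = part,
              dose = d, endpoint = ep, role = "cells",
              replicate = seq_len(config$duplicates),
              signal = mu * exp(eps) + blank_at(d),
              stringsAsFactors = FALSE)
            rows[[length(rows) + 1L]] <- data.frame(
              experiment_id = exp_id, cell_type = ct, particle = part,
              dose = d, endpoint = ep, role = "no_cells", replicate = 1L,
              signal = blank_at(d), stringsAsFactors = FALSE)
          }
        }
        if (ep == "LDH") {
          rows[[length(rows) + 1L]] <- data.frame(
            experiment_id = exp_id, cell_type = ct, particle = "none",
            dose = 0, endpoint = "LDH", role = "lysed_control",
            replicate = 1:2,
            signal = rep(level * config$ldh_total_factor, 2L),
            stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a particle descriptor table coupled to true potency
#'
#' Draws descriptor columns as linear transforms of the (standardized)
#' true signed potency exponent plus Gaussian noise calibrated so the
#' population correlation with the exponent equals the requested target;
#' columns with target 0 are independent noise.
#'
#' @param beta numeric vector of true signed exponents, one per particle.
#' @param coupling named numeric vector of target correlations in
#'   `[-1, 1]`, one per descriptor column.
#' @param seed integer RNG seed.
#' @param location,scale location and scale applied to the standardized
#'   descriptor values (defaults 100 and 20); affine, so correlations are
#'   unchanged.
#' @return a `data.frame` with `particle` labels and one column per
#'   descriptor.
#' @export
simulate_descriptors <- function(beta, coupling, seed = 1L,
                                 location = 100, scale = 20) {
  if (any(!is.finite(coupling)) || any(abs(coupling) > 1)) {
    stop("target correlations must lie in [-1, 1]", call. = FALSE)
  }
  if (length(beta) < 3L) {
    stop("need at least 3 particles", call. = FALSE)
  }
  if (sd(beta) == 0) {
    stop("true exponents are constant; coupling is undefined",
         call. = FALSE)
  }
  .with_seed(seed, {
    n <- length(beta)
    z <- (beta - mean(beta)) / sd(beta)
    out <- data.frame(particle = if (!is.null(names(beta))) {
      names(beta)
    } else {
      sprintf("P%02d", seq_len(n))
    }, stringsAsFactors = FALSE)
    for (nm in names(coupling)) {
      r <- coupling[[nm]]
      y <- r * z + sqrt(1 - r^2) * rnorm(n)
      out[[nm]] <- location + scale * y
    }
    out
  })
}

#' Simulate a GSH/GSSG oxidative-stress table
#'
#' Each treatment suppresses the control GSH/GSSG ratio by a fixed factor;
#' replicate signals carry multiplicative log-normal noise. With zero noise
#' [gsh_gssg_fc()] recovers the suppression factors exactly.
#'
#' @param suppression named numeric vector of per-treatment ratio
#'   suppression factors (1 = no effect, < 1 = oxidative stress).
#' @param n_replicates replicates per treatment (default 3).
#' @param control_ratio control GSH/GSSG ratio (default 20).
#' @param gssg_level mean GSSG signal (default 1000, arbitrary units).
#' @param noise_sigma SD of log-normal noise (default 0.05).
#' @param seed integer RNG seed.
#' @return a `data.frame` with columns `treatment` (including
#'   `"control"`), `replicate`, `gsh`, `gssg`.
#' @export
simulate_stress <- function(suppression, n_replicates = 3L,
                            control_ratio = 20, gssg_level = 1000,
                            noise_sigma = 0.05, seed = 1L) {
  if (is.null(names(suppression)) || any(suppression <= 0)) {
    stop("suppression must be a named vector of positive factors",
         call. = FALSE)
  }
  .with_seed(seed, {
    treatments <- c(control = 1, suppression)
    rows <- lapply(seq_along(treatments), function(i) {
      fac <- treatments[[i]]
      gssg <- gssg_level * exp(rnorm(n_replicates, 0, noise_sigma))
      gsh <- control_ratio * fac * gssg *
        exp(rnorm(n_replicates, 0, noise_sigma))
      data.frame(treatment = names(treatments)[i],
                 replicate = seq_len(n_replicates), gsh = gsh, gssg = gssg,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a secreted-protein fold-change panel
#'
#' Builds a protein x treatment fold-change matrix in log2 space: each
#' treatment block shares a latent per-protein profile (`profile_sd`) plus
#' independent column noise (`noise_sd`), so columns within a block have
#' population correlation `profile_sd^2 / (profile_sd^2 + noise_sd^2)`.
#' Designated responder proteins additionally carry a fixed fold change in
#' the treatments of `responder_block`.
#'
#' @param n_proteins number of panel proteins (default 30).
#' @param blocks named list of treatment-label blocks; default a
#'   coated/uncoated/reference layout of 8 particles.
#' @param responders named numeric vector of fold changes for designated
#'   responder proteins (names must be protein labels `P01`, `P02`, ...);
#'   default none.
#' @param responder_block name of the block whose treatments carry the
#'   responder fold changes (default the first block).
#' @param profile_sd SD of the shared per-block log2 profile (default 1).
#' @param noise_sd SD of independent per-column log2 noise (default 0.23,
#'   giving within-block correlation of about 0.95).
#' @param seed integer RNG seed.
#' @return a positive fold-change matrix, rows = proteins, columns =
#'   treatments.
#' @export
simulate_proteins <- function(n_proteins = 30L,
                              blocks = list(
                                coated = c("AM", "SA", "SO"),
                                uncoated = c("UC-1", "UC-2", "UC-3"),
                                reference = c("ZnO", "ZnCl2")),
                              responders = NULL,
                              responder_block = names(blocks)[1L],
                              profile_sd = 1, noise_sd = 0.23, seed = 1L) {
  proteins <- sprintf("P%02d", seq_len(n_proteins))
  if (!is.null(responders)) {
    bad <- setdiff(names(responders), proteins)
    if (length(bad)) {
      stop("unknown responder protein(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (any(responders <= 0)) {
      stop("responder fold changes must be > 0", call. = FALSE)
    }
  }
  .with_seed(seed, {
    treatments <- unlist(blocks, use.names = FALSE)
    lmat <- matrix(0, n_proteins, length(treatments),
                   dimnames = list(proteins, treatments))
    for (b in names(blocks)) {
      latent <- rnorm(n_proteins, 0, profile_sd)
      for (tr in blocks[[b]]) {
        lmat[, tr] <- latent + rnorm(n_proteins, 0, noise_sd)
      }
    }
    if (!is.null(responders)) {
      for (pr in names(responders)) {
        lmat[pr, blocks[[responder_block]]] <-
          lmat[pr, blocks[[responder_block]]] + log2(responders[[pr]])
      }
    }
    2^lmat
  })
}
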