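#' GSH/GSSG oxidative-stress fold change
#'
#' The reduced-to-oxidized glutathione ratio of a treated group divided by
#' that of the control group. A fold change below 1 indicates oxidation of
#' the cellular glutathione pool, i.e. oxidative stress.
#'
#' @param treated_gsh,treated_gssg,control_gsh,control_gssg positive
#'   signals (vectorized).
#' @return fold change `(treated_gsh/treated_gssg) /
#'   (control_gsh/control_gssg)`.
#' @export
#' @examples
#' gsh_gssg_fc(80, 40, 100, 25)  # 0.5
gsh_gssg_fc <- function(treated_gsh, treated_gssg, control_gsh,
                        control_gssg) {
  vals <- list(treated_gsh, treated_gssg, control_gsh, control_gssg)
  if (!all(vapply(vals, is.numeric, logical(1L))) ||
      any(vapply(vals, function(v) any(!is.finite(v) | v <= 0),
                 logical(1L)))) {
    stop("all glutathione signals must be finite and > 0", call. = FALSE)
  }
  (treated_gsh / treated_gssg) / (control_gsh / control_gssg)
}

#' Oxidative-stress analysis of a GSH/GSSG table
#'
#' Computes per-replicate GSH/GSSG ratios, expresses each treatment as a
#' fold change against the mean control ratio, and tests for a treatment
#' effect on the ratios with a one-way ANOVA followed by Holm-Sidak
#' adjusted treatment-versus-control comparisons.
#'
#' @param stress a `data.frame` with columns `treatment`, `replicate`,
#'   `gsh`, `gssg`; positive signals.
#' @param control label of the control treatment (default `"control"`).
#' @return a list with `summary` (treatment-level mean ratio and
#'   `ratio_fc`), `anova` (an `"anova_result"`), `comparisons` (adjusted
#'   contrasts) and `ratios` (per-replicate table).
#' @export
stress_analysis <- function(stress, control = "control") {
  needed <- c("treatment", "gsh", "gssg")
  if (!all(needed %in% names(stress))) {
    stop("stress table needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (!control %in% stress$treatment) {
    stop("control treatment '", control, "' not found", call. = FALSE)
  }
  if (any(stress$gsh <= 0) || any(stress$gssg <= 0)) {
    stop("glutathione signals must be > 0", call. = FALSE)
  }
  stress$ratio <- stress$gsh / stress$gssg
  ctrl_mean <- mean(stress$ratio[stress$treatment == control])
  stress$ratio_fc <- stress$ratio / ctrl_mean

  summ <- stats::aggregate(cbind(ratio, ratio_fc) ~ treatment, data = stress,
                           FUN = mean)
  av <- one_way_anova(split(stress$ratio, stress$treatment))
  cmp <- adjusted_comparisons(stress$ratio, stress$treatment,
                              control = control)
  list(summary = summ, anova = av, comparisons = cmp, ratios = stress)
}
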