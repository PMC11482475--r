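#' Read a raw plate-assay table
#'
#' Reads a long-format CSV of per-well signals. Required columns:
#' `experiment_id`, `cell_type`, `particle`, `dose` (ug/cm2, >= 0),
#' `endpoint`, `role` (one of `cells`, `no_cells`, `lysed_control`),
#' `replicate`, `signal`.
#'
#' @param path path to a UTF-8 CSV file with a header row.
#' @return a validated `data.frame` of raw well signals.
#' @seealso [compute_fold_effect()]
#' @export
read_assay_table <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  validate_assay_table(raw)
  raw
}

#' Validate a raw plate-assay table
#'
#' Checks the column contract and the structural invariants every
#' downstream step relies on: finite nonnegative doses, finite signals,
#' known well roles, and at least one zero-dose `cells` well per
#' experiment/cell type/endpoint stratum.
#'
#' @param raw a data.frame as returned by [read_assay_table()].
#' @return `raw`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_assay_table <- function(raw) {
  required <- c("experiment_id", "cell_type", "particle", "dose",
                "endpoint", "role", "replicate", "signal")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("assay table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(raw$dose) || any(!is.finite(raw$dose)) || any(raw$dose < 0)) {
    stop("dose must be finite and >= 0", call. = FALSE)
  }
  if (!is.numeric(raw$signal) || any(!is.finite(raw$signal))) {
    stop("signal must be finite numeric", call. = FALSE)
  }
  bad_role <- setdiff(unique(raw$role), c("cells", "no_cells", "lysed_control"))
  if (length(bad_role)) {
    stop("unknown well role(s): ", paste(bad_role, collapse = ", "),
         call. = FALSE)
  }
  cells <- raw[raw$role == "cells", ]
  strata <- unique(cells[, c("experiment_id", "cell_type", "endpoint")])
  ctrl <- unique(cells[cells$dose == 0,
                       c("experiment_id", "cell_type", "endpoint")])
  have <- .group_label(ctrl, names(ctrl))
  need <- .group_label(strata, names(strata))
  lacking <- setdiff(need, have)
  if (length(lacking)) {
    stop("no zero-dose control wells for group(s): ",
         paste(lacking, collapse = "; "), call. = FALSE)
  }
  invisible(raw)
}

#' Blank-correct cell-well signals with matched no-cells wells
#'
#' No-cells wells contain the particle suspension only and capture
#' particle-related interference (e.g. optical) with the readout. The
#' corrected signal is `cells_signal - no_cells_signal`, floored at zero;
#' flooring triggers a warning because it signals interference larger than
#' the biological signal.
#'
#' @param cells_signal numeric vector of signals from wells with cells.
#' @param no_cells_signal numeric vector (recycled if length 1) of matched
#'   blank signals from the same endpoint/dose/particle/experiment.
#' @return corrected signal vector, `>= 0`.
#' @export
#' @examples
#' blank_correct(120, 20)   # 100
blank_correct <- function(cells_signal, no_cells_signal) {
  if (!is.numeric(cells_signal) || !is.numeric(no_cells_signal)) {
    stop("signals must be numeric", call. = FALSE)
  }
  if (length(no_cells_signal) == 1L) {
    no_cells_signal <- rep(no_cells_signal, length(cells_signal))
  }
  if (length(cells_signal) != length(no_cells_signal)) {
    stop("cells and no-cells signals must have matching length (keying error)",
         call. = FALSE)
  }
  corrected <- cells_signal - no_cells_signal
  n_floor <- sum(corrected < 0)
  if (n_floor > 0) {
    warning(sprintf("blank correction floored %d signal(s) at 0", n_floor),
            call. = FALSE)
    corrected[corrected < 0] <- 0
  }
  corrected
}

#' Compute fold effects from raw plate signals
#'
#' Each `cells` well is (optionally) blank-corrected against the mean of
#' matching `no_cells` wells, then normalized within its experiment to the
#' grand mean of all zero-dose control wells of the same cell type and
#' endpoint. The zero-dose rows are retained, so their mean fold effect is
#' exactly 1 within each normalization stratum.
#'
#' Fold effects that end up `<= 0` (possible after aggressive blank
#' correction) are clipped to `1e-6` with a warning so that downstream
#' log-domain fitting is defined.
#'
#' @param raw a raw assay table (see [read_assay_table()]).
#' @param blank logical; subtract matched no-cells blanks when present
#'   (default `TRUE`). When no matching blank exists the signal passes
#'   through unchanged and a notice is emitted once.
#' @return a `data.frame` with columns `experiment_id`, `cell_type`,
#'   `particle`, `dose`, `endpoint`, `replicate`, `fe`.
#' @export
#' @examples
#' raw <- data.frame(
#'   experiment_id = "E1", cell_type = "A549", particle = "NP",
#'   dose = c(0, 0, 10), endpoint = "ATP", role = "cells",
#'   replicate = c(1, 2, 1), signal = c(100, 100, 50))
#' compute_fold_effect(raw)$fe  # 1, 1, 0.5
compute_fold_effect <- function(raw, blank = TRUE) {
  validate_assay_table(raw)
  cells <- raw[raw$role == "cells", , drop = FALSE]
  corrected <- cells$signal

  if (blank) {
    blanks <- raw[raw$role == "no_cells", , drop = FALSE]
    if (nrow(blanks)) {
      keys <- c("experiment_id", "cell_type", "particle", "dose", "endpoint")
      bkey <- .group_label(blanks, keys)
      bmean <- tapply(blanks$signal, bkey, mean)
      ckey <- .group_label(cells, keys)
      matched <- ckey %in% names(bmean)
      if (any(!matched)) {
        message(sprintf(
          "no matching no-cells blank for %d well(s); signals passed through",
          sum(!matched)))
      }
      if (any(matched)) {
        corrected[matched] <- blank_correct(
          cells$signal[matched], as.numeric(bmean[ckey[matched]]))
      }
    } else {
      message("no no-cells wells supplied; blank correction skipped")
    }
  }

  strata <- c("experiment_id", "cell_type", "endpoint")
  skey <- .group_label(cells, strata)
  is_ctrl <- cells$dose == 0
  gm <- tapply(corrected[is_ctrl], skey[is_ctrl], mean)
  bad <- names(gm)[gm <= 0]
  if (length(bad)) {
    stop("zero-dose control grand mean <= 0 in group(s): ",
         paste(bad, collapse = "; "), call. = FALSE)
  }
  fe <- corrected / as.numeric(gm[skey])

  clipped <- fe <= 0
  if (any(clipped)) {
    warning(sprintf("clipped %d nonpositive fold effect(s) to 1e-6",
                    sum(clipped)), call. = FALSE)
    fe[clipped] <- 1e-6
  }

  out <- cells[, c("experiment_id", "cell_type", "particle", "dose",
                   "endpoint", "replicate")]
  out$fe <- fe
  rownames(out) <- NULL
  out
}

#' Percent LDH released
#'
#' Expresses LDH released into the supernatant as a percentage of the total
#' LDH content measured in lysed untreated control wells.
#'
#' @param released numeric vector of supernatant LDH signals.
#' @param lysed_totals nonempty numeric vector of total-LDH signals from
#'   lysed control wells; their mean must be positive.
#' @return `100 * released / mean(lysed_totals)`.
#' @export
#' @examples
#' pct_ldh(50, c(200, 200))  # 25
pct_ldh <- function(released, lysed_totals) {
  if (length(lysed_totals) == 0L || !is.numeric(lysed_totals) ||
      mean(lysed_totals) <= 0) {
    stop("lysed-control totals must be nonempty with positive mean",
         call. = FALSE)
  }
  100 * released / mean(lysed_totals)
}

#' Percent LDH released for every LDH well of an assay table
#'
#' Applies [pct_ldh()] to all `cells` wells of the LDH endpoint, using the
#' `lysed_control` wells of the same experiment and cell type as the total.
#'
#' @param raw a raw assay table containing LDH `cells` wells and matching
#'   `lysed_control` wells.
#' @return a `data.frame` of LDH wells with an added `pct_ldh` column.
#' @export
compute_pct_ldh <- function(raw) {
  validate_assay_table(raw)
  ldh <- raw[raw$endpoint == "LDH" & raw$role == "cells", , drop = FALSE]
  lysed <- raw[raw$endpoint == "LDH" & raw$role == "lysed_control", ,
               drop = FALSE]
  if (!nrow(lysed)) {
    stop("no lysed_control wells available for %LDH calculation",
         call. = FALSE)
  }
  keys <- c("experiment_id", "cell_type")
  lmean <- tapply(lysed$signal, .group_label(lysed, keys), mean)
  lkey <- .group_label(ldh, keys)
  if (any(!(lkey %in% names(lmean)))) {
    stop("missing lysed_control wells for group(s): ",
         paste(setdiff(unique(lkey), names(lmean)), collapse = "; "),
         call. = FALSE)
  }
  totals <- as.numeric(lmean[lkey])
  if (any(totals <= 0)) {
    stop("lysed-control mean <= 0; cannot form %LDH", call. = FALSE)
  }
  ldh$pct_ldh <- 100 * ldh$signal / totals
  rownames(ldh) <- NULL
  ldh
}
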