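#' Validate pipeline input files
#'
#' Schema-checks every supplied CSV (required columns, numeric types,
#' nonnegative doses, finite signals, presence of zero-dose controls) and
#' returns a machine-readable list of violations rather than stopping at
#' the first problem.
#'
#' @param paths named character vector or list; recognized names are
#'   `assay`, `descriptors`, `stress`, `proteins`.
#' @return a `data.frame` with columns `file`, `rule`, `detail` (0 rows
#'   when everything is well-formed).
#' @export
validate_inputs <- function(paths) {
  paths <- as.list(paths)
  viol <- list()
  note <- function(file, rule, detail) {
    viol[[length(viol) + 1L]] <<- data.frame(
      file = file, rule = rule, detail = detail, stringsAsFactors = FALSE)
  }

  read_or_note <- function(path, label) {
    if (!file.exists(path)) {
      note(label, "io", paste("file not found:", path))
      return(NULL)
    }
    tryCatch(read.csv(path, stringsAsFactors = FALSE),
             error = function(e) {
               note(label, "io", conditionMessage(e))
               NULL
             })
  }

  if (!is.null(paths$assay)) {
    raw <- read_or_note(paths$assay, "assay")
    if (!is.null(raw)) {
      required <- c("experiment_id", "cell_type", "particle", "dose",
                    "endpoint", "role", "replicate", "signal")
      missing <- setdiff(required, names(raw))
      if (length(missing)) {
        note("assay", "columns",
             paste("missing columns:", paste(missing, collapse = ", ")))
      } else {
        if (!is.numeric(raw$dose)) {
          note("assay", "types", "dose is not numeric")
        } else {
          bad <- which(!is.finite(raw$dose) | raw$dose < 0)
          if (length(bad)) {
            note("assay", "dose",
                 paste("negative or non-finite dose at row(s):",
                       paste(utils::head(bad, 10L), collapse = ", ")))
          }
        }
        if (!is.numeric(raw$signal) || any(!is.finite(raw$signal))) {
          note("assay", "signal", "signals must be finite numeric")
        }
        bad_role <- setdiff(unique(raw$role),
                            c("cells", "no_cells", "lysed_control"))
        if (length(bad_role)) {
          note("assay", "role",
               paste("unknown role(s):", paste(bad_role, collapse = ", ")))
        }
        if (is.numeric(raw$dose)) {
          cells <- raw[raw$role == "cells", ]
          strata <- unique(cells[, c("experiment_id", "cell_type",
                                     "endpoint")])
          ctrl <- unique(cells[cells$dose == 0,
                               c("experiment_id", "cell_type", "endpoint")])
          lacking <- setdiff(.group_label(strata, names(strata)),
                             .group_label(ctrl, names(ctrl)))
          for (grp in lacking) {
            note("assay", "controls",
                 paste("no zero-dose cells wells for", grp))
          }
        }
      }
    }
  }

  if (!is.null(paths$descriptors)) {
    d <- read_or_note(paths$descriptors, "descriptors")
    if (!is.null(d) && !"particle" %in% names(d)) {
      note("descriptors", "columns", "missing particle column")
    }
  }

  if (!is.null(paths$stress)) {
    s <- read_or_note(paths$stress, "stress")
    if (!is.null(s)) {
      missing <- setdiff(c("treatment", "gsh", "gssg"), names(s))
      if (length(missing)) {
        note("stress", "columns",
             paste("missing columns:", paste(missing, collapse = ", ")))
      } else if (any(s$gsh <= 0) || any(s$gssg <= 0)) {
        note("stress", "signal", "nonpositive glutathione signal")
      }
    }
  }

  if (!is.null(paths$proteins)) {
    p <- read_or_note(paths$proteins, "proteins")
    if (!is.null(p)) {
      num <- p[, vapply(p, is.numeric, logical(1L)), drop = FALSE]
      if (!ncol(num)) {
        note("proteins", "columns", "no numeric fold-change columns")
      } else if (any(!is.finite(as.matrix(num))) ||
                 any(as.matrix(num) <= 0)) {
        note("proteins", "values", "fold changes must be finite and > 0")
      }
    }
  }

  if (length(viol)) {
    do.call(rbind, viol)
  } else {
    data.frame(file = character(0), rule = character(0),
               detail = character(0), stringsAsFactors = FALSE)
  }
}

#' Run the full potency-analysis pipeline
#'
#' Sequences normalization, potency estimation, consensus ranking and the
#' optional descriptor-association, oxidative-stress and secretome stages,
#' writing a deterministic bundle of CSV/JSON reports. Numbers are
#' serialized at full precision; display rounding is left to report
#' consumers.
#'
#' @param config a list with elements:
#'   \describe{
#'     \item{`assay`}{path to a raw assay CSV (required).}
#'     \item{`descriptors`}{optional path to a particle descriptor CSV.}
#'     \item{`stress`}{optional path to a GSH/GSSG CSV.}
#'     \item{`proteins`}{optional path to a protein fold-change CSV (first
#'       column = protein labels).}
#'     \item{`out_dir`}{output directory (created if absent).}
#'     \item{`fit_method`}{`"nls"` (default) or `"loglinear"`.}
#'     \item{`alpha_remove`}{stepwise removal threshold (default 0.10).}
#'     \item{`fc_cutoff`}{responder fold-change cutoff (default 1.5).}
#'     \item{`control`}{stress control treatment label (default
#'       `"control"`).}
#'     \item{`seed`}{integer recorded in the run log (default 1).}
#'   }
#' @return invisibly, a named list of written file paths.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$assay) || is.null(config$out_dir)) {
    stop("config needs at least 'assay' and 'out_dir'", call. = FALSE)
  }
  viol <- validate_inputs(config[intersect(
    names(config), c("assay", "descriptors", "stress", "proteins"))])
  if (nrow(viol)) {
    stop("input validation failed:\n",
         paste(sprintf("  [%s/%s] %s", viol$file, viol$rule, viol$detail),
               collapse = "\n"), call. = FALSE)
  }
  fit_method <- if (is.null(config$fit_method)) "nls" else config$fit_method
  alpha_remove <- if (is.null(config$alpha_remove)) 0.10 else
    config$alpha_remove
  fc_cutoff <- if (is.null(config$fc_cutoff)) 1.5 else config$fc_cutoff
  control <- if (is.null(config$control)) "control" else config$control
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)
  emit_csv <- function(obj, name) {
    path <- file.path(config$out_dir, name)
    write.csv(obj, path, row.names = FALSE)
    written <<- c(written, path)
    path
  }

  out <- list()

  # stage 1: normalization
  raw <- read_assay_table(config$assay)
  fe <- compute_fold_effect(raw)
  out$fold_effects <- emit_csv(fe, "fold_effects.csv")

  # stage 2: potency and consensus ranking
  potency <- fit_potency(fe, method = fit_method)
  consensus <- consensus_potency(potency)
  out$potency <- emit_csv(potency, "potency.csv")
  report <- potency_report(potency, consensus)
  out$potency_report <- emit_csv(report, "potency_report.csv")

  # stage 3: descriptor association
  if (!is.null(config$descriptors)) {
    desc <- read.csv(config$descriptors, stringsAsFactors = FALSE)
    assoc <- pairwise_associations(desc, potency)
    out$associations <- emit_csv(assoc, "associations.csv")
    num_cols <- setdiff(names(desc)[vapply(desc, is.numeric, logical(1L))],
                        "particle")
    step_res <- list()
    combos <- unique(potency[, c("cell_type", "endpoint")])
    for (i in seq_len(nrow(combos))) {
      sub <- potency[potency$cell_type == combos$cell_type[i] &
                       potency$endpoint == combos$endpoint[i], ]
      X <- desc[match(sub$particle, desc$particle), num_cols, drop = FALSE]
      fit <- tryCatch(
        backward_stepwise(X, sub$beta_signed, alpha_remove = alpha_remove),
        error = function(e) conditionMessage(e))
      key <- paste(combos$cell_type[i], combos$endpoint[i], sep = ".")
      step_res[[key]] <- if (is.character(fit)) {
        list(skipped = fit)
      } else {
        list(retained = fit$retained,
             coefficients = as.list(fit$coefficients),
             p_values = as.list(fit$p_values), n = fit$n)
      }
    }
    path <- file.path(config$out_dir, "stepwise.json")
    jsonlite::write_json(step_res, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <- c(written, path)
    out$stepwise <- path
  }

  # stage 4: oxidative stress
  if (!is.null(config$stress)) {
    stress <- read.csv(config$stress, stringsAsFactors = FALSE)
    sa <- stress_analysis(stress, control = control)
    out$stress_summary <- emit_csv(sa$summary, "stress_summary.csv")
    out$stress_comparisons <- emit_csv(sa$comparisons,
                                       "stress_comparisons.csv")
  }

  # stage 5: secretome
  if (!is.null(config$proteins)) {
    ptab <- read.csv(config$proteins, stringsAsFactors = FALSE,
                     check.names = FALSE)
    mat <- as.matrix(ptab[, -1L, drop = FALSE])
    rownames(mat) <- ptab[[1L]]
    resp <- filter_responders(mat, cutoff = fc_cutoff)
    out$responders <- emit_csv(
      data.frame(protein = rownames(resp), resp, check.names = FALSE),
      "responders.csv")
    if (nrow(resp) >= 2L && ncol(resp) >= 2L) {
      cl <- hierarchical_cluster(resp)
      out$cluster_rows <- emit_csv(merge_table(cl$row_hclust),
                                   "cluster_rows.csv")
      out$cluster_cols <- emit_csv(merge_table(cl$col_hclust),
                                   "cluster_cols.csv")
    }
  }

  # run log
  log <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("nanopotency")),
    config = config[setdiff(names(config), "out_dir")],
    outputs = lapply(out, basename))
  log_path <- file.path(config$out_dir, "run_log.json")
  jsonlite::write_json(log, log_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  written <- c(written, log_path)
  out$run_log <- log_path

  ok <- TRUE
  invisible(out)
}

#' Wide potency report
#'
#' Lays the long potency table out one row per particle and cell type with
#' per-endpoint absolute exponents, the consensus average and the rank -
#' the layout of a published potency-ranking table.
#'
#' @param potency long potency `data.frame` (see [fit_potency()]).
#' @param consensus consensus `data.frame` (see [consensus_potency()]);
#'   computed from `potency` when omitted.
#' @return a wide `data.frame` with columns `particle`, `cell_type`,
#'   `beta_ATP`, `beta_LDH`, `beta_CTB`, `beta_avg`, `rank`.
#' @export
potency_report <- function(potency, consensus = NULL) {
  if (is.null(consensus)) consensus <- consensus_potency(potency)
  b <- if ("beta_abs" %in% names(potency)) {
    potency$beta_abs
  } else {
    abs(potency$beta_signed)
  }
  wide <- stats::reshape(
    data.frame(particle = potency$particle, cell_type = potency$cell_type,
               endpoint = potency$endpoint, beta = b,
               stringsAsFactors = FALSE),
    idvar = c("particle", "cell_type"), timevar = "endpoint",
    direction = "wide")
  names(wide) <- sub("^beta\\.", "beta_", names(wide))
  out <- merge(wide, consensus, by = c("particle", "cell_type"),
               sort = FALSE)
  out <- out[order(out$cell_type, out$rank), ]
  rownames(out) <- NULL
  out
}
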