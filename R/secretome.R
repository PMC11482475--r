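#' Per-protein fold change of treated versus control signals
#'
#' @param treated,control named numeric vectors of per-protein signals; the
#'   protein sets must match and control values must be positive.
#' @return named numeric vector of fold changes `treated / control`.
#' @export
#' @examples
#' protein_fold_change(c(IL6 = 25), c(IL6 = 10))  # 2.5
protein_fold_change <- function(treated, control) {
  if (is.null(names(treated)) || is.null(names(control))) {
    stop("treated and control must be named by protein", call. = FALSE)
  }
  missing_t <- setdiff(names(control), names(treated))
  missing_c <- setdiff(names(treated), names(control))
  if (length(missing_t) || length(missing_c)) {
    stop("protein sets do not match; missing: ",
         paste(c(missing_t, missing_c), collapse = ", "), call. = FALSE)
  }
  control <- control[names(treated)]
  if (any(control <= 0)) {
    stop("control signals must be > 0", call. = FALSE)
  }
  treated / control
}

#' Filter a secretome matrix to responder proteins
#'
#' Keeps proteins whose fold change in at least one treatment is at or
#' beyond the cutoff in either direction on the ratio scale:
#' `FC >= cutoff` or `FC <= 1/cutoff` (boundaries inclusive).
#'
#' @param mat numeric matrix of positive fold changes, rows = proteins,
#'   columns = treatments.
#' @param cutoff fold-change threshold `> 1` (default 1.5).
#' @return the responder submatrix (possibly 0 rows), rows in input order.
#' @export
#' @examples
#' m <- rbind(up = c(a = 1.5), flat = c(a = 1.2), down = c(a = 0.6))
#' rownames(filter_responders(m, 1.5))  # "up", "down"
filter_responders <- function(mat, cutoff = 1.5) {
  mat <- as.matrix(mat)
  if (!is.numeric(mat) || any(!is.finite(mat)) || any(mat <= 0)) {
    stop("fold-change matrix must be finite and positive", call. = FALSE)
  }
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 1) {
    stop("cutoff must be a single value > 1", call. = FALSE)
  }
  hit <- apply(mat, 1L, function(v) any(v >= cutoff | v <= 1 / cutoff))
  mat[hit, , drop = FALSE]
}

#' Hierarchical clustering of a secretome fold-change matrix
#'
#' Log2-transforms the fold-change matrix, then agglomeratively clusters
#' rows (proteins) and columns (treatments). The default distance is the
#' Pearson correlation distance `1 - r` with average linkage; Euclidean
#' distance and complete linkage are available. Output is deterministic
#' given the input ordering.
#'
#' @param mat numeric matrix of positive fold changes with at least 2 rows
#'   and 2 columns; row and column names required.
#' @param distance `"pearson"` or `"euclidean"`.
#' @param linkage `"average"` or `"complete"`.
#' @return a list of class `"secretome_clustering"` with `row_hclust`,
#'   `col_hclust` (objects of class [stats::hclust]), `row_order`,
#'   `col_order` (leaf label orders) and `log2_matrix`.
#' @export
hierarchical_cluster <- function(mat, distance = c("pearson", "euclidean"),
                                 linkage = c("average", "complete")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L || ncol(mat) < 2L) {
    stop("need at least 2 rows and 2 columns", call. = FALSE)
  }
  if (any(!is.finite(mat)) || any(mat <= 0)) {
    stop("fold-change matrix must be finite and positive", call. = FALSE)
  }
  lm2 <- log2(mat)

  dist_of <- function(m, what) {
    if (distance == "pearson") {
      const <- apply(m, 1L, sd) == 0
      if (any(const)) {
        stop("constant ", what, "(s) under pearson distance: ",
             paste(rownames(m)[const], collapse = ", "), call. = FALSE)
      }
      as.dist(1 - cor(t(m)))
    } else {
      stats::dist(m)
    }
  }

  row_hc <- hclust(dist_of(lm2, "row"), method = linkage)
  col_hc <- hclust(dist_of(t(lm2), "column"), method = linkage)
  structure(
    list(row_hclust = row_hc, col_hclust = col_hc,
         row_order = rownames(mat)[row_hc$order],
         col_order = colnames(mat)[col_hc$order],
         log2_matrix = lm2, distance = distance, linkage = linkage),
    class = "secretome_clustering")
}

#' @export
print.secretome_clustering <- function(x, ...) {
  cat(sprintf("Secretome clustering (%s distance, %s linkage)\n",
              x$distance, x$linkage))
  cat("column order:", paste(x$col_order, collapse = ", "), "\n")
  invisible(x)
}

#' Merge table of an agglomeration sequence
#'
#' Flattens an [stats::hclust] tree into a step/members/height table, the
#' standard text representation of an agglomeration sequence.
#'
#' @param hc an `hclust` object (e.g. `row_hclust` from
#'   [hierarchical_cluster()]).
#' @return a `data.frame` with columns `step`, `members` (labels joined
#'   with `"+"`) and `height`.
#' @export
merge_table <- function(hc) {
  labs <- hc$labels
  members <- vector("list", nrow(hc$merge))
  get_members <- function(i) {
    if (i < 0) labs[-i] else members[[i]]
  }
  out <- data.frame(step = seq_len(nrow(hc$merge)), members = "",
                    height = hc$height, stringsAsFactors = FALSE)
  for (s in seq_len(nrow(hc$merge))) {
    members[[s]] <- c(get_members(hc$merge[s, 1L]),
                      get_members(hc$merge[s, 2L]))
    out$members[s] <- paste(sort(members[[s]]), collapse = "+")
  }
  out
}
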