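#' Mutual information between a numeric feature and a class label
#'
#' Plug-in mutual information on an equal-frequency binning of the feature,
#' gated by a G-test of independence: when the observed association is not
#' statistically distinguishable from independence (p > `alpha`) the
#' estimate is returned as exactly 0, otherwise the bias-corrected value
#' `(G - df) / (2n)` in nats. The gate is what makes "zero mutual
#' information" an operational rule: a raw plug-in (or nearest-neighbour)
#' estimate is positive for about half of all truly independent features, so
#' thresholding it near zero cannot identify them.
#'
#' Deterministic; `seed` is accepted for interface stability but unused.
#'
#' @param x Numeric feature vector.
#' @param y Class label vector (two or more classes).
#' @param bins Maximum number of equal-frequency bins; default 8.
#' @param alpha Significance level of the independence gate; default 0.01.
#' @param seed Ignored (the estimator has no randomness).
#' @return Non-negative mutual information estimate in nats.
#' @export
mutual_info <- function(x, y, bins = 8, alpha = 0.01, seed = NULL) {
  stopifnot(length(x) == length(y))
  y <- factor(y)
  if (nlevels(y) < 2) stop("labels must contain at least two classes", call. = FALSE)
  ux <- unique(x)
  if (length(ux) <= 1) return(0)
  if (length(ux) <= bins) {
    b <- factor(x)
  } else {
    br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                                 names = FALSE, type = 7))
    if (length(br) < 3) return(0)
    b <- cut(x, br, include.lowest = TRUE)
  }
  tab <- table(b, y)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) return(0)
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  gcells <- tab * log(tab / expected)
  g <- 2 * sum(gcells[tab > 0])
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  p <- stats::pchisq(g, df, lower.tail = FALSE)
  if (p > alpha) return(0)
  max(0, (g - df) / (2 * n))
}

selection_entry <- function(stage, descriptor, reason, value, kept_partner = NA_character_) {
  n <- length(descriptor)
  data.frame(stage = rep_len(stage, n), descriptor = descriptor,
             reason = rep_len(reason, n), value = rep_len(value, n),
             kept_partner = rep_len(kept_partner, n),
             stringsAsFactors = FALSE)
}

empty_selection_entries <- function() {
  selection_entry(character(), character(), character(), numeric(), character())
}

#' Drop zero-variance descriptors
#'
#' Stage one of the three-step descriptor pruning: columns whose variance is
#' not greater than `eps` (default exactly zero) carry no information for
#' classification and are removed.
#'
#' @param matrix Descriptor matrix.
#' @param eps Variance threshold; default 0.
#' @return List with `matrix` (surviving columns) and `report` (dropped
#'   descriptors with their variances).
#' @export
drop_zero_variance <- function(matrix, eps = 0) {
  m <- as.matrix(matrix)
  if (!ncol(m) || !nrow(m)) stop("matrix must be non-empty", call. = FALSE)
  v <- apply(m, 2, stats::var)
  drop <- v <= eps
  if (all(drop)) stop("all descriptors are constant", call. = FALSE)
  report <- selection_entry("variance", colnames(m)[drop], "variance <= eps", v[drop])
  list(matrix = set_provenance(m[, !drop, drop = FALSE], "selected"),
       report = report)
}

#' Drop descriptors with zero mutual information with the label
#'
#' Stage two: descriptors whose estimated mutual information with the class
#' label is at most `mi_epsilon` are independent of the label and removed.
#' See [mutual_info()] for the estimator.
#'
#' The independence gate controls the family-wise error across the panel:
#' the per-descriptor significance level is `alpha / ncol(matrix)`
#' (Bonferroni), so a truly independent descriptor survives the whole stage
#' with probability at most `alpha` regardless of panel width.
#'
#' @param matrix Descriptor matrix.
#' @param labels Class label vector aligned with the rows.
#' @param seed Accepted for interface stability; the estimator is
#'   deterministic.
#' @param mi_epsilon Threshold on the MI estimate; default 1e-6.
#' @param alpha Family-wise significance level of the independence gate;
#'   default 0.01.
#' @return List with `matrix` and `report`.
#' @export
drop_zero_mutual_info <- function(matrix, labels, seed = 1, mi_epsilon = 1e-6,
                                  alpha = 0.01) {
  m <- as.matrix(matrix)
  if (length(labels) != nrow(m)) stop("labels must align with matrix rows", call. = FALSE)
  if (length(unique(labels)) < 2) stop("labels must contain both classes", call. = FALSE)
  mi <- apply(m, 2, mutual_info, y = labels, seed = seed,
              alpha = alpha / ncol(m))
  drop <- mi <= mi_epsilon
  report <- selection_entry("mutual_info", colnames(m)[drop],
                            "MI <= mi_epsilon", mi[drop])
  list(matrix = set_provenance(m[, !drop, drop = FALSE], "selected"),
       report = report)
}

#' Prune highly correlated descriptor pairs
#'
#' Stage three: if the absolute Pearson correlation between any pair of
#' surviving descriptors is strictly greater than `threshold` (default 0.8),
#' only one of them is retained. Columns are visited in input order and the
#' first member of each above-threshold pair is kept, so the policy is
#' deterministic and the report records, for every dropped descriptor, the
#' retained partner and the correlation.
#'
#' @param matrix Descriptor matrix with at least 2 rows.
#' @param threshold Correlation threshold; strict inequality. Default 0.8.
#' @return List with `matrix` and `report`.
#' @export
prune_correlated <- function(matrix, threshold = 0.8) {
  m <- as.matrix(matrix)
  if (nrow(m) < 2) stop("need at least 2 rows to estimate correlations", call. = FALSE)
  p <- ncol(m)
  report <- empty_selection_entries()
  if (p < 2) return(list(matrix = set_provenance(m, "selected"), report = report))
  r <- suppressWarnings(abs(stats::cor(m)))
  r[!is.finite(r)] <- 0
  kept <- logical(p)
  for (j in seq_len(p)) {
    partners <- which(kept & r[j, seq_len(p)] > threshold)
    if (length(partners)) {
      k <- partners[1]
      report <- rbind(report, selection_entry(
        "correlation", colnames(m)[j], "|r| > threshold with kept partner",
        unname(r[j, k]), colnames(m)[k]))
    } else {
      kept[j] <- TRUE
    }
  }
  list(matrix = set_provenance(m[, kept, drop = FALSE], "selected"),
       report = report)
}

#' Three-stage descriptor selection
#'
#' Composes the three pruning stages in their fixed order — zero variance,
#' zero mutual information, correlation — and returns the reduced matrix with
#' a full audit trail. Applying the selector to its own output drops nothing.
#'
#' @param matrix Descriptor matrix.
#' @param labels Class labels aligned with the rows.
#' @param seed Passed to the MI stage (deterministic either way).
#' @param variance_eps,mi_epsilon,cor_threshold Stage thresholds.
#' @return List with `matrix` (provenance `"selected"`) and `report`, a
#'   `selection_report`: data frame `stage, descriptor, reason, value,
#'   kept_partner` with the final `kept` name list as an attribute.
#' @export
select_features <- function(matrix, labels, seed = 1, variance_eps = 0,
                            mi_epsilon = 1e-6, cor_threshold = 0.8) {
  s1 <- drop_zero_variance(matrix, eps = variance_eps)
  s2 <- drop_zero_mutual_info(s1$matrix, labels, seed = seed,
                              mi_epsilon = mi_epsilon)
  s3 <- prune_correlated(s2$matrix, threshold = cor_threshold)
  report <- rbind(s1$report, s2$report, s3$report)
  rownames(report) <- NULL
  attr(report, "kept") <- colnames(s3$matrix)
  attr(report, "input_names") <- colnames(as.matrix(matrix))
  class(report) <- c("selection_report", class(report))
  list(matrix = s3$matrix, report = report)
}

#' Apply a stored selection report to a new matrix
#'
#' Restricts `matrix` to the surviving descriptor panel recorded in a
#' [select_features()] report, in the recorded order.
#'
#' @param report A `selection_report` (or its CSV as read back).
#' @param matrix Descriptor matrix containing at least the kept descriptors.
#' @return The reduced `descriptor_matrix`.
#' @export
apply_selection <- function(report, matrix) {
  kept <- attr(report, "kept")
  if (is.null(kept)) stop("report carries no kept descriptor list", call. = FALSE)
  m <- as.matrix(matrix)
  missing <- setdiff(kept, colnames(m))
  if (length(missing)) {
    stop("matrix lacks selected descriptor(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  set_provenance(m[, kept, drop = FALSE], "selected")
}

#' Write / read a selection report as CSV
#'
#' The CSV schema is `stage, descriptor, reason, value, kept_partner`; kept
#' descriptors are stored as extra rows with stage `"kept"` so the surviving
#' panel (and its order) can be reconstructed exactly.
#'
#' @param report A `selection_report`.
#' @param path CSV path.
#' @return `path` invisibly for the writer; a `selection_report` for the
#'   reader.
#' @export
write_selection_report <- function(report, path) {
  kept <- attr(report, "kept")
  kept_rows <- selection_entry("kept", kept, "retained", NA_real_)
  utils::write.csv(rbind(as.data.frame(report), kept_rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_selection_report
#' @export
read_selection_report <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  kept <- df$descriptor[df$stage == "kept"]
  report <- df[df$stage != "kept", , drop = FALSE]
  rownames(report) <- NULL
  attr(report, "kept") <- kept
  class(report) <- c("selection_report", class(report))
  report
}
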