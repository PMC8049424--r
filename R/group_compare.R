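# Two-group differential abundance: fold change with rank-sum (or Welch)
# p-values and Benjamini-Hochberg correction.

#' Compare joint-feature abundances between two groups
#'
#' For each feature, computes group means, a log2 fold change stabilized by a
#' pseudocount, a two-sided p-value from the chosen test, and
#' Benjamini-Hochberg q-values over all features. Groups are taken in sorted
#' label order (A = first, B = second); the fold change is B over A.
#'
#' Ties policy: the rank-sum test uses the normal approximation with
#' continuity correction; a feature whose values are identical across both
#' groups (zero rank variance) gets p = 1.
#'
#' @param table numeric feature matrix (rows = features, cols = samples).
#' @param labels named character vector (sample -> group) or two-column
#'   data.frame; exactly two groups, each with at least two samples, and
#'   every column of `table` must be labelled.
#' @param test `"ranksum"` (Wilcoxon, default) or `"welch"` (Welch t-test).
#' @param pseudocount added to both means before the log ratio; default is
#'   half the smallest positive value in the table (1e-6 when the table has
#'   no positive value).
#' @return data.frame with columns `feature_key`, `mean_a`, `mean_b`,
#'   `log2_fold_change`, `p_value`, `q_value`, sorted by p-value then key.
#' @export
compare_groups <- function(table, labels, test = c("ranksum", "welch"),
                           pseudocount = NULL) {
  test <- match.arg(test)
  stopifnot(is.matrix(table))
  if (is.data.frame(labels)) {
    labels <- stats::setNames(as.character(labels[[2L]]),
                              as.character(labels[[1L]]))
  }
  samples <- colnames(table)
  unlab <- setdiff(samples, names(labels))
  if (length(unlab)) {
    stop("unlabelled sample(s): ", paste(unlab, collapse = ", "))
  }
  grp <- labels[samples]
  lev <- sort(unique(grp))
  if (length(lev) != 2L) stop("exactly two groups required, got ",
                              length(lev))
  a <- samples[grp == lev[1L]]
  b <- samples[grp == lev[2L]]
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 samples (", lev[1L], ": ", length(a),
         ", ", lev[2L], ": ", length(b), ")")
  }
  if (is.null(pseudocount)) {
    pos <- table[table > 0]
    pseudocount <- if (length(pos)) min(pos) / 2 else 1e-6
  }
  xa <- table[, a, drop = FALSE]
  xb <- table[, b, drop = FALSE]
  mean_a <- rowMeans(xa)
  mean_b <- rowMeans(xb)
  p <- vapply(seq_len(nrow(table)), function(i) {
    va <- xa[i, ]
    vb <- xb[i, ]
    if (all(c(va, vb) == c(va, vb)[1L])) return(1)
    if (test == "ranksum") {
      pv <- suppressWarnings(
        stats::wilcox.test(vb, va, exact = FALSE, correct = TRUE)$p.value)
      if (is.na(pv)) 1 else pv
    } else {
      pv <- tryCatch(stats::t.test(vb, va)$p.value, error = function(e) NA_real_)
      if (is.na(pv)) { if (mean(vb) == mean(va)) 1 else 0 } else pv
    }
  }, numeric(1))
  out <- data.frame(
    feature_key = rownames(table),
    mean_a = unname(mean_a), mean_b = unname(mean_b),
    log2_fold_change = unname(log2((mean_b + pseudocount) /
                                     (mean_a + pseudocount))),
    p_value = p,
    q_value = stats::p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$feature_key), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "groups") <- stats::setNames(lev, c("A", "B"))
  attr(out, "pseudocount") <- pseudocount
  out
}
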