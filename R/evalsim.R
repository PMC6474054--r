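#' Filter a DE result table at fold-change and FDR cutoffs
#'
#' The standard significance filter for calling differentially expressed
#' genes: absolute fold change at least `fc_cut` (i.e. `|log2fc| >=
#' log2(fc_cut)`) and BH-adjusted p-value at most `fdr_cut`.
#'
#' @param table data.frame with columns `gene_id`, `log2fc`, `pvalue`,
#'   `padj`.
#' @param fc_cut Fold-change cutoff on the linear scale (default 2).
#' @param fdr_cut FDR cutoff (default 0.05).
#'
#' @return Character vector of gene ids passing both cutoffs.
#' @export
filter_de <- function(table, fc_cut = 2, fdr_cut = 0.05) {
  stopifnot(all(c("gene_id", "log2fc", "padj") %in% colnames(table)))
  keep <- !is.na(table$log2fc) & !is.na(table$padj) &
    abs(table$log2fc) >= log2(fc_cut) & table$padj <= fdr_cut
  table$gene_id[keep]
}

#' Construct a gold standard from positives and a universe
#'
#' The deepest reference dataset's DE genes serve as a self-assigned gold
#' standard: the positive set; the negatives are every expressed gene not
#' called DE.
#'
#' @param positives Character vector of gold-standard DE gene ids.
#' @param universe Character vector of all expressed gene ids; must contain
#'   `positives`.
#' @return A list of class `GoldStandard` with `positives`, `universe`,
#'   `negatives`.
#' @export
gold_standard <- function(positives, universe) {
  positives <- unique(as.character(positives))
  universe <- unique(as.character(universe))
  if (!all(positives %in% universe)) {
    stop("positives must be a subset of the universe (",
         sum(!(positives %in% universe)), " outside)")
  }
  structure(list(positives = positives, universe = universe,
                 negatives = setdiff(universe, positives)),
            class = "GoldStandard")
}

#' Empirical DE power against a gold standard
#'
#' Counts how many called genes are gold-standard true positives, and the
#' true-positive rate (empirical power) as the recovered fraction of the
#' positive set.
#'
#' @param test_set Character vector of called DE gene ids.
#' @param gold A [gold_standard()].
#' @return List with `n_de` (calls), `n_true_positive`, and `tpr` (0 with a
#'   warning when the positive set is empty).
#' @export
empirical_power <- function(test_set, gold) {
  stopifnot(inherits(gold, "GoldStandard"))
  test_set <- unique(as.character(test_set))
  ntp <- length(intersect(test_set, gold$positives))
  npos <- length(gold$positives)
  if (npos == 0L) {
    warning("empty positive set; TPR reported as 0")
    tpr <- 0
  } else {
    tpr <- ntp / npos
  }
  list(n_de = length(test_set), n_true_positive = ntp, tpr = tpr)
}

#' ROC and precision-recall curves from ranked p-values
#'
#' Sweeps every cutoff of the ranked p-value list: at each unique p-value
#' `t`, genes with `p <= t` are called, and FPR, TPR and precision are
#' computed against the gold standard. The table is restricted to the gold
#' universe; universe genes absent from the table are penalized with
#' p-value 1 (so a method is not rewarded for dropping genes). AUCs are
#' trapezoidal integrals over the swept points, with the (0, 0) anchor for
#' ROC and the full-recall endpoint included by construction.
#'
#' @param table data.frame with `gene_id` and `pvalue`.
#' @param gold A [gold_standard()].
#' @return A list of class `CurveSet`: data.frames `roc` (`fpr`, `tpr`) and
#'   `pr` (`recall`, `precision`), both ordered by threshold, plus `roc_auc`
#'   and `pr_auc`.
#' @export
roc_pr_from_ranked <- function(table, gold) {
  stopifnot(inherits(gold, "GoldStandard"))
  if (length(gold$positives) == 0L || length(gold$negatives) == 0L) {
    stop("ROC/PR undefined: gold standard needs non-empty positives and negatives")
  }
  p <- stats::setNames(rep(1, length(gold$universe)), gold$universe)
  in_univ <- table$gene_id %in% gold$universe
  p[table$gene_id[in_univ]] <- table$pvalue[in_univ]
  is_pos <- names(p) %in% gold$positives
  P <- sum(is_pos)
  N <- sum(!is_pos)
  ord <- order(p)
  p <- p[ord]
  is_pos <- is_pos[ord]
  cum_tp <- cumsum(is_pos)
  cum_fp <- cumsum(!is_pos)
  # indices of the last gene at each unique p-value = the swept cutoffs
  last <- which(!duplicated(p, fromLast = TRUE))
  tp <- cum_tp[last]
  fp <- cum_fp[last]
  tpr <- tp / P
  fpr <- fp / N
  precision <- tp / (tp + fp)
  roc <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  # anchor the PR curve at recall 0 with the earliest cutoff's precision
  pr <- data.frame(recall = c(0, tpr), precision = c(precision[1], precision))
  structure(list(roc = roc, pr = pr,
                 roc_auc = trapezoid_auc(roc$fpr, roc$tpr),
                 pr_auc = trapezoid_auc(pr$recall, pr$precision)),
            class = "CurveSet")
}

trapezoid_auc <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Minimal sequencing depth for reliable gene detection
#'
#' For a gene expressed at `cpm` counts per million, each sequenced read
#' hits it with probability `cpm / 1e6`; the gene is "detected" when at
#' least one read does. The smallest depth D with detection probability at
#' least `prob` has the closed form `D = ceil(log(1 - prob) / log(1 - cpm /
#' 1e6))`.
#'
#' @param cpm Expression level in counts per million, in `(0, 1e6]`.
#' @param prob Required detection probability, in `(0, 1)` (default 0.95).
#' @return Integer depth (number of reads), at least 1. Vectorized over
#'   `cpm`.
#' @export
depth_for_detection <- function(cpm, prob = 0.95) {
  if (any(cpm <= 0) || any(cpm > 1e6)) {
    stop("cpm must be in (0, 1e6]: detection depth is unbounded at cpm <= 0")
  }
  if (prob <= 0 || prob >= 1) stop("prob must be strictly between 0 and 1")
  q <- cpm / 1e6
  d <- ifelse(q >= 1, 1, ceiling(log1p(-prob) / log1p(-q)))
  as.integer(pmax(d, 1))
}
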