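## Negative-binomial simulation and a basic two-group test for power
## analysis. The test is deliberately simple plumbing (method-of-moments
## dispersion + Wald statistic); externally produced DE tables are equally
## accepted by the evaluation functions.

# Median-of-ratios size factors (the "MR" normalization of DESeq).
size_factors_mor <- function(counts) {
  logg <- rowMeans(log(counts))
  use <- is.finite(logg)
  if (!any(use)) return(colSums(counts) / mean(colSums(counts)))
  sf <- apply(counts, 2, function(x) {
    stats::median(exp(log(x[use]) - logg[use]), na.rm = TRUE)
  })
  sf / exp(mean(log(sf)))
}

#' Estimate negative-binomial mean and dispersion parameters
#'
#' Empirical model estimation from a count matrix: size-factor-normalized
#' (median-of-ratios) per-gene means, gene-wise method-of-moments
#' dispersions `max((var - mean) / mean^2, 0)`, and a log-linear
#' mean-dispersion trend `log(phi) = a + b log(mu)` fitted over genes with
#' positive dispersion estimates. When `groups` is given, variances are
#' pooled within groups so condition differences do not inflate dispersion.
#'
#' @param counts Integer matrix, genes x samples.
#' @param groups Optional factor/vector of sample group labels.
#'
#' @return A list of class `NBParams`: `mean`, `dispersion` (per gene),
#'   `size_factors`, `trend_coef` (intercept, slope on the log scale) and
#'   `trend` (function mu -> fitted dispersion).
#' @export
estimate_nb_params <- function(counts, groups = NULL) {
  counts <- as.matrix(counts)
  sf <- size_factors_mor(counts)
  norm <- sweep(counts, 2, sf, "/")
  mu <- rowMeans(norm)
  if (is.null(groups)) {
    v <- apply(norm, 1, stats::var)
  } else {
    groups <- as.factor(groups)
    ssq <- 0
    df <- 0
    for (g in levels(groups)) {
      sub <- norm[, groups == g, drop = FALSE]
      if (ncol(sub) > 1L) {
        ssq <- ssq + apply(sub, 1, stats::var) * (ncol(sub) - 1L)
        df <- df + ncol(sub) - 1L
      }
    }
    if (df == 0) stop("need at least one group with >= 2 samples")
    v <- ssq / df
  }
  phi <- ifelse(mu > 0, pmax((v - mu) / mu^2, 0), 0)
  use <- phi > 0 & mu > 0
  if (sum(use) >= 10L) {
    fit <- stats::lm(log(phi[use]) ~ log(mu[use]))
    coefs <- unname(stats::coef(fit))
  } else {
    # too few informative genes: flat trend at the median positive value
    coefs <- c(log(stats::median(phi[use]) %||% 0.1), 0)
    if (!is.finite(coefs[1])) coefs <- c(log(0.1), 0)
  }
  trend <- function(m) exp(coefs[1] + coefs[2] * log(pmax(m, 1e-8)))
  structure(list(mean = mu, dispersion = phi, size_factors = sf,
                 trend_coef = c(intercept = coefs[1], slope = coefs[2]),
                 trend = trend),
            class = "NBParams")
}

#' Simulate a two-group negative-binomial DE experiment
#'
#' Simulates `n_genes` genes over two groups of `n_reps` replicates each,
#' with a fraction `frac_de` of genes differentially expressed. Absolute
#' log2 fold changes of DE genes are drawn from a narrow
#' Gamma(`lfc_shape`, scale = `lfc_scale`) distribution with random sign;
#' each group's mean is shifted symmetrically, `mu * 2^(+-lfc/2)`. Counts
#' are NB with gene-wise dispersion from the mean-dispersion trend.
#' Defaults emulate a bulk RNA-seq library: baseline means log-normal
#' (meanlog 3, sdlog 1.5) and trend `phi(mu) = 0.1 + 1/mu`; both are
#' replaced by the empirical model when `params` (an [estimate_nb_params()]
#' fit) is supplied.
#'
#' @param n_genes Number of genes (default 10000).
#' @param frac_de Fraction of DE genes (default 0.10).
#' @param n_reps Replicates per group.
#' @param params Optional `NBParams`; baseline means are resampled from its
#'   `mean` vector and dispersions come from its `trend`.
#' @param lfc_shape,lfc_scale Gamma parameters of `|log2fc|` (defaults 2 and
#'   0.5, mean 1).
#' @param seed Integer seed; the simulation is fully reproducible.
#'
#' @return A list of class `SimData`: `counts` (genes x 2*n_reps), `groups`
#'   (factor `g1`/`g2`), and `truth` (data.frame `gene_id`, `is_de`,
#'   `log2fc`, `mean`, `dispersion`), with exactly
#'   `round(frac_de * n_genes)` DE genes and `log2fc = 0` elsewhere.
#' @export
simulate_de_counts <- function(n_genes = 10000L, frac_de = 0.10,
                               n_reps = 5L, params = NULL,
                               lfc_shape = 2, lfc_scale = 0.5, seed = 1L) {
  with_local_seed(seed, {
    if (is.null(params)) {
      mu <- stats::rlnorm(n_genes, meanlog = 3, sdlog = 1.5)
      phi <- 0.1 + 1 / mu
    } else {
      stopifnot(inherits(params, "NBParams"))
      mu <- sample(params$mean[params$mean > 0], n_genes, replace = TRUE)
      phi <- params$trend(mu)
    }
    n_de <- round(frac_de * n_genes)
    is_de <- rep(FALSE, n_genes)
    is_de[sample.int(n_genes, n_de)] <- TRUE
    lfc <- numeric(n_genes)
    if (n_de > 0) {
      lfc[is_de] <- stats::rgamma(n_de, shape = lfc_shape, scale = lfc_scale) *
        sample(c(-1, 1), n_de, replace = TRUE)
    }
    mu1 <- mu * 2^(-lfc / 2)
    mu2 <- mu * 2^(+lfc / 2)
    size <- 1 / pmax(phi, 1e-8)
    draw <- function(m) {
      matrix(stats::rnbinom(n_genes * n_reps, mu = rep(m, n_reps),
                            size = rep(size, n_reps)),
             nrow = n_genes, ncol = n_reps)
    }
    counts <- cbind(draw(mu1), draw(mu2))
    gene_id <- sprintf("G%05d", seq_len(n_genes))
    rownames(counts) <- gene_id
    colnames(counts) <- c(paste0("g1_", seq_len(n_reps)),
                          paste0("g2_", seq_len(n_reps)))
    structure(
      list(counts = counts,
           groups = factor(rep(c("g1", "g2"), each = n_reps)),
           truth = data.frame(gene_id = gene_id, is_de = is_de,
                              log2fc = lfc, mean = mu, dispersion = phi,
                              stringsAsFactors = FALSE)),
      class = "SimData")
  })
}

#' Basic negative-binomial two-group Wald test
#'
#' Per-gene Wald test on the difference of log normalized group means, with
#' method-of-moments dispersion and a t reference distribution
#' (`df = n1 + n2 - 2`) for small-sample calibration. Log2 fold changes use
#' a pseudocount of 0.5; p-values are BH-adjusted. All-zero genes get
#' `pvalue = 1`, `log2fc = 0`. This is plumbing for power simulations, not
#' a reimplementation of a full DE framework.
#'
#' @param counts Integer matrix, genes x samples.
#' @param groups Factor/vector with exactly two levels, one per sample.
#'
#' @return A data.frame (`gene_id`, `log2fc`, `pvalue`, `padj`) — the
#'   `DEResultTable` layout consumed by [filter_de()] and
#'   [roc_pr_from_ranked()].
#' @export
nb_two_group_test <- function(counts, groups) {
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  sf <- size_factors_mor(counts)
  norm <- sweep(counts, 2, sf, "/")
  i1 <- groups == levels(groups)[1L]
  i2 <- groups == levels(groups)[2L]
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 replicates per group")
  m1 <- rowMeans(norm[, i1, drop = FALSE])
  m2 <- rowMeans(norm[, i2, drop = FALSE])
  v1 <- apply(norm[, i1, drop = FALSE], 1, stats::var)
  v2 <- apply(norm[, i2, drop = FALSE], 1, stats::var)
  # pooled MoM dispersion across both groups
  phi1 <- ifelse(m1 > 0, (v1 - m1) / m1^2, NA)
  phi2 <- ifelse(m2 > 0, (v2 - m2) / m2^2, NA)
  phi <- pmax(rowMeans(cbind(phi1, phi2), na.rm = TRUE), 0)
  phi[is.nan(phi)] <- 0
  c0 <- 0.5
  log2fc <- log2((m2 + c0) / (m1 + c0))
  se1 <- (m1 + phi * m1^2) / n1 / (m1 + c0)^2
  se2 <- (m2 + phi * m2^2) / n2 / (m2 + c0)^2
  se <- sqrt(se1 + se2)
  z <- log((m2 + c0) / (m1 + c0)) / se
  pvalue <- 2 * stats::pt(-abs(z), df = n1 + n2 - 2L)
  zero <- m1 == 0 & m2 == 0
  pvalue[zero | !is.finite(pvalue)] <- 1
  log2fc[zero] <- 0
  data.frame(
    gene_id = rownames(counts) %||% sprintf("G%05d", seq_len(nrow(counts))),
    log2fc = log2fc,
    pvalue = pvalue,
    padj = stats::p.adjust(pvalue, method = "BH"),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Average simulated DE power across replicate levels
#'
#' For each replication level, simulates `n_sims` datasets
#' ([simulate_de_counts()]), tests them ([nb_two_group_test()]), calls DE at
#' adjusted p-value `alpha`, and averages the true-positive rate against the
#' simulation truth.
#'
#' @param replicate_levels Integer vector of per-group replicate numbers
#'   (default `c(5, 20, 50)`).
#' @param n_sims Simulations per level (default 100).
#' @param n_genes,frac_de,params,lfc_shape,lfc_scale Passed to
#'   [simulate_de_counts()].
#' @param alpha FDR threshold for calling DE (default 0.05).
#' @param seed Base seed; simulation `j` at level `i` uses
#'   `seed + 1000 * i + j`.
#'
#' @return data.frame with `n_reps`, `mean_tpr`, `sd_tpr`, `n_sims`.
#' @export
power_curve <- function(replicate_levels = c(5L, 20L, 50L), n_sims = 100L,
                        n_genes = 10000L, frac_de = 0.10, params = NULL,
                        lfc_shape = 2, lfc_scale = 0.5, alpha = 0.05,
                        seed = 1L) {
  out <- lapply(seq_along(replicate_levels), function(i) {
    nr <- replicate_levels[i]
    tprs <- vapply(seq_len(n_sims), function(j) {
      sim <- simulate_de_counts(n_genes = n_genes, frac_de = frac_de,
                                n_reps = nr, params = params,
                                lfc_shape = lfc_shape, lfc_scale = lfc_scale,
                                seed = seed + 1000L * i + j)
      res <- nb_two_group_test(sim$counts, sim$groups)
      called <- res$gene_id[!is.na(res$padj) & res$padj <= alpha]
      truth_pos <- sim$truth$gene_id[sim$truth$is_de]
      if (length(truth_pos) == 0L) return(0)
      length(intersect(called, truth_pos)) / length(truth_pos)
    }, numeric(1))
    data.frame(n_reps = nr, mean_tpr = mean(tprs),
               sd_tpr = stats::sd(tprs), n_sims = n_sims)
  })
  do.call(rbind, out)
}
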