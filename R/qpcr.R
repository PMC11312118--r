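# RT-qPCR analysis: reference-gene stability (BestKeeper-, geNorm- and
# NormFinder-style), efficiency-corrected relative expression with
# significance testing, and net growth-rate estimation.

#' Construct a Cq table
#'
#' Quantification-cycle values for a panel of genes across samples, with
#' gene roles (candidate reference gene or target), sample condition labels
#' and per-assay amplification efficiencies.
#'
#' @param cq Numeric matrix, genes x samples, finite Cq values; dimnames
#'   required.
#' @param gene_info Data frame \code{gene}, \code{role} with role in
#'   \code{"candidate_RG"} / \code{"target"}; defaults to all candidates.
#' @param sample_info Data frame \code{sample}, \code{condition}.
#' @param efficiency Named numeric vector of fold-per-cycle amplification
#'   efficiencies in (1, 2]; default 2 (perfect doubling) for every gene.
#' @return A \code{cq_table} object.
#' @export
cq_table <- function(cq, gene_info = NULL, sample_info = NULL,
                     efficiency = NULL) {
  if (!is.matrix(cq) || is.null(rownames(cq)) || is.null(colnames(cq)))
    stopf("cq must be a matrix with gene rownames and sample colnames")
  if (any(!is.finite(cq))) stopf("Cq values must be finite")
  genes <- rownames(cq)
  if (is.null(gene_info))
    gene_info <- data.frame(gene = genes, role = "candidate_RG",
                            stringsAsFactors = FALSE)
  if (is.null(sample_info))
    sample_info <- data.frame(sample = colnames(cq), condition = "control",
                              stringsAsFactors = FALSE)
  if (!setequal(gene_info$gene, genes) ||
      !setequal(sample_info$sample, colnames(cq)))
    stopf("gene_info/sample_info must cover exactly the cq dimnames")
  if (!all(gene_info$role %in% c("candidate_RG", "target")))
    stopf("roles must be 'candidate_RG' or 'target'")
  if (is.null(efficiency)) efficiency <- stats::setNames(rep(2, length(genes)), genes)
  if (!all(genes %in% names(efficiency)))
    stopf("efficiency must be named for every gene")
  if (any(efficiency[genes] <= 1 | efficiency[genes] > 2))
    stopf("efficiencies must lie in (1, 2]")
  structure(list(cq = cq,
                 gene_info = gene_info[match(genes, gene_info$gene), , drop = FALSE],
                 sample_info = sample_info[match(colnames(cq), sample_info$sample), ,
                                           drop = FALSE],
                 efficiency = efficiency[genes]),
            class = "cq_table")
}

#' @export
print.cq_table <- function(x, ...) {
  cat(sprintf("cq_table: %d genes (%d candidate RGs) x %d samples, %d condition(s)\n",
              nrow(x$cq), sum(x$gene_info$role == "candidate_RG"), ncol(x$cq),
              length(unique(x$sample_info$condition))))
  invisible(x)
}

candidate_genes <- function(cq) cq$gene_info$gene[cq$gene_info$role == "candidate_RG"]

subset_genes <- function(cq, genes) {
  cq_table(cq$cq[genes, , drop = FALSE],
           gene_info = cq$gene_info[cq$gene_info$gene %in% genes, , drop = FALSE],
           sample_info = cq$sample_info,
           efficiency = cq$efficiency[genes])
}

#' Efficiency-corrected relative quantities
#'
#' Q(g, s) = E_g ^ (min_s Cq(g, .) - Cq(g, s)), so the best-expressed sample
#' of each gene has quantity 1.
#'
#' @param cq A \code{\link{cq_table}}.
#' @return Numeric matrix of relative quantities, genes x samples.
#' @export
relative_quantities <- function(cq) {
  mins <- apply(cq$cq, 1, min)
  cq$efficiency ^ (mins - cq$cq)
}

new_stability_report <- function(method, stat, genes, statistic_name,
                                 trace = NULL) {
  ranking <- data.frame(gene = genes, statistic = unname(stat[genes]),
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(ranking$statistic, ranking$gene), , drop = FALSE]
  ranking$rank <- seq_len(nrow(ranking))
  rownames(ranking) <- NULL
  structure(list(method = method, ranking = ranking,
                 statistic_name = statistic_name,
                 best_pair = sort(ranking$gene[1:2]), trace = trace),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("%s stability (%s, ascending = most stable):\n",
              x$method, x$statistic_name))
  print(x$ranking, row.names = FALSE)
  cat("best pair:", paste(x$best_pair, collapse = " + "), "\n")
  invisible(x)
}

#' BestKeeper-style reference-gene stability
#'
#' Ranks candidate reference genes by the dispersion of their raw Cq values
#' across all samples: the sample standard deviation by default, or the mean
#' absolute deviation from the mean (the original tool's descriptor) with
#' \code{use_mad = TRUE}. Also reports the coefficient of variation
#' (SD/mean x 100).
#'
#' @param cq A \code{\link{cq_table}}; only candidate reference genes are
#'   used.
#' @param use_mad Rank by mean absolute deviation instead of SD.
#' @return A \code{stability_report} (ranking ascending; \code{best_pair}
#'   holds the two most stable genes). The ranking data frame carries a
#'   \code{cv_pct} column.
#' @export
bestkeeper_stats <- function(cq, use_mad = FALSE) {
  genes <- candidate_genes(cq)
  if (length(genes) < 2L) stopf("need >= 2 candidate reference genes")
  if (ncol(cq$cq) < 2L) stopf("need >= 2 samples")
  x <- cq$cq[genes, , drop = FALSE]
  sds <- apply(x, 1, stats::sd)
  mad <- apply(x, 1, function(v) mean(abs(v - mean(v))))
  stat <- if (use_mad) mad else sds
  rep <- new_stability_report("BestKeeper", stat, genes,
                              if (use_mad) "MAD of Cq (cycles)" else "SD of Cq (cycles)")
  rep$ranking$cv_pct <- unname((sds / rowMeans(x) * 100)[rep$ranking$gene])
  rep
}

#' geNorm reference-gene stability with stepwise exclusion
#'
#' For each candidate pair (j, k), V_jk is the standard deviation across
#' samples of log2(Q_j / Q_k); a gene's expression stability M_j is the mean
#' of V_jk over all other candidates. The least stable gene (highest M) is
#' excluded and M recomputed, down to the final, most stable pair.
#'
#' @param cq A \code{\link{cq_table}} with >= 3 candidate reference genes.
#' @return A \code{stability_report}; \code{ranking$statistic} is each
#'   gene's M in the round it was excluded (the final pair shares the
#'   2-gene M), and \code{trace} records the per-round M values.
#' @export
genorm <- function(cq) {
  genes <- candidate_genes(cq)
  if (length(genes) < 3L)
    stopf("geNorm stepwise exclusion needs >= 3 candidate genes")
  if (ncol(cq$cq) < 2L) stopf("need >= 2 samples")
  lq <- log2(relative_quantities(subset_genes(cq, genes)))
  m_values <- function(mat) {
    g <- rownames(mat)
    v <- sapply(g, function(j) sapply(g, function(k)
      stats::sd(mat[j, ] - mat[k, ])))
    stats::setNames(colMeans(v) * length(g) / (length(g) - 1), g)  # mean over k != j
  }
  trace <- list()
  remaining <- lq
  excluded <- character(0)
  excluded_m <- numeric(0)
  while (nrow(remaining) > 2L) {
    M <- m_values(remaining)
    trace[[length(trace) + 1L]] <- M
    # ties broken toward the lexicographically greatest so the kept set is
    # deterministic
    worst <- names(M)[M == max(M)]
    worst <- worst[order(worst, decreasing = TRUE)][1]
    excluded <- c(excluded, worst)
    excluded_m <- c(excluded_m, M[worst])
    remaining <- remaining[setdiff(rownames(remaining), worst), , drop = FALSE]
  }
  M_final <- m_values(remaining)
  trace[[length(trace) + 1L]] <- M_final
  stat <- c(stats::setNames(excluded_m, excluded), M_final)
  rep <- new_stability_report("geNorm", stat, genes, "expression stability M",
                             trace = trace)
  rep$best_pair <- sort(rownames(remaining))
  # ranking by exclusion order: final pair first, then reverse exclusion
  order_genes <- c(sort(rownames(remaining)), rev(excluded))
  rep$ranking <- data.frame(gene = order_genes,
                            statistic = unname(stat[order_genes]),
                            rank = seq_along(order_genes),
                            stringsAsFactors = FALSE)
  rep
}

#' NormFinder-style model-based stability
#'
#' Fits the additive two-way model x(g, s) = gene effect + sample effect +
#' residual on log2 relative quantities via row/column means; a gene's
#' stability value is the bias-corrected standard deviation of its
#' residuals: because the fitted sample effect contains a 1/G share of every
#' gene's noise, the raw residual mean square of gene g has expectation
#' (1 - 2/G) sigma_g^2 + S/G^2 (S the summed gene variances), and the
#' estimator inverts this relation so that one gene's instability does not
#' inflate the others' values. Sample effects absorb loading shifts, so
#' adding a constant to one sample's Cq across all genes leaves every
#' stability unchanged. With \code{grouped = TRUE} the sample conditions are
#' used as groups and the stability combines the between-group gene effect
#' magnitude with the within-group residual SD (a simplified form of the
#' original grouped estimator, which additionally shrinks the group effects
#' toward zero by their sampling variance).
#'
#' @param cq A \code{\link{cq_table}} with >= 3 candidate reference genes.
#' @param grouped Use sample conditions as groups.
#' @return A \code{stability_report} (ascending stability values).
#' @export
normfinder <- function(cq, grouped = FALSE) {
  genes <- candidate_genes(cq)
  if (length(genes) < 3L) stopf("need >= 3 candidate reference genes")
  if (ncol(cq$cq) < 2L) stopf("need >= 2 samples")
  x <- log2(relative_quantities(subset_genes(cq, genes)))
  G <- nrow(x)
  resid_sd <- function(mat) {
    S <- ncol(mat)
    r <- mat - rowMeans(mat) -
      matrix(colMeans(mat), nrow(mat), S, byrow = TRUE) + mean(mat)
    z <- rowSums(r^2) / (S - 1)  # raw residual mean square per gene
    # E[z_g] = (1 - 2/G) sigma_g^2 + S_tot/G^2 with S_tot = sum_h sigma_h^2;
    # invert it so other genes' noise does not bleed into gene g's value
    s_tot <- sum(z) * G / (G - 1)
    sqrt(pmax((z - s_tot / G^2) * G / (G - 2), 0))
  }
  if (grouped) {
    groups <- split(seq_len(ncol(x)), cq$sample_info$condition)
    if (length(groups) < 2L) {
      warning("grouped NormFinder needs >= 2 conditions; falling back to ungrouped",
              call. = FALSE)
      grouped <- FALSE
    }
  }
  if (!grouped) {
    stat <- resid_sd(x)
  } else {
    centered <- x - rowMeans(x)
    within <- sapply(groups, function(j) resid_sd(x[, j, drop = FALSE]))
    d <- sapply(groups, function(j) {
      gm <- rowMeans(centered[, j, drop = FALSE])
      gm - mean(gm)
    })
    stat <- sqrt(rowMeans(d^2)) + rowMeans(within) / sqrt(min(lengths(groups)))
  }
  new_stability_report("NormFinder", stat, genes, "stability value")
}

#' Consensus reference-gene pair across stability methods
#'
#' Ranks genes by mean rank across the supplied reports and returns the two
#' best; ties are broken by how often a gene appears in a method's top 2,
#' then lexicographically.
#'
#' @param reports List of \code{stability_report}s (>= 1).
#' @return Character vector of two gene names, sorted.
#' @export
select_reference_pair <- function(reports) {
  if (!length(reports)) stopf("at least one stability report required")
  genes <- reports[[1]]$ranking$gene
  ranks <- sapply(reports, function(r)
    r$ranking$rank[match(genes, r$ranking$gene)])
  ranks <- matrix(ranks, nrow = length(genes))
  top2 <- sapply(reports, function(r) genes %in% r$best_pair)
  top2 <- matrix(top2, nrow = length(genes))
  o <- order(rowMeans(ranks), -rowSums(top2), genes)
  sort(genes[o][1:2])
}

star_class <- function(p) {
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
      labels = c("***", "**", "*", "ns"))
}

#' Efficiency-corrected relative expression vs a control condition
#'
#' For each target gene g and treatment condition c the expression ratio is
#' E_g^(dCq_g) normalized by the geometric mean of the reference genes'
#' E_r^(dCq_r), where dCq = mean Cq(control) - mean Cq(c). Significance is a
#' two-sided Student's t-test on per-replicate reference-normalized log2
#' expression values (control vs treatment); a REST-style randomization test
#' (permuting condition labels) is available with \code{method =
#' "permutation"}.
#'
#' @param cq A \code{\link{cq_table}}.
#' @param targets Target gene names (default: all genes with role
#'   \code{"target"}).
#' @param refs Reference gene pair (or more), e.g. from
#'   \code{\link{select_reference_pair}}.
#' @param control_condition Label of the control condition.
#' @param conditions Treatment conditions to test (default: all others).
#' @param method \code{"ttest"} (default) or \code{"permutation"}.
#' @param n_perm Number of label permutations for the randomization test.
#' @param seed Seed for the randomization test.
#' @return Data frame \code{gene}, \code{condition}, \code{delta_cq},
#'   \code{ratio}, \code{log2_ratio}, \code{p_value}, \code{significance}
#'   (\code{ns}/\code{*}/\code{**}/\code{***} at 0.05/0.01/0.001).
#' @export
rel_expression <- function(cq, targets = NULL, refs, control_condition = "control",
                           conditions = NULL, method = c("ttest", "permutation"),
                           n_perm = 2000L, seed = 1L) {
  method <- match.arg(method)
  if (is.null(targets))
    targets <- cq$gene_info$gene[cq$gene_info$role == "target"]
  missing_genes <- setdiff(c(targets, refs), rownames(cq$cq))
  if (length(missing_genes)) stopf("genes absent from the Cq table: %s",
                                   toString(missing_genes))
  cond <- cq$sample_info$condition
  if (!control_condition %in% cond)
    stopf("control condition '%s' absent", control_condition)
  if (is.null(conditions)) conditions <- setdiff(unique(cond), control_condition)
  missing_conds <- setdiff(conditions, cond)
  if (length(missing_conds)) stopf("conditions absent from the Cq table: %s",
                                   toString(missing_conds))
  logE <- log2(cq$efficiency)
  ctrl <- which(cond == control_condition)
  # per-sample reference-normalized log2 expression of gene g
  norm_expr <- function(g, idx) {
    ref_term <- colMeans(matrix(cq$cq[refs, idx, drop = FALSE] * logE[refs],
                                nrow = length(refs)))
    -cq$cq[g, idx] * logE[g] + ref_term
  }
  if (method == "permutation") set.seed(seed)
  out <- list()
  for (g in targets) for (cc in conditions) {
    trt <- which(cond == cc)
    dcq_g <- mean(cq$cq[g, ctrl]) - mean(cq$cq[g, trt])
    dcq_r <- rowMeans(cq$cq[refs, ctrl, drop = FALSE]) -
      rowMeans(cq$cq[refs, trt, drop = FALSE])
    ratio <- cq$efficiency[g]^dcq_g / geomean(cq$efficiency[refs]^dcq_r)
    a <- norm_expr(g, ctrl)
    b <- norm_expr(g, trt)
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (isTRUE(all.equal(mean(a), mean(b)))) {
        p <- 1
      } else {
        warning(sprintf("%s/%s: zero replicate variance in both groups; p set to 0",
                        g, cc), call. = FALSE)
        p <- 0
      }
    } else if (method == "ttest") {
      p <- stats::t.test(b, a, var.equal = TRUE)$p.value
    } else {
      obs <- abs(mean(b) - mean(a))
      z <- c(a, b)
      na <- length(a)
      perm <- replicate(n_perm, {
        i <- sample(length(z), na)
        abs(mean(z[-i]) - mean(z[i]))
      })
      p <- (1 + sum(perm >= obs - 1e-12)) / (n_perm + 1)
    }
    out[[length(out) + 1L]] <- data.frame(
      gene = g, condition = cc, delta_cq = unname(dcq_g),
      ratio = unname(ratio), log2_ratio = unname(log2(ratio)),
      p_value = p, significance = as.character(star_class(p)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Net growth rate from a cell-density time series
#'
#' Least-squares slope of ln(density) versus time over the fit window; with
#' only two points this reduces to ln(N_t / N_0) / (t - t_0).
#'
#' @param series A \code{growth_series} data frame (\code{day},
#'   \code{density}) or any data frame with those columns.
#' @param window Optional length-2 numeric, time window (inclusive) to fit;
#'   default uses all points.
#' @return List with \code{rate} (per day), \code{r_squared}, \code{n},
#'   \code{window}, of class \code{growth_rate}.
#' @export
growth_rate <- function(series, window = NULL) {
  t <- series$day
  n <- series$density
  if (any(n <= 0)) stopf("densities must be positive")
  if (any(diff(t) <= 0)) stopf("times must be strictly increasing")
  if (!is.null(window)) {
    keep <- t >= window[1] & t <= window[2]
    t <- t[keep]; n <- n[keep]
  }
  if (length(t) < 2L) stopf("need >= 2 points in the fit window")
  fit <- stats::lm(log(n) ~ t)
  ss_tot <- sum((log(n) - mean(log(n)))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(list(rate = unname(stats::coef(fit)[2]), r_squared = r2,
                 n = length(t), window = window %||% range(t)),
            class = "growth_rate")
}

#' @export
print.growth_rate <- function(x, ...) {
  cat(sprintf("net growth rate: %.3f / day (R^2 = %.3f, n = %d, window %g-%g d)\n",
              x$rate, x$r_squared, x$n, x$window[1], x$window[2]))
  invisible(x)
}

# Cq table IO -----------------------------------------------------------------

#' Write / read a Cq table as TSV files
#'
#' Three tab-separated files: the Cq matrix (rows = genes with a role
#' column, columns = samples), the sample metadata (sample, condition) and
#' the per-gene efficiencies.
#'
#' @param cq A \code{\link{cq_table}}.
#' @param cq_path,samples_path,efficiency_path File paths; the sample and
#'   efficiency paths default to the Cq path with \code{.samples} /
#'   \code{.efficiency} inserted.
#' @return \code{read_cq_table} returns a \code{\link{cq_table}}.
#' @export
write_cq_table <- function(cq, cq_path,
                           samples_path = sub("(\\.[^.]+)?$", ".samples.tsv", cq_path),
                           efficiency_path = sub("(\\.[^.]+)?$", ".efficiency.tsv", cq_path)) {
  d <- data.frame(gene = rownames(cq$cq), role = cq$gene_info$role,
                  cq$cq, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, cq_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cq$sample_info, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(gene = names(cq$efficiency), efficiency = unname(cq$efficiency)),
    efficiency_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(cq_path)
}

#' @rdname write_cq_table
#' @export
read_cq_table <- function(cq_path,
                          samples_path = sub("(\\.[^.]+)?$", ".samples.tsv", cq_path),
                          efficiency_path = sub("(\\.[^.]+)?$", ".efficiency.tsv", cq_path)) {
  d <- utils::read.delim(cq_path, check.names = FALSE, stringsAsFactors = FALSE)
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  m <- as.matrix(d[, setdiff(names(d), c("gene", "role")), drop = FALSE])
  rownames(m) <- d$gene
  eff <- NULL
  if (file.exists(efficiency_path)) {
    e <- utils::read.delim(efficiency_path, stringsAsFactors = FALSE)
    eff <- stats::setNames(e$efficiency, e$gene)
  }
  cq_table(m, gene_info = d[, c("gene", "role")], sample_info = samples,
           efficiency = eff)
}
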