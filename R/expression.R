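#' Read a qPCR Ct table
#'
#' Delimited text (CSV or TSV, chosen by extension or sniffed from the
#' header line) with columns `genotype`, `timepoint`, `replicate`, `gene`
#' and `ct`. Each (genotype, timepoint, replicate, gene) combination must
#' be unique and every Ct finite and positive.
#'
#' @param path file path.
#' @param timepoint_levels optional ordered vector of time-point labels;
#'   defaults to order of first appearance.
#' @return Data frame of class `ct_table`; `timepoint` is an ordered
#'   factor.
#' @export
read_ct_table <- function(path, timepoint_levels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  ct_table(df, timepoint_levels = timepoint_levels)
}

#' Validate a data frame of qPCR measurements
#'
#' @param df data frame with columns `genotype`, `timepoint`, `replicate`,
#'   `gene`, `ct`.
#' @inheritParams read_ct_table
#' @return The validated data frame with class `ct_table` prepended.
#' @export
ct_table <- function(df, timepoint_levels = NULL) {
  need <- c("genotype", "timepoint", "replicate", "gene", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(df$ct) || any(!is.finite(df$ct)) || any(df$ct <= 0)) {
    stop("ct values must be finite and > 0", call. = FALSE)
  }
  key <- interaction(df$genotype, df$timepoint, df$replicate, df$gene,
                     drop = TRUE)
  if (anyDuplicated(key)) {
    stop("duplicated (genotype, timepoint, replicate, gene) rows",
         call. = FALSE)
  }
  if (is.null(timepoint_levels)) {
    timepoint_levels <- unique(as.character(df$timepoint))
  }
  df$timepoint <- factor(as.character(df$timepoint),
                         levels = timepoint_levels, ordered = TRUE)
  if (anyNA(df$timepoint)) {
    stop("timepoint labels outside declared levels", call. = FALSE)
  }
  class(df) <- c("ct_table", class(df))
  df
}

#' Relative expression by the delta-Ct method
#'
#' `2^(ct_ref - ct_gene)`: expression of a target gene relative to the
#' reference gene measured in the same sample. One qPCR cycle corresponds
#' to a two-fold difference, so the result is strictly positive and
#' monotone decreasing in `ct_gene`.
#'
#' @param ct_gene Ct of the target gene.
#' @param ct_ref Ct of the reference gene in the same sample.
#' @return Relative expression ratio (vectorised).
#' @examples
#' relative_expression(21, 20)  # 0.5
#' relative_expression(15, 18)  # 8
#' @export
relative_expression <- function(ct_gene, ct_ref) {
  if (anyNA(ct_gene) || anyNA(ct_ref)) {
    stop("missing Ct value: reference and target Ct are both required",
         call. = FALSE)
  }
  2^(ct_ref - ct_gene)
}

#' Per-timepoint mean relative expression
#'
#' For one genotype and one target gene, pairs each replicate's Ct with the
#' reference gene's Ct in the same (genotype, timepoint, replicate) sample,
#' transforms to relative expression, and returns the mean and standard
#' error per time point in declared order. Lost samples reduce `n` at that
#' cell; a time point with no replicates is reported as `NA` with a
#' warning.
#'
#' @param records a [ct_table()].
#' @param genotype,gene labels selecting the series.
#' @param reference reference gene label (default `"ACT2"`).
#' @return Data frame with columns `timepoint`, `mean`, `sem`, `n`.
#' @export
timepoint_means <- function(records, genotype, gene, reference = "ACT2") {
  stopifnot(inherits(records, "ct_table"))
  if (!reference %in% records$gene) {
    stop("reference gene '", reference, "' absent from table", call. = FALSE)
  }
  tps <- levels(records$timepoint)
  g <- records[records$genotype == genotype & records$gene == gene, ]
  r <- records[records$genotype == genotype & records$gene == reference, ]
  key <- function(d) paste(as.character(d$timepoint), d$replicate, sep = "\r")
  ref_ct <- stats::setNames(r$ct, key(r))
  g$ref <- ref_ct[key(g)]
  if (anyNA(g$ref)) {
    stop("missing reference Ct for sample(s): ",
         paste(utils::head(key(g)[is.na(g$ref)]), collapse = "; "),
         call. = FALSE)
  }
  g$rel <- relative_expression(g$ct, g$ref)
  out <- data.frame(timepoint = factor(tps, levels = tps, ordered = TRUE),
                    mean = NA_real_, sem = NA_real_, n = 0L)
  for (i in seq_along(tps)) {
    v <- g$rel[as.character(g$timepoint) == tps[i]]
    out$n[i] <- length(v)
    if (length(v) > 0) {
      out$mean[i] <- mean(v)
      out$sem[i] <- if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
    }
  }
  if (any(out$n == 0)) {
    warning("no replicates for ", genotype, "/", gene, " at timepoint(s): ",
            paste(tps[out$n == 0], collapse = ", "), call. = FALSE)
  }
  out
}

#' Spearman correlation between two stage-expression series
#'
#' Rank correlation (average ranks for ties) between two equal-length
#' series of per-timepoint means. The permutation p-value is exact when
#' `n <= exact_max` (all `n!` rank assignments enumerated); otherwise the
#' large-sample t approximation is used for both. Both one-sided tails and
#' a two-sided value (twice the smaller tail, capped at 1) are reported,
#' together with the t-approximation `p_approx =` two-sided p from
#' `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` degrees of freedom -- the
#' value statistical packages typically print.
#'
#' @param series_a,series_b numeric vectors of equal length `n >= 3`.
#' @param exact_max largest `n` for exact permutation enumeration
#'   (default 8).
#' @return Object of class `stage_correlation` with `rho`, `n`, `p_exact`
#'   (two-sided permutation), `p_greater`, `p_less` (one-sided permutation
#'   tails), `p_approx` and `method`. `rho` is `NA` for a constant series.
#' @examples
#' stage_correlation(1:6, c(6, 5, 4, 3, 1, 2))  # rho = -0.943
#' @export
stage_correlation <- function(series_a, series_b, exact_max = 8L) {
  n <- length(series_a)
  if (length(series_b) != n) stop("series lengths differ", call. = FALSE)
  if (n < 3) stop("need at least 3 time points", call. = FALSE)
  if (length(unique(series_a)) == 1L || length(unique(series_b)) == 1L) {
    return(structure(list(rho = NA_real_, n = n, p_exact = NA_real_,
                          p_greater = NA_real_, p_less = NA_real_,
                          p_approx = NA_real_, method = "undefined"),
                     class = "stage_correlation"))
  }
  rho <- stats::cor(series_a, series_b, method = "spearman")
  ra <- rank(series_a); rb <- rank(series_b)

  t_p <- function(r) {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  p_approx <- if (abs(rho) >= 1) t_p(sign(rho) * (1 - 1e-12)) else t_p(rho)

  if (n <= exact_max) {
    eps <- 1e-12
    perms <- .permutations(seq_len(n))
    rhos <- vapply(perms, function(p) stats::cor(ra, rb[p]), numeric(1))
    p_ge <- mean(rhos >= rho - eps)
    p_le <- mean(rhos <= rho + eps)
    p_two <- min(1, 2 * min(p_ge, p_le))
    method <- "exact permutation"
  } else {
    p_ge <- if (rho >= 0) p_approx / 2 else 1 - p_approx / 2
    p_le <- if (rho <= 0) p_approx / 2 else 1 - p_approx / 2
    p_two <- p_approx
    method <- "t approximation"
  }
  structure(list(rho = rho, n = n, p_exact = p_two, p_greater = p_ge,
                 p_less = p_le, p_approx = p_approx, method = method),
            class = "stage_correlation")
}

#' @export
print.stage_correlation <- function(x, ...) {
  if (is.na(x$rho)) {
    cat("stage correlation: undefined (constant series)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "stage correlation: rho = %.4f (n = %d), %s P = %.4g, t-approx P = %.4g\n",
    x$rho, x$n, x$method, x$p_exact, x$p_approx))
  invisible(x)
}

#' All pairwise stage correlations for one genotype
#'
#' Computes [timepoint_means()] for every target gene and the Spearman
#' correlation for every gene pair, mirroring a pairwise correlation
#' table over time-point means.
#'
#' @param records a [ct_table()].
#' @param genotype genotype label.
#' @param genes target genes; defaults to all non-reference genes present.
#' @param reference reference gene label.
#' @return Data frame with one row per unordered gene pair: `gene_a`,
#'   `gene_b`, `rho`, `p_exact`, `p_approx`, `n_timepoints`.
#' @export
expression_correlations <- function(records, genotype, genes = NULL,
                                    reference = "ACT2") {
  stopifnot(inherits(records, "ct_table"))
  if (is.null(genes)) {
    genes <- setdiff(unique(records$gene[records$genotype == genotype]),
                     reference)
  }
  series <- lapply(genes, function(g)
    timepoint_means(records, genotype, g, reference = reference)$mean)
  names(series) <- genes
  pairs <- utils::combn(genes, 2)
  out <- data.frame(gene_a = pairs[1, ], gene_b = pairs[2, ],
                    rho = NA_real_, p_exact = NA_real_, p_approx = NA_real_,
                    n_timepoints = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    a <- series[[pairs[1, i]]]; b <- series[[pairs[2, i]]]
    ok <- !is.na(a) & !is.na(b)
    res <- stage_correlation(a[ok], b[ok])
    out$rho[i] <- res$rho
    out$p_exact[i] <- res$p_exact
    out$p_approx[i] <- res$p_approx
    out$n_timepoints[i] <- sum(ok)
  }
  out
}
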