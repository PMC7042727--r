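# Probe-level expression QC and gene-level correlation analysis:
# quantile normalization, detection-p call-rate filtering, probe
# averaging, linear-model fits, anchor-target correlation screens and
# Fisher-z comparison of correlations between tissues.

#' Expression data container
#'
#' Probe-level intensities with per-cell detection p-values, case/control
#' group labels and a probe-to-gene map.
#'
#' @param intensities numeric matrix, probes in rows (named), samples in
#'   columns (named).
#' @param detection_p matrix of detection p-values, same shape.
#' @param groups named character vector (`"AD"`/`"control"`) per sample.
#' @param probe_map data frame with columns `probe`, `gene`.
#' @param log2_transformed whether intensities are already on the log2
#'   scale.
#' @return An object of class `expression_set`.
#' @export
expression_set <- function(intensities, detection_p, groups, probe_map,
                           log2_transformed = FALSE) {
  stopifnot(is.matrix(intensities), identical(dim(intensities),
                                              dim(detection_p)),
            !is.null(rownames(intensities)),
            !is.null(colnames(intensities)))
  if (any(detection_p < 0 | detection_p > 1, na.rm = TRUE))
    stop_input("detection p-values must lie in [0, 1]")
  if (!all(colnames(intensities) %in% names(groups)))
    stop_input("every sample needs a group label")
  groups <- groups[colnames(intensities)]
  if (!all(groups %in% c("AD", "control")))
    stop_input("groups must be 'AD' or 'control'")
  if (!all(c("probe", "gene") %in% names(probe_map)))
    stop_input("probe_map needs columns probe, gene")
  structure(list(intensities = intensities, detection_p = detection_p,
                 groups = groups, probe_map = probe_map,
                 log2_transformed = isTRUE(log2_transformed)),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("expression_set: %d probes x %d samples (%d AD, %d control)\n",
              nrow(x$intensities), ncol(x$intensities),
              sum(x$groups == "AD"), sum(x$groups == "control")))
  invisible(x)
}

#' Quantile normalization
#'
#' Forces every sample column onto the common reference distribution
#' formed by the row means of the column-sorted matrix. Ties within a
#' column receive the mean of the reference values they span (average
#' ranks, linearly interpolated).
#'
#' @param mat numeric matrix, probes x samples, no missing values.
#' @return Matrix of the same shape; all columns share the identical
#'   sorted value vector.
#' @export
quantile_normalize <- function(mat) {
  stopifnot(is.matrix(mat), !anyNA(mat))
  n <- nrow(mat)
  if (n == 0L || ncol(mat) == 0L) return(mat)
  ref <- rowMeans(apply(mat, 2, sort))
  out <- apply(mat, 2, function(x) {
    r <- rank(x, ties.method = "average")
    if (n == 1L) ref[1] else approx(seq_len(n), ref, xout = r)$y
  })
  if (!is.matrix(out)) out <- matrix(out, nrow = n)
  dimnames(out) <- dimnames(mat)
  out
}

#' Detection call-rate filter
#'
#' A probe's call rate in a group is the fraction of that group's
#' samples with detection p-value below `alpha` (p at or above `alpha`
#' is a no-call). Probes with call rate below `min_rate` in the AD group
#' AND in the control group are non-informative and removed; failing in
#' only one group keeps the probe.
#'
#' @param es an [expression_set()].
#' @param alpha detection p-value threshold (default 0.05).
#' @param min_rate minimum call rate (default 0.90).
#' @return Character vector of retained probe names, with attribute
#'   `rates` (per-group call-rate matrix).
#' @export
call_rate_filter <- function(es, alpha = 0.05, min_rate = 0.90) {
  for (g in c("AD", "control"))
    if (!any(es$groups == g)) stop_input("group ", g, " is empty")
  called <- es$detection_p < alpha
  rate <- sapply(c("AD", "control"), function(g)
    rowMeans(called[, es$groups == g, drop = FALSE]))
  keep <- !(rate[, "AD"] < min_rate & rate[, "control"] < min_rate)
  structure(rownames(es$intensities)[keep], rates = rate)
}

#' Gene-level expression signal
#'
#' Per-sample arithmetic mean of the log2 intensities of a gene's
#' retained probes.
#'
#' @param es an [expression_set()].
#' @param gene gene symbol to summarize.
#' @param retained optional probe whitelist (e.g. from
#'   [call_rate_filter()]).
#' @return Named numeric vector over samples.
#' @export
gene_signal <- function(es, gene, retained = NULL) {
  probes <- es$probe_map$probe[es$probe_map$gene == gene]
  probes <- intersect(probes, rownames(es$intensities))
  if (!is.null(retained)) probes <- intersect(probes, retained)
  if (length(probes) == 0L)
    stop_input("no retained probes for gene ", gene)
  x <- es$intensities[probes, , drop = FALSE]
  if (!es$log2_transformed) x <- log2(x)
  colMeans(x)
}

#' Linear-model fit of one gene signal on another
#'
#' Ordinary least squares of `y` on `x` with the Pearson correlation,
#' the slope, the two-sided t-test p-value of the slope (n - 2 df) and
#' the adjusted coefficient of determination
#' `1 - (1 - R^2) (n - 1) / (n - 2)`.
#'
#' @param x,y numeric vectors of equal length (n >= 3); `x` must vary.
#' @return An object of class `correlation_result`: list with `n`, `r`,
#'   `r2`, `r2_adj`, `slope`, `intercept`, `slope_p`.
#' @export
fit_pair <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop_input("need at least 3 complete observations")
  if (var(x) == 0) stop_input("zero variance in x")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  r <- cor(x, y)
  r2 <- unname(sm$r.squared)
  structure(list(n = n, r = r, r2 = r2,
                 r2_adj = unname(sm$adj.r.squared),
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 slope_p = unname(sm$coefficients[2, 4])),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("n = %d, r = %.4f, adj r2 = %.4f, slope = %.4f (p = %.3g)\n",
              x$n, x$r, x$r2_adj, x$slope, x$slope_p))
  invisible(x)
}

#' Anchor-target correlation screen
#'
#' Pearson correlation of an anchor gene's signal with each target
#' gene's signal, ranked by absolute correlation; targets with
#' `|r| >= high_threshold` are flagged as highly correlated.
#'
#' @param es an [expression_set()].
#' @param anchor anchor gene symbol.
#' @param targets character vector of target gene symbols.
#' @param retained optional probe whitelist.
#' @param high_threshold flag threshold on `|r|` (default 0.7).
#' @return Data frame with columns `gene`, `r`, `p`, `n`, `high`,
#'   sorted by decreasing `|r|`. Targets with no retained probes are
#'   dropped with a message.
#' @export
pearson_screen <- function(es, anchor, targets, retained = NULL,
                           high_threshold = 0.7) {
  a <- gene_signal(es, anchor, retained)
  rows <- lapply(targets, function(g) {
    t <- tryCatch(gene_signal(es, g, retained), error = function(e) NULL)
    if (is.null(t)) {
      message("target ", g, " has no retained probes; dropped")
      return(NULL)
    }
    ct <- cor.test(a, t, method = "pearson")
    data.frame(gene = g, r = unname(ct$estimate), p = ct$p.value,
               n = sum(!is.na(a) & !is.na(t)))
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    return(data.frame(gene = character(), r = numeric(), p = numeric(),
                      n = integer(), high = logical()))
  out <- out[order(-abs(out$r)), , drop = FALSE]
  out$high <- abs(out$r) >= high_threshold
  rownames(out) <- NULL
  out
}

#' Compare two correlation coefficients (Fisher z)
#'
#' Tests the difference between two correlations estimated in
#' independent samples: each r is Fisher z-transformed (`atanh`) and the
#' contrast `z = (z1 - z2) / sqrt(1/(n1-3) + 1/(n2-3))` is referred to
#' the standard normal. One-sided tests the alternative `r1 < r2` when
#' `z < 0` direction is of interest: the reported one-sided p is
#' `P(Z <= z)`.
#'
#' @param r1,r2 correlation coefficients with `|r| < 1`.
#' @param n1,n2 sample sizes (>= 4).
#' @param sided `"one"` or `"two"`.
#' @return List with `z` and `p`.
#' @export
compare_correlations <- function(r1, n1, r2, n2,
                                 sided = c("two", "one")) {
  sided <- match.arg(sided)
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop_input("Fisher transform diverges at |r| = 1")
  if (n1 < 4 || n2 < 4) stop_input("need n >= 4 in both samples")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- if (sided == "two") 2 * pnorm(-abs(z)) else pnorm(z)
  list(z = z, p = p)
}
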