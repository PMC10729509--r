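# Two-group differential-expression screening on a log2-scale matrix.
#
# Two tests are provided behind one surface: a plain Welch unequal-variance
# t, and a moderated t that shrinks per-gene pooled variances toward a
# common prior estimated by the method of moments on log sample variances
# (empirical-Bayes moderation in the classic microarray style). Data are
# assumed to be on the log2 scale already, so the log2 fold change is simply
# the case-minus-control difference of group means.

#' Two-group expression matrix
#'
#' @param values Numeric matrix, genes in rows (rownames are gene ids,
#'   unique), samples in columns (colnames are sample ids).
#' @param groups Factor or character of per-sample labels with exactly two
#'   levels, `control` first. Anything coercible to a two-level factor
#'   works; levels are taken in the order given if `groups` is a factor.
#' @return An `expr_matrix` object.
#' @export
expr_matrix <- function(values, groups) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    stop_invalid("`values` must have gene ids as rownames")
  }
  if (anyDuplicated(rownames(values))) {
    stop_invalid("gene ids must be unique; collapse duplicates first ",
                 "(see `collapse_duplicates()`)")
  }
  if (!is.factor(groups)) groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) != 2L) {
    stop_invalid("`groups` must have exactly two levels")
  }
  if (length(groups) != ncol(values)) {
    stop_invalid("`groups` length must equal the number of samples")
  }
  if (anyNA(groups)) stop_invalid("group labels must not be missing")
  if (any(table(groups) < 2L)) {
    stop_invalid("each group needs at least 2 samples")
  }
  structure(list(values = values, groups = groups), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%d %s", table(x$groups), levels(x$groups)),
                    collapse = " / ")))
  invisible(x)
}

#' Collapse duplicate gene ids, keeping the highest-mean row
#'
#' A deterministic convention for multi-probe arrays: among rows sharing a
#' symbol, the one with the highest mean expression is kept.
#'
#' @param values Numeric matrix with (possibly duplicated) rownames.
#' @return The matrix with one row per unique symbol.
#' @export
collapse_duplicates <- function(values) {
  values <- as.matrix(values)
  means <- rowMeans(values)
  ord <- order(rownames(values), -means)
  values <- values[ord, , drop = FALSE]
  values[!duplicated(rownames(values)), , drop = FALSE]
}

#' Two-group differential-expression test per gene
#'
#' @param matrix An [expr_matrix()]. The second group level is treated as
#'   case; `log2fc` is case mean minus control mean.
#' @param method `"welch"` for the unequal-variance two-sample t;
#'   `"moderated"` for the empirical-Bayes moderated t (pooled per-gene
#'   variances shrunk toward a moments-estimated prior; see Details).
#' @details The moderated test models per-gene pooled variances s^2 (d
#'   residual df each) as scaled chi-square around a gene-specific variance,
#'   with an inverse-chi-square prior (s0^2, d0). The prior is estimated by
#'   matching the mean and variance of log s^2: the excess of var(log s^2)
#'   over trigamma(d/2) identifies d0 through the trigamma inverse, and the
#'   mean identifies s0^2. The posterior variance (d0*s0^2 + d*s^2)/(d0 + d)
#'   replaces s^2 in the t statistic, which gains d0 extra degrees of
#'   freedom. When log-variances show no excess dispersion, d0 is infinite
#'   and all genes share the common variance.
#' @return A `data.frame` (one row per gene, in input order) with columns
#'   `gene`, `log2fc`, `t_stat`, `p_value`, `direction` (`up`/`down`/`none`
#'   at the default thresholds of [screen_degs()]), `passes`.
#' @export
test_two_groups <- function(matrix, method = c("moderated", "welch")) {
  method <- match.arg(method)
  x <- matrix$values
  case <- matrix$groups == levels(matrix$groups)[2]
  x1 <- x[, !case, drop = FALSE] # control
  x2 <- x[, case, drop = FALSE]  # case
  n1 <- ncol(x1)
  n2 <- ncol(x2)

  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  log2fc <- m2 - m1

  if (method == "welch") {
    se2 <- v1 / n1 + v2 / n2
    t_stat <- log2fc / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * pt(-abs(t_stat), df)
  } else {
    d <- n1 + n2 - 2
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d
    fit <- fit_variance_prior(s2, d)
    s2_post <- if (is.finite(fit$d0)) {
      (fit$d0 * fit$s0_sq + d * s2) / (fit$d0 + d)
    } else {
      rep(fit$s0_sq, length(s2))
    }
    t_stat <- log2fc / sqrt(s2_post * (1 / n1 + 1 / n2))
    df_total <- min(fit$d0 + d, .Machine$double.xmax)
    p <- 2 * pt(-abs(t_stat), df_total)
  }

  constant <- (v1 + v2) == 0
  if (any(constant)) {
    warning(sum(constant), " constant gene(s): p set to 1", call. = FALSE)
    t_stat[constant] <- 0
    p[constant] <- 1
  }

  out <- data.frame(
    gene = rownames(x), log2fc = log2fc, t_stat = t_stat, p_value = p,
    stringsAsFactors = FALSE, row.names = NULL
  )
  passes <- abs(out$log2fc) > 1 & out$p_value < 0.05
  out$direction <- ifelse(passes, ifelse(out$log2fc > 0, "up", "down"),
                          "none")
  out$passes <- passes
  out
}

# Method-of-moments fit of the inverse-chi-square variance prior (d0, s0^2)
# from per-gene pooled variances s2 with d residual df each. Works on
# z = log(s2): E z = log sigma^2 + digamma(d/2) - log(d/2),
# Var z = trigamma(d/2) + trigamma(d0/2) across genes.
fit_variance_prior <- function(s2, d) {
  ok <- s2 > 0
  if (sum(ok) < 2L) {
    return(list(d0 = Inf, s0_sq = mean(s2)))
  }
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  excess <- mean((e - mean(e))^2) * length(e) / (length(e) - 1) -
    trigamma(d / 2)
  if (excess <= 0) {
    return(list(d0 = Inf, s0_sq = exp(mean(e))))
  }
  d0 <- 2 * trigamma_inverse(excess)
  s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

# Newton inversion of trigamma on (0, Inf); trigamma is convex decreasing,
# the iteration below converges monotonically from the large-x asymptote.
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Screen a DEG table at fold-change and p-value thresholds
#'
#' Both comparisons are strict: a gene passes when `|log2fc| >
#' fc_threshold` and `p_value < p_threshold`, so boundary values are
#' excluded.
#'
#' @param deg Output of [test_two_groups()].
#' @param fc_threshold Positive log2 fold-change threshold (default 1.0).
#' @param p_threshold P-value threshold in (0, 1] (default 0.05).
#' @return A list with character vectors `up` and `down` (disjoint; their
#'   union is the passing set).
#' @export
screen_degs <- function(deg, fc_threshold = 1.0, p_threshold = 0.05) {
  if (fc_threshold <= 0) stop_invalid("`fc_threshold` must be positive")
  if (p_threshold <= 0) stop_invalid("`p_threshold` must be positive")
  pass <- abs(deg$log2fc) > fc_threshold & deg$p_value < p_threshold
  list(
    up = sort(deg$gene[pass & deg$log2fc > 0]),
    down = sort(deg$gene[pass & deg$log2fc < 0])
  )
}
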