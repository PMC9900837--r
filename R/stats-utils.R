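#' Holm-Sidak step-down multiple-testing correction
#'
#' Sorted raw p-values p_(1) <= ... <= p_(m) are adjusted as
#' 1 - (1 - p_(i))^(m - i + 1) with a cumulative maximum to enforce
#' monotonicity; adjusted values are returned in the input order.
#'
#' @param p numeric vector of raw p-values
#' @return adjusted p-values, same length and order as \code{p}
#' @export
holm_sidak <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' F1 score from confusion counts
#' @param tp,fp,fn true positives, false positives, false negatives
#' @export
f1_from_confusion <- function(tp, fp, fn) {
  2 * tp / (2 * tp + fp + fn)
}

#' Minimal SMOTE oversampling for a two-class problem
#'
#' New minority samples are linear interpolations between a minority
#' point and one of its k nearest minority neighbours. Used to balance
#' classes before random-forest feature-importance fits.
#'
#' @param x numeric matrix (rows = samples)
#' @param y logical or factor with two levels; minority class oversampled
#'   until balanced
#' @param k neighbours (default 5, capped at minority size - 1)
#' @return list \code{x}, \code{y} with synthetic rows appended
#' @export
smote_balance <- function(x, y, k = 5) {
  y <- factor(y)
  stopifnot(nlevels(y) == 2)
  tab <- table(y)
  minority <- names(tab)[which.min(tab)]
  n_min <- min(tab); n_maj <- max(tab)
  need <- n_maj - n_min
  if (need == 0 || n_min < 2) return(list(x = x, y = y))
  xm <- x[y == minority, , drop = FALSE]
  k <- min(k, nrow(xm) - 1)
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
  i <- sample(nrow(xm), need, replace = TRUE)
  j <- nn[cbind(i, sample(k, need, replace = TRUE))]
  lam <- stats::runif(need)
  synth <- xm[i, , drop = FALSE] + lam * (xm[j, , drop = FALSE] - xm[i, , drop = FALSE])
  list(x = rbind(x, synth), y = factor(c(as.character(y), rep(minority, need))))
}

#' Davies-Bouldin index of a clustering (lower is better)
#' @param x numeric matrix (rows = samples)
#' @param labels cluster labels (>= 2 clusters with >= 1 member)
#' @export
davies_bouldin <- function(x, labels) {
  labels <- as.integer(factor(labels))
  ks <- sort(unique(labels))
  cent <- t(vapply(ks, function(k) colMeans(x[labels == k, , drop = FALSE]),
                   numeric(ncol(x))))
  s <- vapply(ks, function(k) {
    xi <- x[labels == k, , drop = FALSE]
    mean(sqrt(rowSums((xi - matrix(cent[k, ], nrow(xi), ncol(x), byrow = TRUE))^2)))
  }, numeric(1))
  m <- as.matrix(stats::dist(cent))
  r <- vapply(seq_along(ks), function(i) {
    max(vapply(seq_along(ks)[-i], function(j) (s[i] + s[j]) / m[i, j], numeric(1)))
  }, numeric(1))
  mean(r)
}

#' Simple grouped statistics with exact inputs logged
#'
#' Thin, uniform wrappers over standard tests used throughout the
#' connectivity analyses: Spearman correlation against depth, one-way
#' ANOVA across groups, two-sample Kolmogorov-Smirnov, and Welch t-test.
#'
#' @param values numeric vector
#' @param groups grouping vector (for anova/ks/t) or depth vector (for
#'   spearman)
#' @param test one of "spearman_depth", "anova", "ks", "t"
#' @return list with \code{statistic}, \code{p}, and the inputs
#' @export
simple_stats <- function(values, groups, test = c("spearman_depth", "anova", "ks", "t")) {
  test <- match.arg(test)
  if (length(values) < 3) stop("degenerate input: need at least 3 observations")
  out <- switch(test,
    spearman_depth = {
      ct <- stats::cor.test(values, groups, method = "spearman", exact = FALSE)
      list(statistic = unname(ct$estimate), p = ct$p.value)
    },
    anova = {
      g <- factor(groups)
      if (nlevels(g) < 2) stop("degenerate input: need >= 2 groups")
      fit <- stats::aov(values ~ g)
      sm <- summary(fit)[[1]]
      list(statistic = sm$`F value`[1], p = sm$`Pr(>F)`[1])
    },
    ks = {
      g <- factor(groups)
      if (nlevels(g) != 2) stop("KS test needs exactly 2 groups")
      sp <- split(values, g)
      ct <- suppressWarnings(stats::ks.test(sp[[1]], sp[[2]]))
      list(statistic = unname(ct$statistic), p = ct$p.value)
    },
    t = {
      g <- factor(groups)
      if (nlevels(g) != 2) stop("t test needs exactly 2 groups")
      sp <- split(values, g)
      ct <- stats::t.test(sp[[1]], sp[[2]])
      list(statistic = unname(ct$statistic), p = ct$p.value)
    })
  c(out, list(test = test, values = values, groups = groups))
}

#' Percentile bootstrap confidence interval for a statistic
#' @param x numeric vector
#' @param stat function of a numeric vector (default median)
#' @param n_boot bootstrap resamples (default 1000)
#' @param conf confidence level (default 0.95)
#' @return list \code{estimate}, \code{lower}, \code{upper}
#' @export
bootstrap_ci <- function(x, stat = stats::median, n_boot = 1000, conf = 0.95) {
  if (length(x) < 2) stop("CI undefined for groups of size < 2")
  est <- stat(x)
  bs <- vapply(seq_len(n_boot), function(i) stat(sample(x, replace = TRUE)), numeric(1))
  a <- (1 - conf) / 2
  q <- stats::quantile(bs, c(a, 1 - a), names = FALSE)
  list(estimate = est, lower = q[1], upper = q[2])
}

## deterministic per-unit substream seed (kept below 2^31)
substream_seed <- function(seed, i) {
  (as.numeric(seed) * 48271 + as.numeric(i) * 16807) %% 2147483647
}
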