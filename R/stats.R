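# Pixel-wise group statistics over aligned projection-map stacks and
# scalar-level statistics (Grubbs outlier exclusion, normality-gated test
# selection, Pearson correlation).

#' Stack aligned projection maps of one group
#'
#' @param maps list of aligned `projection_map`s (identical grids)
#' @param group,timepoint optional labels carried along
#' @return object of class `map_stack`
#' @export
map_stack <- function(maps, group = NA_character_, timepoint = NA_character_) {
  stopifnot(length(maps) >= 1)
  d <- dim(maps[[1]]$values)
  for (m in maps) {
    stopifnot(inherits(m, "projection_map"), identical(dim(m$values), d))
  }
  arr <- array(NA_real_, c(d, length(maps)))
  for (i in seq_along(maps)) arr[, , i] <- maps[[i]]$values
  valid <- Reduce(`&`, lapply(maps, `[[`, "valid"))
  structure(list(data = arr, valid = valid, n = length(maps),
                 grid_z = maps[[1]]$grid_z, grid_theta = maps[[1]]$grid_theta,
                 group = group, timepoint = timepoint),
            class = "map_stack")
}

#' @export
print.map_stack <- function(x, ...) {
  cat("map_stack:", x$n, "animals,", paste(dim(x$data)[1:2], collapse = " x "),
      "grid", if (!is.na(x$group)) paste0("(", x$group,
      if (!is.na(x$timepoint)) paste0(", ", x$timepoint), ")") else "", "\n")
  invisible(x)
}

#' Pixel-wise two-group comparison of map stacks
#'
#' Per pixel: group means, SDs, the difference (a - b), and a two-sided
#' p-value. The default test is the unpaired Welch t-test (per-pixel
#' normality testing at n of 4-6 animals is uninformative); an exact-free
#' Mann-Whitney option is available. Pixels invalid in either group, or
#' with zero variance in both groups, carry NA p-values.
#'
#' @param a,b `map_stack`s with identical grids, each >= 2 animals
#' @param test `"welch_t"` (default) or `"mann_whitney"`
#' @param alpha significance threshold for the significance mask
#' @return object of class `comparison_maps`: matrices `mean_a`, `mean_b`,
#'   `sd_a`, `sd_b`, `difference`, `p_map`, logical `sig_mask`, plus
#'   `sig_fraction` (fraction of valid pixels with p < alpha, a gauge of
#'   inflation given that no multiplicity correction is applied)
#' @export
pixelwise_compare <- function(a, b, test = c("welch_t", "mann_whitney"),
                              alpha = 0.05) {
  test <- match.arg(test)
  stopifnot(inherits(a, "map_stack"), inherits(b, "map_stack"))
  if (!identical(dim(a$data)[1:2], dim(b$data)[1:2]))
    stop("map stacks have different grid shapes")
  if (a$n < 2 || b$n < 2) stop("each group needs at least 2 animals")
  valid <- a$valid & b$valid
  d <- dim(a$data)[1:2]
  n1 <- a$n; n2 <- b$n
  m1 <- rowMeans(a$data, dims = 2); m2 <- rowMeans(b$data, dims = 2)
  v1 <- rowSums((a$data - as.vector(m1))^2, dims = 2) / (n1 - 1)
  v2 <- rowSums((b$data - as.vector(m2))^2, dims = 2) / (n2 - 1)

  if (test == "welch_t") {
    se2 <- v1 / n1 + v2 / n2
    tstat <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * stats::pt(-abs(tstat), df)
    p[se2 == 0] <- NA_real_  # zero variance: test undefined
  } else {
    p <- matrix(NA_real_, d[1], d[2])
    idx <- which(valid)
    x1 <- matrix(a$data, prod(d), n1)
    x2 <- matrix(b$data, prod(d), n2)
    for (i in idx) {
      if (stats::sd(c(x1[i, ], x2[i, ])) == 0) next
      p[i] <- suppressWarnings(
        stats::wilcox.test(x1[i, ], x2[i, ], exact = FALSE)$p.value)
    }
  }
  p[!valid] <- NA_real_
  diffm <- m1 - m2
  diffm[!valid] <- NA_real_
  sig <- !is.na(p) & p < alpha
  structure(list(mean_a = m1, mean_b = m2, sd_a = sqrt(v1), sd_b = sqrt(v2),
                 difference = diffm, p_map = p, sig_mask = sig,
                 valid = valid, test = test, alpha = alpha,
                 sig_fraction = mean(sig[valid])),
            class = "comparison_maps")
}

#' @export
print.comparison_maps <- function(x, ...) {
  cat("comparison_maps (", x$test, "): ",
      round(100 * x$sig_fraction, 1), "% of valid pixels p < ", x$alpha,
      ", mean difference ", signif(mean(x$difference[x$valid]), 4), "\n",
      sep = "")
  invisible(x)
}

#' Inter-animal dispersion summary of a map stack
#'
#' Pixel-wise SD over animals, summarized spatially by the median and
#' quartiles over valid pixels.
#'
#' @param stack a `map_stack` with >= 2 animals
#' @return list: `median_sd`, `lower_quartile_sd`, `upper_quartile_sd`
#' @export
dispersion_summary <- function(stack) {
  stopifnot(inherits(stack, "map_stack"))
  if (stack$n < 2) stop("dispersion needs at least 2 animals")
  m <- rowMeans(stack$data, dims = 2)
  sdm <- sqrt(rowSums((stack$data - as.vector(m))^2, dims = 2) / (stack$n - 1))
  if (!any(stack$valid)) stop("no valid pixels")
  q <- stats::quantile(sdm[stack$valid], c(0.25, 0.5, 0.75), names = FALSE)
  list(median_sd = q[2], lower_quartile_sd = q[1], upper_quartile_sd = q[3])
}

#' Grubbs test for a single outlier
#'
#' @param x numeric vector (n >= 3)
#' @param alpha significance level (default 0.05)
#' @return list: `outlier_index` (NA if none), `g` (statistic),
#'   `critical` (two-sided critical value from the t quantile)
#' @export
grubbs_test <- function(x, alpha = 0.05) {
  n <- length(x)
  stopifnot(n >= 3)
  s <- stats::sd(x)
  if (s == 0) return(list(outlier_index = NA_integer_, g = 0, critical = Inf))
  dev <- abs(x - mean(x))
  g <- max(dev) / s
  tq <- stats::qt(1 - alpha / (2 * n), n - 2)
  crit <- (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
  list(outlier_index = if (g > crit) which.max(dev) else NA_integer_,
       g = g, critical = crit)
}

# iterative Grubbs exclusion, capped to guard small groups
remove_outliers <- function(x, alpha = 0.05, max_remove = 2L) {
  removed <- integer(0)
  idx <- seq_along(x)
  while (length(removed) < max_remove && length(x) >= 3) {
    g <- grubbs_test(x, alpha)
    if (is.na(g$outlier_index)) break
    removed <- c(removed, idx[g$outlier_index])
    x <- x[-g$outlier_index]
    idx <- idx[-g$outlier_index]
  }
  list(x = x, removed = removed)
}

#' Scalar group test with outlier exclusion and normality gating
#'
#' Reproduces the scalar testing cascade: iterative Grubbs outlier
#' exclusion per group (alpha = 0.05, at most 2 removals), Shapiro-Wilk
#' normality gate on every group, then an unpaired t-test / ANOVA when
#' all groups pass, or Mann-Whitney / Kruskal-Wallis when any fails.
#' Groups too small for the gate (n < 3) fall back to the non-parametric
#' branch.
#'
#' @param groups list of numeric vectors (2 for a two-group design, more
#'   for a multi-group design)
#' @param alpha significance level for the Grubbs and Shapiro-Wilk gates
#' @return list: `test` (name used), `statistic`, `p`, `removed`
#'   (per-group indices of excluded outliers), `normal` (gate outcome)
#' @export
scalar_test <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2)
  cleaned <- lapply(groups, remove_outliers, alpha = alpha)
  xs <- lapply(cleaned, `[[`, "x")
  gate_ok <- all(vapply(xs, length, 1L) >= 3)
  normal <- gate_ok && all(vapply(xs, function(v) {
    if (stats::sd(v) == 0) return(TRUE)  # degenerate: treat as normal
    stats::shapiro.test(v)$p.value >= alpha
  }, logical(1)))
  two <- length(xs) == 2
  if (normal) {
    if (two) {
      ht <- stats::t.test(xs[[1]], xs[[2]])
      out <- list(test = "unpaired_t", statistic = unname(ht$statistic),
                  p = ht$p.value)
    } else {
      dat <- data.frame(y = unlist(xs),
                        g = factor(rep(seq_along(xs), lengths(xs))))
      av <- summary(stats::aov(y ~ g, dat))[[1]]
      out <- list(test = "anova", statistic = av$`F value`[1],
                  p = av$`Pr(>F)`[1])
    }
  } else {
    if (two) {
      ht <- suppressWarnings(stats::wilcox.test(xs[[1]], xs[[2]],
                                                exact = FALSE))
      out <- list(test = "mann_whitney", statistic = unname(ht$statistic),
                  p = ht$p.value)
    } else {
      dat <- data.frame(y = unlist(xs),
                        g = factor(rep(seq_along(xs), lengths(xs))))
      ht <- stats::kruskal.test(y ~ g, dat)
      out <- list(test = "kruskal_wallis", statistic = unname(ht$statistic),
                  p = ht$p.value)
    }
  }
  out$removed <- lapply(cleaned, `[[`, "removed")
  out$normal <- normal
  out
}

#' Pearson correlation with listwise deletion
#'
#' @param x,y equal-length numeric vectors (pairs with any NA dropped)
#' @return list: `r`, `p` (two-sided), `n` (pairs used)
#' @export
correlate_metrics <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}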