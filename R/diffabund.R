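#' Median-of-ratios size factors
#'
#' Per-sample sequencing-depth normalization in the DESeq lineage: each
#' sample's factor is the median, over guides, of its counts divided by the
#' guide's geometric mean across samples; guides with a zero anywhere are
#' excluded from the reference. Factors are rescaled to geometric mean 1 so
#' normalized counts stay on the scale of the raw data.
#'
#' @param counts integer matrix (guides x samples) or a [screen_counts()].
#' @param pseudo_reference if `TRUE`, the geometric-mean reference for each
#'   guide is computed over its positive counts only, so guides with
#'   sporadic zeros still inform the median (useful for severely
#'   bottlenecked samples where no guide is positive everywhere).
#' @return numeric vector of positive size factors, named by sample.
#' @export
estimate_size_factors <- function(counts, pseudo_reference = FALSE) {
  m <- if (inherits(counts, "screen_counts")) counts$counts else as.matrix(counts)
  stopifnot(ncol(m) >= 1L, all(m >= 0))
  logm <- log(m)
  if (pseudo_reference) {
    logm[!is.finite(logm)] <- NA
    loggeo <- rowMeans(logm, na.rm = TRUE)
    usable <- is.finite(loggeo)
  } else {
    loggeo <- rowMeans(logm)
    usable <- is.finite(loggeo)  # rows positive in every sample
  }
  if (!any(usable)) {
    stop("no guide has nonzero counts in all samples; ",
         "rerun with pseudo_reference = TRUE")
  }
  sf <- vapply(seq_len(ncol(m)), function(s) {
    ratio <- exp(logm[usable, s] - loggeo[usable])
    stats::median(ratio[is.finite(ratio)])
  }, numeric(1))
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- colnames(m)
  sf
}

#' Total-count size factors
#'
#' Simple library-size normalization (column sums scaled to geometric mean
#' 1), provided for comparison with [estimate_size_factors()].
#'
#' @inheritParams estimate_size_factors
#' @return numeric vector of positive size factors.
#' @export
total_count_size_factors <- function(counts) {
  m <- if (inherits(counts, "screen_counts")) counts$counts else as.matrix(counts)
  sf <- colSums(m)
  stopifnot(all(sf > 0))
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- colnames(m)
  sf
}

#' Estimate NB dispersions with trend shrinkage
#'
#' Per-guide overdispersion alpha in \eqn{Var = \mu + \alpha\mu^2} is first
#' estimated by method of moments on normalized counts from the pooled
#' within-group variance, \eqn{\hat\alpha = (s^2 - c\bar\mu)/(\bar\mu^2 -
#' s^2/n)} truncated at 0, where \eqn{c\bar\mu} is the shot-noise term and
#' the \eqn{s^2/n} denominator correction removes the upward bias of
#' \eqn{\bar\mu^2} as an estimate of \eqn{\mu^2}. A mean-dispersion trend
#' \eqn{\alpha(\mu) = a_1/\mu + a_0} is then fitted by least squares
#' (mean-unbiased under the skewed sampling noise of the raw estimates),
#' and the final dispersion is a weighted blend of raw and trend. With the
#' few replicates typical of screens the per-guide estimates are very
#' noisy, so most of the weight goes to the trend; the blend keeps some
#' adaptivity for guides whose dispersion genuinely departs from it.
#'
#' @param counts matrix or [screen_counts()].
#' @param size_factors from [estimate_size_factors()].
#' @param group factor/vector of two group labels, one per sample. With no
#'   replication in both groups the trend-only dispersion is used, with a
#'   warning.
#' @param raw_weight weight on the per-guide raw estimate in the blend
#'   (default 0.25; the remainder goes to the trend).
#' @return list of class `dispersion_model` with `raw`, `trend`, `final`
#'   (per-guide alphas), `coef` (trend coefficients a0, a1) and `raw_weight`.
#' @export
estimate_dispersions <- function(counts, size_factors, group,
                                 raw_weight = 0.25) {
  m <- if (inherits(counts, "screen_counts")) counts$counts else as.matrix(counts)
  stopifnot(length(size_factors) == ncol(m), ncol(m) >= 2L,
            length(group) == ncol(m), raw_weight >= 0, raw_weight <= 1)
  group <- as.factor(group)
  q <- sweep(m, 2L, size_factors, "/")
  mu <- rowMeans(q)

  tab <- table(group)
  replicated <- any(tab >= 2L)
  if (!replicated) {
    warning("no replicated group; using trend-only dispersions")
    raw_weight <- 0
  }
  # pooled within-group variance so real fold changes do not inflate alpha
  s2 <- numeric(nrow(m))
  df <- 0L
  for (g in levels(group)) {
    idx <- which(group == g)
    if (length(idx) >= 2L) {
      qg <- q[, idx, drop = FALSE]
      s2 <- s2 + rowSums((qg - rowMeans(qg))^2)
      df <- df + length(idx) - 1L
    }
  }
  if (df > 0L) s2 <- s2 / df else s2 <- mu  # Poisson fallback
  # moment variance on normalized scale: E s2 ~ mu * mean(1/sf) + alpha mu^2;
  # mu^2 - s2/n corrects E[mu_hat^2] = mu^2 + var(mu_hat)
  shot <- mu * mean(1 / size_factors)
  denom <- pmax(mu^2 - s2 / ncol(m), 0.2 * mu^2)
  raw <- pmax(0, (s2 - shot) / denom)
  raw[!is.finite(raw)] <- 0
  raw <- pmin(raw, 20)  # guard against pathological low-count estimates

  use <- is.finite(mu) & mu >= 1
  if (sum(use) >= 3L) {
    x <- 1 / mu[use]
    cf <- stats::lm.fit(cbind(1, x), raw[use])$coefficients
    cf[is.na(cf)] <- 0
  } else {
    cf <- c(mean(raw[use]), 0)
  }
  a <- cf
  trend <- pmax(1e-8, a[1] + a[2] / pmax(mu, 1e-8))
  final <- pmax(0, raw_weight * raw + (1 - raw_weight) * trend)
  structure(list(raw = raw, trend = trend, final = final,
                 coef = c(a0 = unname(a[1]), a1 = unname(a[2])),
                 raw_weight = raw_weight, mu = mu),
            class = "dispersion_model")
}

# Vectorized IRLS for the two-group NB GLM with log link and log(sf)
# offsets, identical design for every guide. Returns beta1 (log fold
# change, treated vs control) and its Wald SE per guide.
nb_glm_two_group <- function(m, size_factors, treated, alpha, maxit = 30L) {
  t_ind <- as.numeric(treated)           # 0/1 per sample
  off <- matrix(log(size_factors), nrow(m), ncol(m), byrow = TRUE)
  mean_c <- rowMeans(sweep(m, 2L, size_factors, "/")[, !treated, drop = FALSE])
  mean_t <- rowMeans(sweep(m, 2L, size_factors, "/")[, treated, drop = FALSE])
  beta0 <- log(pmax(mean_c, 1e-8))
  beta1 <- log(pmax(mean_t, 1e-8)) - beta0
  tmat <- matrix(t_ind, nrow(m), ncol(m), byrow = TRUE)
  for (it in seq_len(maxit)) {
    eta <- beta0 + beta1 * tmat + off
    mu <- pmin(exp(eta), 1e12)
    w <- mu / (1 + alpha * mu)
    z <- (eta - off) + (m - mu) / mu
    a_ <- rowSums(w)
    b_ <- rowSums(w * tmat)
    r1 <- rowSums(w * z)
    r2 <- rowSums(w * z * tmat)
    denom0 <- pmax(a_ - b_, 1e-12)
    new0 <- (r1 - r2) / denom0
    new1 <- r2 / pmax(b_, 1e-12) - new0
    step0 <- pmin(pmax(new0 - beta0, -3), 3)
    step1 <- pmin(pmax(new1 - beta1, -3), 3)
    beta0 <- beta0 + step0
    beta1 <- beta1 + step1
    if (max(abs(step0), abs(step1)) < 1e-10) break
  }
  eta <- beta0 + beta1 * tmat + off
  mu <- pmin(exp(eta), 1e12)
  w <- mu / (1 + alpha * mu)
  a_ <- rowSums(w)
  b_ <- rowSums(w * tmat)
  se <- sqrt(a_ / pmax(b_ * (a_ - b_), 1e-300))
  list(beta1 = beta1, se = se)
}

#' Per-guide negative-binomial Wald test
#'
#' Fits, for every guide, a two-group NB generalized linear model with log
#' link and log size-factor offsets at the given fixed dispersions, and
#' tests the group coefficient with a Wald statistic against the standard
#' normal reference. The reported `log2fc` is the descriptive log2 ratio of
#' group mean normalized counts with a 0.5 pseudo-count (always finite);
#' the test statistic comes from the GLM coefficient. Guides with all-zero
#' counts in both groups are reported with `log2fc = 0`, `p_value = 1` and
#' flagged in `all_zero`.
#'
#' @param counts matrix or [screen_counts()].
#' @param size_factors from [estimate_size_factors()].
#' @param dispersions a `dispersion_model` or numeric vector of per-guide
#'   alphas.
#' @param group two-group label vector, one per sample.
#' @param treated_level label of the treated group (default: the second
#'   level of `factor(group)`).
#' @return data.frame with `sgrna_id`, `base_mean`, `log2fc`, `p_value`,
#'   `treated_raw_count` (max raw count in the treated group), `stat`,
#'   `all_zero`.
#' @export
nb_wald_test <- function(counts, size_factors, dispersions, group,
                         treated_level = NULL) {
  m <- if (inherits(counts, "screen_counts")) counts$counts else as.matrix(counts)
  group <- as.factor(group)
  stopifnot(nlevels(group) == 2L, length(group) == ncol(m),
            length(size_factors) == ncol(m))
  if (is.null(treated_level)) treated_level <- levels(group)[2L]
  stopifnot(treated_level %in% levels(group))
  treated <- group == treated_level
  stopifnot(any(treated), any(!treated))
  alpha <- if (inherits(dispersions, "dispersion_model")) {
    dispersions$final
  } else {
    rep_len(dispersions, nrow(m))
  }

  q <- sweep(m, 2L, size_factors, "/")
  base_mean <- rowMeans(q)
  mean_c <- rowMeans(q[, !treated, drop = FALSE])
  mean_t <- rowMeans(q[, treated, drop = FALSE])
  log2fc <- log2((mean_t + 0.5) / (mean_c + 0.5))

  fit <- nb_glm_two_group(m, size_factors, treated, alpha)
  stat <- fit$beta1 / fit$se
  p <- 2 * stats::pnorm(-abs(stat))
  p <- pmin(1, pmax(p, 1e-300))

  all_zero <- rowSums(m) == 0L
  log2fc[all_zero] <- 0
  p[all_zero] <- 1
  stat[all_zero] <- 0

  data.frame(
    sgrna_id = if (!is.null(rownames(m))) rownames(m) else
      sprintf("sg%06d", seq_len(nrow(m))),
    base_mean = base_mean,
    log2fc = log2fc,
    p_value = p,
    treated_raw_count = apply(m[, treated, drop = FALSE], 1L, max),
    stat = stat,
    all_zero = all_zero,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Fit per-guide differential abundance for one screen comparison
#'
#' The main fitting function of the package: given a screen count matrix
#' and a treated/control condition pair, it estimates median-of-ratios size
#' factors, trend-shrunken NB dispersions and per-guide Wald statistics,
#' and returns a classed fit with the usual accessor methods (`print`,
#' `summary`, `coef`, `plot`).
#'
#' @param counts a [screen_counts()] object.
#' @param treated,control condition labels in `counts$sample_meta$condition`.
#' @param normalization `"median-ratio"` (default) or `"total"`.
#' @param pseudo_reference passed to [estimate_size_factors()].
#' @param raw_weight passed to [estimate_dispersions()].
#' @return An object of class `screen_da`: list with `table` (the
#'   [nb_wald_test()] data.frame), `size_factors`, `dispersions`,
#'   `treated`, `control`, `samples`.
#' @export
screen_da <- function(counts, treated, control,
                      normalization = c("median-ratio", "total"),
                      pseudo_reference = FALSE, raw_weight = 0.5) {
  stopifnot(inherits(counts, "screen_counts"))
  normalization <- match.arg(normalization)
  cond <- counts$sample_meta$condition
  keep <- cond %in% c(treated, control)
  if (!any(cond == treated)) stop("no sample with condition '", treated, "'")
  if (!any(cond == control)) stop("no sample with condition '", control, "'")
  m <- counts$counts[, keep, drop = FALSE]
  group <- factor(cond[keep], levels = c(control, treated))
  sf <- if (normalization == "median-ratio") {
    estimate_size_factors(m, pseudo_reference = pseudo_reference)
  } else {
    total_count_size_factors(m)
  }
  disp <- estimate_dispersions(m, sf, group, raw_weight = raw_weight)
  tab <- nb_wald_test(m, sf, disp, group, treated_level = treated)
  structure(list(table = tab, size_factors = sf, dispersions = disp,
                 treated = treated, control = control,
                 samples = colnames(m)),
            class = "screen_da")
}

#' @export
print.screen_da <- function(x, ...) {
  cat("NB differential abundance: ", x$treated, " vs ", x$control, " (",
      length(x$samples), " samples, ", nrow(x$table), " guides)\n", sep = "")
  cat("  size factors: ",
      paste(names(x$size_factors), round(x$size_factors, 3), sep = "=",
            collapse = ", "), "\n", sep = "")
  cat("  guides with p < 0.05: ", sum(x$table$p_value < 0.05),
      "; median dispersion: ",
      signif(stats::median(x$dispersions$final), 3), "\n", sep = "")
  invisible(x)
}

#' @method summary screen_da
#' @export
summary.screen_da <- function(object, ...) {
  tab <- object$table
  out <- list(comparison = paste(object$treated, "vs", object$control),
              n_guides = nrow(tab),
              log2fc = summary(tab$log2fc),
              n_enriched = sum(tab$log2fc > 0 & tab$p_value < 0.05),
              n_depleted = sum(tab$log2fc < 0 & tab$p_value < 0.05),
              top = utils::head(tab[order(tab$p_value,
                                          -abs(tab$log2fc)), ], 10L))
  class(out) <- "summary.screen_da"
  out
}

#' @export
print.summary.screen_da <- function(x, ...) {
  cat("Comparison:", x$comparison, "—", x$n_guides, "guides\n")
  cat("Enriched (p<0.05, lfc>0):", x$n_enriched,
      "  Depleted:", x$n_depleted, "\n")
  cat("log2 fold change:\n")
  print(x$log2fc)
  cat("Top guides by p-value:\n")
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' @method coef screen_da
#' @export
coef.screen_da <- function(object, ...) {
  stats::setNames(object$table$log2fc, object$table$sgrna_id)
}

#' MA plot of a differential-abundance fit
#'
#' @param x a [screen_da()] fit.
#' @param alpha significance level used to colour guides (default 0.05).
#' @param ... passed to [graphics::plot()].
#' @method plot screen_da
#' @export
plot.screen_da <- function(x, alpha = 0.05, ...) {
  tab <- x$table
  sig <- tab$p_value < alpha
  graphics::plot(log10(tab$base_mean + 1), tab$log2fc,
                 pch = 20, cex = 0.4,
                 col = ifelse(sig, "firebrick", "grey50"),
                 xlab = "log10 mean normalized count",
                 ylab = "log2 fold change",
                 main = paste(x$treated, "vs", x$control), ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
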