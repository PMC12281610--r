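#' Median-of-ratios size factors
#'
#' Each sample's factor is the median ratio of its counts to the
#' geometric-mean reference gene profile, computed over genes with
#' all-positive counts. Falls back to relative library size (with a
#' warning) when no gene is positive everywhere.
#'
#' @param counts Genes x samples integer matrix.
#' @return Named per-sample size factors.
#' @export
size_factors <- function(counts) {
  logg <- rowMeans(log(counts))
  use <- is.finite(logg)
  if (!any(use)) {
    warning("no gene with all-positive counts; ",
            "falling back to library-size factors")
    cs <- colSums(counts)
    return(cs / exp(mean(log(cs))))
  }
  sf <- apply(counts, 2L, function(cnt) {
    exp(median(log(cnt[use]) - logg[use]))
  })
  setNames(sf, colnames(counts))
}

# Gene-wise NB dispersions: method-of-moments on normalized counts using
# the within-condition pooled variance, floored at 1e-8, then shrunk half
# way towards the a + b/mean trend fitted by least squares on the raw
# gene-wise values.
estimate_dispersions <- function(counts, sf, condition) {
  norm <- sweep(counts, 2L, sf, "/")
  m <- rowMeans(norm)
  groups <- split(seq_along(condition), condition)
  ssq <- 0
  df <- 0
  for (g in groups) {
    if (length(g) >= 2L) {
      ssq <- ssq + apply(norm[, g, drop = FALSE], 1L, var) *
        (length(g) - 1L)
      df <- df + length(g) - 1L
    }
  }
  v <- ssq / df
  raw <- (v - m) / m^2
  floored <- pmax(raw, 1e-8)
  trend <- if (sum(is.finite(raw)) >= 3L && length(unique(m)) >= 2L) {
    fit <- tryCatch(lm(raw ~ I(1 / m)), error = function(e) NULL)
    if (is.null(fit)) rep(mean(floored), length(m)) else
      pmax(predict(fit, data.frame(m = m)), 1e-8)
  } else {
    rep(mean(floored), length(m))
  }
  list(raw = raw, trend = trend,
       final = pmax(0.5 * floored + 0.5 * trend, 1e-8))
}

#' Differential spacer acquisition between conditions
#'
#' Negative binomial Wald test of treated versus control spacer counts,
#' gene by gene: (1) median-of-ratios size factors; (2) gene-wise
#' method-of-moments dispersions shrunk half way towards an `a + b/mean`
#' trend; (3) an NB log-linear model `~ condition` per gene, fitted by
#' iteratively reweighted least squares with the size factors as offsets
#' and the shrunk dispersion held fixed; (4) a Wald test of the condition
#' coefficient against the standard normal; (5) Benjamini-Hochberg
#' adjustment across the tested genes. This follows the standard model
#' class for differential count analysis; it does not claim numerical
#' equality with any particular published implementation (its operating
#' characteristics are established by simulation instead, see the methods
#' vignette).
#'
#' @param counts Genes x samples integer matrix, already filtered with
#'   [filter_low_counts()].
#' @param condition Factor or character with values `control` / `treated`,
#'   one per sample, at least two samples each.
#' @return A data frame with columns `gene_id`, `base_mean`, `log2fc`
#'   (treated vs control), `se`, `wald_stat`, `pvalue`, `padj`. Genes with
#'   all-zero counts are excluded; their ids are attached as attribute
#'   `excluded`.
#' @export
diff_acquisition <- function(counts, condition) {
  condition <- as.character(condition)
  if (!all(condition %in% c("control", "treated"))) {
    stop("condition values must be 'control' or 'treated'")
  }
  if (length(condition) != ncol(counts)) {
    stop("condition length must match the number of samples")
  }
  if (any(table(factor(condition,
                       levels = c("control", "treated"))) < 2L)) {
    stop("each condition needs at least 2 samples")
  }
  cond <- factor(condition, levels = c("control", "treated"))
  zero <- rowSums(counts) == 0L
  excluded <- rownames(counts)[zero]
  counts <- counts[!zero, , drop = FALSE]
  if (!nrow(counts)) stop("no non-zero genes to test")
  sf <- size_factors(counts)
  disp <- estimate_dispersions(counts, sf, cond)
  norm <- sweep(counts, 2L, sf, "/")
  off <- log(sf)
  n <- nrow(counts)
  est <- se <- numeric(n)
  for (g in seq_len(n)) {
    y <- counts[g, ]
    fit <- suppressWarnings(tryCatch(
      glm(y ~ cond, offset = off,
          family = MASS::negative.binomial(theta = 1 / disp$final[g],
                                           link = "log"),
          control = glm.control(maxit = 100L)),
      error = function(e) NULL))
    if (is.null(fit)) {
      est[g] <- NA_real_; se[g] <- NA_real_
    } else {
      # dispersion fixed at 1: the NB variance is carried by theta
      co <- coef(summary(fit, dispersion = 1))
      est[g] <- co["condtreated", "Estimate"]
      se[g] <- co["condtreated", "Std. Error"]
    }
  }
  wald <- est / se
  pval <- 2 * pnorm(-abs(wald))
  res <- data.frame(gene_id = rownames(counts),
                    base_mean = rowMeans(norm),
                    log2fc = est / log(2), se = se / log(2),
                    wald_stat = wald, pvalue = pval,
                    padj = bh_adjust(pval),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "excluded") <- excluded
  attr(res, "size_factors") <- sf
  attr(res, "dispersions") <- disp$final
  res
}
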