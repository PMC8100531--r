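#' Median-of-ratios size factors
#'
#' Per-library scale factor: the median, over features positive in every
#' library, of the ratio between the feature's count and its geometric mean
#' across libraries.
#'
#' @param mat Numeric count matrix, features x libraries.
#' @return Numeric vector of size factors, one per column.
#' @export
size_factors <- function(mat) {
  mat <- as.matrix(mat)
  loggeo <- rowMeans(log(mat))
  ok <- is.finite(loggeo)
  if (!any(ok)) {
    stop("size factors undefined: no feature has nonzero counts in every ",
         "library", call. = FALSE)
  }
  apply(mat, 2, function(x) exp(median((log(x) - loggeo)[ok])))
}

#' Blind negative-binomial dispersion estimation with a fitted trend
#'
#' With a single library per condition, dispersion must be estimated
#' "blind": both libraries are treated as replicates of one pooled
#' pseudo-group. Per feature, a method-of-moments raw dispersion is
#' computed from the normalised counts, then a parametric mean-dispersion
#' trend `dispersion = a0 + a1 / mean` is fitted across features. Because
#' the two-value raw estimate is distributed as a scaled chi-square with
#' one degree of freedom, the trend is fitted by median (least absolute
#' deviation) regression of the unfloored raw values on `1/mean` and then
#' rescaled by the chi-square(1) median (0.4549): the median regression is
#' insensitive to the minority of genuinely differential features whose
#' between-condition shift masquerades as enormous biological variance,
#' and the rescaling makes the trend median-unbiased for the true
#' dispersion under the null.
#'
#' With `sharing_mode = "fit-only"` (default) the working per-feature
#' dispersion is the fitted trend value: this is the only mode under which
#' differential features remain testable at n = 1 vs 1, since their own
#' fold change inflates the raw estimate without bound. `"maximum"` takes
#' the larger of raw and fitted per feature and is strictly conservative;
#' with it, a blind raw estimate of a strongly differential feature
#' swallows the signal, so it is offered for exploration only.
#'
#' @param mat Count matrix, features x 2 libraries.
#' @param sf Size factors (default: computed from `mat`).
#' @param sharing_mode How raw and fitted dispersions combine.
#' @param min_dispersion Floor applied to the working dispersions.
#' @return List with `raw`, `fitted`, `final` per-feature dispersions and
#'   the trend `coefficients` (a0, a1).
#' @export
estimate_dispersions <- function(mat, sf = size_factors(mat),
                                 sharing_mode = c("fit-only", "maximum"),
                                 min_dispersion = 1e-8) {
  sharing_mode <- match.arg(sharing_mode)
  mat <- as.matrix(mat)
  norm <- sweep(mat, 2, sf, "/")
  m <- rowMeans(norm)
  v <- rowSums((norm - m)^2) / (ncol(norm) - 1L)
  xim <- mean(1 / sf)
  raw_unfloored <- ifelse(m > 0, (v - xim * m) / m^2, 0)
  raw_unfloored[!is.finite(raw_unfloored)] <- 0
  raw <- pmax(raw_unfloored, 0)
  fit_idx <- which(m > 0)
  chi1_median <- qchisq(0.5, df = 1)
  if (length(fit_idx) >= 10L) {
    # LAD regression via iteratively reweighted least squares
    y <- raw_unfloored[fit_idx]
    x <- 1 / m[fit_idx]
    fit <- lm(y ~ x)
    for (iter in seq_len(20L)) {
      w <- 1 / pmax(abs(y - fitted(fit)), 1e-8)
      fit <- lm(y ~ x, weights = w)
    }
    # under the null, median(raw) = chi1_median * (a0 + a1/m) +
    # (chi1_median - 1) * xim / m; invert for the trend coefficients
    a0 <- max(coef(fit)[1] / chi1_median, min_dispersion)
    a1 <- max((coef(fit)[2] + (1 - chi1_median) * xim) / chi1_median, 0)
  } else {
    a0 <- max(mean(raw[m > 0]), 0.1)
    a1 <- 0
  }
  fitted <- ifelse(m > 0, a0 + a1 / m, a0)
  final <- if (sharing_mode == "maximum") pmax(raw, fitted) else fitted
  final <- pmax(final, min_dispersion)
  list(raw = raw, fitted = fitted, final = final,
       coefficients = c(a0 = unname(a0), a1 = unname(a1)))
}

#' Two-sided exact negative-binomial test for one pair of counts
#'
#' Conditions on the total `ka + kb`: under the null hypothesis of equal
#' means, each library's count is NB with mean `(ka + kb) / 2` and the
#' given size (1/dispersion); the p-value is the total probability of all
#' splits `(a, b)` of the observed sum that are no more probable than the
#' observed split, renormalised over all splits.
#'
#' @param ka,kb Non-negative integer counts (fresh, frozen).
#' @param size NB size parameter (reciprocal dispersion).
#' @return p-value in `[0, 1]`; `1` when the total count is zero.
#' @export
nb_exact_test <- function(ka, kb, size) {
  stopifnot(ka >= 0, kb >= 0, size > 0)
  s <- ka + kb
  if (s == 0) return(1)
  mu <- s / 2
  lp <- dnbinom(0:s, mu = mu, size = size, log = TRUE) +
    dnbinom(s:0, mu = mu, size = size, log = TRUE)
  lp <- lp - max(lp)
  p_all <- exp(lp)
  p_obs <- p_all[ka + 1L]
  min(1, sum(p_all[p_all <= p_obs * (1 + 1e-8)]) / sum(p_all))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment; order-preserving with
#' monotonicity enforcement.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Differential piRNA expression between two libraries
#'
#' Full no-replicate pipeline: median-of-ratios normalisation, blind
#' dispersion estimation with a parametric trend, per-feature two-sided
#' exact NB test on the rounded normalised counts, BH adjustment, and
#' classification with strict thresholds (`padj < padj_cut` and
#' `|log2FC| > lfc_cut`). The fold change is frozen over fresh, computed on
#' normalised counts with a pseudocount of 1 on both sides.
#'
#' @param mat Count matrix with two columns (fresh, frozen); rownames are
#'   the piRNA sequences.
#' @param padj_cut Adjusted-p threshold (strict `<`).
#' @param lfc_cut Absolute log2 fold-change threshold (strict `>`).
#' @param pseudocount Added to both normalised counts in the fold change.
#' @return Tibble with `pirna_seq`, `norm_count_fresh`, `norm_count_frozen`,
#'   `log2fc`, `p`, `padj`, `call` (`up`, `down`, `ns`).
#' @export
de_table <- function(mat, padj_cut = 0.01, lfc_cut = 1, pseudocount = 1) {
  mat <- as.matrix(mat)
  stopifnot(ncol(mat) == 2L)
  sf <- size_factors(mat)
  norm <- sweep(mat, 2, sf, "/")
  disp <- estimate_dispersions(mat, sf)
  ka <- round(norm[, 1])
  kb <- round(norm[, 2])
  p <- vapply(seq_len(nrow(mat)), function(i) {
    nb_exact_test(ka[i], kb[i], size = 1 / disp$final[i])
  }, numeric(1))
  res <- tibble::tibble(
    pirna_seq = rownames(mat) %||% as.character(seq_len(nrow(mat))),
    norm_count_fresh = norm[, 1],
    norm_count_frozen = norm[, 2],
    log2fc = log2((norm[, 2] + pseudocount) / (norm[, 1] + pseudocount)),
    p = p,
    padj = bh_adjust(p)
  )
  res$call <- call_de(res, padj_cut, lfc_cut)$call
  res
}

#' Classify differential expression calls
#'
#' Strict thresholds: `up` iff `padj < padj_cut` and `log2fc > lfc_cut`;
#' `down` iff `padj < padj_cut` and `log2fc < -lfc_cut`; otherwise `ns`.
#'
#' @param res Tibble with columns `padj` and `log2fc`.
#' @param padj_cut,lfc_cut Thresholds (strict inequalities).
#' @return List with `call` (factor-free character vector), `up`, `down`
#'   (row subsets) and `counts` (`n_up`, `n_down`, `n_de`).
#' @export
call_de <- function(res, padj_cut = 0.01, lfc_cut = 1) {
  sig <- res$padj < padj_cut
  call <- ifelse(sig & res$log2fc > lfc_cut, "up",
                 ifelse(sig & res$log2fc < -lfc_cut, "down", "ns"))
  list(call = call,
       up = res[call == "up", , drop = FALSE],
       down = res[call == "down", , drop = FALSE],
       counts = list(n_up = sum(call == "up"), n_down = sum(call == "down"),
                     n_de = sum(call != "ns")))
}

#' Hierarchical clustering order for a DE piRNA heatmap
#'
#' Values are transformed as `log10(TPM + 1)` and clustered with Euclidean
#' distance and complete linkage; the leaf order is deterministic for a
#' given input.
#'
#' @param tpm Numeric TPM matrix (rows = DE piRNAs).
#' @return List with `order` (row order), `matrix` (transformed values) and
#'   `hclust` (the tree, `NULL` for fewer than two rows).
#' @export
cluster_heatmap_order <- function(tpm) {
  tpm <- as.matrix(tpm)
  m <- log10(tpm + 1)
  if (nrow(m) < 2L) {
    return(list(order = seq_len(nrow(m)), matrix = m, hclust = NULL))
  }
  hc <- hclust(dist(m, method = "euclidean"), method = "complete")
  list(order = hc$order, matrix = m, hclust = hc)
}
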