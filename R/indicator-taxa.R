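#' ANCOM-style W statistic for two-group differential abundance
#'
#' Compositional screen for taxa whose abundance differs between two groups
#' (e.g. homes with and without visible mold). For each taxon i the
#' additive log-ratio against every other taxon j,
#' `log((x_i + 1) / (x_j + 1))`, is compared between groups with a
#' two-sided Mann-Whitney test; the m - 1 p-values for taxon i are
#' Benjamini-Hochberg adjusted, and W_i is the fraction of them rejected at
#' `alpha`. A taxon is called differentially abundant when W_i reaches
#' `cutoff` — the loose 0.6 by default. Working on log-ratios makes the
#' statistic invariant to per-sample scaling (up to the +1 pseudocount).
#'
#' Taxa with zero total count are removed before testing.
#'
#' @param x A `count_matrix` (taxa x samples).
#' @param groups Two-level group label per sample.
#' @param cutoff Detection cutoff on W (default 0.6).
#' @param alpha Per-pair significance level after BH adjustment (0.05).
#' @return Data frame with `asv_id`, `W` (in \[0, 1\]) and `detected`.
#' @export
ancom_w <- function(x, groups, cutoff = 0.6, alpha = 0.05) {
  stopifnot(inherits(x, "count_matrix"))
  g <- as.factor(groups)
  if (nlevels(g) != 2)
    stop("ancom_w needs exactly two groups, got ", nlevels(g))
  if (any(table(g) < 5))
    stop("need at least 5 samples per group")
  keep <- rowSums(x$counts) > 0
  m <- sum(keep)
  if (m < 2) stop("need at least two taxa with nonzero counts")
  lc <- log(x$counts[keep, , drop = FALSE] + 1)
  ids <- rownames(lc)
  in1 <- g == levels(g)[1]
  pmat <- matrix(NA_real_, m, m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      r <- lc[i, ] - lc[j, ]
      p <- suppressWarnings(
        stats::wilcox.test(r[in1], r[!in1], exact = FALSE)$p.value)
      if (is.nan(p)) p <- 1  # all ratios tied across both groups
      pmat[i, j] <- pmat[j, i] <- p
    }
  }
  W <- vapply(seq_len(m), function(i) {
    padj <- stats::p.adjust(pmat[i, -i], method = "BH")
    mean(padj < alpha)
  }, 0)
  data.frame(asv_id = ids, W = W, detected = W >= cutoff,
             stringsAsFactors = FALSE)
}

#' Alpha diversity of one sample
#'
#' Observed richness (taxa with positive count), Shannon diversity in nats
#' (`-sum p log p`), and the inverse Simpson index (`1 / sum p^2`, an
#' effective taxon count). Shannon and inverse Simpson are computed with
#' \pkg{vegan}.
#'
#' @param counts Nonnegative count (or abundance) vector for one sample
#'   with positive total.
#' @return List with `observed_richness`, `shannon`, `inverse_simpson`.
#' @examples
#' alpha_diversity(c(5, 5, 5, 5))  # richness 4, shannon log(4), invsimpson 4
#' @export
alpha_diversity <- function(counts) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (sum(counts) <= 0) stop("sample has no counts")
  list(observed_richness = sum(counts > 0),
       shannon = unname(vegan::diversity(counts, index = "shannon")),
       inverse_simpson = unname(vegan::diversity(counts,
                                                 index = "invsimpson")))
}

#' Alpha diversity for every sample of a count matrix
#'
#' @param x A `count_matrix`.
#' @return Data frame with one row per sample.
#' @export
alpha_diversity_all <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  rows <- lapply(colnames(x$counts), function(s) {
    d <- alpha_diversity(x$counts[, s])
    data.frame(sample_id = s, observed_richness = d$observed_richness,
               shannon = d$shannon, inverse_simpson = d$inverse_simpson,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare alpha-diversity metrics between two damage groups
#'
#' Welch two-sided t test per metric. If both groups have zero variance the
#' test statistic is undefined; equal means then give p = 1 and unequal
#' means p = 0.
#'
#' @param metrics Data frame of per-sample metrics (e.g. from
#'   [alpha_diversity_all()]); every numeric column is compared.
#' @param groups Two-level group label per row of `metrics`.
#' @return Data frame with `metric`, `p_value`, and the two group means.
#' @export
compare_diversity <- function(metrics, groups) {
  g <- as.factor(groups)
  if (nlevels(g) != 2)
    stop("t tests compare exactly two groups, got ", nlevels(g))
  if (any(table(g) < 2)) stop("need at least 2 samples per group")
  num <- names(metrics)[vapply(metrics, is.numeric, TRUE)]
  rows <- lapply(num, function(mname) {
    v <- metrics[[mname]]
    m1 <- mean(v[g == levels(g)[1]]); m2 <- mean(v[g == levels(g)[2]])
    p <- tryCatch(stats::t.test(v ~ g)$p.value,
                  error = function(e) if (isTRUE(all.equal(m1, m2))) 1 else 0)
    data.frame(metric = mname, p_value = p, mean_group1 = m1,
               mean_group2 = m2, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- levels(g)
  out
}
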