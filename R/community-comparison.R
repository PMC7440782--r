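#' Pool outdoor samples into a composite profile
#'
#' Outdoor settled-dust samples from one location-season pairing are pooled
#' by taking, for each taxon, the mean of its relative abundances across
#' the pairing's samples, then renormalizing to sum to one. Each indoor
#' sample is later compared with the composite of its own location and
#' season.
#'
#' @param x A `count_matrix` containing (at least) the outdoor samples.
#' @param metadata Sample metadata covering the matrix's samples.
#' @param location,season The pairing to pool (e.g. `"Brooklyn"`,
#'   `"winter"`).
#' @return An `outdoor_profile`: list with `location`, `season`, `profile`
#'   (named per-taxon mean relative abundance, summing to 1) and
#'   `n_source_samples`.
#' @export
pool_outdoor <- function(x, metadata, location, season) {
  stopifnot(inherits(x, "count_matrix"))
  md <- metadata[match(colnames(x$counts), metadata$sample_id), ]
  sel <- md$sample_type == "outdoor_dust_fall" & md$location == location &
    md$season == season & !as.logical(md$is_control)
  if (!any(sel)) {
    have <- unique(paste(md$location[md$sample_type == "outdoor_dust_fall"],
                         md$season[md$sample_type == "outdoor_dust_fall"],
                         sep = "-"))
    stop("no outdoor samples for pairing ", location, "-", season,
         "; available pairings: ", paste(have, collapse = ", "))
  }
  sub <- x$counts[, sel, drop = FALSE]
  tot <- colSums(sub)
  if (any(tot <= 0)) stop("outdoor samples must have positive totals")
  prof <- rowMeans(sweep(sub, 2, tot, "/"))
  prof <- prof / sum(prof)
  structure(list(location = location, season = season, profile = prof,
                 n_source_samples = sum(sel)),
            class = "outdoor_profile")
}

#' @export
print.outdoor_profile <- function(x, ...) {
  cat("Composite outdoor profile", paste0(x$location, "-", x$season),
      "from", x$n_source_samples, "samples;",
      sum(x$profile > 0), "taxa\n")
  invisible(x)
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `sum(|p - q|) / sum(p + q)` over paired taxon abundances: 0 for
#' identical composition, 1 for disjoint supports. Computed here on
#' relative abundances so that samples of different sequencing depth and
#' collection method are comparable; the value is then invariant to
#' rescaling either vector.
#'
#' @param p,q Nonnegative abundance vectors on the same taxon index.
#' @return Dissimilarity in \[0, 1\].
#' @examples
#' bray_curtis(c(6, 2), c(2, 2))  # 1/3
#' @export
bray_curtis <- function(p, q) {
  if (length(p) != length(q))
    stop("p and q must share one taxon index")
  if (any(p < 0) || any(q < 0)) stop("abundances must be nonnegative")
  s <- sum(p) + sum(q)
  if (s == 0) stop("Bray-Curtis is undefined for two all-zero vectors")
  sum(abs(p - q)) / s
}

#' Distance of every indoor sample to its matching outdoor composite
#'
#' Pairs each indoor (non-control, non-outdoor) sample with the composite
#' outdoor profile of the same location and season, and records the
#' Bray-Curtis distance on relative abundances together with the number of
#' shared taxa (positive in both).
#'
#' @param x A `count_matrix` containing the indoor samples.
#' @param metadata Sample metadata.
#' @param composites List of [pool_outdoor()] profiles covering every
#'   indoor (location, season) pairing.
#' @return Data frame with one row per indoor sample: `sample_id`,
#'   `home_id`, `location`, `season`, `sample_type`, `bray_curtis`,
#'   `shared_taxa`.
#' @export
match_and_measure <- function(x, metadata, composites) {
  stopifnot(inherits(x, "count_matrix"))
  keys <- vapply(composites, function(cp) paste(cp$location, cp$season,
                                                sep = "-"), "")
  names(composites) <- keys
  md <- metadata[match(colnames(x$counts), metadata$sample_id), ]
  indoor <- which(md$sample_type %in% c("vacuum", "dust_fall", "swab") &
                    !as.logical(md$is_control))
  rows <- lapply(indoor, function(i) {
    key <- paste(md$location[i], md$season[i], sep = "-")
    if (!key %in% keys)
      stop("no outdoor composite for pairing ", key)
    prof <- composites[[key]]$profile
    v <- x$counts[names(prof), i]
    tot <- sum(x$counts[, i])
    if (tot <= 0) stop("indoor sample ", md$sample_id[i], " has no reads")
    p <- v / tot
    data.frame(sample_id = md$sample_id[i], home_id = md$home_id[i],
               location = md$location[i], season = md$season[i],
               sample_type = md$sample_type[i],
               bray_curtis = bray_curtis(p, prof),
               shared_taxa = sum(p > 0 & prof > 0),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare indoor-outdoor distance distributions across damage levels
#'
#' Rank-based comparison of the ecological distances across levels of a
#' building damage indicator: a Wilcoxon-Mann-Whitney test for two
#' categories, Kruskal-Wallis for three or more (both with the standard tie
#' corrections). Groups with fewer than two records are dropped with a
#' warning.
#'
#' @param values Numeric distances (or shared-taxa counts).
#' @param groups Damage level per value.
#' @return List with `p_value`, `test`, `medians` (named per group), `n`
#'   (per group).
#' @export
compare_distance_distributions <- function(values, groups) {
  g <- as.factor(groups)
  tab <- table(g)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warning("dropping group(s) with fewer than 2 records: ",
            paste(small, collapse = ", "))
    keep <- !(g %in% small)
    values <- values[keep]
    g <- droplevels(g[keep])
  }
  if (nlevels(g) < 2)
    stop("need at least two nonempty groups")
  if (nlevels(g) == 2) {
    p <- suppressWarnings(
      stats::wilcox.test(values ~ g, exact = FALSE)$p.value)
    test <- "wilcoxon_mann_whitney"
  } else {
    p <- stats::kruskal.test(values, g)$p.value
    test <- "kruskal_wallis"
  }
  list(p_value = p, test = test,
       medians = tapply(values, g, stats::median),
       n = as.integer(table(g)))
}
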