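#' Construct an ASV-by-sample count matrix
#'
#' A `count_matrix` wraps a nonnegative integer matrix (ASVs as rows,
#' samples as columns) together with the per-sample total read counts of the
#' community it was derived from. When a matrix is subset to the taxa of
#' interest the original whole-community totals are retained, because
#' relative abundance — and the model offset built from it — is defined
#' against the total assessed community, not against the reduced table.
#'
#' @param counts Integer matrix, ASVs x samples, with dimnames.
#' @param orig_totals Per-sample totals of the parent community; defaults to
#'   the column sums of `counts`.
#' @return An object of class `count_matrix` with elements `counts` and
#'   `orig_totals`.
#' @export
count_matrix <- function(counts, orig_totals = colSums(counts)) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have ASV rownames and sample colnames")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("ASV and sample identifiers must be unique")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  storage.mode(counts) <- "double"  # exact up to 2^53
  orig_totals <- orig_totals[colnames(counts)]
  structure(list(counts = counts, orig_totals = orig_totals),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "ASVs x", ncol(x$counts), "samples;",
      "median depth", stats::median(colSums(x$counts)), "\n")
  invisible(x)
}

#' Per-sample totals of a count matrix
#'
#' @param x A `count_matrix`.
#' @param original If `TRUE`, return the totals of the parent (whole)
#'   community stored at construction — the quantity used as the model
#'   offset; otherwise the column sums of the current table.
#' @return Named numeric vector of totals.
#' @export
sample_totals <- function(x, original = FALSE) {
  stopifnot(inherits(x, "count_matrix"))
  if (original) x$orig_totals else colSums(x$counts)
}

#' Read an ASV count table
#'
#' Reads a tab-separated table with ASVs as rows (first column `asv_id`) and
#' samples as columns. A BIOM file in the JSON dialect is also accepted
#' (detected by the `.biom` extension) and read through the biomformat
#' package. Cells must be nonnegative integers; violations are reported with
#' their coordinates.
#'
#' @param path Input path.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path) {
  if (grepl("\\.biom$", path, ignore.case = TRUE)) {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM files requires the biomformat package")
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    return(count_matrix(m))
  }
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(raw)[1] != "asv_id")
    stop("first column of a counts TSV must be 'asv_id'")
  ids <- raw[[1]]
  m <- as.matrix(raw[, -1, drop = FALSE])
  bad <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-integer or negative count at ASV '%s', sample '%s'",
                 ids[bad[1, 1]], colnames(m)[bad[1, 2]]))
  rownames(m) <- ids
  count_matrix(m)
}

#' Write an ASV count table
#'
#' @param x A `count_matrix`.
#' @param path Output path (TSV; first column `asv_id`).
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  out <- data.frame(asv_id = rownames(x$counts), x$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Flag likely reagent/handling contaminants from negative controls
#'
#' Prevalence-based contaminant scoring in the spirit of the decontam
#' prevalence method. For each ASV, presence/absence prevalences are
#' computed in negative-control and true samples with a mild shrinkage
#' correction, P = (k + 0.5) / (n + 1), and the contaminant score is
#' P_control / (P_control + P_true): monotonically increasing in control
#' prevalence and decreasing in true-sample prevalence, 0.5 at indifference.
#' ASVs scoring at or above `threshold` are flagged.
#'
#' @param x A `count_matrix`.
#' @param metadata Sample metadata data frame with columns `sample_id` and
#'   logical `is_control` covering the matrix's samples.
#' @param threshold Score threshold; the conventional 0.5 by default.
#' @return Character vector of flagged ASV ids, with the full score vector
#'   attached as attribute `score`.
#' @export
flag_contaminants <- function(x, metadata, threshold = 0.5) {
  stopifnot(inherits(x, "count_matrix"))
  ctrl_ids <- metadata$sample_id[as.logical(metadata$is_control)]
  samp <- colnames(x$counts)
  is_ctrl <- samp %in% ctrl_ids
  if (!any(is_ctrl))
    stop("no negative-control samples present; skip decontamination ",
         "explicitly rather than calling flag_contaminants")
  if (all(is_ctrl)) stop("no true samples present")
  pres <- x$counts > 0
  k_c <- rowSums(pres[, is_ctrl, drop = FALSE])
  k_t <- rowSums(pres[, !is_ctrl, drop = FALSE])
  p_c <- (k_c + 0.5) / (sum(is_ctrl) + 1)
  p_t <- (k_t + 0.5) / (sum(!is_ctrl) + 1)
  score <- p_c / (p_c + p_t)
  flagged <- rownames(x$counts)[score >= threshold & k_c > 0]
  attr(flagged, "score") <- score
  flagged
}

#' Remove ASVs from a count matrix
#'
#' @param x A `count_matrix`.
#' @param asv_ids ASVs to drop (e.g. the output of [flag_contaminants()]).
#' @return A `count_matrix` without those rows; original totals are
#'   recomputed since decontamination redefines the assessed community.
#' @export
drop_asvs <- function(x, asv_ids) {
  stopifnot(inherits(x, "count_matrix"))
  keep <- !(rownames(x$counts) %in% asv_ids)
  count_matrix(x$counts[keep, , drop = FALSE])
}

#' Reduce a count matrix to ASVs of selected species
#'
#' Keeps every ASV whose species-level taxonomy matches one of the given
#' canonical names; one species is typically represented by several ASVs and
#' all are retained. ASVs without species-level resolution never match. The
#' original whole-community per-sample totals are carried along so that
#' downstream offsets express relative abundance against the full assessed
#' community.
#'
#' @param x A `count_matrix`.
#' @param taxonomy Data frame with columns `asv_id` and `species` (empty
#'   string where unresolved).
#' @param species Character vector of canonical species names.
#' @return A reduced `count_matrix` (possibly with zero rows, with a
#'   warning).
#' @export
subset_by_species <- function(x, taxonomy, species) {
  stopifnot(inherits(x, "count_matrix"))
  sp <- taxonomy$species[match(rownames(x$counts), taxonomy$asv_id)]
  keep <- !is.na(sp) & nzchar(sp) & sp %in% species
  if (!any(keep)) warning("no ASVs match the requested species")
  structure(list(counts = x$counts[keep, , drop = FALSE],
                 orig_totals = x$orig_totals),
            class = "count_matrix")
}

#' Sum member-ASV counts into group counts per sample
#'
#' @param x A `count_matrix`.
#' @param asv_to_group Named character vector mapping ASV ids (names) to
#'   group labels; ASVs not named are left unaggregated.
#' @param groups Optional group labels to report (defaults to those present
#'   in the map); groups with no member ASVs get zero counts.
#' @return Numeric matrix, groups x samples.
#' @export
aggregate_group <- function(x, asv_to_group, groups = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  if (is.null(groups)) groups <- sort(unique(unname(asv_to_group)))
  out <- matrix(0, length(groups), ncol(x$counts),
                dimnames = list(groups, colnames(x$counts)))
  map <- asv_to_group[names(asv_to_group) %in% rownames(x$counts)]
  for (g in groups) {
    members <- names(map)[map == g]
    if (length(members))
      out[g, ] <- colSums(x$counts[members, , drop = FALSE])
  }
  out
}

#' Relative abundance of a group within a sample
#'
#' @param group_count Group read count(s).
#' @param total_reads Total reads in the sample(s); must be positive.
#' @return Proportion(s) in \[0, 1\].
#' @export
relative_abundance <- function(group_count, total_reads) {
  if (any(total_reads <= 0)) stop("total_reads must be positive")
  p <- group_count / total_reads
  if (any(p < 0 | p > 1)) stop("group_count must lie in [0, total_reads]")
  p
}

#' Absolute abundance (load) from relative abundance and qPCR biomass
#'
#' Converts a proportion of the sequenced community into an estimated
#' environmental load by multiplying with the total fungal biomass measured
#' by qPCR. Loads are only meaningful for sample types with standardized
#' collection (vacuum and dust fall collector samples); requesting them for
#' swabs is an error because swabbed area and pressure are not standardized.
#'
#' @param proportion Relative abundance(s) in \[0, 1\].
#' @param biomass Total fungal biomass for the sample(s); positive.
#' @param sample_type Optional sample type string(s); if supplied, anything
#'   other than `"vacuum"` or `"dust_fall"` errors.
#' @return Load(s), `proportion * biomass`.
#' @export
absolute_abundance <- function(proportion, biomass, sample_type = NULL) {
  if (!is.null(sample_type) &&
      !all(sample_type %in% c("vacuum", "dust_fall")))
    stop("absolute abundance is defined only for vacuum and dust fall ",
         "collector samples")
  if (any(biomass <= 0)) stop("biomass must be positive")
  if (any(proportion < 0 | proportion > 1))
    stop("proportion must lie in [0, 1]")
  proportion * biomass
}

#' Average door-trim swabs into home-level pseudo-samples
#'
#' Homes with at least two swabs get a composite sample whose per-ASV
#' relative abundances are the mean of the member swabs' relative
#' abundances; compositing on proportions (rather than pooling raw counts)
#' prevents one deeply sequenced swab from dominating the home. The
#' composite's total is the mean of the member totals and counts are
#' reconstituted by rounding proportion x mean total. Homes with a single
#' swab are excluded (with a message).
#'
#' @param x A `count_matrix` of swab samples only.
#' @param metadata Data frame with `sample_id` and `home_id` covering the
#'   swab samples.
#' @return A `count_matrix` of home-level composites (columns named by
#'   home id).
#' @export
average_home_swabs <- function(x, metadata) {
  stopifnot(inherits(x, "count_matrix"))
  home <- metadata$home_id[match(colnames(x$counts), metadata$sample_id)]
  if (any(is.na(home))) stop("metadata must cover every swab sample")
  n_by_home <- table(home)
  excluded <- names(n_by_home)[n_by_home < 2]
  if (length(excluded))
    message("excluding ", length(excluded),
            " home(s) with a single swab: ", paste(excluded, collapse = ", "))
  homes <- names(n_by_home)[n_by_home >= 2]
  if (!length(homes)) stop("no home has two or more swabs")
  tot <- colSums(x$counts)
  if (any(tot <= 0)) stop("swab samples must have positive totals")
  props <- sweep(x$counts, 2, tot, "/")
  comp <- vapply(homes, function(h) {
    cols <- which(home == h)
    p <- rowMeans(props[, cols, drop = FALSE])
    round(p * mean(tot[cols]))
  }, numeric(nrow(x$counts)))
  comp <- matrix(comp, nrow = nrow(x$counts),
                 dimnames = list(rownames(x$counts), homes))
  count_matrix(comp)
}

#' Drop taxa that never exceed a relative-abundance floor
#'
#' Removes taxa whose relative abundance never exceeds `min_rel` (default
#' 0.1%) in any sample of the set under comparison, the filter used before
#' indoor-outdoor community comparisons.
#'
#' @param x A `count_matrix`.
#' @param min_rel Relative-abundance floor; a taxon is kept iff it exceeds
#'   this in at least one sample. `0` keeps everything.
#' @return Filtered `count_matrix` (original totals preserved).
#' @export
filter_rare <- function(x, min_rel = 0.001) {
  stopifnot(inherits(x, "count_matrix"))
  tot <- colSums(x$counts)
  tot[tot == 0] <- 1
  rel <- sweep(x$counts, 2, tot, "/")
  keep <- apply(rel, 1, max) > min_rel
  structure(list(counts = x$counts[keep, , drop = FALSE],
                 orig_totals = x$orig_totals),
            class = "count_matrix")
}

#' Read a taxonomy table
#'
#' @param path TSV with columns `asv_id` and the seven ranks `kingdom`,
#'   `phylum`, `class`, `order`, `family`, `genus`, `species` (species may
#'   be empty where unresolved).
#' @return Data frame.
#' @export
read_taxonomy <- function(path) {
  tx <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("asv_id", "kingdom", "phylum", "class", "order", "family",
            "genus", "species")
  if (!all(need %in% names(tx)))
    stop("taxonomy file must have columns: ", paste(need, collapse = ", "))
  tx
}

#' Read sample metadata
#'
#' @param path TSV with columns `sample_id`, `home_id`, `room`,
#'   `sample_type`, `location`, `season`, `is_control`.
#' @return Data frame with `is_control` as logical.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "home_id", "room", "sample_type", "location",
            "season", "is_control")
  if (!all(need %in% names(md)))
    stop("metadata file must have columns: ", paste(need, collapse = ", "))
  md$is_control <- as.logical(md$is_control)
  bad <- md$sample_type == "outdoor_dust_fall" & !is.na(md$home_id) &
    nzchar(md$home_id)
  if (any(bad)) md$home_id[bad] <- ""
  md
}

#' Read qPCR biomass measurements
#'
#' @param path TSV with columns `sample_id` and `biomass` (positive).
#' @return Data frame.
#' @export
read_qpcr <- function(path) {
  q <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "biomass") %in% names(q)))
    stop("qPCR file must have columns sample_id, biomass")
  if (any(q$biomass <= 0)) stop("biomass must be positive")
  q
}
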