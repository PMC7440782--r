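# Orchestration of the four analytical approaches over a study (generated
# or read from disk): guild targeting (1), ERMI group-1 targeting (2),
# indoor-outdoor ecological distance (3), indicator taxa + diversity (4).

# canonical level order per damage indicator; the first level is the
# no-damage reference
home_indicator_levels <- list(
  mold_damage = c("no", "yes"),
  n_mold_areas = c("0", "1", "2+"),
  mold_size_cat = c("0", "low", "high"),
  mold_other_damage = c("no", "yes"),
  n_mold_other_areas = c("0", "1", "2+"),
  mold_other_size_cat = c("0", "low", "high"),
  n_readings_gt15 = c("0", "1+"),
  composite_cat = c("0", "1-2", "3-6"))

room_indicator_levels <- home_indicator_levels[
  c("mold_damage", "mold_size_cat", "mold_other_damage",
    "mold_other_size_cat")]

# subset a count_matrix's samples, keeping original offsets for those samples
subset_samples <- function(x, ids) {
  structure(list(counts = x$counts[, ids, drop = FALSE],
                 orig_totals = x$orig_totals[ids]),
            class = "count_matrix")
}

# asv -> moisture guild, via species-level taxonomy resolved against db
guild_asv_map <- function(taxonomy, db) {
  canon <- normalize_name(taxonomy$species, db)
  g <- db$records$guild[match(canon, db$records$canonical_name)]
  ok <- !is.na(g)
  stats::setNames(g[ok], taxonomy$asv_id[ok])
}

# asv -> "group1" for ASVs resolving to ERMI group-1 taxa
group1_asv_map <- function(taxonomy, db) {
  canon <- normalize_name(taxonomy$species, db)
  ok <- !is.na(canon) & canon %in% db$ermi$group1
  stats::setNames(rep("group1", sum(ok)), taxonomy$asv_id[ok])
}

# one NB screen: counts for one fungal group across samples vs one damage
# indicator; 2 remaining levels -> Wald Z, 3+ -> LRT against intercept-only
nb_screen_one <- function(y, offs, values, level_order, indicator, group,
                          sample_type, analysis_level, abundance) {
  ok <- !is.na(values)
  y <- y[ok]; values <- values[ok]
  if (!is.null(offs)) offs <- offs[ok]
  x <- factor(values, levels = level_order)
  x <- droplevels(x)
  keep_lv <- names(which(table(x) >= 2))
  sel <- x %in% keep_lv
  y <- y[sel]; x <- droplevels(x[sel])
  if (!is.null(offs)) offs <- offs[sel]
  if (nlevels(x) < 2 || all(y == 0)) return(NULL)
  fit <- tryCatch(fit_nb(y, x, offs, damage_var = indicator),
                  error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  non_ref <- fit$design$levels[-1]
  if (nlevels(x) == 2) {
    p <- vapply(non_ref, function(l) wald_z_p(fit, l), 0)
    test <- "wald_z"
  } else {
    red <- tryCatch(fit_nb(y, rep("all", length(y)), offs,
                           damage_var = indicator),
                    error = function(e) NULL)
    if (is.null(red)) return(NULL)
    p <- rep(lrt_2df(fit, red), length(non_ref))
    test <- "lrt_chi2"
  }
  data.frame(sample_type = sample_type, analysis_level = analysis_level,
             abundance = abundance, group = group, indicator = indicator,
             level = non_ref,
             n = as.integer(table(x)[non_ref]),
             relative_change = unname(exp(fit$coefficients[non_ref])),
             p_value = unname(p), test = test,
             stringsAsFactors = FALSE)
}

# shared engine of approaches 1 and 2
run_targeted <- function(study, db, asv_map, groups, abundance, decontam) {
  counts <- study$counts
  if (decontam) {
    flagged <- flag_contaminants(counts, study$metadata)
    counts <- drop_asvs(counts, flagged)
  }
  md <- study$metadata
  hind <- derive_all_home_indicators(
    study$inspections$observations, study$inspections$readings,
    study$inspections$condensation,
    home_ids = sort(unique(md$home_id[nzchar(md$home_id)])))
  res <- list()

  for (stype in c("vacuum", "dust_fall")) {
    sel <- md$sample_type == stype & md$season == "winter" & !md$is_control &
      nzchar(md$home_id)
    ids <- md$sample_id[sel]
    if (!length(ids)) next
    sub <- subset_samples(counts, ids)
    grp <- aggregate_group(sub, asv_map, groups = groups)
    offs <- log(sample_totals(sub, original = TRUE))
    homes <- md$home_id[match(ids, md$sample_id)]
    if (abundance == "absolute") {
      biomass <- study$qpcr$biomass[match(ids, study$qpcr$sample_id)]
      if (any(is.na(biomass)))
        stop("absolute abundance requires qPCR biomass for every ", stype,
             " sample")
    }
    for (g in groups) {
      y <- grp[g, ]
      if (abundance == "absolute") {
        y <- round(relative_abundance(y, exp(offs)) * biomass)
        off_use <- NULL
      } else off_use <- offs
      for (ind in names(home_indicator_levels)) {
        vals <- hind[[ind]][match(homes, hind$home_id)]
        res[[length(res) + 1]] <- nb_screen_one(
          y, off_use, vals, home_indicator_levels[[ind]], ind, g, stype,
          "home", abundance)
      }
    }
  }

  # door trim swabs: absolute abundance is undefined (no standardized area)
  if (abundance == "relative") {
    sel <- md$sample_type == "swab" & md$season == "winter" & !md$is_control
    ids <- md$sample_id[sel]
    if (length(ids)) {
      sub <- subset_samples(counts, ids)
      # home level: composite of each home's swabs
      comp <- suppressMessages(average_home_swabs(sub, md))
      grp <- aggregate_group(comp, asv_map, groups = groups)
      offs <- log(sample_totals(comp))
      homes <- colnames(comp$counts)
      for (g in groups) {
        for (ind in names(home_indicator_levels)) {
          vals <- hind[[ind]][match(homes, hind$home_id)]
          res[[length(res) + 1]] <- nb_screen_one(
            grp[g, ], offs, vals, home_indicator_levels[[ind]], ind, g,
            "swab", "home", abundance)
        }
      }
      # room level: rooms with both a swab and a damage assessment
      assessed <- unique(rbind(
        study$inspections$readings[, c("home_id", "room")],
        study$inspections$observations[, c("home_id", "room")]))
      swab_md <- md[match(ids, md$sample_id), ]
      eligible <- paste(swab_md$home_id, swab_md$room) %in%
        paste(assessed$home_id, assessed$room)
      rids <- ids[eligible]
      if (length(rids)) {
        rind <- derive_all_room_indicators(
          study$inspections$observations,
          rooms = unique(swab_md[eligible, c("home_id", "room")]))
        rsub <- subset_samples(counts, rids)
        rgrp <- aggregate_group(rsub, asv_map, groups = groups)
        roffs <- log(sample_totals(rsub, original = TRUE))
        key <- paste(swab_md$home_id, swab_md$room)[eligible]
        for (g in groups) {
          for (ind in names(room_indicator_levels)) {
            vals <- rind[[ind]][match(key, paste(rind$home_id, rind$room))]
            res[[length(res) + 1]] <- nb_screen_one(
              rgrp[g, ], roffs, vals, room_indicator_levels[[ind]], ind, g,
              "swab", "room", abundance)
          }
        }
      }
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Approach 1: moisture-guild abundance vs damage indicators
#'
#' Aggregates counts of hydrophilic, mesophilic and xerophilic fungi
#' (species resolved against the moisture-requirement reference) per
#' sample, then fits a negative binomial model of each guild's counts
#' against every building damage indicator: vacuum and dust-fall samples at
#' the home level, door trim swabs at both home level (swabs averaged per
#' home) and room level (rooms with both a swab and a damage assessment).
#' Relative abundance uses the log whole-community total as offset;
#' absolute abundance multiplies by qPCR biomass and fits without offset
#' (vacuum and dust-fall samples only).
#'
#' @param study A `generated_study` or the list returned by [read_study()].
#' @param db Guild reference database; defaults to the bundled synthetic
#'   reference.
#' @param abundance `"relative"` or `"absolute"`.
#' @param decontam Whether to flag and drop contaminants using the
#'   negative controls first.
#' @return Data frame: one row per (sample type, analysis level, guild,
#'   indicator, non-reference level) with the relative change, p-value and
#'   test used.
#' @export
run_approach1 <- function(study, db = read_guild_reference(mycodamp_reference()),
                          abundance = c("relative", "absolute"),
                          decontam = TRUE) {
  abundance <- match.arg(abundance)
  map <- guild_asv_map(study$taxonomy, db)
  run_targeted(study, db, map,
               c("hydrophilic", "mesophilic", "xerophilic"),
               abundance, decontam)
}

#' Approach 2: ERMI group-1 abundance vs damage indicators
#'
#' Same screen as [run_approach1()] with the single aggregate of ERMI
#' group-1 taxa in place of the three moisture guilds.
#'
#' @inheritParams run_approach1
#' @return Data frame as in [run_approach1()] with `group == "group1"`.
#' @export
run_approach2 <- function(study, db = read_guild_reference(mycodamp_reference()),
                          abundance = c("relative", "absolute"),
                          decontam = TRUE) {
  abundance <- match.arg(abundance)
  map <- group1_asv_map(study$taxonomy, db)
  if (!length(map)) {
    warning("no ASVs resolve to ERMI group-1 taxa; returning empty result")
    return(NULL)
  }
  run_targeted(study, db, map, "group1", abundance, decontam)
}

#' Approach 3: indoor-outdoor ecological distance vs damage
#'
#' Pools outdoor dust-fall samples into one composite profile per
#' location-season pairing, measures the Bray-Curtis distance (on relative
#' abundances) and shared-taxa count of every indoor sample against its
#' matching composite, and compares the distance distributions across
#' levels of each home-level damage indicator with rank tests
#' (Wilcoxon-Mann-Whitney for two categories, Kruskal-Wallis for three).
#'
#' @inheritParams run_approach1
#' @param min_rel If positive, taxa never exceeding this relative abundance
#'   are dropped before distances are computed (`0` disables; the
#'   conventional filter is 0.001).
#' @return List with `distances` (per indoor sample) and `comparisons`
#'   (per indicator x metric).
#' @export
run_approach3 <- function(study, decontam = TRUE, min_rel = 0) {
  counts <- study$counts
  if (decontam) {
    flagged <- flag_contaminants(counts, study$metadata)
    counts <- drop_asvs(counts, flagged)
  }
  if (min_rel > 0) counts <- filter_rare(counts, min_rel)
  md <- study$metadata
  out_md <- md[md$sample_type == "outdoor_dust_fall", ]
  pairings <- unique(out_md[, c("location", "season")])
  composites <- lapply(seq_len(nrow(pairings)), function(i)
    pool_outdoor(counts, md, pairings$location[i], pairings$season[i]))
  dist <- match_and_measure(counts, md, composites)
  hind <- derive_all_home_indicators(
    study$inspections$observations, study$inspections$readings,
    study$inspections$condensation,
    home_ids = sort(unique(md$home_id[nzchar(md$home_id)])))
  comp_rows <- list()
  for (ind in names(home_indicator_levels)) {
    vals <- hind[[ind]][match(dist$home_id, hind$home_id)]
    for (metric in c("bray_curtis", "shared_taxa")) {
      cm <- tryCatch(
        suppressWarnings(compare_distance_distributions(
          dist[[metric]], factor(vals,
                                 levels = home_indicator_levels[[ind]]))),
        error = function(e) NULL)
      if (is.null(cm)) next
      comp_rows[[length(comp_rows) + 1]] <- data.frame(
        indicator = ind, metric = metric, test = cm$test,
        p_value = cm$p_value,
        medians = paste(sprintf("%s=%.4g", names(cm$medians), cm$medians),
                        collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  list(distances = dist, comparisons = do.call(rbind, comp_rows))
}

#' Approach 4: indicator taxa and alpha diversity vs mold damage
#'
#' Runs the ANCOM-style W screen for taxa differing between homes with and
#' without visible mold (per sample type), and compares observed richness,
#' Shannon diversity and the inverse Simpson index between the same groups
#' with Welch t tests.
#'
#' @inheritParams run_approach1
#' @param sample_types Sample types to screen (winter samples).
#' @param cutoff W detection cutoff (0.6).
#' @return List with `ancom` (per sample type x taxon), `diversity` (per
#'   sample) and `diversity_comparison` (per sample type x metric).
#' @export
run_approach4 <- function(study, decontam = TRUE,
                          sample_types = c("vacuum", "dust_fall"),
                          cutoff = 0.6) {
  counts <- study$counts
  if (decontam) {
    flagged <- flag_contaminants(counts, study$metadata)
    counts <- drop_asvs(counts, flagged)
  }
  md <- study$metadata
  hind <- derive_all_home_indicators(
    study$inspections$observations, study$inspections$readings,
    study$inspections$condensation,
    home_ids = sort(unique(md$home_id[nzchar(md$home_id)])))
  ancom_rows <- list(); divcmp_rows <- list(); div_rows <- list()
  for (stype in sample_types) {
    sel <- md$sample_type == stype & md$season == "winter" &
      !md$is_control & nzchar(md$home_id)
    ids <- md$sample_id[sel]
    if (!length(ids)) next
    sub <- subset_samples(counts, ids)
    groups <- hind$mold_damage[match(md$home_id[match(ids, md$sample_id)],
                                     hind$home_id)]
    aw <- ancom_w(sub, groups, cutoff = cutoff)
    aw$sample_type <- stype
    ancom_rows[[length(ancom_rows) + 1]] <- aw
    dv <- alpha_diversity_all(sub)
    dv$sample_type <- stype
    div_rows[[length(div_rows) + 1]] <- dv
    cmp <- compare_diversity(dv[, c("observed_richness", "shannon",
                                    "inverse_simpson")], groups)
    cmp$sample_type <- stype
    divcmp_rows[[length(divcmp_rows) + 1]] <- cmp
  }
  list(ancom = do.call(rbind, ancom_rows),
       diversity = do.call(rbind, div_rows),
       diversity_comparison = do.call(rbind, divcmp_rows))
}

# small polynomial rolling hash for provenance lines (kept in doubles to
# stay exact below 2^53; no external digest dependency)
fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "")))
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

write_result <- function(d, path, seed, hash) {
  con <- file(path, "w", encoding = "UTF-8")
  writeLines(sprintf("# mycodamp %s seed=%s config_hash=%s",
                     as.character(utils::packageVersion("mycodamp")),
                     seed, hash), con)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
}

#' Run every approach on a synthetic scenario and write results
#'
#' Generates a study from the scenario, runs approaches 1-4, and writes
#' each result table as TSV (with a provenance header recording the
#' package version, seed and a configuration hash) into `outdir`. Output
#' is deterministic: the same config and seed produce byte-identical
#' files.
#'
#' @param config A [scenario_config()].
#' @param seed Integer seed.
#' @param outdir Output directory.
#' @param abundance `"relative"` or `"absolute"` for approaches 1-2.
#' @return Invisibly, the list of result objects.
#' @export
run_all <- function(config = scenario_config(), seed = 1,
                    outdir = "mycodamp_results",
                    abundance = c("relative", "absolute")) {
  abundance <- match.arg(abundance)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  study <- generate_study(config, seed)
  db <- read_guild_reference(mycodamp_reference())
  a1 <- run_approach1(study, db, abundance = abundance)
  a2 <- run_approach2(study, db, abundance = abundance)
  a3 <- run_approach3(study)
  a4 <- run_approach4(study)
  hash <- fnv1a(config)
  write_result(a1, file.path(outdir, "approach1_guilds.tsv"), seed, hash)
  write_result(a2, file.path(outdir, "approach2_group1.tsv"), seed, hash)
  write_result(a3$distances, file.path(outdir, "approach3_distances.tsv"),
               seed, hash)
  write_result(a3$comparisons, file.path(outdir, "approach3_comparisons.tsv"),
               seed, hash)
  write_result(a4$ancom, file.path(outdir, "approach4_ancom.tsv"), seed, hash)
  write_result(a4$diversity, file.path(outdir, "approach4_diversity.tsv"),
               seed, hash)
  write_result(a4$diversity_comparison,
               file.path(outdir, "approach4_diversity_tests.tsv"), seed, hash)
  invisible(list(approach1 = a1, approach2 = a2, approach3 = a3,
                 approach4 = a4, study = study))
}
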