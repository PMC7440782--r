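# fit the guild's relative-abundance rate ratio for vacuum samples of a
# generated study, against true damage status — used for recovery checks
fit_guild_rr <- function(study, guild) {
  md <- study$metadata
  sel <- md$sample_type == "vacuum" & md$season == "winter" & !md$is_control
  ids <- md$sample_id[sel]
  map <- study$truth$guild_by_asv
  map <- setNames(map[!is.na(map)], names(map)[!is.na(map)])
  sub <- structure(list(counts = study$counts$counts[, ids, drop = FALSE],
                        orig_totals = study$counts$orig_totals[ids]),
                   class = "count_matrix")
  y <- aggregate_group(sub, map)[guild, ]
  dmg <- study$truth$damage$damaged[match(md$home_id[match(ids, md$sample_id)],
                                          study$truth$damage$home_id)]
  fit <- fit_nb(y, ifelse(dmg, "yes", "no"), log(sample_totals(sub, TRUE)),
                ref = "no")
  unname(exp(coef(fit)["yes"]))
}

test_that("the same seed reproduces a study exactly", {
  a <- generate_study(scenario_config(), 7)
  b <- generate_study(scenario_config(), 7)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$inspections, b$inspections)
  expect_identical(a$qpcr, b$qpcr)
  c2 <- generate_study(scenario_config(), 8)
  expect_false(identical(a$counts$counts, c2$counts$counts))
})

test_that("generated studies have the configured shape and consistency", {
  st <- default_study()
  md <- st$metadata
  expect_equal(length(unique(md$home_id[nzchar(md$home_id)])), 60)
  # outdoor pools at the configured pairing sizes
  out <- md[md$sample_type == "outdoor_dust_fall", ]
  expect_equal(as.vector(table(paste(out$location, out$season, sep = "-"))[
    c("Brooklyn-winter", "Brooklyn-summer", "Manhattan-winter",
      "Manhattan-summer")]), c(10L, 21L, 7L, 3L))
  expect_equal(sum(md$is_control), 3)
  # damaged homes have mold observations, undamaged never do
  mold_homes <- unique(st$inspections$observations$home_id[
    st$inspections$observations$damage_type == "visible_mold"])
  dmg <- st$truth$damage
  expect_setequal(mold_homes, dmg$home_id[dmg$damaged])
  # qPCR only for standardized indoor sample types, all positive
  qmd <- md[match(st$qpcr$sample_id, md$sample_id), ]
  expect_true(all(qmd$sample_type %in% c("vacuum", "dust_fall")))
  expect_false(any(qmd$is_control))
  expect_true(all(st$qpcr$biomass > 0))
  # taxonomy covers every ASV; species resolve against the bundled reference
  expect_setequal(st$taxonomy$asv_id, rownames(st$counts$counts))
  resolved <- normalize_name(st$taxonomy$species, bundled_db())
  expect_gt(sum(!is.na(resolved)), 40)
})

test_that("contaminant taxa are confined to controls plus sparse cross-talk", {
  st <- default_study()
  md <- st$metadata
  fl <- flag_contaminants(st$counts, md)
  contam_ids <- st$taxonomy$asv_id[st$taxonomy$species %in%
                                     mycodamp:::contaminant_names]
  expect_true(all(contam_ids %in% fl))
  # no genuine community taxon is flagged
  expect_length(setdiff(fl, contam_ids), 0)
})

test_that("default effects are recovered from the generated counts", {
  ests_h <- ests_m <- numeric(10)
  for (i in 1:10) {
    st <- generate_study(scenario_config(), 200 + i)
    ests_h[i] <- fit_guild_rr(st, "hydrophilic")
    ests_m[i] <- fit_guild_rr(st, "mesophilic")
  }
  expect_gt(median(ests_h), 2)    # truth 2.5
  expect_lt(median(ests_h), 3)
  expect_gt(median(ests_m), 0.4)  # truth 0.5
  expect_lt(median(ests_m), 0.65)
})

test_that("a null scenario centers guild rate ratios on 1", {
  cfg <- scenario_config(effects = list())
  ests <- vapply(1:10, function(i)
    fit_guild_rr(generate_study(cfg, 300 + i), "hydrophilic"), 0)
  expect_gt(median(ests), 0.9)
  expect_lt(median(ests), 1.1)
})

test_that("inspections populate the composite categories", {
  cfg <- scenario_config()
  # all undamaged: every composite index is 0
  insp0 <- generate_inspections(
    data.frame(home_id = sprintf("H%02d", 1:20), damaged = FALSE), cfg, 5)
  tab0 <- derive_all_home_indicators(insp0$observations, insp0$readings,
                                     insp0$condensation,
                                     home_ids = sprintf("H%02d", 1:20))
  expect_true(all(tab0$composite_index == 0))
  # default prevalence: all three composite categories occupied in most seeds
  occupied <- vapply(1:10, function(s) {
    dmg <- data.frame(home_id = sprintf("H%02d", 1:60),
                      damaged = rep(c(TRUE, FALSE), 30))
    insp <- generate_inspections(dmg, cfg, s)
    tab <- derive_all_home_indicators(insp$observations, insp$readings,
                                      insp$condensation,
                                      home_ids = dmg$home_id)
    all(c("0", "1-2", "3-6") %in% tab$composite_cat)
  }, TRUE)
  expect_gte(sum(occupied), 9)
})

test_that("study TSVs round trip through write_study/read_study", {
  st <- generate_study(scenario_config(n_homes = 6, n_taxa = c(
    hydrophilic = 3, mesophilic = 4, xerophilic = 3, group1_only = 2,
    unclassified = 4)), 9)
  dir <- tempfile()
  write_study(st, dir)
  back <- read_study(dir)
  expect_identical(back$counts$counts, st$counts$counts)
  expect_equal(back$metadata$sample_id, st$metadata$sample_id)
  expect_equal(back$qpcr$biomass, st$qpcr$biomass, tolerance = 1e-9)
})

test_that("scenario configs round trip through YAML", {
  skip_if_not_installed("yaml")
  cfg <- scenario_config(n_homes = 20, theta = 1.5,
                         effects = list(vacuum = c(hydrophilic = 2),
                                        swab = c(group1 = 3)))
  p <- tempfile(fileext = ".yaml")
  write_scenario_config(cfg, p)
  back <- read_scenario_config(p)
  expect_equal(back$n_homes, 20L)
  expect_equal(back$theta, 1.5)
  expect_equal(back$effects$vacuum, c(hydrophilic = 2))
  expect_identical(generate_study(back, 3)$counts$counts,
                   generate_study(cfg, 3)$counts$counts)
})

test_that("infeasible configurations are refused", {
  expect_error(scenario_config(damage_prevalence = 0), "damage_prevalence")
  expect_error(scenario_config(theta = -1))
  # effects so large the unaffected taxa cannot compensate
  cfg <- scenario_config(effects = list(vacuum = c(
    hydrophilic = 1e6, mesophilic = 1e6, xerophilic = 1e6)))
  expect_error(generate_study(cfg, 1), "infeasible")
})
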