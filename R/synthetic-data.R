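#' Scenario configuration for synthetic study generation
#'
#' Encodes the study conditions emulated by the generator: a two-borough,
#' two-season home survey with researcher inspection in winter, vacuum /
#' dust-fall / door-trim-swab sampling indoors, pooled outdoor dust-fall
#' samples, unexposed negative-control samplers, and qPCR biomass for the
#' standardized sample types. Defaults mirror the emulated survey: 60 homes
#' (75% returning in summer), roughly half with damage, outdoor pools of
#' 10/21/7/3 for Brooklyn-winter / Brooklyn-summer / Manhattan-winter /
#' Manhattan-summer, and ground-truth multiplicative damage effects of 2.5
#' on hydrophiles and 0.5 on mesophiles in vacuum dust and 3.2 on ERMI
#' group-1 fungi in door trim swabs (all other guild x sample-type effects
#' are 1).
#'
#' @param n_homes Number of inspected homes.
#' @param damage_prevalence Probability a home has visible mold damage.
#' @param effects Named list `sample_type -> named vector of multiplicative
#'   rate ratios` applied to taxa of a guild (or of ERMI group 1) in
#'   damaged homes. Effects multiply when a taxon belongs to several
#'   affected sets.
#' @param theta Negative binomial dispersion of taxon counts.
#' @param depth_range Integer range of per-sample read depth.
#' @param n_taxa Named integer vector: taxa per moisture guild, group-1-only
#'   taxa, and species-unresolved ASVs.
#' @param outdoor_n Named integer vector of outdoor sample counts per
#'   location-season pairing.
#' @param summer_fraction Fraction of homes resampled in summer.
#' @param n_controls Number of negative-control samplers.
#' @param n_contaminants Number of contaminant taxa seeded into controls.
#' @param qpcr_noise_cv Coefficient of variation of the lognormal qPCR
#'   measurement noise.
#' @param baseline_sd Spread (sd, nats) of the lognormal baseline taxon
#'   log-abundances within a guild block.
#' @param guild_shares Expected undamaged community share of each moisture
#'   guild; the remainder goes to unclassified and group-1-only taxa.
#'   Defaults mirror the sequence shares the emulated survey reports for
#'   its guild subsets (about 3%, 20% and 6%).
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_homes = 60,
                            damage_prevalence = 0.5,
                            effects = list(
                              vacuum = c(hydrophilic = 2.5,
                                         mesophilic = 0.5),
                              swab = c(group1 = 3.2)),
                            theta = 2,
                            depth_range = c(10000L, 50000L),
                            n_taxa = c(hydrophilic = 8, mesophilic = 20,
                                       xerophilic = 12, group1_only = 5,
                                       unclassified = 25),
                            outdoor_n = c("Brooklyn-winter" = 10,
                                          "Brooklyn-summer" = 21,
                                          "Manhattan-winter" = 7,
                                          "Manhattan-summer" = 3),
                            summer_fraction = 0.75,
                            n_controls = 3,
                            n_contaminants = 3,
                            qpcr_noise_cv = 0.3,
                            baseline_sd = 1,
                            guild_shares = c(hydrophilic = 0.032,
                                             mesophilic = 0.196,
                                             xerophilic = 0.056)) {
  stopifnot(n_homes >= 2,
            damage_prevalence > 0, damage_prevalence < 1,
            theta > 0, length(depth_range) == 2,
            depth_range[1] > 0, depth_range[2] >= depth_range[1],
            all(unlist(effects) > 0), all(n_taxa >= 0), n_controls >= 1,
            all(guild_shares > 0), sum(guild_shares) < 1)
  structure(list(n_homes = as.integer(n_homes),
                 damage_prevalence = damage_prevalence,
                 effects = effects, theta = theta,
                 depth_range = as.integer(depth_range),
                 n_taxa = n_taxa, outdoor_n = outdoor_n,
                 summer_fraction = summer_fraction,
                 n_controls = as.integer(n_controls),
                 n_contaminants = as.integer(n_contaminants),
                 qpcr_noise_cv = qpcr_noise_cv,
                 baseline_sd = baseline_sd,
                 guild_shares = guild_shares),
            class = "scenario_config")
}

# species drawn from the bundled reference so that the generated taxonomy
# resolves against it; contaminants get common reagent/skin fungi names
contaminant_names <- c("Malassezia restricta", "Malassezia globosa",
                       "Saccharomyces cerevisiae", "Candida albicans",
                       "Meyerozyma guilliermondii")

#' Generate a complete synthetic study
#'
#' Draws a full study — counts, taxonomy, sample metadata, building
#' inspections, qPCR biomass, and negative controls — with known ground
#' truth. Species names are sampled from the bundled reference so the
#' generated taxonomy resolves against it. Per sample, the expected
#' relative abundance of a taxon is its lognormal baseline, multiplied in
#' damaged homes by the configured effect for its guild (or group-1
#' membership) and the sample's type, renormalized; counts are negative
#' binomial draws at a uniform random depth. Controls contain contaminant
#' taxa plus sparse cross-talk from the real community. qPCR biomass is
#' proportional to the sample's unnormalized community weight with
#' lognormal measurement noise.
#'
#' @param config A [scenario_config()].
#' @param seed Integer seed; the same seed reproduces the study exactly.
#' @return A `generated_study` list: `counts` (a [count_matrix()]),
#'   `taxonomy`, `metadata`, `inspections` (list of `observations`,
#'   `readings`, `condensation`), `qpcr`, and `truth` (the config plus
#'   per-home damage status).
#' @export
generate_study <- function(config = scenario_config(), seed = 1) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(as.integer(seed %% 2147483647))
  db <- read_guild_reference(mycodamp_reference())
  aw <- db$records[!is.na(db$records$guild), ]
  g1_noaw <- setdiff(db$ermi$group1,
                     aw$canonical_name)

  pick <- function(pool, n, what) {
    if (length(pool) < n)
      stop("infeasible config: need ", n, " ", what, " but reference has ",
           length(pool))
    sample(pool, n)
  }
  nt <- config$n_taxa
  species <- c(
    pick(aw$canonical_name[aw$guild == "hydrophilic"], nt[["hydrophilic"]],
         "hydrophilic species"),
    pick(aw$canonical_name[aw$guild == "mesophilic"], nt[["mesophilic"]],
         "mesophilic species"),
    pick(aw$canonical_name[aw$guild == "xerophilic"], nt[["xerophilic"]],
         "xerophilic species"),
    pick(g1_noaw, nt[["group1_only"]], "group-1-only species"))
  guild <- c(rep("hydrophilic", nt[["hydrophilic"]]),
             rep("mesophilic", nt[["mesophilic"]]),
             rep("xerophilic", nt[["xerophilic"]]),
             rep(NA_character_, nt[["group1_only"]]))
  # a few species carried by two ASVs, as in real amplicon tables
  dup_sp <- species[seq_len(min(3, length(species)))]
  species_asv <- c(species, dup_sp,
                   rep("", nt[["unclassified"]]))
  guild_asv <- c(guild, guild[seq_len(length(dup_sp))],
                 rep(NA_character_, nt[["unclassified"]]))
  n_real <- length(species_asv)
  contam <- contaminant_names[seq_len(config$n_contaminants)]
  m <- n_real + length(contam)
  asv_id <- sprintf("ASV_%04d", seq_len(m))
  sp_all <- c(species_asv, contam)
  genus <- vapply(strsplit(sp_all, " "), function(v)
    if (length(v)) v[1] else "", "")
  taxonomy <- data.frame(asv_id = asv_id, kingdom = "Fungi",
                         phylum = "", class = "", order = "", family = "",
                         genus = genus, species = sp_all,
                         stringsAsFactors = FALSE)
  in_group1 <- sp_all %in% db$ermi$group1

  ## homes and samples -------------------------------------------------------
  homes <- sprintf("H%02d", seq_len(config$n_homes))
  location <- sample(c("Brooklyn", "Manhattan"), config$n_homes, TRUE,
                     prob = c(0.7, 0.3))
  damaged <- stats::rbinom(config$n_homes, 1, config$damage_prevalence) == 1
  summer_homes <- homes[seq_len(round(config$summer_fraction *
                                        config$n_homes))]

  md <- list()
  add <- function(home, room, type, loc, season) {
    md[[length(md) + 1]] <<- data.frame(
      sample_id = sprintf("S%03d", length(md) + 1), home_id = home,
      room = room, sample_type = type, location = loc, season = season,
      is_control = FALSE, stringsAsFactors = FALSE)
  }
  for (i in seq_along(homes)) {
    n_swab <- sample(2:4, 1)
    swab_rooms <- c("bathroom", "front_door",
                    sample(c("bedroom", "kitchen")))[seq_len(n_swab)]
    for (season in c("winter",
                     if (homes[i] %in% summer_homes) "summer")) {
      add(homes[i], "living_room", "vacuum", location[i], season)
      add(homes[i], "living_room", "dust_fall", location[i], season)
      for (r in swab_rooms) add(homes[i], r, "swab", location[i], season)
    }
  }
  for (key in names(config$outdoor_n)) {
    parts <- strsplit(key, "-", fixed = TRUE)[[1]]
    for (k in seq_len(config$outdoor_n[[key]]))
      add("", "other", "outdoor_dust_fall", parts[1], parts[2])
  }
  for (k in seq_len(config$n_controls)) {
    md[[length(md) + 1]] <- data.frame(
      sample_id = sprintf("S%03d", length(md) + 1), home_id = "",
      room = "other", sample_type = "dust_fall", location = "Brooklyn",
      season = "winter", is_control = TRUE, stringsAsFactors = FALSE)
  }
  metadata <- do.call(rbind, md)

  ## counts ------------------------------------------------------------------
  baseline <- exp(stats::rnorm(n_real, 0, config$baseline_sd))
  names(baseline) <- asv_id[seq_len(n_real)]
  # calibrate guild blocks to the configured undamaged community shares
  # (remainder to unclassified + group-1-only taxa)
  rest_share <- 1 - sum(config$guild_shares)
  in_rest <- is.na(guild_asv)
  blocks <- c(as.list(config$guild_shares), list(rest = rest_share))
  for (bn in names(blocks)) {
    idx <- if (bn == "rest") in_rest else (!in_rest & guild_asv == bn)
    if (!any(idx))
      stop("infeasible config: zero taxa in block '", bn,
           "' with nonzero share")
    baseline[idx] <- baseline[idx] / sum(baseline[idx]) * blocks[[bn]]
  }
  # Damage multiplies the expected *share* of each affected set by exactly
  # its configured effect; unaffected taxa absorb the compensation so the
  # ground-truth rate ratio on relative abundances equals the effect.
  effect_for <- function(type) {
    e <- rep(1, n_real)
    ev <- config$effects[[type]]
    if (is.null(ev)) return(e)
    affected <- rep(FALSE, n_real)
    for (set in names(ev)) {
      hit <- if (set == "group1") in_group1[seq_len(n_real)]
             else !is.na(guild_asv) & guild_asv == set
      e[hit] <- e[hit] * ev[[set]]
      affected <- affected | hit
    }
    S <- sum(baseline)
    w_aff_new <- sum(baseline[affected] * e[affected])
    w_rest <- S - sum(baseline[affected])
    if (w_rest <= 0 || S - w_aff_new <= 0)
      stop("infeasible config: damage effects leave no room for ",
           "unaffected taxa (affected share too large)")
    e[!affected] <- (S - w_aff_new) / w_rest
    e
  }
  dmap <- stats::setNames(damaged, homes)
  counts <- matrix(0, m, nrow(metadata),
                   dimnames = list(asv_id, metadata$sample_id))
  true_load <- stats::setNames(rep(NA_real_, nrow(metadata)),
                               metadata$sample_id)
  for (s in seq_len(nrow(metadata))) {
    rec <- metadata[s, ]
    if (rec$is_control) {
      y <- numeric(m)
      w_c <- exp(stats::rnorm(length(contam), 0, 0.5))
      depth <- sample(300:1500, 1)
      rel <- w_c / sum(w_c)
      y[n_real + seq_along(contam)] <-
        stats::rnbinom(length(contam), mu = rel * depth, size = config$theta)
      xtalk <- stats::runif(n_real) < 0.05
      y[seq_len(n_real)][xtalk] <- stats::rpois(sum(xtalk), 2)
      counts[, s] <- y
      next
    }
    w <- baseline
    if (rec$sample_type != "outdoor_dust_fall" &&
        isTRUE(dmap[[rec$home_id]]))
      w <- w * effect_for(rec$sample_type)
    true_load[s] <- sum(w)
    rel <- w / sum(w)
    depth <- sample(config$depth_range[1]:config$depth_range[2], 1)
    y <- stats::rnbinom(n_real, mu = rel * depth, size = config$theta)
    yc <- numeric(length(contam))
    hitc <- stats::runif(length(contam)) < 0.15
    yc[hitc] <- stats::rpois(sum(hitc), 15)
    counts[, s] <- c(y, yc)
  }

  ## qPCR for standardized sample types --------------------------------------
  qsel <- metadata$sample_type %in% c("vacuum", "dust_fall") &
    !metadata$is_control & metadata$home_id != ""
  sdlog <- sqrt(log(1 + config$qpcr_noise_cv^2))
  qpcr <- data.frame(
    sample_id = metadata$sample_id[qsel],
    biomass = 1e6 * true_load[qsel] / sum(baseline) *
      stats::rlnorm(sum(qsel), -sdlog^2 / 2, sdlog),
    stringsAsFactors = FALSE)

  insp <- generate_inspections(
    data.frame(home_id = homes, damaged = damaged,
               stringsAsFactors = FALSE),
    config, seed = as.integer((seed + 1) %% 2147483647))

  structure(list(counts = count_matrix(counts),
                 taxonomy = taxonomy, metadata = metadata,
                 inspections = insp, qpcr = qpcr,
                 truth = list(config = config,
                              damage = data.frame(home_id = homes,
                                                  damaged = damaged,
                                                  stringsAsFactors = FALSE),
                              guild_by_asv = stats::setNames(guild_asv,
                                asv_id[seq_len(n_real)]),
                              group1_by_asv = stats::setNames(
                                in_group1[seq_len(n_real)],
                                asv_id[seq_len(n_real)]))),
            class = "generated_study")
}

#' Generate building inspections consistent with damage status
#'
#' Damaged homes receive one to three visible-mold observations with
#' lognormal areas spanning both size categories; other damage (cracking
#' paint, peeling, water maps) occurs in damaged and undamaged homes alike;
#' moisture-meter readings are drawn per room with damaged homes shifted
#' upward so that some homes exceed the elevated threshold of 15; window
#' condensation with growth is more likely in damaged homes. Undamaged
#' homes never receive a mold observation.
#'
#' @param damage_status Data frame with `home_id` and logical `damaged`.
#' @param config A [scenario_config()].
#' @param seed Integer seed.
#' @return List of `observations`, `readings`, `condensation` data frames.
#' @export
generate_inspections <- function(damage_status, config = scenario_config(),
                                 seed = 1) {
  set.seed(as.integer(seed %% 2147483647))
  rooms <- c("bathroom", "bedroom", "living_room", "kitchen")
  obs <- list(); rds <- list(); cond <- list()
  for (i in seq_len(nrow(damage_status))) {
    h <- damage_status$home_id[i]
    dmg <- isTRUE(damage_status$damaged[i])
    if (dmg) {
      n_mold <- sample(1:3, 1)
      for (k in seq_len(n_mold))
        obs[[length(obs) + 1]] <- data.frame(
          home_id = h, room = sample(rooms, 1),
          surface = sample(c("wall", "ceiling", "window"), 1,
                           prob = c(0.7, 0.2, 0.1)),
          damage_type = "visible_mold",
          area_m2 = round(stats::rlnorm(1, log(0.8), 1), 2),
          stringsAsFactors = FALSE)
    }
    n_other <- stats::rbinom(1, 2, if (dmg) 0.45 else 0.25)
    for (k in seq_len(n_other))
      obs[[length(obs) + 1]] <- data.frame(
        home_id = h, room = sample(rooms, 1), surface = "wall",
        damage_type = sample(c("cracking_paint", "peeling", "water_map"), 1),
        area_m2 = round(stats::rlnorm(1, log(0.6), 0.8), 2),
        stringsAsFactors = FALSE)
    for (r in rooms) {
      v <- round(pmax(stats::rnorm(1, if (dmg) 12 else 9, 3), 0), 1)
      if (!dmg) v <- min(v, 15)  # elevated moisture only with actual damage
      rds[[length(rds) + 1]] <- data.frame(
        home_id = h, room = r, value = v, stringsAsFactors = FALSE)
    }
    cond[[length(cond) + 1]] <- data.frame(
      home_id = h,
      condensation_growth = dmg && stats::runif(1) < 0.35,
      stringsAsFactors = FALSE)
  }
  list(observations = if (length(obs)) do.call(rbind, obs) else
         data.frame(home_id = character(), room = character(),
                    surface = character(), damage_type = character(),
                    area_m2 = numeric(), stringsAsFactors = FALSE),
       readings = do.call(rbind, rds),
       condensation = do.call(rbind, cond))
}

#' @export
print.generated_study <- function(x, ...) {
  cat("Synthetic mycobiome study:", nrow(x$truth$damage), "homes (",
      sum(x$truth$damage$damaged), "damaged ),",
      ncol(x$counts$counts), "samples,", nrow(x$counts$counts), "ASVs\n")
  invisible(x)
}

#' Write a generated study as the package's TSV dialects
#'
#' Writes `counts.tsv`, `taxonomy.tsv`, `metadata.tsv`, `qpcr.tsv`,
#' `observations.tsv`, `readings.tsv` and `condensation.tsv` into a
#' directory, the same formats the readers in this package accept.
#'
#' @param study A `generated_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "generated_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, f)
    utils::write.table(d, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  write_counts(study$counts, file.path(dir, "counts.tsv"))
  wt(study$taxonomy, "taxonomy.tsv")
  wt(study$metadata, "metadata.tsv")
  wt(study$qpcr, "qpcr.tsv")
  wt(study$inspections$observations, "observations.tsv")
  wt(study$inspections$readings, "readings.tsv")
  wt(study$inspections$condensation, "condensation.tsv")
  invisible(dir)
}

#' Write or read a scenario configuration as YAML
#'
#' @param config A [scenario_config()].
#' @param path YAML file path.
#' @return `write_scenario_config` returns `path` invisibly;
#'   `read_scenario_config` returns a validated `scenario_config`.
#' @export
write_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("scenario config files need the yaml package")
  out <- unclass(config)
  # named vectors must become maps, or yaml drops the names
  out$effects <- lapply(out$effects, as.list)
  for (f in c("n_taxa", "outdoor_n", "guild_shares"))
    out[[f]] <- as.list(out[[f]])
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("scenario config files need the yaml package")
  raw <- yaml::read_yaml(path)
  raw$effects <- lapply(raw$effects, unlist)
  for (f in c("n_taxa", "outdoor_n", "guild_shares"))
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  do.call(scenario_config, raw)
}

#' Read a study previously written with [write_study()]
#'
#' @param dir Directory holding the TSVs.
#' @return A list with the same components as a `generated_study`, minus
#'   the ground truth.
#' @export
read_study <- function(dir) {
  list(counts = read_counts(file.path(dir, "counts.tsv")),
       taxonomy = read_taxonomy(file.path(dir, "taxonomy.tsv")),
       metadata = read_metadata(file.path(dir, "metadata.tsv")),
       inspections = list(
         observations = utils::read.delim(file.path(dir, "observations.tsv"),
                                          stringsAsFactors = FALSE),
         readings = utils::read.delim(file.path(dir, "readings.tsv"),
                                      stringsAsFactors = FALSE),
         condensation = utils::read.delim(file.path(dir, "condensation.tsv"),
                                          stringsAsFactors = FALSE)),
       qpcr = read_qpcr(file.path(dir, "qpcr.tsv")))
}
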