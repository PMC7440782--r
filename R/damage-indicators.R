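#' Is a moisture-meter reading elevated?
#'
#' Wall moisture content is screened with a pinless moisture meter on a
#' unitless meter scale; readings strictly above 15 are considered elevated
#' (15 itself is not).
#'
#' @param value Numeric reading(s).
#' @return Logical vector.
#' @export
elevated_reading <- function(value) value > 15

# area-category labels for a summed damage area against a cut:
# "0" / "low" (0 < x < cut) / "high" (x >= cut)
size_category <- function(total_area, cut) {
  if (total_area <= 0) "0" else if (total_area < cut) "low" else "high"
}

count_category <- function(n) if (n == 0) "0" else if (n == 1) "1" else "2+"

#' Derive the eight home-level building damage indicators
#'
#' From a home's researcher-recorded damage observations, moisture-meter
#' readings and window-condensation assessment, derives the standard
#' indicator set: visible mold (yes/no), number of separate mold areas
#' (0/1/2+), total mold area category (0 / low / high with the house cut at
#' 1.9 m2, boundary in the high category), the same three indicators for
#' mold-plus-other damage ("other damage" covers cracking paint, peeling
#' materials and water maps), the count of elevated moisture readings
#' (0/1+), and a composite damage index. The composite (range 0-6) is the
#' sum of a mold-area-count score (0/1/2), a mold-size score (0/1/2 using
#' the same house cuts), an any-elevated-reading score (0/1), and a
#' window-condensation-with-growth score (0/1).
#'
#' Observations with zero area are ignored: only damage with recorded
#' surface area counts as a damage area.
#'
#' @param observations Data frame of this home's damage observations with
#'   columns `damage_type` (one of `visible_mold`, `cracking_paint`,
#'   `peeling`, `water_map`) and `area_m2`; may have zero rows.
#' @param readings Numeric vector of the home's moisture-meter readings.
#' @param condensation Logical: any observed window condensation with
#'   microbial growth.
#' @param mold_cut House-level area cut in m2 (default 1.9).
#' @return One-row data frame with the eight indicators, the integer
#'   `composite_index`, and its category (`0`, `1-2`, `3-6`).
#' @export
derive_home_indicators <- function(observations, readings,
                                   condensation = FALSE, mold_cut = 1.9) {
  obs <- observations[observations$area_m2 > 0, , drop = FALSE]
  mold <- obs[obs$damage_type == "visible_mold", , drop = FALSE]
  n_mold <- nrow(mold)
  n_all <- nrow(obs)
  mold_area <- sum(mold$area_m2)
  all_area <- sum(obs$area_m2)
  n_elev <- sum(elevated_reading(readings))

  count_score <- min(n_mold, 2L)
  size_score <- if (mold_area <= 0) 0L else if (mold_area < mold_cut) 1L else 2L
  composite <- count_score + size_score + as.integer(n_elev > 0) +
    as.integer(isTRUE(condensation))

  data.frame(
    mold_damage = if (n_mold > 0) "yes" else "no",
    n_mold_areas = count_category(n_mold),
    mold_size_cat = size_category(mold_area, mold_cut),
    mold_other_damage = if (n_all > 0) "yes" else "no",
    n_mold_other_areas = count_category(n_all),
    mold_other_size_cat = size_category(all_area, mold_cut),
    n_readings_gt15 = if (n_elev > 0) "1+" else "0",
    composite_index = composite,
    composite_cat = if (composite == 0) "0" else
      if (composite <= 2) "1-2" else "3-6",
    stringsAsFactors = FALSE)
}

#' Derive the four room-level damage indicators
#'
#' Room-level analysis uses only visible-mold presence and size, and
#' mold-plus-other-damage presence and size, with the room area cut at
#' 0.9 m2 (boundary in the high category).
#'
#' @param observations Data frame of one room's damage observations
#'   (`damage_type`, `area_m2`); may have zero rows.
#' @param mold_cut Room-level area cut in m2 (default 0.9).
#' @return One-row data frame with `mold_damage`, `mold_size_cat`,
#'   `mold_other_damage`, `mold_other_size_cat`.
#' @export
derive_room_indicators <- function(observations, mold_cut = 0.9) {
  obs <- observations[observations$area_m2 > 0, , drop = FALSE]
  mold <- obs[obs$damage_type == "visible_mold", , drop = FALSE]
  data.frame(
    mold_damage = if (nrow(mold) > 0) "yes" else "no",
    mold_size_cat = size_category(sum(mold$area_m2), mold_cut),
    mold_other_damage = if (nrow(obs) > 0) "yes" else "no",
    mold_other_size_cat = size_category(sum(obs$area_m2), mold_cut),
    stringsAsFactors = FALSE)
}

#' Home-level indicators for every home in an inspection set
#'
#' @param observations All damage observations (`home_id`, `room`,
#'   `surface`, `damage_type`, `area_m2`).
#' @param readings All moisture readings (`home_id`, `room`, `value`).
#' @param condensation Data frame (`home_id`, `condensation_growth`
#'   logical) or `NULL` for none.
#' @param home_ids Homes to report (defaults to those appearing anywhere in
#'   the inputs).
#' @return Data frame, one row per home, `home_id` first.
#' @export
derive_all_home_indicators <- function(observations, readings,
                                       condensation = NULL,
                                       home_ids = NULL) {
  if (is.null(home_ids))
    home_ids <- sort(unique(c(observations$home_id, readings$home_id,
                              condensation$home_id)))
  rows <- lapply(home_ids, function(h) {
    cond <- FALSE
    if (!is.null(condensation) && h %in% condensation$home_id)
      cond <- isTRUE(as.logical(
        condensation$condensation_growth[condensation$home_id == h][1]))
    cbind(data.frame(home_id = h, stringsAsFactors = FALSE),
          derive_home_indicators(
            observations[observations$home_id == h, , drop = FALSE],
            readings$value[readings$home_id == h],
            cond))
  })
  do.call(rbind, rows)
}

#' Room-level indicators for every (home, room) with observations
#'
#' @param observations All damage observations.
#' @param rooms Optional data frame (`home_id`, `room`) of rooms to assess;
#'   defaults to every room mentioned in `observations`.
#' @return Data frame keyed by `home_id`, `room`.
#' @export
derive_all_room_indicators <- function(observations, rooms = NULL) {
  if (is.null(rooms))
    rooms <- unique(observations[, c("home_id", "room"), drop = FALSE])
  rows <- lapply(seq_len(nrow(rooms)), function(i) {
    sel <- observations$home_id == rooms$home_id[i] &
      observations$room == rooms$room[i]
    cbind(rooms[i, , drop = FALSE],
          derive_room_indicators(observations[sel, , drop = FALSE]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
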