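#' Classify dendritic spines as thin or mushroom
#'
#' Applies the 2D head-diameter rule: spines with head diameter below
#' 350 nm are thin, at or above 350 nm mushroom. The boundary value itself
#' is assigned to mushroom — a fixed, documented tie-break, since the rule
#' only specifies "lower or higher".
#'
#' @param spines A data frame with a `head_diameter_nm` column, or a
#'   numeric vector of diameters.
#' @param boundary_nm Class boundary (default 350 nm).
#' @return The input as a tibble with a `class` column
#'   (`"thin"`/`"mushroom"`); for vector input, a character vector.
#' @examples
#' classify_spines(c(200, 600, 350))
#' @export
classify_spines <- function(spines, boundary_nm = 350) {
  .check_number(boundary_nm, "boundary_nm", lower = 0, strict_lower = TRUE)
  if (is.numeric(spines)) {
    if (any(spines <= 0)) abort("head diameters must be positive.")
    return(ifelse(spines < boundary_nm, "thin", "mushroom"))
  }
  if (!is.data.frame(spines) || !"head_diameter_nm" %in% names(spines)) {
    abort("`spines` needs a `head_diameter_nm` column.")
  }
  d <- spines$head_diameter_nm
  if (length(d) && (anyNA(d) || any(d <= 0))) {
    abort("head diameters must be positive.")
  }
  out <- as_tibble(spines)
  out$class <- ifelse(d < boundary_nm, "thin", "mushroom")
  out
}

#' Spine densities per 10 micrometers of dendrite
#'
#' Computes total, thin and mushroom spine densities normalized per 10 µm
#' of dendritic length: `density = 10 * count / length_um`. Thin and
#' mushroom densities sum to the total by construction, and pooling
#' sub-segments (summing counts and lengths) leaves the density of the
#' whole unchanged. Segment lengths outside 10--200 µm are accepted with a
#' warning, as typical analyses use 50--70 µm segments.
#'
#' @param spines A data frame of spines with a `class` column (from
#'   [classify_spines()]) and a `dendrite_id` column, or with
#'   `head_diameter_nm` (then classification is applied first). May be
#'   empty.
#' @param segments A data frame with columns `dendrite_id`, `length_um`
#'   (> 0).
#' @return A tibble with one row per segment: `dendrite_id`, `length_um`,
#'   `n_spines`, `n_thin`, `n_mushroom`, `density_total`, `density_thin`,
#'   `density_mushroom` (all per 10 µm).
#' @examples
#' sp <- data.frame(dendrite_id = "d1", head_diameter_nm = c(200, 300, 600))
#' spine_density(sp, data.frame(dendrite_id = "d1", length_um = 60))
#' @export
spine_density <- function(spines, segments) {
  if (!is.data.frame(segments) ||
      !all(c("dendrite_id", "length_um") %in% names(segments))) {
    abort("`segments` needs columns `dendrite_id` and `length_um`.")
  }
  if (any(segments$length_um <= 0)) abort("segment lengths must be > 0.")
  if (any(segments$length_um < 10 | segments$length_um > 200)) {
    warn("segment length outside the usual 10-200 um analysis range.")
  }
  if (!is.data.frame(spines)) abort("`spines` must be a data frame.")
  if (nrow(spines) > 0 && !"class" %in% names(spines)) {
    spines <- classify_spines(spines)
  }
  counts <- if (nrow(spines) == 0) {
    tibble(dendrite_id = character(), n_thin = integer(),
           n_mushroom = integer())
  } else {
    if (!"dendrite_id" %in% names(spines)) {
      abort("`spines` needs a `dendrite_id` column.")
    }
    spines |>
      group_by(.data$dendrite_id) |>
      summarise(
        n_thin = sum(.data$class == "thin"),
        n_mushroom = sum(.data$class == "mushroom"),
        .groups = "drop"
      )
  }
  as_tibble(segments) |>
    left_join(counts, by = "dendrite_id") |>
    mutate(
      n_thin = dplyr::coalesce(.data$n_thin, 0L),
      n_mushroom = dplyr::coalesce(.data$n_mushroom, 0L),
      n_spines = .data$n_thin + .data$n_mushroom,
      density_thin = 10 * .data$n_thin / .data$length_um,
      density_mushroom = 10 * .data$n_mushroom / .data$length_um,
      density_total = 10 * .data$n_spines / .data$length_um
    ) |>
    select("dendrite_id", "length_um", "n_spines", "n_thin", "n_mushroom",
           "density_total", "density_thin", "density_mushroom")
}

#' Varicosity density per 10-µm-side cube
#'
#' Normalizes a varicosity count within an imaged stack volume to a
#' standard cube of 10 µm side (1000 µm³):
#' `density = count * 1000 / (x * y * z)` with dimensions in µm.
#'
#' @param count Non-negative varicosity count.
#' @param volume_dims_um Length-3 numeric `c(x, y, z)` stack dimensions in
#'   µm, all > 0.
#' @return Density (varicosities per 10-µm cube).
#' @examples
#' varicosity_density(108, c(60, 60, 3)) # 10
#' @export
varicosity_density <- function(count, volume_dims_um) {
  .check_number(count, "count", lower = 0)
  if (length(volume_dims_um) != 3L || any(!is.finite(volume_dims_um)) ||
      any(volume_dims_um <= 0)) {
    abort("`volume_dims_um` must be three positive dimensions c(x, y, z).")
  }
  count * 1000 / prod(volume_dims_um)
}

#' Per-dendrite and per-group spine morphometry summary
#'
#' Convenience wrapper: classifies spines, computes per-dendrite densities
#' and, when the segment table carries a `group` column, group-level mean
#' densities and the mushroom proportion.
#'
#' @inheritParams spine_density
#' @return A list with `per_dendrite` (from [spine_density()], plus
#'   `group` if present) and `per_group` (NULL without groups).
#' @export
morpho_summarize <- function(spines, segments) {
  per_dend <- spine_density(spines, segments)
  if (!"group" %in% names(segments)) {
    return(list(per_dendrite = per_dend, per_group = NULL))
  }
  per_dend <- per_dend |>
    left_join(select(as_tibble(segments), "dendrite_id", "group"),
              by = "dendrite_id")
  per_group <- per_dend |>
    group_by(.data$group) |>
    summarise(
      n_dendrites = dplyr::n(),
      mean_density_total = mean(.data$density_total),
      mean_density_thin = mean(.data$density_thin),
      mean_density_mushroom = mean(.data$density_mushroom),
      prop_mushroom = sum(.data$n_mushroom) / pmax(sum(.data$n_spines), 1L),
      .groups = "drop"
    )
  list(per_dendrite = per_dend, per_group = per_group)
}
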