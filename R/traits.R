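#' Elliptical leaf-area proxy from length and width
#'
#' Returns `factor * length * width` (cm^2), the classical proxy for leaf
#' area from linear leaf dimensions; the correction factor accounts for the
#' difference between a rectangle and the elliptical leaf outline. Default
#' 2/3; 3/4 is the common alternative.
#'
#' @param length,width leaf length and width (cm), > 0.
#' @param factor shape correction factor, default 2/3.
#' @return leaf area proxy in cm^2.
#' @export
leaf_area_proxy <- function(length, width, factor = 2 / 3) {
  if (any(!is.finite(length)) || any(!is.finite(width)) ||
      any(length <= 0) || any(width <= 0))
    stop("length and width must be positive")
  factor * length * width
}

#' Per-species trait scalars from flora min-max ranges
#'
#' Collapses each species' reported leaf length/width range into a single
#' scalar. The "median" statistic is the range midpoint (min + max)/2 --
#' floras report ranges, not measurement sets -- and "maximum" is the upper
#' bound. The length-width product is computed from the chosen statistic of
#' length and of width via [leaf_area_proxy()]. Species with a missing
#' required bound are skipped and counted.
#'
#' @param traits data.frame with species, length_min, length_max,
#'   width_min, width_max (cm); any bound may be NA.
#' @param measure "length", "width" or "lw_product".
#' @param statistic "median" (range midpoint) or "maximum".
#' @param factor area-proxy correction factor.
#' @return data.frame (species, value); units cm, or cm^2 for lw_product.
#'   `attr(, "n_skipped")` counts species dropped for missing bounds.
#' @export
species_trait_scalars <- function(traits, measure = c("length", "width",
                                                      "lw_product"),
                                  statistic = c("median", "maximum"),
                                  factor = 2 / 3) {
  measure <- match.arg(measure)
  statistic <- match.arg(statistic)
  scal <- function(mn, mx) {
    if (statistic == "median") (mn + mx) / 2 else mx
  }
  if (measure == "length") {
    v <- scal(traits$length_min, traits$length_max)
  } else if (measure == "width") {
    v <- scal(traits$width_min, traits$width_max)
  } else {
    l <- scal(traits$length_min, traits$length_max)
    w <- scal(traits$width_min, traits$width_max)
    v <- ifelse(is.na(l) | is.na(w), NA_real_, factor * l * w)
  }
  keep <- !is.na(v)
  bad_bounds <- with(traits, (!is.na(length_min) & !is.na(length_max) &
                                (length_min <= 0 | length_min > length_max)) |
                       (!is.na(width_min) & !is.na(width_max) &
                          (width_min <= 0 | width_min > width_max)))
  if (any(bad_bounds))
    stop("invalid trait ranges (need 0 < min <= max) for species: ",
         paste(head(traits$species[bad_bounds], 5L), collapse = ", "))
  out <- data.frame(species = as.character(traits$species[keep]),
                    value = v[keep], stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- sum(!keep)
  attr(out, "measure") <- measure
  attr(out, "statistic") <- statistic
  out
}

#' Unweighted community mean trait per grid cell
#'
#' Per-cell arithmetic mean of the trait scalar over the species present,
#' unweighted by abundance (presence/absence only), optionally restricted
#' to a life form. Species with no scalar are skipped (and counted);
#' species with missing phenology are not excluded from habit-based
#' subsets.
#'
#' @param presence a `presence_matrix` (cells x species).
#' @param scalars data.frame (species, value) from
#'   [species_trait_scalars()].
#' @param traits optional species trait table with habit/phenology columns,
#'   required when filtering by life form.
#' @param habit optional habit filter: "tree", "shrub" or "liana".
#' @param phenology optional phenology filter: "deciduous" or "evergreen".
#' @return data.frame (cell_id, mean_value, n_contributing); cells with no
#'   contributing species get NA. `attr(, "n_missing_scalar")` counts
#'   present species lacking a scalar.
#' @export
community_mean <- function(presence, scalars, traits = NULL,
                           habit = NULL, phenology = NULL) {
  sp <- colnames(presence)
  keep <- rep(TRUE, length(sp))
  if (!is.null(habit) || !is.null(phenology)) {
    if (is.null(traits)) stop("life-form filtering needs the traits table")
    tt <- traits[match(sp, traits$species), ]
    if (!is.null(habit)) keep <- keep & tt$habit %in% habit
    if (!is.null(phenology)) keep <- keep & tt$phenology %in% phenology
  }
  val <- scalars$value[match(sp, scalars$species)]
  n_missing <- sum(keep & is.na(val) & colSums(presence) > 0)
  use <- keep & !is.na(val)

  pm <- presence[, use, drop = FALSE]
  v <- val[use]
  n_contrib <- as.integer(pm %*% rep(1, length(v)))
  total <- as.numeric(pm %*% v)
  out <- data.frame(
    cell_id = as.integer(rownames(presence)),
    mean_value = ifelse(n_contrib > 0, total / pmax(n_contrib, 1L), NA_real_),
    n_contributing = n_contrib)
  attr(out, "n_missing_scalar") <- n_missing
  out
}

#' Assemble the community-trait cell table
#'
#' Convenience wrapper building a cell table with richness and the three
#' community mean leaf-size surfaces (length, width, length-width product)
#' from a presence matrix and species trait ranges.
#'
#' @param presence a `presence_matrix`.
#' @param traits species trait table.
#' @param climate optional climate cell table to join on cell_id.
#' @param statistic per-species statistic, "median" or "maximum".
#' @return cell table with richness, mean_length, mean_width,
#'   mean_lw_product (plus climate columns when supplied).
#' @export
community_trait_table <- function(presence, traits, climate = NULL,
                                  statistic = "median") {
  out <- data.frame(cell_id = as.integer(rownames(presence)),
                    richness = as.integer(rowSums(presence)))
  for (m in c("length", "width", "lw_product")) {
    sc <- species_trait_scalars(traits, m, statistic)
    cm <- community_mean(presence, sc)
    out[[paste0("mean_", m)]] <- cm$mean_value[match(out$cell_id, cm$cell_id)]
  }
  if (!is.null(climate)) out <- merge(climate, out, by = "cell_id")
  out[order(out$cell_id), , drop = FALSE]
}
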