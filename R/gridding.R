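#' Analysis grid specification
#'
#' Planar grid in km. Cell membership is half-open: a point belongs to cell
#' (i, j), 0-based, iff x0 + i*s <= x < x0 + (i+1)*s (likewise for y), and
#' cell_id = j*nx + i.
#'
#' @param nx,ny number of cells along x and y.
#' @param cell_km cell size (km), default 50.
#' @param x0,y0 grid origin (km).
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(nx, ny, cell_km = 50, x0 = 0, y0 = 0) {
  stopifnot(nx >= 1, ny >= 1)
  if (cell_km <= 0) stop("cell size must be > 0")
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 cell_km = cell_km, x0 = x0, y0 = y0),
            class = "grid_spec")
}

#' Cell centres of a grid
#'
#' @param grid a [grid_spec()].
#' @return data.frame with cell_id, i, j, x, y (cell-centre km).
#' @export
cell_centres <- function(grid) {
  i <- rep(seq_len(grid$nx) - 1L, times = grid$ny)
  j <- rep(seq_len(grid$ny) - 1L, each = grid$nx)
  data.frame(cell_id = j * grid$nx + i, i = i, j = j,
             x = grid$x0 + (i + 0.5) * grid$cell_km,
             y = grid$y0 + (j + 0.5) * grid$cell_km)
}

# point -> 0-based cell indices; NA outside the grid
point_cell_index <- function(grid, x, y) {
  i <- floor((x - grid$x0) / grid$cell_km)
  j <- floor((y - grid$y0) / grid$cell_km)
  bad <- i < 0 | i >= grid$nx | j < 0 | j >= grid$ny
  i[bad] <- NA_integer_; j[bad] <- NA_integer_
  list(i = as.integer(i), j = as.integer(j),
       cell_id = as.integer(j * grid$nx + i))
}

#' Rasterise occurrence records to a presence/absence matrix
#'
#' @param occurrences data.frame with columns `species`, `x`, `y` (km).
#' @param grid a [grid_spec()].
#' @param strict if TRUE (default) out-of-bounds records are an error listing
#'   the offending row indices; if FALSE they are dropped and counted in
#'   `attr(, "n_dropped")`.
#' @return logical matrix cells x species (class `presence_matrix`), with
#'   rownames the cell ids and colnames the species ids. Duplicated records
#'   are idempotent.
#' @export
rasterize_occurrences <- function(occurrences, grid, strict = TRUE) {
  stopifnot(all(c("species", "x", "y") %in% names(occurrences)))
  idx <- point_cell_index(grid, occurrences$x, occurrences$y)
  oob <- which(is.na(idx$cell_id))
  if (length(oob) && strict)
    stop("out-of-bounds occurrence rows: ",
         paste(head(oob, 10L), collapse = ", "),
         if (length(oob) > 10L) " ..." else "")
  keep <- !is.na(idx$cell_id)
  sp <- sort(unique(as.character(occurrences$species)))
  ncell <- grid$nx * grid$ny
  pm <- matrix(FALSE, nrow = ncell, ncol = length(sp),
               dimnames = list(as.character(seq_len(ncell) - 1L), sp))
  if (any(keep)) {
    rows <- idx$cell_id[keep] + 1L
    cols <- match(as.character(occurrences$species[keep]), sp)
    pm[cbind(rows, cols)] <- TRUE
  }
  attr(pm, "n_dropped") <- sum(!keep)
  class(pm) <- c("presence_matrix", class(pm))
  pm
}

#' Resample a fine surface onto a coarser grid
#'
#' The coarse value is the chosen statistic (default mean) of the fine cells
#' whose centres fall inside each coarse cell; coarse cells receiving no
#' fine centre get NA.
#'
#' @param fine data.frame with `x`, `y` and one or more value columns.
#' @param grid coarse [grid_spec()].
#' @param statistic aggregation function, default `mean`.
#' @return data.frame with cell_id, x, y (coarse centres) and aggregated
#'   value columns; `attr(, "n_empty")` counts empty coarse cells.
#' @export
resample_surface <- function(fine, grid, statistic = mean) {
  stopifnot(all(c("x", "y") %in% names(fine)))
  if (nrow(fine) == 0L) {
    warning("empty fine input; returning all-NA coarse table")
    out <- cell_centres(grid)[, c("cell_id", "x", "y")]
    attr(out, "n_empty") <- nrow(out)
    return(out)
  }
  vals <- setdiff(names(fine), c("x", "y", "cell_id", "i", "j"))
  idx <- point_cell_index(grid, fine$x, fine$y)
  out <- cell_centres(grid)[, c("cell_id", "x", "y")]
  for (v in vals) {
    agg <- tapply(fine[[v]], idx$cell_id, function(z) {
      z <- z[!is.na(z)]
      if (length(z)) statistic(z) else NA_real_
    })
    col <- rep(NA_real_, nrow(out))
    col[match(as.integer(names(agg)), out$cell_id)] <- as.numeric(agg)
    out[[v]] <- col
  }
  attr(out, "n_empty") <-
    sum(!out$cell_id %in% unique(idx$cell_id[!is.na(idx$cell_id)]))
  out
}

#' Drop species-poor cells
#'
#' Retains cells whose species richness is at least `min_species`
#' (cells with fewer than `min_species` species are removed, so the
#' boundary is kept).
#'
#' @param cells data.frame with a `richness` column.
#' @param min_species minimum richness retained, default 20.
#' @return filtered data.frame; `attr(, "n_removed")` records the count.
#' @export
filter_richness <- function(cells, min_species = 20) {
  stopifnot("richness" %in% names(cells))
  keep <- cells$richness >= min_species
  out <- cells[keep, , drop = FALSE]
  if (nrow(out) == 0L) warning("all cells fall below the richness threshold")
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Mean of the m highest (or lowest) yearly values per cell
#'
#' Ties are broken by year order (earlier year first).
#'
#' @param stack numeric matrix, cells x years.
#' @param m number of years to average, e.g. 2, 4 or 8.
#' @param side `"highest"` or `"lowest"`.
#' @return numeric vector, one value per cell.
#' @export
ranked_year_mean <- function(stack, m, side = c("highest", "lowest")) {
  side <- match.arg(side)
  stack <- as.matrix(stack)
  if (m > ncol(stack)) stop("m exceeds the number of years (", ncol(stack), ")")
  if (m < 1) stop("m must be >= 1")
  apply(stack, 1L, function(z) {
    ord <- order(z, seq_along(z),
                 decreasing = c(side == "highest", FALSE), method = "radix")
    mean(z[ord[seq_len(m)]])
  })
}
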