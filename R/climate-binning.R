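#' Read a grid-cell climate table
#'
#' Delimited text with header `cell_id`, `map_mm`, `mat_c`: one row per
#' 100 x 100 km (or any) grid cell with its mean annual precipitation
#' (mm/yr, >= 0) and mean annual temperature (degrees C).
#'
#' @param file path.
#' @param sep field separator.
#' @return data frame with the three columns above.
#' @export
read_cells <- function(file, sep = ",") {
  x <- utils::read.table(file, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  if (!"cell_id" %in% names(x)) stop("cell table needs a 'cell_id' column", call. = FALSE)
  if (anyDuplicated(x$cell_id)) stop("duplicated cell_id in cell table", call. = FALSE)
  if (!is.null(x$map_mm) && any(x$map_mm < 0, na.rm = TRUE)) {
    stop("map_mm must be >= 0", call. = FALSE)
  }
  x
}

#' Read a species-by-cell occurrence table
#'
#' Delimited text with header `species`, `cell_id`; one row per occupied cell.
#'
#' @inheritParams read_cells
#' @return data frame with columns `species`, `cell_id`.
#' @export
read_occurrences <- function(file, sep = ",") {
  x <- utils::read.table(file, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  if (!all(c("species", "cell_id") %in% names(x))) {
    stop("occurrence table needs columns 'species' and 'cell_id'", call. = FALSE)
  }
  unique(x[, c("species", "cell_id")])
}

#' Summarize species climatic distributions over occupied grid cells
#'
#' For each species, the minimum, mean and maximum of each climate variable
#' across all grid cells where it occurs, plus the occupied-cell count. The
#' species' mean value (used for genus means and trait models) and its
#' min-max envelope (used for bin assignment) both come from this summary.
#'
#' @param occurrences data frame with columns `species`, `cell_id`.
#' @param cells data frame with `cell_id` and one or more numeric climate
#'   columns (e.g. `map_mm`, `mat_c`).
#' @param vars climate columns of `cells` to summarize; defaults to all
#'   numeric columns other than `cell_id`.
#' @return data frame with one row per species: `species`, `n_cells`, and
#'   `min_<var>`, `mean_<var>`, `max_<var>` for each variable.
#' @export
#' @examples
#' cells <- data.frame(cell_id = 1:3, map_mm = c(250, 300, 350))
#' occ <- data.frame(species = "sp1", cell_id = 1:3)
#' species_climate_summary(occ, cells)
species_climate_summary <- function(occurrences, cells,
                                    vars = setdiff(names(cells), "cell_id")) {
  stopifnot(all(c("species", "cell_id") %in% names(occurrences)),
            "cell_id" %in% names(cells), length(vars) >= 1L)
  occurrences <- unique(occurrences[, c("species", "cell_id")])
  bad <- is.na(occurrences$cell_id) | is.na(occurrences$species)
  if (any(bad)) {
    warning(sum(bad), " occurrence row(s) with missing species/cell dropped",
            call. = FALSE)
    occurrences <- occurrences[!bad, , drop = FALSE]
  }
  idx <- match(occurrences$cell_id, cells$cell_id)
  if (anyNA(idx)) {
    stop("occurrences reference unknown cell id(s): ",
         paste(utils::head(unique(occurrences$cell_id[is.na(idx)]), 5L),
               collapse = ", "), call. = FALSE)
  }
  sp <- sort(unique(occurrences$species))
  g <- factor(occurrences$species, levels = sp)
  out <- data.frame(species = sp,
                    n_cells = as.integer(table(g)),
                    stringsAsFactors = FALSE)
  for (v in vars) {
    vals <- cells[[v]][idx]
    out[[paste0("min_", v)]] <- as.numeric(tapply(vals, g, min))
    out[[paste0("mean_", v)]] <- as.numeric(tapply(vals, g, mean))
    out[[paste0("max_", v)]] <- as.numeric(tapply(vals, g, max))
  }
  out
}

#' Build climatic bins over the observed range of a variable
#'
#' Bins are half-open intervals `[lower, upper)` with the top bin closed,
#' spanning the min-max range of the supplied cell values; by default
#' equal-width. Explicit edges override `n_bins`. Conventional defaults for
#' the two variables handled here are 17 bins for MAP and 14 for MAT (pass
#' via `n_bins`).
#'
#' @param values numeric climate values over grid cells (used for the range).
#' @param n_bins number of equal-width bins (>= 2); ignored when `edges` given.
#' @param edges optional strictly increasing numeric vector of bin edges.
#' @param variable label stored with the bins (e.g. `"map"`, `"mat"`).
#' @return data frame of class `"climate_bins"` with columns `variable`,
#'   `lower`, `upper`.
#' @export
#' @examples
#' make_bins(c(0, 1700), n_bins = 17, variable = "map")
#' make_bins(edges = c(200, 300, 400), variable = "map")
make_bins <- function(values = NULL, n_bins = NULL, edges = NULL,
                      variable = "climate") {
  if (is.null(edges)) {
    if (is.null(n_bins) || n_bins < 2L) {
      stop("n_bins must be >= 2 (or supply explicit edges)", call. = FALSE)
    }
    stopifnot(is.numeric(values), length(values) >= 1L)
    rng <- range(values, finite = TRUE)
    if (rng[1] == rng[2]) stop("all values identical; cannot bin", call. = FALSE)
    edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  } else {
    if (length(edges) < 3L) stop("need >= 2 bins (>= 3 edges)", call. = FALSE)
    if (any(diff(edges) <= 0)) stop("bin edges must be strictly increasing", call. = FALSE)
  }
  out <- data.frame(variable = variable,
                    lower = edges[-length(edges)],
                    upper = edges[-1L],
                    stringsAsFactors = FALSE)
  class(out) <- c("climate_bins", "data.frame")
  out
}

# In-bin test honoring the half-open convention (top bin closed).
# `i` indexes the bin row; vectorized over x.
.in_bin <- function(x, bins, i) {
  if (i < nrow(bins)) {
    x >= bins$lower[i] & x < bins$upper[i]
  } else {
    x >= bins$lower[i] & x <= bins$upper[i]
  }
}

# Interval-overlap test between species envelopes [mn, mx] and bin i.
.overlaps_bin <- function(mn, mx, bins, i) {
  if (i < nrow(bins)) {
    mx >= bins$lower[i] & mn < bins$upper[i]
  } else {
    mx >= bins$lower[i] & mn <= bins$upper[i]
  }
}

#' Assign species to climatic bins by their min-max envelope
#'
#' A species belongs to every bin its occupied-cell envelope
#' `[min, max]` intersects, so a species spanning 250-350 mm under 100-mm
#' bins lands in both the 200-300 and the 300-400 bin; a point value of
#' 300 lands only in `[300, 400)` under the half-open convention.
#'
#' @param summaries output of [species_climate_summary()].
#' @param bins output of [make_bins()].
#' @param var cell-table column name the bins refer to (e.g. `"map_mm"`);
#'   `min_<var>`/`max_<var>` must exist in `summaries`.
#' @return data frame with columns `bin` (row index into `bins`), `species`.
#'   Species whose envelope misses all bins are dropped with a warning.
#' @export
assign_species_to_bins <- function(summaries, bins, var) {
  mn <- summaries[[paste0("min_", var)]]
  mx <- summaries[[paste0("max_", var)]]
  if (is.null(mn) || is.null(mx)) {
    stop("summaries lack min_/max_ columns for variable '", var, "'", call. = FALSE)
  }
  res <- vector("list", nrow(bins))
  hit <- logical(nrow(summaries))
  for (i in seq_len(nrow(bins))) {
    in_i <- .overlaps_bin(mn, mx, bins, i)
    hit <- hit | in_i
    res[[i]] <- data.frame(bin = rep(i, sum(in_i)),
                           species = summaries$species[in_i],
                           stringsAsFactors = FALSE)
  }
  if (any(!hit)) {
    warning(sum(!hit), " species outside all '", bins$variable[1],
            "' bins dropped from this variable", call. = FALSE)
  }
  do.call(rbind, res)
}

#' Fill per-bin richness and area
#'
#' Regional richness of a bin is the number of species assigned to it
#' (species whose climatic envelope intersects the bin). Area is the number
#' of grid cells whose climate value lies in the bin. Local richness is the
#' mean, over those cells, of the cell's species count -- cells with no
#' resident species count as 0, and a bin with no cells gets `NA` local
#' richness.
#'
#' @param bins output of [make_bins()].
#' @param membership output of [assign_species_to_bins()].
#' @param cells grid-cell table.
#' @param occurrences species-by-cell table (cell richness is tallied from it).
#' @param var cell-table column the bins refer to.
#' @return `bins` with columns `area`, `local_richness`, `regional_richness`
#'   added.
#' @export
bin_richness <- function(bins, membership, cells, occurrences, var) {
  vals <- cells[[var]]
  if (is.null(vals)) stop("cells lack column '", var, "'", call. = FALSE)
  occurrences <- unique(occurrences[, c("species", "cell_id")])
  cr <- table(factor(occurrences$cell_id, levels = cells$cell_id))
  cell_rich <- as.numeric(cr)
  bins$area <- NA_integer_
  bins$local_richness <- NA_real_
  bins$regional_richness <- NA_integer_
  for (i in seq_len(nrow(bins))) {
    in_i <- .in_bin(vals, bins, i)
    bins$area[i] <- sum(in_i, na.rm = TRUE)
    bins$local_richness[i] <- if (bins$area[i] > 0) {
      mean(cell_rich[which(in_i)])
    } else NA_real_
    bins$regional_richness[i] <- length(unique(membership$species[membership$bin == i]))
  }
  bins
}

#' Bin midpoints
#'
#' Convenience accessor used as the climate value of a bin in bin-level
#' regressions.
#'
#' @param bins output of [make_bins()].
#' @return numeric vector of `(lower + upper)/2`.
#' @export
bin_midpoints <- function(bins) {
  (bins$lower + bins$upper) / 2
}

#' Write the per-bin report
#'
#' @param bins bins with any computed columns.
#' @param file path to a CSV file.
#' @return the path, invisibly.
#' @export
write_bin_report <- function(bins, file) {
  utils::write.csv(as.data.frame(bins), file, row.names = FALSE)
  invisible(file)
}
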