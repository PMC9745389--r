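#' First colonization time of each climatic bin
#'
#' The colonization time of a bin is the age of the oldest lineage
#' reconstructed as occurring in that bin. Candidates are (i) internal nodes
#' whose reconstructed value falls in the bin, at their node age, and (ii)
#' extant tips whose climatic range (or mean, see `tip_mode`) intersects the
#' bin, dated at half the tip's terminal branch length (plus the tip's own
#' age when tips are not at the present, as on a genus-level tree). The
#' recorded time is the maximum over candidates -- a minimum age for the
#' first colonization; bins with no candidates are returned with `NA` time
#' and status `"uncolonized"`.
#'
#' @param asr an `"asr_result"` (data frame with `node`, `age`, `value`).
#' @param tips data frame with columns `tip`, `min`, `max` (climatic
#'   envelope; equal for a point value), `terminal` (terminal branch length,
#'   Myr) and optionally `age` (tip age, default 0).
#' @param bins output of [make_bins()].
#' @param tip_mode `"range"` (default: a tip is a candidate for every bin its
#'   min-max envelope intersects) or `"mean"` (only the bin containing the
#'   midpoint of `min` and `max`).
#' @return data frame of class `"colonization_records"`: one row per bin with
#'   `variable`, `lower`, `upper`, `time` (Myr), `source_kind`
#'   (`"internal"` or `"tip-half-age"`), `source_id` (node number or tip
#'   label; ties joined with `";"`), `n_candidates`, `status`.
#' @export
first_colonization_times <- function(asr, tips, bins,
                                     tip_mode = c("range", "mean")) {
  tip_mode <- match.arg(tip_mode)
  stopifnot(all(c("node", "age", "value") %in% names(asr)),
            all(c("tip", "min", "max", "terminal") %in% names(tips)))
  if (any(tips$min > tips$max)) stop("tip min > max", call. = FALSE)
  tip_age <- if (is.null(tips$age)) rep(0, nrow(tips)) else tips$age
  tip_time <- tip_age + tips$terminal / 2
  if (tip_mode == "mean") {
    tmn <- tmx <- (tips$min + tips$max) / 2
  } else {
    tmn <- tips$min
    tmx <- tips$max
  }
  out <- data.frame(variable = bins$variable, lower = bins$lower,
                    upper = bins$upper, time = NA_real_,
                    source_kind = NA_character_, source_id = NA_character_,
                    n_candidates = 0L, status = "uncolonized",
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(bins))) {
    node_in <- .in_bin(asr$value, bins, i)
    tip_in <- .overlaps_bin(tmn, tmx, bins, i)
    cand_time <- c(asr$age[node_in], tip_time[tip_in])
    if (!length(cand_time)) next
    cand_id <- c(as.character(asr$node[node_in]), tips$tip[tip_in])
    cand_kind <- c(rep("internal", sum(node_in)), rep("tip-half-age", sum(tip_in)))
    best <- max(cand_time)
    at <- which(cand_time >= best - 1e-12)
    out$time[i] <- best
    out$source_kind[i] <- paste(unique(cand_kind[at]), collapse = ";")
    out$source_id[i] <- paste(cand_id[at], collapse = ";")
    out$n_candidates[i] <- length(cand_time)
    out$status[i] <- "colonized"
  }
  class(out) <- c("colonization_records", "data.frame")
  out
}

#' Pair colonization times with bin richness
#'
#' Joins the per-bin colonization records with per-bin richness, dropping
#' bins missing either quantity (the number dropped is reported as an
#' attribute and a warning is emitted when the result is empty).
#'
#' @param colonizations output of [first_colonization_times()].
#' @param bins bins with `local_richness` and `regional_richness` filled by
#'   [bin_richness()].
#' @return data frame with `lower`, `upper`, `time`, `local_richness`,
#'   `regional_richness`; attribute `n_dropped` counts excluded bins.
#' @export
time_richness_table <- function(colonizations, bins) {
  m <- merge(colonizations[, c("lower", "upper", "time")],
             as.data.frame(bins)[, c("lower", "upper", "local_richness",
                                     "regional_richness")],
             by = c("lower", "upper"), sort = TRUE)
  keep <- !is.na(m$time) & !(is.na(m$local_richness) & is.na(m$regional_richness))
  out <- m[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  if (!nrow(out)) warning("no bin has both colonization time and richness",
                          call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Write colonization records to CSV
#'
#' @param records output of [first_colonization_times()].
#' @param file path.
#' @return the path, invisibly.
#' @export
write_colonization <- function(records, file) {
  utils::write.csv(as.data.frame(records), file, row.names = FALSE)
  invisible(file)
}
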