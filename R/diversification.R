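#' Method-of-moments net diversification rate from stem age
#'
#' The stem-age method-of-moments estimator of the net diversification rate
#' (speciation minus extinction, events/lineage/Myr) of a clade with `n`
#' extant species and stem age `t` Myr, under an assumed relative extinction
#' fraction `epsilon` = extinction/speciation:
#'
#' \deqn{\hat r = \log[n(1-\epsilon)+\epsilon]/t}
#'
#' A monotypic clade (`n = 1`) gets rate 0 for every `epsilon`.
#'
#' @param n clade richness (>= 1); vectorized.
#' @param t stem age in Myr (> 0); vectorized.
#' @param epsilon relative extinction fraction in `[0, 1)`.
#' @return net diversification rate(s).
#' @export
#' @examples
#' ms_stem_rate(100, 10, 0)    # log(100)/10
#' ms_stem_rate(100, 10, 0.5)  # log(50.5)/10
ms_stem_rate <- function(n, t, epsilon = 0) {
  if (any(n < 1)) stop("n must be >= 1", call. = FALSE)
  if (any(t <= 0)) stop("stem age t must be > 0", call. = FALSE)
  if (any(epsilon < 0 | epsilon >= 1)) stop("epsilon must be in [0, 1)", call. = FALSE)
  log(n * (1 - epsilon) + epsilon) / t
}

#' Species-level diversification rate (DR statistic)
#'
#' The equal-splits speciation-rate proxy of a tip: walking from the tip
#' towards the root, edge `j` (terminal edge is `j = 1`; the root's
#' subtending edge is excluded) contributes its length weighted by
#' `(1/2)^(j-1)` to the equal-splits measure `ES`; the DR statistic is
#' `1/ES`.
#'
#' @param phy a rooted `"phylo"` object with branch lengths.
#' @return data frame with columns `species`, `rate`, `provenance` (`"DR"`),
#'   one row per tip in tip-label order.
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1):0;")
#' dr_statistic(tr)  # ES = 1 + 0.5 = 1.5 for every tip
dr_statistic <- function(phy) {
  validate_phylogeny(phy)
  n <- length(phy$tip.label)
  parent_edge <- match(seq_len(n + phy$Nnode), phy$edge[, 2])
  es <- numeric(n)
  for (i in seq_len(n)) {
    node <- i
    w <- 1
    repeat {
      e <- parent_edge[node]
      if (is.na(e)) break
      es[i] <- es[i] + phy$edge.length[e] * w
      w <- w / 2
      node <- phy$edge[e, 1]
    }
    if (es[i] == 0) {
      stop("equal-splits measure is 0 for tip '", phy$tip.label[i],
           "' (all-zero root path)", call. = FALSE)
    }
  }
  data.frame(species = phy$tip.label, rate = 1 / es, provenance = "DR",
             stringsAsFactors = FALSE)
}

#' Per-clade method-of-moments rates inherited by member species
#'
#' Applies [ms_stem_rate()] to each clade record, with `n` drawn either from
#' the regional (e.g. species in China) or the global richness of the clade,
#' and assigns each member species its clade's rate.
#'
#' @param records clade records (see [clade_records()]) with columns `clade`,
#'   `stem_age`, `richness_region`, `richness_global`.
#' @param membership data frame with columns `tip` (species) and `clade`.
#' @param epsilon relative extinction fraction.
#' @param richness_source `"region"` or `"global"`.
#' @return data frame with columns `species`, `rate`,
#'   `provenance` (`"genus-MS"`), `clade`. Clades without a stem age are
#'   skipped with a warning.
#' @export
clade_rates <- function(records, membership, epsilon = 0.5,
                        richness_source = c("region", "global")) {
  richness_source <- match.arg(richness_source)
  miss <- is.na(records$stem_age)
  if (any(miss)) {
    warning(sum(miss), " clade(s) without stem age skipped", call. = FALSE)
    records <- records[!miss, , drop = FALSE]
  }
  nfield <- if (richness_source == "region") "richness_region" else "richness_global"
  rate <- ms_stem_rate(records[[nfield]], records$stem_age, epsilon)
  idx <- match(membership$clade, records$clade)
  out <- data.frame(species = membership$tip,
                    rate = rate[idx],
                    provenance = "genus-MS",
                    clade = membership$clade,
                    stringsAsFactors = FALSE)
  out[!is.na(out$rate), , drop = FALSE]
}

#' Per-bin mean and median diversification rate
#'
#' Aggregates species rates within each climatic bin, optionally excluding
#' species whose rate exceeds a threshold first (the sensitivity analysis for
#' exceptionally high DR values uses 1.5). Species in the membership without
#' a rate are ignored and counted.
#'
#' @param membership output of [assign_species_to_bins()].
#' @param rates data frame with columns `species`, `rate` (from
#'   [dr_statistic()] or [clade_rates()]).
#' @param exclude_above optional rate threshold; species with `rate >`
#'   threshold are dropped before aggregation.
#' @return data frame with one row per bin: `bin`, `mean_rate`,
#'   `median_rate`, `n_rated`, `n_unrated`, `n_excluded`. Bins with no rated
#'   species get `NA` summaries.
#' @export
bin_rate_summary <- function(membership, rates, exclude_above = NULL) {
  r <- rates$rate[match(membership$species, rates$species)]
  excl <- if (is.null(exclude_above)) rep(FALSE, length(r)) else !is.na(r) & r > exclude_above
  bins <- sort(unique(membership$bin))
  out <- data.frame(bin = bins, mean_rate = NA_real_, median_rate = NA_real_,
                    n_rated = 0L, n_unrated = 0L, n_excluded = 0L)
  for (k in seq_along(bins)) {
    sel <- membership$bin == bins[k]
    ri <- r[sel & !excl]
    out$n_unrated[k] <- sum(is.na(r[sel]))
    out$n_excluded[k] <- sum(excl[sel])
    ri <- ri[!is.na(ri)]
    out$n_rated[k] <- length(ri)
    if (length(ri)) {
      out$mean_rate[k] <- mean(ri)
      out$median_rate[k] <- stats::median(ri)
    }
  }
  out
}

#' Keep clades occurring predominantly in the focal region
#'
#' Retains clade records whose fraction of species in the focal region
#' (`richness_region / richness_global`) is at least `min_fraction`
#' (boundary inclusive; the headline analysis uses 0.60).
#'
#' @param records clade records with both richness fields.
#' @param min_fraction minimum regional fraction.
#' @return the filtered records.
#' @export
filter_predominantly_regional <- function(records, min_fraction = 0.60) {
  if (any(records$richness_global <= 0)) {
    stop("richness_global must be > 0", call. = FALSE)
  }
  records[records$richness_region / records$richness_global >= min_fraction, ,
          drop = FALSE]
}
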