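make_cells <- function(values, var = "map_mm") {
  cells <- data.frame(cell_id = paste0("c", seq_along(values)),
                      stringsAsFactors = FALSE)
  cells[[var]] <- values
  cells
}

test_that("species climate summaries match a brute-force tally", {
  cells <- make_cells(c(250, 300, 350, 500))
  occ <- data.frame(species = c("s1", "s1", "s1", "s2"),
                    cell_id = c("c1", "c2", "c3", "c2"))
  s <- species_climate_summary(occ, cells)
  expect_equal(s$min_map_mm[s$species == "s1"], 250)
  expect_equal(s$mean_map_mm[s$species == "s1"], 300)
  expect_equal(s$max_map_mm[s$species == "s1"], 350)
  # single cell: min = mean = max
  expect_equal(unname(unlist(s[s$species == "s2",
                               c("min_map_mm", "mean_map_mm", "max_map_mm")])),
               rep(300, 3))

  set.seed(21)
  cells2 <- make_cells(stats::runif(40, 0, 2000))
  occ2 <- unique(data.frame(
    species = sample(paste0("sp", 1:100), 600, replace = TRUE),
    cell_id = sample(cells2$cell_id, 600, replace = TRUE)))
  s2 <- species_climate_summary(occ2, cells2)
  for (j in sample(nrow(s2), 10)) {
    sp <- s2$species[j]
    v <- cells2$map_mm[match(occ2$cell_id[occ2$species == sp], cells2$cell_id)]
    expect_equal(s2$min_map_mm[j], min(v))
    expect_equal(s2$mean_map_mm[j], mean(v))
    expect_equal(s2$max_map_mm[j], max(v))
    expect_equal(s2$n_cells[j], length(v))
  }
  expect_error(species_climate_summary(
    data.frame(species = "x", cell_id = "missing"), cells), "unknown cell")
})

test_that("equal-width bins span the range with half-open intervals", {
  b <- make_bins(c(0, 1700), n_bins = 17, variable = "map")
  expect_equal(nrow(b), 17L)
  expect_equal(b$lower[1], 0)
  expect_equal(b$upper[1], 100)
  expect_equal(b$upper[17], 1700)
  b2 <- make_bins(edges = c(200, 300, 400))
  expect_equal(b2$lower, c(200, 300))
  expect_error(make_bins(c(0, 10), n_bins = 1), "n_bins")
  expect_error(make_bins(edges = c(1, 3, 2)), "increasing")
})

test_that("species envelopes land in every intersecting bin", {
  # the worked assignment example: range 250-350 under 100-mm bins
  b <- make_bins(edges = seq(0, 1700, by = 100), variable = "map_mm")
  s <- data.frame(species = c("wide", "point"),
                  min_map_mm = c(250, 300), max_map_mm = c(350, 300),
                  stringsAsFactors = FALSE)
  m <- assign_species_to_bins(s, b, "map_mm")
  expect_setequal(m$bin[m$species == "wide"], c(3L, 4L))
  expect_equal(m$bin[m$species == "point"], 4L)  # half-open convention

  # bins form a contiguous run and match the pairwise oracle
  set.seed(3)
  s2 <- data.frame(species = paste0("sp", 1:500))
  s2$min_map_mm <- stats::runif(500, 0, 1500)
  s2$max_map_mm <- s2$min_map_mm + stats::runif(500, 0, 400)
  m2 <- assign_species_to_bins(s2, b, "map_mm")
  o <- membership_oracle(s2, b, "map_mm")
  expect_equal(m2[order(m2$bin, m2$species), ],
               o[order(o$bin, o$species), ], ignore_attr = TRUE)
  runs <- tapply(m2$bin, m2$species, function(x) all(diff(sort(x)) == 1))
  expect_true(all(runs))
})

test_that("bin richness separates local, regional and area correctly", {
  cells <- make_cells(c(50, 150, 160, 250))
  occ <- data.frame(species = c("a", "b", "a", "b", "c"),
                    cell_id = c("c2", "c2", "c3", "c4", "c4"))
  b <- make_bins(edges = c(0, 100, 200, 300), variable = "map_mm")
  s <- species_climate_summary(occ, cells)
  m <- assign_species_to_bins(s, b, "map_mm")
  br <- bin_richness(b, m, cells, occ, "map_mm")
  expect_equal(br$area, c(1L, 2L, 1L))
  # cell c1 empty: local richness of bin 1 counts it as 0
  expect_equal(br$local_richness[1], 0)
  expect_equal(br$local_richness[2], mean(c(2, 1)))
  expect_true(all(br$local_richness <= br$regional_richness, na.rm = TRUE))
})

test_that("empty bins get zero area and missing local richness", {
  cells <- make_cells(c(50, 250))
  occ <- data.frame(species = "a", cell_id = "c1")
  b <- make_bins(edges = c(0, 100, 200, 300), variable = "map_mm")
  s <- species_climate_summary(occ, cells)
  m <- suppressWarnings(assign_species_to_bins(s, b, "map_mm"))
  br <- bin_richness(b, m, cells, occ, "map_mm")
  expect_equal(br$area[2], 0L)
  expect_true(is.na(br$local_richness[2]))
})

test_that("duplicating the landscape doubles area but not richness", {
  set.seed(9)
  cells <- make_cells(stats::runif(30, 0, 1000))
  occ <- unique(data.frame(
    species = sample(paste0("sp", 1:40), 200, replace = TRUE),
    cell_id = sample(cells$cell_id, 200, replace = TRUE)))
  b <- make_bins(cells$map_mm, n_bins = 8, variable = "map_mm")
  s <- species_climate_summary(occ, cells)
  m <- assign_species_to_bins(s, b, "map_mm")
  br <- bin_richness(b, m, cells, occ, "map_mm")

  cells2 <- cells
  cells2$cell_id <- paste0(cells$cell_id, "_dup")
  occ2 <- occ
  occ2$cell_id <- paste0(occ$cell_id, "_dup")
  cells_d <- rbind(cells, cells2)
  occ_d <- rbind(occ, occ2)
  s_d <- species_climate_summary(occ_d, cells_d)
  m_d <- assign_species_to_bins(s_d, b, "map_mm")
  br_d <- bin_richness(b, m_d, cells_d, occ_d, "map_mm")
  expect_equal(br_d$area, br$area * 2L)
  expect_equal(br_d$local_richness, br$local_richness)
  expect_equal(br_d$regional_richness, br$regional_richness)
})

test_that("every cell value falls in exactly one bin", {
  set.seed(13)
  vals <- stats::runif(200, 0, 1700)
  b <- make_bins(vals, n_bins = 17)
  counts <- colSums(vapply(vals, function(v) {
    vapply(seq_len(nrow(b)), function(i) climrich:::.in_bin(v, b, i), logical(1))
  }, logical(nrow(b))))
  expect_true(all(counts == 1))
})
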