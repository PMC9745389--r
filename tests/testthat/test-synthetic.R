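test_that("birth-death simulator hits the tip count, reproducibly", {
  tr <- sim_bd_tree(50, 1, 0, seed = 8)
  expect_equal(length(tr$tip.label), 50L)
  expect_true(ape::is.ultrametric(tr))
  tr2 <- sim_bd_tree(50, 1, 0, seed = 8)
  expect_identical(write_newick(tr), write_newick(tr2))
  expect_error(sim_bd_tree(10, 0.5, 0.6), "death")
})

test_that("whole-tree stem estimate tracks the generating birth rate", {
  set.seed(71)
  rates <- replicate(150, {
    tr <- sim_bd_tree(40, 1, 0)
    # no stem branch is observable on an n-conditioned simulation, so use
    # the crown-corrected method-of-moments form ln(n/2)/crown age
    (log(40) - log(2)) / tree_height(tr)
  })
  expect_equal(mean(rates), 1, tolerance = 0.15)
})

test_that("trait simulation respects each model's moments", {
  set.seed(72)
  tr <- rand_ultra(12)
  # sigma2 = 0: everything equals the root state
  s0 <- sim_trait(tr, "BM", sigma2 = 0, z0 = 5)
  expect_true(all(s0$tips == 5) && all(s0$nodes == 5))
  # BM: cross-replicate tip variance ~ sigma2 * depth
  H <- tree_height(tr)
  tipvals <- replicate(400, sim_trait(tr, "BM", sigma2 = 2, z0 = 0)$tips[1])
  expect_equal(stats::var(tipvals), 2 * H, tolerance = 0.25 * 2 * H)
  # WN leaves no phylogenetic signal for the estimator to find
  set.seed(73)
  lams <- replicate(15, {
    tr2 <- rand_ultra(80)
    pagel_lambda(tr2, sim_trait(tr2, "WN", sigma2 = 1)$tips)$lambda
  })
  expect_lt(mean(lams), 0.2)
})

test_that("landscape occupancy mirrors the species envelope", {
  tr <- setNames(c(500, 500, 820), c("s1", "s2", "s3"))
  ls <- build_landscape(tr, halfwidth = 50, step = 10, value_col = "map_mm")
  # ~11 cells within +/- 50 of a species on a 10-unit grid
  n1 <- sum(ls$occurrences$species == "s1")
  expect_true(n1 >= 10 && n1 <= 11)
  # identical niche values occupy identical cells
  expect_identical(ls$occurrences$cell_id[ls$occurrences$species == "s1"],
                   ls$occurrences$cell_id[ls$occurrences$species == "s2"])
  # recovered summaries sit inside the true envelope
  s <- species_climate_summary(ls$occurrences, ls$cells)
  for (i in seq_len(nrow(s))) {
    v <- tr[s$species[i]]
    expect_gte(s$min_map_mm[i], v - 50)
    expect_lte(s$max_map_mm[i], v + 50)
  }
  expect_warning(build_landscape(tr, 50, 10, range = c(0, 700)), "clamped")
})

test_that("state-dependent simulator links richness to the niche-rate ramp", {
  sd_sim <- sim_statedep_tree(120, seed = 9)
  expect_equal(length(sd_sim$phy$tip.label), 120L)
  expect_true(ape::is.ultrametric(sd_sim$phy))
  expect_equal(names(sd_sim$tip_traits), sd_sim$phy$tip.label)
  # birth rates are the deterministic ramp of the traits
  expect_true(all(sd_sim$tip_birth >= 0.05 & sd_sim$tip_birth <= 0.5))
  # more tips should sit on the high-rate side than the low-rate side
  expect_gt(mean(sd_sim$tip_traits > 1500), 0.5)
  sd2 <- sim_statedep_tree(120, seed = 9)
  expect_identical(write_newick(sd_sim$phy), write_newick(sd2$phy))
})

test_that("scenario bundles are reproducible and carry coherent truth", {
  sc <- make_scenario("time", n_tips = 60, seed = 5)
  sc2 <- make_scenario("time", n_tips = 60, seed = 5)
  expect_identical(write_newick(sc$tree), write_newick(sc2$tree))
  expect_identical(sc$data$map$occurrences, sc2$data$map$occurrences)
  expect_identical(sc$config$scenario, "time")
  # truth tables line up with the tree
  expect_setequal(names(sc$truth$map$tip_traits), sc$tree$tip.label)
  expect_equal(nrow(sc$truth$map$asr), sc$tree$Nnode)
  expect_true(all(sc$truth$rates$rate == 0.1 - 0.02))
  # taxonomy is monophyletic: stem ages resolve for multi-species genera
  multi <- sc$clades$records[sc$clades$records$n_tips >= 2, ]
  expect_true(all(!is.na(multi$stem_age[multi$n_tips < 60])))
})

test_that("time scenario orders colonization with richness by construction", {
  found <- 0L
  for (s in 1:5) {
    sc <- make_scenario("time", n_tips = 150, seed = s, vars = "map")
    tru <- sc$truth$map
    bins <- make_bins(sc$data$map$cells$map_mm, n_bins = 10, variable = "map_mm")
    col <- first_colonization_times(tru$asr, tru$tips, bins)
    s2 <- species_climate_summary(sc$data$map$occurrences, sc$data$map$cells)
    m <- assign_species_to_bins(s2, bins, "map_mm")
    br <- bin_richness(bins, m, sc$data$map$cells, sc$data$map$occurrences,
                       "map_mm")
    ok <- !is.na(col$time) & !is.na(br$regional_richness)
    if (stats::cor(col$time[ok], br$regional_richness[ok],
                   method = "spearman") > 0) {
      found <- found + 1L
    }
  }
  expect_gte(found, 4L)
})

test_that("rate scenario's true rates rise with bin richness", {
  found <- 0L
  for (s in 1:5) {
    sc <- make_scenario("rate", n_tips = 150, seed = s, vars = "map")
    bins <- make_bins(sc$data$map$cells$map_mm, n_bins = 10, variable = "map_mm")
    s2 <- species_climate_summary(sc$data$map$occurrences, sc$data$map$cells)
    m <- assign_species_to_bins(s2, bins, "map_mm")
    br <- bin_richness(bins, m, sc$data$map$cells, sc$data$map$occurrences,
                       "map_mm")
    tb <- bin_rate_summary(m, data.frame(species = sc$truth$rates$species,
                                         rate = sc$truth$rates$rate))
    ok <- !is.na(tb$mean_rate) & !is.na(br$regional_richness[tb$bin])
    if (stats::cor(tb$mean_rate[ok], br$regional_richness[tb$bin][ok]) > 0) {
      found <- found + 1L
    }
  }
  expect_gte(found, 4L)
})

test_that("reconstruction error shrinks as niche evolution slows", {
  set.seed(74)
  tr <- rand_ultra(100)
  H <- tree_height(tr)
  maes <- vapply(c(4, 1, 0.25), function(s2) {
    mean(replicate(10, {
      sim <- sim_trait(tr, "BM", sigma2 = s2, z0 = 0)
      a <- asr(tr, sim$tips, model = "BM")
      mean(abs(a$value - sim$nodes[as.character(a$node)]))
    }))
  }, numeric(1))
  expect_true(all(diff(maes) < 0))
})
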