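test_that("trait covariance matrices follow each model's definition", {
  t2 <- parse_newick("(A:1,B:1):0;")
  expect_equal(trait_covariance(t2, "BM", sigma2 = 2),
               2 * diag(2), ignore_attr = TRUE)
  t3 <- parse_newick("((A:1,B:1):1,C:2):0;")
  Cbm <- trait_covariance(t3, "BM")
  expect_equal(Cbm["A", "B"], 1)
  expect_equal(Cbm["A", "A"], 2)
  # lambda = 0 keeps the BM diagonal but zeroes shared history
  C0 <- trait_covariance(t3, "LA", lambda = 0)
  expect_equal(C0, diag(diag(Cbm)), ignore_attr = TRUE)
  # OU: stationary variance and exponential decay in patristic distance
  Cou <- trait_covariance(t3, "OU", sigma2 = 2, alpha = 0.5)
  expect_equal(Cou["A", "A"], 2 / (2 * 0.5))
  expect_equal(Cou["A", "B"], 2 * exp(-0.5 * 2))
  expect_error(trait_covariance(parse_newick("((A:1,B:5):1,C:2):0;"),
                                "OU", alpha = 1), "ultrametric")
})

test_that("pruning likelihood equals the dense multivariate normal", {
  set.seed(202)
  for (i in 1:25) {
    tr <- rand_ultra(sample(5:12, 1))
    y <- stats::setNames(stats::rnorm(length(tr$tip.label), 10, 3), tr$tip.label)
    fb <- fit_trait_model(tr, y, "BM")
    expect_equal(fb$lnL, dense_lnl(ape::vcv.phylo(tr), y[tr$tip.label]),
                 tolerance = 1e-8)
    fl <- fit_trait_model(tr, y, "LA")
    expect_equal(fl$lnL,
                 dense_lnl(trait_covariance(tr, "LA", lambda = fl$lambda),
                           y[tr$tip.label]),
                 tolerance = 1e-8)
    fo <- fit_trait_model(tr, y, "OU")
    expect_equal(fo$lnL,
                 dense_lnl(trait_covariance(tr, "OU", sigma2 = 2 * fo$alpha,
                                            alpha = fo$alpha),
                           y[tr$tip.label]),
                 tolerance = 1e-8)
    fw <- fit_trait_model(tr, y, "WN")
    expect_equal(fw$lnL, dense_lnl(diag(length(y)), y[tr$tip.label]),
                 tolerance = 1e-8)
  }
  # non-ultrametric trees: BM and LA must still match the dense route
  for (i in 1:10) {
    tr <- rand_tree(sample(5:12, 1))
    y <- stats::setNames(stats::rnorm(length(tr$tip.label)), tr$tip.label)
    fb <- fit_trait_model(tr, y, "BM")
    expect_equal(fb$lnL, dense_lnl(ape::vcv.phylo(tr), y[tr$tip.label]),
                 tolerance = 1e-8)
    lam <- stats::runif(1)
    p <- climrich:::.peel_lnl(climrich:::.bm_peel(climrich:::.lambda_tree(tr, lam), y))
    expect_equal(p$lnL,
                 dense_lnl(trait_covariance(tr, "LA", lambda = lam),
                           y[tr$tip.label]),
                 tolerance = 1e-8)
  }
})

test_that("likelihood is invariant to tip ordering and AIC identity holds", {
  set.seed(5)
  tr <- rand_ultra(15)
  y <- stats::setNames(stats::rnorm(15), tr$tip.label)
  f1 <- fit_trait_model(tr, y, "LA")
  f2 <- fit_trait_model(tr, y[sample(names(y))], "LA")
  expect_equal(f1$lnL, f2$lnL, tolerance = 1e-12)
  for (m in c("BM", "LA", "OU", "WN")) {
    f <- fit_trait_model(tr, y, m)
    expect_identical(f$AIC, 2 * f$k - 2 * f$lnL)
    expect_identical(f$k, if (m %in% c("LA", "OU")) 3L else 2L)
  }
})

test_that("degenerate constant input short-circuits with a flag", {
  tr <- rand_ultra(6)
  y <- stats::setNames(rep(3.3, 6), tr$tip.label)
  f <- fit_trait_model(tr, y, "BM")
  expect_equal(f$sigma2, 0)
  expect_true("degenerate" %in% f$flags)
  expect_true(is.na(f$lnL))
})

test_that("model selection prefers the generating model and breaks ties", {
  expect_equal(best_model(list(
    structure(list(model = "BM", k = 2L, lnL = -48, AIC = 100), class = "trait_fit"),
    structure(list(model = "LA", k = 3L, lnL = -46, AIC = 98), class = "trait_fit")
  ))$best, "LA")
  # exact tie goes to fewer parameters, whatever the order
  tie <- list(
    structure(list(model = "LA", k = 3L, lnL = -46, AIC = 98), class = "trait_fit"),
    structure(list(model = "BM", k = 2L, lnL = -47, AIC = 98), class = "trait_fit"))
  expect_equal(best_model(tie)$best, "BM")
  expect_equal(best_model(rev(tie))$best, "BM")

  # WN-generated data should be recognized most of the time
  set.seed(77)
  wins <- 0L
  for (i in 1:50) {
    tr <- rand_ultra(40)
    y <- sim_trait(tr, "WN", sigma2 = 4, z0 = 0)$tips
    fits <- list(fit_trait_model(tr, y, "BM"), fit_trait_model(tr, y, "WN"))
    if (best_model(fits)$best == "WN") wins <- wins + 1L
  }
  expect_gte(wins, 45L)
})

test_that("Pagel's lambda flags flat profiles and degenerate LRTs", {
  # star tree: lambda unidentifiable
  star <- ape::stree(8, type = "star")
  star$edge.length <- rep(1, 8)
  set.seed(2)
  y <- stats::setNames(stats::rnorm(8), star$tip.label)
  s <- pagel_lambda(star, y)
  expect_true("unidentifiable" %in% s$flags)
  expect_gte(s$p, 0)
  # when the estimate is at 0 the LRT is 0 and p = 1
  set.seed(3)
  tr <- rand_ultra(30)
  yw <- sim_trait(tr, "WN", sigma2 = 1, z0 = 0)$tips
  s2 <- pagel_lambda(tr, yw)
  if (s2$lambda == 0) {
    expect_equal(s2$LRT, 0)
    expect_equal(s2$p, 1)
  }
  expect_true(s2$LRT >= 0 && s2$p <= 1)
})

test_that("lambda agrees with an independent implementation", {
  skip_if_not_installed("phytools")
  set.seed(404)
  tr <- rand_ultra(60)
  y <- sim_trait(tr, "LA", sigma2 = 1, lambda = 0.6, z0 = 0)$tips
  mine <- pagel_lambda(tr, y)
  ref <- phytools::phylosig(tr, y, method = "lambda", test = TRUE)
  expect_equal(mine$lambda, min(1, ref$lambda), tolerance = 0.02)
  expect_equal(mine$lnL, ref$logL, tolerance = 1e-3)
})

test_that("ancestral estimates equal the GLS conditional expectation", {
  # two-tip symmetric and asymmetric cases
  expect_equal(asr(parse_newick("(A:1,B:1):0;"), c(A = 0, B = 2),
                   model = "BM")$value, 1)
  expect_equal(asr(parse_newick("(A:1,B:3):0;"), c(A = 0, B = 4),
                   model = "BM")$value, 1)
  set.seed(303)
  for (i in 1:20) {
    tr <- rand_tree(sample(4:10, 1))
    y <- stats::setNames(stats::rnorm(length(tr$tip.label), 0, 2), tr$tip.label)
    a <- asr(tr, y, model = "BM")
    expect_lt(max(abs(a$value - asr_matrix_oracle(tr, y, 1))), 1e-8)
    lam <- stats::runif(1)
    al <- asr(tr, y, model = "LA", lambda = lam)
    expect_lt(max(abs(al$value - asr_matrix_oracle(tr, y, lam))), 1e-8)
  }
})

test_that("BM ancestral estimates stay inside the tip range", {
  set.seed(99)
  for (i in 1:100) {
    tr <- rand_tree(sample(5:25, 1))
    y <- stats::setNames(stats::rnorm(length(tr$tip.label), 0, 5), tr$tip.label)
    a <- asr(tr, y, model = "BM")
    expect_true(all(a$value >= min(y) - 1e-10 & a$value <= max(y) + 1e-10))
  }
})

test_that("asr at lambda endpoints reduces to BM and to the grand mean", {
  set.seed(404)
  tr <- rand_ultra(12)
  y <- stats::setNames(stats::rnorm(12, 4, 1), tr$tip.label)
  expect_equal(asr(tr, y, "LA", lambda = 1)$value, asr(tr, y, "BM")$value,
               tolerance = 1e-12)
  a0 <- asr(tr, y, "LA", lambda = 0)
  expect_lt(diff(range(a0$value)), 1e-10)  # GLS grand mean everywhere
  expect_equal(a0$value[1], mean(y), tolerance = 1e-10)
})

test_that("two-stage reconstruction honors genus structure", {
  # genus of two species with equal branches averages their values
  tr <- parse_newick("(((a1:1,a2:1):2,b1:3):1,(c1:2,c2:2):2):0;")
  memb <- data.frame(tip = c("a1", "a2", "b1", "c1", "c2"),
                     clade = c("A", "A", "B", "C", "C"))
  ts <- two_stage_asr(tr, c(a1 = 10, a2 = 20, b1 = 5, c1 = 0, c2 = 2), memb,
                      model = "BM")
  expect_equal(unname(ts$genus_values["A"]), 15)
  expect_equal(unname(ts$genus_values["B"]), 5)  # monotypic passes through
  expect_equal(ts$genus_tips$age[ts$genus_tips$genus == "A"], 1)
  expect_equal(ts$genus_tips$terminal[ts$genus_tips$genus == "A"], 2)
  # stage-2 estimates stay within the genus data range
  expect_true(all(ts$asr$value >= min(ts$genus_values) &
                    ts$asr$value <= max(ts$genus_values)))

  # all-monotypic taxonomy reduces stage 2 to plain asr on the species tree
  tr2 <- rand_ultra(8)
  y2 <- stats::setNames(stats::rnorm(8), tr2$tip.label)
  memb2 <- data.frame(tip = tr2$tip.label, clade = paste0("m_", tr2$tip.label))
  ts2 <- two_stage_asr(tr2, y2, memb2, model = "BM")
  plain <- asr(tr2, y2, model = "BM")
  expect_equal(sort(ts2$asr$value), sort(plain$value), tolerance = 1e-10)

  # non-monophyletic genera are refused by name
  memb3 <- data.frame(tip = c("a1", "a2", "b1", "c1", "c2"),
                      clade = c("A", "B", "A", "C", "C"))
  expect_error(two_stage_asr(tr, c(a1 = 1, a2 = 2, b1 = 3, c1 = 4, c2 = 5),
                             memb3), "non-monophyletic.*A")
})

test_that("simulated genus-level workflow keeps ages on the original scale", {
  set.seed(12)
  sc <- make_scenario("time", n_tips = 80, seed = 12, vars = "map")
  ts <- two_stage_asr(sc$tree, sc$truth$map$tip_traits, sc$clades$membership,
                      model = "BM")
  H <- tree_height(sc$tree)
  expect_true(all(ts$asr$age >= 0 & ts$asr$age <= H + 1e-9))
  expect_true(all(ts$genus_tips$age < H))
  crown_check <- ts$stage1[ts$stage1$n_members >= 2, ]
  for (g in crown_check$genus[seq_len(min(3, nrow(crown_check)))]) {
    tips <- sc$clades$membership$tip[sc$clades$membership$clade == g]
    expect_equal(ts$genus_tips$age[ts$genus_tips$genus == g],
                 crown_age(sc$tree, tips), tolerance = 1e-9)
  }
})
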