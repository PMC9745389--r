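## Synthetic trees, trait histories and climate-structured landscapes with
## known ground truth. The generator exists so every pipeline stage -- and
## the central time-vs-rate contrast -- can be validated end to end without
## external data.

#' Simulate an ultrametric birth-death tree conditioned on tip count
#'
#' Constant-rate birth-death simulation conditioned on the number of
#' surviving tips (via [ape::rphylo()]), reproducible per seed.
#'
#' @param n_tips number of extant tips.
#' @param birth speciation rate (events/lineage/Myr).
#' @param death extinction rate (`0 <= death < birth`).
#' @param seed optional integer seed.
#' @return an ultrametric `"phylo"` object with `n_tips` tips.
#' @export
sim_bd_tree <- function(n_tips, birth, death = 0, seed = NULL) {
  stopifnot(n_tips >= 2, birth > 0, death >= 0, death < birth)
  if (!is.null(seed)) set.seed(seed)
  phy <- ape::rphylo(n_tips, birth = birth, death = death)
  validate_phylogeny(phy)
}

#' Forward-simulate a continuous trait along a tree
#'
#' Exact forward simulation under the four Gaussian models, retaining the
#' true internal-node values so that ancestral reconstructions can be scored
#' against the truth. LA simulates Brownian motion on the lambda-transformed
#' tree; OU draws the root from the stationary distribution
#' `N(z0, sigma2/(2 alpha))` and uses the exact transition kernel; WN draws
#' tips iid around `z0`.
#'
#' @param phy a `"phylo"` object.
#' @param model `"BM"`, `"LA"`, `"OU"` or `"WN"`.
#' @param sigma2 rate (trait^2/Myr); `sigma2 = 0` gives constant values.
#' @param z0 root state.
#' @param lambda Pagel's lambda (LA).
#' @param alpha OU pull strength.
#' @param seed optional integer seed.
#' @return list with `tips` (named vector), `nodes` (true internal-node
#'   values, named by node number), `model`, `params`.
#' @export
sim_trait <- function(phy, model = c("BM", "LA", "OU", "WN"), sigma2 = 1,
                      z0 = 0, lambda = 1, alpha = 1, seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  n <- length(phy$tip.label)
  nn <- n + phy$Nnode
  val <- numeric(nn)
  if (model == "WN") {
    val[seq_len(n)] <- z0 + stats::rnorm(n, 0, sqrt(sigma2))
    val[(n + 1L):nn] <- z0
  } else {
    wphy <- if (model == "LA") .lambda_tree(phy, lambda) else phy
    root <- n + 1L
    val[root] <- if (model == "OU") {
      stats::rnorm(1, z0, sqrt(sigma2 / (2 * alpha)))
    } else z0
    pre <- ape::reorder.phylo(wphy, "postorder")
    ord <- rev(seq_len(nrow(pre$edge)))
    for (k in ord) {
      p <- pre$edge[k, 1]
      ch <- pre$edge[k, 2]
      b <- pre$edge.length[k]
      val[ch] <- if (model == "OU") {
        w <- exp(-alpha * b)
        z0 + (val[p] - z0) * w +
          stats::rnorm(1, 0, sqrt(sigma2 / (2 * alpha) * (1 - w^2)))
      } else {
        val[p] + stats::rnorm(1, 0, sqrt(sigma2 * b))
      }
    }
  }
  tips <- stats::setNames(val[seq_len(n)], phy$tip.label)
  nodes <- stats::setNames(val[(n + 1L):nn], as.character((n + 1L):nn))
  list(tips = tips, nodes = nodes, model = model,
       params = list(sigma2 = sigma2, z0 = z0, lambda = lambda, alpha = alpha))
}

#' Build a one-dimensional gradient landscape from species niche values
#'
#' Grid cells carry a regularly spaced climate gradient; each species
#' occupies every cell whose climate value lies within `halfwidth` of the
#' species' niche value. By default the gradient spans the niche range plus
#' one halfwidth on each side, so every species occupies at least one cell;
#' with an explicit `range`, niche values outside it are clamped with a
#' warning.
#'
#' @param traits named numeric vector of species niche values.
#' @param halfwidth species climatic range halfwidth (> 0, climate units).
#' @param step cell-to-cell climate spacing (must be `<= halfwidth` so no
#'   species falls between cells).
#' @param range optional numeric length-2 gradient range.
#' @param value_col name of the climate column in the cell table (e.g.
#'   `"map_mm"`).
#' @return list with `cells` (data frame: `cell_id`, `<value_col>`) and
#'   `occurrences` (data frame: `species`, `cell_id`).
#' @export
build_landscape <- function(traits, halfwidth, step, range = NULL,
                            value_col = "climate") {
  stopifnot(halfwidth > 0, step > 0, step <= halfwidth, length(traits) >= 1L)
  if (is.null(names(traits))) stop("traits must be named by species", call. = FALSE)
  if (is.null(range)) {
    range <- c(min(traits) - halfwidth, max(traits) + halfwidth)
  } else {
    out_of <- traits < range[1] | traits > range[2]
    if (any(out_of)) {
      warning(sum(out_of), " niche value(s) outside the gradient clamped",
              call. = FALSE)
      traits <- pmin(pmax(traits, range[1]), range[2])
    }
  }
  grid <- seq(range[1], range[2], by = step)
  cells <- data.frame(cell_id = paste0("c", seq_along(grid)),
                      stringsAsFactors = FALSE)
  cells[[value_col]] <- grid
  occ <- do.call(rbind, lapply(names(traits), function(sp) {
    hit <- abs(grid - traits[[sp]]) <= halfwidth
    data.frame(species = sp, cell_id = cells$cell_id[hit],
               stringsAsFactors = FALSE)
  }))
  list(cells = cells, occurrences = occ)
}

#' Simulate a tree with trait-dependent speciation
#'
#' Discrete-time forward (Gillespie-style) simulation in which each lineage
#' carries a Brownian niche value (reflected at the landscape bounds) and
#' branches with per-step probability `b(trait) * dt`, where `b` rises
#' linearly from `birth_range[1]` at `bounds[1]` to `birth_range[2]` at
#' `bounds[2]`. The simulation stops the moment the `n_tips`-th lineage is
#' born, giving an ultrametric tree whose richness tracks the niche-rate
#' relationship rather than colonization order. No extinction is applied.
#'
#' @param n_tips number of extant tips to stop at.
#' @param birth_range speciation rate at the two gradient ends.
#' @param sigma2 niche Brownian rate (trait^2/Myr).
#' @param z0 root niche value.
#' @param bounds gradient bounds for the reflection and the rate ramp.
#' @param dt time step (Myr); `max(birth_range) * dt` should be well below 1.
#' @param seed optional integer seed.
#' @param max_steps safety cap on the number of steps.
#' @return list with `phy` (ultrametric `"phylo"` with node labels),
#'   `tip_traits`, `node_traits`, `node_ages` (named by node label), and
#'   `tip_birth` (the true per-tip speciation rate `b(tip trait)`).
#' @export
sim_statedep_tree <- function(n_tips, birth_range = c(0.05, 0.5), sigma2 = 30000,
                              z0 = 1500, bounds = c(0, 3000), dt = 0.2,
                              seed = NULL, max_steps = 2e5) {
  stopifnot(n_tips >= 2, birth_range[1] > 0, birth_range[2] >= birth_range[1],
            max(birth_range) * dt < 0.5)
  if (!is.null(seed)) set.seed(seed)
  bfun <- function(tr) {
    f <- (tr - bounds[1]) / (bounds[2] - bounds[1])
    birth_range[1] + (birth_range[2] - birth_range[1]) * pmin(pmax(f, 0), 1)
  }
  reflect <- function(tr) {
    w <- 2 * (bounds[2] - bounds[1])
    tr <- (tr - bounds[1]) %% w
    tr <- ifelse(tr > w / 2, w - tr, tr)
    tr + bounds[1]
  }
  # lineage bookkeeping; a lineage ends by splitting into two children
  id_max <- 1L
  t_start <- c(0)
  t_end <- c(NA_real_)
  child1 <- c(NA_integer_)
  child2 <- c(NA_integer_)
  split_trait <- c(NA_real_)
  alive <- 1L
  trait <- c(`1` = z0)
  t_now <- 0
  for (step in seq_len(max_steps)) {
    if (length(alive) >= n_tips) break
    t_now <- t_now + dt
    trait <- reflect(trait + stats::rnorm(length(trait), 0, sqrt(sigma2 * dt)))
    births <- which(stats::runif(length(alive)) < bfun(trait) * dt)
    for (j in births) {
      if (length(alive) >= n_tips) break
      lin <- alive[j]
      k1 <- id_max + 1L
      k2 <- id_max + 2L
      id_max <- k2
      t_start[c(k1, k2)] <- t_now
      t_end[c(k1, k2)] <- NA_real_
      child1[c(k1, k2)] <- NA_integer_
      child2[c(k1, k2)] <- NA_integer_
      split_trait[c(k1, k2)] <- NA_real_
      t_end[lin] <- t_now
      child1[lin] <- k1
      child2[lin] <- k2
      split_trait[lin] <- trait[[as.character(lin)]]
      trait[[as.character(k1)]] <- trait[[as.character(lin)]]
      trait[[as.character(k2)]] <- trait[[as.character(lin)]]
      alive[j] <- k1
      alive <- c(alive, k2)
      trait <- trait[as.character(alive)]
    }
  }
  if (length(alive) < n_tips) {
    stop("state-dependent simulation did not reach ", n_tips,
         " tips within max_steps", call. = FALSE)
  }
  # one final trait-updating step without births, so the last-born pair does
  # not end on zero-length terminal branches
  t_now <- t_now + dt
  trait <- reflect(trait + stats::rnorm(length(trait), 0, sqrt(sigma2 * dt)))
  t_end[alive] <- t_now
  newick_of <- function(lin) {
    len <- t_end[lin] - t_start[lin]
    if (is.na(child1[lin])) {
      sprintf("t%d:%.10f", lin, len)
    } else {
      sprintf("(%s,%s)n%d:%.10f", newick_of(child1[lin]), newick_of(child2[lin]),
              lin, len)
    }
  }
  txt <- if (is.na(child1[1])) {
    stop("no speciation event occurred", call. = FALSE)
  } else {
    sprintf("(%s,%s)n1;", newick_of(child1[1]), newick_of(child2[1]))
  }
  phy <- parse_newick(txt)
  tip_ids <- as.integer(sub("^t", "", phy$tip.label))
  internal_ids <- as.integer(sub("^n", "", phy$node.label))
  list(phy = phy,
       tip_traits = stats::setNames(as.numeric(trait[as.character(tip_ids)]),
                                    phy$tip.label),
       node_traits = stats::setNames(split_trait[internal_ids], phy$node.label),
       node_ages = stats::setNames(t_now - t_end[internal_ids], phy$node.label),
       tip_birth = stats::setNames(bfun(as.numeric(trait[as.character(tip_ids)])),
                                   phy$tip.label))
}

#' Generate a random monophyletic taxonomy on a tree
#'
#' Partitions the tips into "genera" by a stochastic preorder descent: at
#' each internal node not yet inside a genus, the whole subtree becomes one
#' genus when the node's age falls below a per-node uniform threshold on
#' `(0, 2 * mean_cut_frac * height)`. Genus stem ages therefore vary (as in
#' real taxonomies) and every genus is monophyletic by construction. Tips
#' not captured by any stopped subtree become monotypic genera.
#'
#' @param phy a `"phylo"` object.
#' @param mean_cut_frac mean stopping age as a fraction of tree height.
#' @param seed optional integer seed.
#' @return data frame with columns `tip`, `clade` (genus label).
#' @export
sim_taxonomy <- function(phy, mean_cut_frac = 0.35, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ages <- suppressWarnings(node_ages(phy))
  H <- max(ages)
  n <- length(phy$tip.label)
  kids <- split(seq_len(nrow(phy$edge)), phy$edge[, 1])
  genus <- integer(n)
  assign_g <- function(node, gid) {
    if (node <= n) {
      genus[node] <<- if (gid == 0L) node else gid
      return(invisible())
    }
    if (gid == 0L && ages[node] <= stats::runif(1, 0, 2 * mean_cut_frac * H)) {
      gid <- node
    }
    for (k in kids[[as.character(node)]]) assign_g(phy$edge[k, 2], gid)
  }
  assign_g(n + 1L, 0L)
  data.frame(tip = phy$tip.label, clade = paste0("g", genus),
             stringsAsFactors = FALSE)
}

#' Generate a full synthetic study with known ground truth
#'
#' Builds the complete input bundle the pipeline consumes -- an ultrametric
#' tree, per-variable grid-cell and occurrence tables -- under one of three
#' scenarios, and a ground-truth ledger (true tip/node niche values, node
#' ages, and per-lineage diversification rates) for scoring.
#'
#' Scenarios:
#' \describe{
#'   \item{`"time"`}{time-for-speciation: homogeneous birth-death tree;
#'     strongly conserved niche (Brownian, lambda = 1) whose spread is
#'     calibrated to the tree height, so climatic zones near the root niche
#'     are colonized earlier and accumulate more species.}
#'   \item{`"rate"`}{rate-driven: speciation rate rises with the niche value
#'     (trait-dependent branching, [sim_statedep_tree()]) and the niche
#'     evolves fast, so richness tracks diversification rate rather than
#'     colonization order.}
#'   \item{`"null"`}{homogeneous tree and a signal-free (white-noise) niche:
#'     species values are iid, so neither colonization order nor rates carry
#'     any engineered relation to richness.}
#' }
#'
#' The bundle also carries a synthetic taxonomy ([sim_taxonomy()]) with true
#' per-genus richness, so the clade-level (method-of-moments) rate path can
#' run on synthetic data.
#'
#' @param scenario `"time"`, `"rate"` or `"null"`.
#' @param n_tips number of species.
#' @param seed integer seed (all randomness flows from it).
#' @param vars climate variables to generate (any of `"map"`, `"mat"`;
#'   generated independently, each with its own 1-D gradient landscape).
#' @return list with `tree`, `data` (per variable: `cells`, `occurrences`,
#'   `value_col`), `clades` (list of `records` and `membership`, see
#'   [clade_records()]), `truth` (per variable: `tip_traits`, `asr` data
#'   frame of true node values/ages, `tips` table for
#'   [first_colonization_times()]; plus `rates`: true per-species net
#'   diversification rate), and `config` (the echoed generator settings).
#' @export
make_scenario <- function(scenario = c("time", "rate", "null"), n_tips = 200,
                          seed = 1, vars = c("map", "mat")) {
  scenario <- match.arg(scenario)
  vars <- match.arg(vars, c("map", "mat"), several.ok = TRUE)
  set.seed(seed)
  land <- list(
    map = list(value_col = "map_mm", halfwidth = 150, step = 50, z0 = 1500,
               spread_sd = 600),
    mat = list(value_col = "mat_c", halfwidth = 1.5, step = 0.5, z0 = 10,
               spread_sd = 6)
  )
  config <- list(scenario = scenario, n_tips = n_tips, seed = seed, vars = vars,
                 birth = 0.1, death = if (scenario == "time") 0.02 else 0,
                 birth_range = c(0.05, 0.5), statedep_sigma2 = 30000,
                 statedep_dt = 0.2, taxonomy_cut = 0.35,
                 landscape = land[vars])
  truth <- list()
  if (scenario == "rate") {
    sd_sim <- sim_statedep_tree(n_tips, birth_range = config$birth_range,
                                sigma2 = config$statedep_sigma2, z0 = 1500,
                                bounds = c(0, 3000), dt = config$statedep_dt)
    phy <- sd_sim$phy
    truth$rates <- data.frame(species = names(sd_sim$tip_birth),
                              rate = as.numeric(sd_sim$tip_birth),
                              stringsAsFactors = FALSE)
  } else {
    phy <- sim_bd_tree(n_tips, birth = config$birth, death = config$death)
    truth$rates <- data.frame(species = phy$tip.label,
                              rate = config$birth - config$death,
                              stringsAsFactors = FALSE)
  }
  height <- tree_height(phy)
  ages <- suppressWarnings(node_ages(phy))
  n <- length(phy$tip.label)
  data <- list()
  for (v in vars) {
    L <- land[[v]]
    if (scenario == "rate" && v == "map") {
      tips <- sd_sim$tip_traits
      node_vals <- sd_sim$node_traits
      node_age <- sd_sim$node_ages
      # map node labels to ape node numbers
      node_ids <- n + match(names(node_vals), phy$node.label)
      tr_asr <- data.frame(node = node_ids, age = as.numeric(node_age),
                           value = as.numeric(node_vals))
    } else {
      sim <- if (scenario == "null") {
        sim_trait(phy, "WN", sigma2 = L$spread_sd^2, z0 = L$z0)
      } else {
        sim_trait(phy, "BM", sigma2 = L$spread_sd^2 / height, z0 = L$z0)
      }
      tips <- sim$tips
      ids <- (n + 1L):(n + phy$Nnode)
      tr_asr <- data.frame(node = ids, age = unname(ages[ids]),
                           value = unname(sim$nodes))
    }
    ls <- build_landscape(tips, halfwidth = L$halfwidth, step = L$step,
                          value_col = L$value_col)
    term <- match(seq_len(n), phy$edge[, 2])
    truth[[v]] <- list(
      tip_traits = tips,
      asr = tr_asr,
      tips = data.frame(tip = phy$tip.label, min = unname(tips),
                        max = unname(tips),
                        terminal = phy$edge.length[term], age = 0,
                        stringsAsFactors = FALSE)
    )
    data[[v]] <- list(cells = ls$cells, occurrences = ls$occurrences,
                      value_col = L$value_col)
  }
  membership <- sim_taxonomy(phy, mean_cut_frac = config$taxonomy_cut)
  sz <- table(membership$clade)
  richness <- data.frame(clade = names(sz), richness_region = as.integer(sz),
                         richness_global = as.integer(sz),
                         stringsAsFactors = FALSE)
  records <- suppressWarnings(clade_records(phy, membership, richness))
  list(tree = phy, data = data,
       clades = list(records = records, membership = membership),
       truth = truth, config = config)
}
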