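## Gaussian trait-evolution models on trees.
##
## All likelihoods are computed by Felsenstein's pruning (peeling) algorithm
## on a possibly transformed tree, in O(n) per evaluation:
##   BM  - the tree itself;
##   LA  - Pagel's lambda transform (internal structure shrunk, tip heights
##         preserved), valid for non-ultrametric trees too;
##   OU  - stationary Ornstein-Uhlenbeck realized as a node-height transform
##         of an ultrametric tree plus a root edge, giving the exact
##         covariance (sigma2/2alpha) * exp(-alpha * d_ij);
##   WN  - closed form (iid normal).
## The dense multivariate-normal route is kept in trait_covariance() and is
## used by the test suite as an independent oracle, never by the fits.

.tip_depths <- function(phy) {
  d <- ape::node.depth.edgelength(phy)
  d[seq_along(phy$tip.label)]
}

# Pagel lambda branch-length transform: scale every edge by lambda, then
# stretch each terminal edge so the tip's root-to-tip depth is unchanged.
.lambda_tree <- function(phy, lambda) {
  if (lambda == 1) return(phy)
  depths <- .tip_depths(phy)
  el <- phy$edge.length * lambda
  term <- phy$edge[, 2] <= length(phy$tip.label)
  el[term] <- el[term] + (1 - lambda) * depths[phy$edge[term, 2]]
  phy$edge.length <- el
  phy
}

# Stationary-OU node-height transform (ultrametric trees): a node of age `a`
# gets height exp(-2 alpha a); the residual root height becomes a root edge.
# The resulting tree has unit tip height and tip covariance
# exp(-alpha d_ij), the correlation structure of the stationary OU.
.ou_tree <- function(phy, alpha) {
  ages <- suppressWarnings(node_ages(phy))
  h <- unname(exp(-2 * alpha * ages))
  el <- h[phy$edge[, 2]] - h[phy$edge[, 1]]
  el[el < 0] <- 0  # numerical guard; exact on ultrametric input
  phy$edge.length <- el
  list(phy = phy, root.edge = unname(h[length(phy$tip.label) + 1L]))
}

.assert_ultrametric <- function(phy, what, tol = 1e-6) {
  d <- .tip_depths(phy)
  if (diff(range(d)) > tol * max(d)) {
    stop(what, " requires an ultrametric tree (tip depth spread ",
         signif(diff(range(d)), 4), ")", call. = FALSE)
  }
}

# One pass of Felsenstein peeling. Returns the sufficient statistics of the
# profiled Gaussian likelihood: with V = sigma2 * R,
#   lnL(sigma2) = -0.5 * (n log(2 pi sigma2) + sumlog + ss / sigma2)
# where sumlog = log|R| and ss is the GLS residual quadratic form; the
# GLS mean (root estimate) is xroot and its relative variance vroot.
.bm_peel <- function(phy, x, root.edge = 0) {
  po <- ape::reorder.phylo(phy, "postorder")
  n <- length(po$tip.label)
  nn <- n + po$Nnode
  xv <- numeric(nn)
  vv <- numeric(nn)
  seen <- logical(nn)
  xv[seq_len(n)] <- x[po$tip.label]
  seen[seq_len(n)] <- TRUE
  ss <- 0
  sumlog <- 0
  E <- po$edge
  EL <- po$edge.length
  for (k in seq_len(nrow(E))) {
    p <- E[k, 1]
    ch <- E[k, 2]
    mx <- xv[ch]
    mv <- vv[ch] + EL[k]
    if (!seen[p]) {
      xv[p] <- mx
      vv[p] <- mv
      seen[p] <- TRUE
    } else {
      vsum <- vv[p] + mv
      if (vsum <= 0) {
        stop("singular phylogenetic covariance: zero-length sister branches",
             call. = FALSE)
      }
      ss <- ss + (xv[p] - mx)^2 / vsum
      sumlog <- sumlog + log(vsum)
      xv[p] <- (xv[p] * mv + mx * vv[p]) / vsum
      vv[p] <- vv[p] * mv / vsum
    }
  }
  root <- n + 1L
  vroot <- vv[root] + root.edge
  if (vroot <= 0) {
    stop("singular phylogenetic covariance: zero variance at root", call. = FALSE)
  }
  sumlog <- sumlog + log(vroot)
  list(xroot = xv[root], vroot = vroot, ss = ss, sumlog = sumlog, n = n)
}

# Maximized lnL given peeling statistics; sigma2 profiled as ss/n.
.peel_lnl <- function(peel) {
  s2 <- peel$ss / peel$n
  list(sigma2 = s2,
       z0 = peel$xroot,
       lnL = -0.5 * (peel$n * (log(2 * pi * s2) + 1) + peel$sumlog))
}

#' Tip-by-tip covariance matrix of a trait-evolution model
#'
#' The dense multivariate-normal specification underlying each model:
#' BM has `C_ij = sigma2 *` (shared root-to-MRCA path length); LA multiplies
#' the off-diagonal entries of the BM matrix by `lambda`; WN is
#' `sigma2 * I`; the stationary OU is
#' `(sigma2 / (2 alpha)) * exp(-alpha * d_ij)` with `d_ij` the patristic
#' distance (ultrametric trees only).
#'
#' @param phy a `"phylo"` object.
#' @param model one of `"BM"`, `"LA"`, `"OU"`, `"WN"`.
#' @param sigma2 rate parameter (trait^2/Myr; variance for WN).
#' @param lambda Pagel's lambda in `[0, 1]` (LA only).
#' @param alpha OU pull strength (> 0).
#' @return a symmetric matrix with tip labels as dimnames.
#' @export
trait_covariance <- function(phy, model = c("BM", "LA", "OU", "WN"),
                             sigma2 = 1, lambda = NULL, alpha = NULL) {
  model <- match.arg(model)
  n <- length(phy$tip.label)
  switch(model,
    BM = sigma2 * ape::vcv.phylo(phy),
    LA = {
      stopifnot(!is.null(lambda), lambda >= 0, lambda <= 1)
      C <- ape::vcv.phylo(phy)
      V <- lambda * C
      diag(V) <- diag(C)
      sigma2 * V
    },
    WN = {
      V <- sigma2 * diag(n)
      dimnames(V) <- list(phy$tip.label, phy$tip.label)
      V
    },
    OU = {
      stopifnot(!is.null(alpha), alpha > 0)
      .assert_ultrametric(phy, "stationary OU covariance")
      D <- ape::cophenetic.phylo(phy)
      (sigma2 / (2 * alpha)) * exp(-alpha * D)
    }
  )
}

.match_trait <- function(phy, x) {
  if (is.null(names(x))) {
    if (length(x) != length(phy$tip.label)) {
      stop("tip values must be named or match the number of tips", call. = FALSE)
    }
    names(x) <- phy$tip.label
  }
  if (!all(phy$tip.label %in% names(x))) {
    stop("tip values missing for: ",
         paste(utils::head(setdiff(phy$tip.label, names(x)), 5L), collapse = ", "),
         call. = FALSE)
  }
  x <- x[phy$tip.label]
  if (anyNA(x) || any(!is.finite(x))) stop("non-finite tip values", call. = FALSE)
  x
}

.new_trait_fit <- function(model, sigma2, z0, lnL, n, lambda = NA_real_,
                           alpha = NA_real_, flags = character(0)) {
  k <- if (model %in% c("LA", "OU")) 3L else 2L
  structure(list(model = model, sigma2 = sigma2, lambda = lambda, alpha = alpha,
                 z0 = z0, lnL = lnL, k = k, AIC = 2 * k - 2 * lnL, n = n,
                 flags = flags),
            class = "trait_fit")
}

#' @export
print.trait_fit <- function(x, ...) {
  cat("Trait-evolution model fit:", x$model, "\n")
  cat(sprintf("  n = %d tips; sigma2 = %.6g; z0 = %.6g\n", x$n, x$sigma2, x$z0))
  if (x$model == "LA") cat(sprintf("  lambda = %.6g\n", x$lambda))
  if (x$model == "OU") cat(sprintf("  alpha = %.6g\n", x$alpha))
  cat(sprintf("  lnL = %.6g; k = %d; AIC = %.6g\n", x$lnL, x$k, x$AIC))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Fit a continuous trait-evolution model by maximum likelihood
#'
#' Fits one of four standard Gaussian models -- Brownian motion (BM),
#' Pagel's lambda (LA), single-peak stationary Ornstein-Uhlenbeck (OU), or
#' white noise (WN) -- to tip values on a time-calibrated tree. The root/mean
#' state `z0` is the generalized least squares mean and `sigma2` its profiled
#' ML value; `lambda` and `alpha` are found by bounded one-dimensional
#' optimization (tolerance 1e-8; `lambda` in `[0, 1]`, `alpha` in
#' `[1e-8, 50/height]`). AIC is `2k - 2 lnL` with `k = 2` (BM, WN) or 3
#' (LA, OU).
#'
#' Constant tip values short-circuit to a degenerate fit (`sigma2 = 0`,
#' `lnL = NA`) flagged `"degenerate"` rather than failing in the optimizer;
#' an estimate at a parameter bound is flagged `"at_bound"`.
#'
#' @param phy a `"phylo"` object.
#' @param x tip values, named by tip label.
#' @param model `"BM"`, `"LA"`, `"OU"` or `"WN"`.
#' @return an object of class `"trait_fit"`.
#' @seealso [best_model()], [pagel_lambda()], [asr()]
#' @export
fit_trait_model <- function(phy, x, model = c("BM", "LA", "OU", "WN")) {
  model <- match.arg(model)
  x <- .match_trait(phy, x)
  n <- length(x)
  if (model %in% c("LA", "OU") && n < 4L) {
    stop(model, " requires >= 4 tips", call. = FALSE)
  }
  if (stats::var(x) == 0) {
    return(.new_trait_fit(model, sigma2 = 0, z0 = x[[1]], lnL = NA_real_, n = n,
                          flags = "degenerate"))
  }
  switch(model,
    BM = {
      p <- .peel_lnl(.bm_peel(phy, x))
      .new_trait_fit("BM", p$sigma2, p$z0, p$lnL, n)
    },
    WN = {
      z0 <- mean(x)
      s2 <- mean((x - z0)^2)
      lnL <- -0.5 * n * (log(2 * pi * s2) + 1)
      .new_trait_fit("WN", s2, z0, lnL, n)
    },
    LA = {
      f <- function(lam) .peel_lnl(.bm_peel(.lambda_tree(phy, lam), x))$lnL
      opt <- stats::optimize(f, c(0, 1), maximum = TRUE, tol = 1e-8)
      cand <- c(opt$maximum, 0, 1)
      vals <- c(opt$objective, f(0), f(1))
      lam <- cand[which.max(vals)]
      p <- .peel_lnl(.bm_peel(.lambda_tree(phy, lam), x))
      flags <- if (lam < 1e-6 || lam > 1 - 1e-6) "at_bound" else character(0)
      .new_trait_fit("LA", p$sigma2, p$z0, p$lnL, n, lambda = lam, flags = flags)
    },
    OU = {
      .assert_ultrametric(phy, "stationary OU fit")
      hmax <- tree_height(phy)
      lo <- 1e-8
      hi <- 50 / hmax
      f <- function(a) {
        tt <- .ou_tree(phy, a)
        .peel_lnl(.bm_peel(tt$phy, x, root.edge = tt$root.edge))$lnL
      }
      opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-8)
      cand <- c(opt$maximum, lo, hi)
      vals <- c(opt$objective, f(lo), f(hi))
      a <- cand[which.max(vals)]
      tt <- .ou_tree(phy, a)
      p <- .peel_lnl(.bm_peel(tt$phy, x, root.edge = tt$root.edge))
      flags <- if (a <= lo * (1 + 1e-3) || a >= hi * (1 - 1e-6)) "at_bound" else character(0)
      # peeling profiles the stationary variance v = sigma2 / (2 alpha)
      .new_trait_fit("OU", 2 * a * p$sigma2, p$z0, p$lnL, n, alpha = a,
                     flags = flags)
    }
  )
}

#' Pick the best-fitting model by AIC
#'
#' Lowest AIC wins; exact ties are broken towards the model with fewer
#' parameters. The comparison is invariant to the order of the fits.
#'
#' @param fits a list of `"trait_fit"` objects on the same data.
#' @return list with `best` (model name) and `table` (data frame of model,
#'   k, lnL, AIC, dAIC sorted by AIC then k).
#' @export
best_model <- function(fits) {
  stopifnot(length(fits) >= 2L)
  tab <- data.frame(
    model = vapply(fits, `[[`, "", "model"),
    k = vapply(fits, `[[`, 0L, "k"),
    lnL = vapply(fits, `[[`, 0, "lnL"),
    AIC = vapply(fits, `[[`, 0, "AIC"),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$AIC, tab$k, tab$model), , drop = FALSE]
  tab$dAIC <- tab$AIC - tab$AIC[1]
  rownames(tab) <- NULL
  list(best = tab$model[1], table = tab)
}

#' Pagel's lambda phylogenetic signal with likelihood-ratio test
#'
#' Estimates `lambda` as the maximizer of the LA profile likelihood over
#' `[0, 1]` and tests `lambda = 0` (no signal: trait values independent of
#' the tree) with a likelihood-ratio test against a chi-squared distribution
#' with 1 degree of freedom. High lambda (near 1) indicates strong
#' phylogenetic conservatism of the trait.
#'
#' @inheritParams fit_trait_model
#' @return object of class `"signal_fit"`: list with `lambda`, `lnL`
#'   (at the estimate), `lnL0` (at lambda = 0), `LRT` (`2 * (lnL - lnL0)`,
#'   clamped at 0), `p`, `n`, `flags` (`"unidentifiable"` when the profile is
#'   flat, e.g. on a star tree).
#' @export
pagel_lambda <- function(phy, x) {
  x <- .match_trait(phy, x)
  fit <- fit_trait_model(phy, x, "LA")
  lnl0 <- .peel_lnl(.bm_peel(.lambda_tree(phy, 0), x))$lnL
  lnl_mid <- .peel_lnl(.bm_peel(.lambda_tree(phy, 0.5), x))$lnL
  flags <- fit$flags
  if (abs(fit$lnL - lnl0) < 1e-8 && abs(lnl_mid - lnl0) < 1e-8) {
    flags <- union(flags, "unidentifiable")
  }
  lrt <- max(0, 2 * (fit$lnL - lnl0))
  structure(list(lambda = fit$lambda, lnL = fit$lnL, lnL0 = lnl0, LRT = lrt,
                 p = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
                 n = fit$n, flags = flags),
            class = "signal_fit")
}

#' @export
print.signal_fit <- function(x, ...) {
  cat(sprintf("Pagel's lambda = %.4f (n = %d)\n", x$lambda, x$n))
  cat(sprintf("  lnL = %.4f, lnL(lambda=0) = %.4f, LRT = %.4f, p = %.4g\n",
              x$lnL, x$lnL0, x$LRT, x$p))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

## Two-pass (belief-propagation) ancestral state machinery ------------------

# Combine two finite Gaussian messages; v = 0 is a point mass.
.gcombine <- function(x1, v1, x2, v2) {
  if (v1 == 0 && v2 == 0) {
    if (abs(x1 - x2) > 1e-9 * (1 + abs(x1))) {
      stop("singular covariance: conflicting point-mass messages", call. = FALSE)
    }
    return(c(x1, 0))
  }
  if (v1 == 0) return(c(x1, 0))
  if (v2 == 0) return(c(x2, 0))
  v <- 1 / (1 / v1 + 1 / v2)
  c(v * (x1 / v1 + x2 / v2), v)
}

# As .gcombine but tolerating an uninformative (infinite-variance) message.
.gcombine_inf <- function(x1, v1, x2, v2) {
  if (!is.finite(v1)) return(c(x2, v2))
  if (!is.finite(v2)) return(c(x1, v1))
  .gcombine(x1, v1, x2, v2)
}

# Linear-time conditional expectations of internal-node states under BM on
# `phy` (call on a lambda-transformed tree for the LA model). Downward pass
# peels tip information rootwards; upward pass sends the complement back
# down; each node's estimate combines the two.
.bp_asr <- function(phy, x) {
  po <- ape::reorder.phylo(phy, "postorder")
  n <- length(po$tip.label)
  nn <- n + po$Nnode
  E <- po$edge
  EL <- po$edge.length
  dx <- numeric(nn)
  dv <- numeric(nn)
  seen <- logical(nn)
  dx[seq_len(n)] <- x[po$tip.label]
  seen[seq_len(n)] <- TRUE
  for (k in seq_len(nrow(E))) {
    p <- E[k, 1]; ch <- E[k, 2]
    msg <- c(dx[ch], dv[ch] + EL[k])
    if (!seen[p]) {
      dx[p] <- msg[1]; dv[p] <- msg[2]; seen[p] <- TRUE
    } else {
      cmb <- .gcombine(dx[p], dv[p], msg[1], msg[2])
      dx[p] <- cmb[1]; dv[p] <- cmb[2]
    }
  }
  children <- split(seq_len(nrow(E)), E[, 1])
  ux <- numeric(nn)
  uv <- rep(Inf, nn)
  for (k in rev(seq_len(nrow(E)))) {
    p <- E[k, 1]; ch <- E[k, 2]
    ox <- ux[p]; ov <- uv[p]
    for (k2 in children[[as.character(p)]]) {
      sib <- E[k2, 2]
      if (sib == ch) next
      cmb <- .gcombine_inf(ox, ov, dx[sib], dv[sib] + EL[k2])
      ox <- cmb[1]; ov <- cmb[2]
    }
    ux[ch] <- ox
    uv[ch] <- if (is.finite(ov)) ov + EL[k] else Inf
  }
  est <- numeric(nn)
  for (i in (n + 1L):nn) {
    est[i] <- .gcombine_inf(dx[i], dv[i], ux[i], uv[i])[1]
  }
  est[(n + 1L):nn]
}

#' Ancestral state reconstruction of a continuous trait
#'
#' Maximum-likelihood (equivalently, conditional-expectation) estimates of
#' internal-node trait values under Brownian motion or under the fitted
#' Pagel's-lambda (LA) model, computed by a linear-time two-pass algorithm.
#' The LA reconstruction applies the lambda branch-length transform and runs
#' the BM machinery on the transformed tree, so `lambda = 1` reproduces BM
#' exactly and `lambda = 0` returns the GLS grand mean at every node.
#'
#' @param phy a `"phylo"` object.
#' @param x tip values, named by tip label.
#' @param model `"LA"` (default) or `"BM"`.
#' @param lambda fixed lambda for `model = "LA"`; when `NULL` it is first
#'   estimated by ML.
#' @return object of class `"asr_result"`: data frame with columns `node`
#'   (ape internal node numbers), `age` (Myr, from the input tree) and
#'   `value`, with the model, fitted parameters and `"trait_fit"` stored in
#'   attributes.
#' @export
#' @examples
#' tr <- parse_newick("(A:1,B:1):0;")
#' asr(tr, c(A = 0, B = 2), model = "BM")  # root = 1
asr <- function(phy, x, model = c("LA", "BM"), lambda = NULL) {
  model <- match.arg(model)
  x <- .match_trait(phy, x)
  fit <- NULL
  if (model == "BM") {
    lambda <- 1
    fit <- fit_trait_model(phy, x, "BM")
  } else {
    if (is.null(lambda)) {
      fit <- fit_trait_model(phy, x, "LA")
      lambda <- fit$lambda
    }
    stopifnot(lambda >= 0, lambda <= 1)
  }
  tphy <- .lambda_tree(phy, lambda)
  vals <- .bp_asr(tphy, x)
  n <- length(phy$tip.label)
  ages <- suppressWarnings(node_ages(phy))
  out <- data.frame(node = (n + 1L):(n + phy$Nnode),
                    age = unname(ages[(n + 1L):(n + phy$Nnode)]),
                    value = vals)
  attr(out, "model") <- model
  attr(out, "lambda") <- lambda
  attr(out, "fit") <- fit
  class(out) <- c("asr_result", "data.frame")
  out
}

#' Two-stage ancestral reconstruction through a genus-level tree
#'
#' Stage 1 reconstructs the trait within each genus subtree (BM) and takes
#' the value at the genus crown node as the genus datum (a monotypic genus
#' contributes the species' own value). Stage 2 builds the genus-level tree
#' -- one tip per genus, placed at the genus crown age, with terminal branch
#' length stem age minus crown age -- and reconstructs on it using the genus
#' data. Genera must be monophyletic on the tree.
#'
#' @param phy the full species-level `"phylo"` object.
#' @param x species tip values, named.
#' @param membership data frame with columns `tip`, `clade` (genus) covering
#'   every tip of `phy`.
#' @param model stage-2 reconstruction model, `"LA"` (default) or `"BM"`.
#' @return list with `genus_tree` (tips at crown ages; non-ultrametric by
#'   construction), `genus_values` (stage-1 data, named by genus),
#'   `genus_tips` (data frame: genus, age = crown age, terminal branch
#'   length), `asr` (stage-2 `"asr_result"`, ages on the original
#'   timescale), and `stage1` (per-genus detail).
#' @export
two_stage_asr <- function(phy, x, membership, model = c("LA", "BM")) {
  model <- match.arg(model)
  x <- .match_trait(phy, x)
  stopifnot(all(c("tip", "clade") %in% names(membership)))
  missing_tips <- setdiff(phy$tip.label, membership$tip)
  if (length(missing_tips)) {
    stop("membership lacks tips: ",
         paste(utils::head(missing_tips, 5L), collapse = ", "), call. = FALSE)
  }
  genus_of <- membership$clade[match(phy$tip.label, membership$tip)]
  genera <- unique(genus_of)
  if (length(genera) < 2L) stop("need >= 2 genera", call. = FALSE)
  n <- length(phy$tip.label)
  ages <- suppressWarnings(node_ages(phy))
  # monophyly check + stage 1
  bad <- character(0)
  stage1 <- data.frame(genus = genera, value = NA_real_, crown_age = 0,
                       n_members = NA_integer_, rep = NA_character_,
                       stringsAsFactors = FALSE)
  for (i in seq_along(genera)) {
    tips <- phy$tip.label[genus_of == genera[i]]
    stage1$n_members[i] <- length(tips)
    stage1$rep[i] <- tips[1]
    if (length(tips) == 1L) {
      stage1$value[i] <- x[[tips]]
      next
    }
    mrca <- ape::getMRCA(phy, tips)
    desc <- ape::extract.clade(phy, mrca)$tip.label
    if (length(setdiff(desc, tips))) {
      bad <- c(bad, genera[i])
      next
    }
    sub <- extract_clade(phy, tips)
    rec <- asr(sub, x[tips], model = "BM")
    stage1$value[i] <- rec$value[rec$node == length(sub$tip.label) + 1L]
    stage1$crown_age[i] <- unname(ages[mrca])
  }
  if (length(bad)) {
    stop("non-monophyletic genera: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  gt <- ape::keep.tip(phy, stage1$rep)
  gt$tip.label <- stage1$genus[match(gt$tip.label, stage1$rep)]
  # retract each genus tip to its crown age: terminal branch = stem - crown
  # gt is still ultrametric here, so its internal-node ages (and hence the
  # stem-attachment age above each genus tip) match the full tree's
  gt_ages <- suppressWarnings(node_ages(gt))
  term <- match(seq_along(gt$tip.label), gt$edge[, 2])
  crown <- stage1$crown_age[match(gt$tip.label, stage1$genus)]
  gt$edge.length[term] <- pmax(0, unname(gt_ages[gt$edge[term, 1]]) - crown)
  gv <- stats::setNames(stage1$value, stage1$genus)
  rec2 <- asr(gt, gv, model = model)
  # ages of gt internal nodes relative to present: root of gt keeps its
  # full-tree age, and tips now sit at their crown ages
  root_age <- unname(ages[ape::getMRCA(phy, stage1$rep)])
  depth <- ape::node.depth.edgelength(gt)
  ng <- length(gt$tip.label)
  rec2$age <- root_age - depth[(ng + 1L):(ng + gt$Nnode)]
  genus_tips <- data.frame(genus = gt$tip.label,
                           age = crown,
                           terminal = gt$edge.length[term],
                           stringsAsFactors = FALSE)
  list(genus_tree = gt, genus_values = gv, genus_tips = genus_tips,
       asr = rec2, stage1 = stage1)
}
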