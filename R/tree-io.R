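#' Parse a Newick string into a validated phylogeny
#'
#' Thin, strict front end to [ape::read.tree()]. The returned tree is the
#' standard `"phylo"` object used throughout the package. Square-bracket
#' comments are stripped and quoted labels are accepted; polytomies are kept
#' as-is. Every non-root edge must carry a finite, non-negative branch length
#' (in Myr for time-calibrated trees).
#'
#' @param text a single Newick string, terminated by `;`.
#' @return an object of class `"phylo"`.
#' @seealso [read_chronogram()] for reading from a file, [write_newick()].
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2):0;")
#' node_ages(tr)
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- gsub("\\[[^]]*\\]", "", text)
  .check_newick_syntax(text)
  phy <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(phy)) stop("Newick parse error: input did not yield a tree", call. = FALSE)
  phy$tip.label <- gsub("^'(.*)'$", "\\1", phy$tip.label)
  if (!is.null(phy$node.label)) {
    phy$node.label <- gsub("^'(.*)'$", "\\1", phy$node.label)
  }
  validate_phylogeny(phy)
}

# Pre-scan so malformed input fails with a character offset instead of an
# obscure ape error (or silent misparse).
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  quoted <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") quoted <- !quoted
    if (quoted) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("Newick parse error: unbalanced ')' at character ", i, call. = FALSE)
      }
    }
  }
  if (quoted) stop("Newick parse error: unterminated quoted label", call. = FALSE)
  if (depth != 0L) {
    stop("Newick parse error: ", depth, " unclosed '(' at character ",
         length(chars), call. = FALSE)
  }
  if (!grepl(";\\s*$", text)) {
    stop("Newick parse error: missing terminal ';' at character ",
         length(chars), call. = FALSE)
  }
  invisible(TRUE)
}

#' Validate the structural invariants of a phylogeny
#'
#' Checks that a `"phylo"` object is rooted with a single root, has unique
#' tip labels, and carries finite non-negative branch lengths on every edge.
#'
#' @param phy a `"phylo"` object.
#' @return `phy`, invisibly unchanged, or an error.
#' @export
validate_phylogeny <- function(phy) {
  if (!inherits(phy, "phylo")) stop("not a 'phylo' object", call. = FALSE)
  if (anyDuplicated(phy$tip.label)) {
    dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
    stop("duplicated tip labels: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (is.null(phy$edge.length)) {
    stop("tree has no branch lengths; time-calibrated branch lengths are required",
         call. = FALSE)
  }
  if (anyNA(phy$edge.length) || any(!is.finite(phy$edge.length))) {
    stop("missing or non-finite branch length on ",
         sum(!is.finite(phy$edge.length)), " edge(s)", call. = FALSE)
  }
  if (any(phy$edge.length < 0)) {
    stop("negative branch lengths are not allowed", call. = FALSE)
  }
  n <- length(phy$tip.label)
  parents <- tabulate(phy$edge[, 2], nbins = n + phy$Nnode)
  if (any(parents > 1L)) stop("a node has more than one parent", call. = FALSE)
  roots <- setdiff(phy$edge[, 1], phy$edge[, 2])
  if (length(unique(roots)) != 1L) stop("tree must have a single root", call. = FALSE)
  invisible(phy)
}

#' Read a time-calibrated tree from a Newick file
#'
#' @param file path to a Newick file (one tree).
#' @return a validated `"phylo"` object.
#' @export
read_chronogram <- function(file) {
  parse_newick(paste(readLines(file, warn = FALSE), collapse = ""))
}

#' Serialize a phylogeny to Newick
#'
#' @param phy a `"phylo"` object.
#' @param file optional path; if `NULL` the Newick string is returned.
#' @return the Newick string (invisibly when writing to file).
#' @export
write_newick <- function(phy, file = NULL) {
  txt <- ape::write.tree(phy, digits = 12)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Node ages (Myr before present)
#'
#' The age of a node is the maximum path length from the node to any of its
#' descendant tips, so tips of an ultrametric tree have age 0 and
#' `age(parent) = age(child) + branch(child)` holds exactly. Non-ultrametric
#' trees are tolerated: ages remain max-depth-based and a warning is emitted
#' when the spread of tip depths exceeds `tol` times the tree height
#' (empirical chronograms carry rounding noise).
#'
#' @param phy a `"phylo"` object.
#' @param tol relative tolerance for the ultrametricity warning.
#' @return a numeric vector of length `Ntip + Nnode`, named by tip label for
#'   tips and by node number for internal nodes, in ape node order.
#' @export
node_ages <- function(phy, tol = 1e-6) {
  validate_phylogeny(phy)
  n <- length(phy$tip.label)
  nn <- n + phy$Nnode
  po <- ape::reorder.phylo(phy, "postorder")
  age <- numeric(nn)
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]
    ch <- po$edge[k, 2]
    age[p] <- max(age[p], age[ch] + po$edge.length[k])
  }
  depth <- ape::node.depth.edgelength(phy)
  spread <- diff(range(depth[seq_len(n)]))
  if (spread > tol * max(depth)) {
    warning("tree is not ultrametric: tip depth spread ", signif(spread, 4),
            " exceeds ", tol, " x tree height; ages are max-depth-based",
            call. = FALSE)
  }
  names(age) <- c(phy$tip.label, as.character((n + 1L):nn))
  age
}

#' Tree height
#'
#' Maximum root-to-tip path length.
#'
#' @param phy a `"phylo"` object.
#' @return a single number (Myr).
#' @export
tree_height <- function(phy) {
  max(ape::node.depth.edgelength(phy))
}

.match_tips <- function(phy, members) {
  idx <- match(members, phy$tip.label)
  if (anyNA(idx)) {
    stop("tips not in tree: ", paste(members[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  idx
}

.mrca_node <- function(phy, tip_idx) {
  if (length(tip_idx) == 1L) return(tip_idx)
  ape::getMRCA(phy, tip_idx)
}

#' Stem age of a clade
#'
#' Age of the parent of the clade's most recent common ancestor, i.e. the node
#' at which the clade attaches to the rest of the tree. On an ultrametric tree
#' this equals crown age plus the subtending branch length. For a single tip
#' the stem age is the age of its parent node. The members must be
#' monophyletic; intruding tips trigger an error, as does a clade whose MRCA
#' is the root (which has no stem).
#'
#' @param phy a `"phylo"` object.
#' @param members character vector of tip labels forming the clade.
#' @return stem age in Myr.
#' @seealso [crown_age()]
#' @export
stem_age <- function(phy, members) {
  stopifnot(length(members) >= 1L)
  idx <- .match_tips(phy, members)
  n <- length(phy$tip.label)
  root <- n + 1L
  mrca <- .mrca_node(phy, idx)
  if (mrca > n) {
    desc <- ape::extract.clade(phy, mrca)$tip.label
    intruders <- setdiff(desc, members)
    if (length(intruders)) {
      stop("members are not monophyletic; intruding tips: ",
           paste(utils::head(intruders, 10L), collapse = ", "),
           if (length(intruders) > 10L) ", ..." else "", call. = FALSE)
    }
  }
  if (mrca == root) {
    stop("clade MRCA is the root: no stem age defined", call. = FALSE)
  }
  parent <- phy$edge[match(mrca, phy$edge[, 2]), 1]
  ages <- suppressWarnings(node_ages(phy))
  unname(ages[parent])
}

#' Crown age of a clade
#'
#' Age of the most recent common ancestor of the members (>= 2 tips).
#'
#' @inheritParams stem_age
#' @return crown age in Myr.
#' @export
crown_age <- function(phy, members) {
  stopifnot(length(members) >= 2L)
  idx <- .match_tips(phy, members)
  mrca <- .mrca_node(phy, idx)
  ages <- suppressWarnings(node_ages(phy))
  unname(ages[mrca])
}

#' Extract the subtree spanning a set of tips
#'
#' Degree-2 internal nodes left by the pruning are collapsed with branch
#' lengths summed, so patristic distances among the retained tips are
#' preserved exactly.
#'
#' @param phy a `"phylo"` object.
#' @param members character vector of tip labels to keep (>= 2).
#' @return a `"phylo"` object.
#' @export
extract_clade <- function(phy, members) {
  stopifnot(length(members) >= 2L)
  .match_tips(phy, members)
  ape::keep.tip(phy, members)
}

#' Build clade records from a membership table
#'
#' Combines tip membership, regional/global richness, and the tree into the
#' per-clade record used by the diversification estimators: stem age is taken
#' from the tree for every clade whose members are present (clades whose
#' members are absent or whose MRCA is the root are skipped with a warning).
#'
#' @param phy a `"phylo"` object.
#' @param membership data frame with columns `tip` and `clade`.
#' @param richness data frame with columns `clade`, `richness_region` and
#'   (optionally) `richness_global`. When `richness_global` is absent it
#'   defaults to `richness_region`.
#' @return data frame with columns `clade`, `n_tips`, `richness_region`,
#'   `richness_global`, `china_fraction` (`richness_region/richness_global`)
#'   and `stem_age`.
#' @export
clade_records <- function(phy, membership, richness) {
  stopifnot(all(c("tip", "clade") %in% names(membership)),
            all(c("clade", "richness_region") %in% names(richness)))
  if (is.null(richness$richness_global)) {
    richness$richness_global <- richness$richness_region
  }
  if (any(richness$richness_region < 1L)) {
    stop("richness_region must be >= 1", call. = FALSE)
  }
  if (any(richness$richness_global < richness$richness_region)) {
    stop("richness_global must be >= richness_region", call. = FALSE)
  }
  clades <- unique(membership$clade)
  rec <- data.frame(
    clade = clades,
    n_tips = NA_integer_,
    stem_age = NA_real_,
    stringsAsFactors = FALSE
  )
  for (i in seq_along(clades)) {
    tips <- intersect(membership$tip[membership$clade == clades[i]], phy$tip.label)
    rec$n_tips[i] <- length(tips)
    if (length(tips) == 0L) next
    rec$stem_age[i] <- tryCatch(stem_age(phy, tips), error = function(e) NA_real_)
  }
  skipped <- rec$clade[is.na(rec$stem_age)]
  if (length(skipped)) {
    warning(length(skipped), " clade(s) without a stem age (absent tips, ",
            "non-monophyly, or MRCA at root) skipped: ",
            paste(utils::head(skipped, 5L), collapse = ", "), call. = FALSE)
  }
  out <- merge(rec, richness, by = "clade", all.x = TRUE, sort = TRUE)
  out$china_fraction <- out$richness_region / out$richness_global
  out
}

#' Read a clade membership/richness table
#'
#' Delimited text with header columns `clade`, `tip`, `richness_region`,
#' `richness_global` (one row per tip; richness repeated within a clade).
#'
#' @param file path to the delimited file.
#' @param sep field separator.
#' @return list with `membership` (tip, clade) and `richness` (one row per
#'   clade) data frames.
#' @export
read_clade_table <- function(file, sep = ",") {
  x <- utils::read.table(file, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  need <- c("clade", "tip", "richness_region", "richness_global")
  if (!all(need %in% names(x))) {
    stop("clade table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  richness <- unique(x[, c("clade", "richness_region", "richness_global")])
  if (anyDuplicated(richness$clade)) {
    stop("inconsistent richness values within a clade", call. = FALSE)
  }
  list(membership = x[, c("tip", "clade")], richness = richness)
}
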