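# Clade partitioning: the survey's post-hoc clade definition is codified as
# a recursive rule on the rooted tree — a major clade is a maximal subtree
# containing both core dinoflagellates and the outgroup heterokonts; within
# a major clade, lettered sub-clades are maximal monophyletic groups of core
# dinoflagellates (syndinean/Perkinsus leaves are masked so they never break
# sub-clade monophyly, and are reported separately).

.tips_under <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, .tips_under, tree = tree))
}

.root_tree <- function(tree, groups, rooting, outgroup_group) {
  if (!is.null(outgroup_group)) {
    og <- tree$tip.label[groups[tree$tip.label] == outgroup_group]
    if (!length(og)) stop("no tips in outgroup group '", outgroup_group, "'")
    return(tryCatch(ape::root(tree, outgroup = og, resolve.root = TRUE),
                    error = function(e)
                      ape::root(tree, outgroup = og[1], resolve.root = TRUE)))
  }
  if (identical(rooting, "midpoint"))
    return(.group_midpoint_root(tree, groups))
  tree
}

# midpoint rooting restricted to the groups that define the partition
# (core dinoflagellates and heterokonts), so that long-branch lineages in
# other groups (e.g. composition-biased ciliates) cannot drag the root onto
# a pendant edge
.group_midpoint_root <- function(tree, groups,
                                 use = c("core_dino", "heterokont")) {
  tips <- tree$tip.label[groups[tree$tip.label] %in% use]
  if (length(tips) < 2) return(phangorn::midpoint(tree))
  D <- ape::cophenetic.phylo(tree)[tips, tips]
  ij <- which(D == max(D), arr.ind = TRUE)[1, ]
  ta <- match(tips[ij[1]], tree$tip.label)
  tb <- match(tips[ij[2]], tree$tip.label)
  half <- D[ij[1], ij[2]] / 2
  if (half == 0) return(phangorn::midpoint(tree))
  path <- ape::nodepath(tree, ta, tb)
  elen <- function(u, v) {
    e <- which((tree$edge[, 1] == u & tree$edge[, 2] == v) |
                 (tree$edge[, 1] == v & tree$edge[, 2] == u))
    tree$edge.length[e[1]]
  }
  acc <- 0
  for (k in seq_len(length(path) - 1)) {
    u <- path[k]; v <- path[k + 1]
    L <- elen(u, v)
    if (acc + L >= half && L > 0) {
      delta <- half - acc                 # distance beyond u, toward v
      child_is_v <- any(tree$edge[, 1] == u & tree$edge[, 2] == v)
      rooted <- if (child_is_v) {
        phytools::reroot(tree, v, position = delta)
      } else {
        phytools::reroot(tree, u, position = L - delta)
      }
      return(rooted)
    }
    acc <- acc + L
  }
  phangorn::midpoint(tree)
}

#' Partition a tree into major clades by taxon representation
#'
#' Roots the tree (midpoint by default) and descends from the root: at any
#' node where at least two child subtrees each contain both a core
#' dinoflagellate and a heterokont leaf, the descent recurses into those
#' children; otherwise the node is a major-clade root. The result is the
#' set of maximal disjoint clades each containing both groups, numbered
#' "eIF4E-1", "eIF4E-2", ... in decreasing core-dinoflagellate leaf count
#' (ties by traversal order).
#'
#' @param tree `phylo`; needs at least one core_dino and one heterokont tip.
#' @param groups Named character vector mapping tip labels to taxon groups.
#' @param rooting `"midpoint"` (default) or `"none"` (tree used as given).
#' @param outgroup_group Optional group name used to root instead of the
#'   midpoint rule.
#' @return Object of class `clade_partition`: the rooted tree, `clades`
#'   (list of name/node/leaves), `unplaced` leaves, and `subclades` (filled
#'   by [find_subclades()]).
#' @export
partition_major_clades <- function(tree, groups, rooting = "midpoint",
                                   outgroup_group = NULL) {
  stopifnot(inherits(tree, "phylo"))
  miss <- setdiff(tree$tip.label, names(groups))
  if (length(miss)) stop("tip without group label: ", miss[1])
  has_both <- function(tips)
    any(groups[tips] == "core_dino") && any(groups[tips] == "heterokont")
  if (!has_both(tree$tip.label)) {
    warning("no node contains both core dinoflagellates and heterokonts; ",
            "returning a single unresolved partition")
    return(structure(list(tree = tree,
                          clades = list(list(name = "unresolved",
                                             node = NA_integer_,
                                             leaves = tree$tip.label)),
                          unplaced = character(0),
                          subclades = NULL, groups = groups),
                     class = "clade_partition"))
  }
  tr <- .root_tree(tree, groups, rooting, outgroup_group)
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  clade_nodes <- integer(0)
  descend <- function(node) {
    kids <- if (node <= ntip) integer(0) else
      tr$edge[tr$edge[, 1] == node, 2]
    kid_tips <- lapply(kids, function(k) tr$tip.label[.tips_under(tr, k)])
    qual <- vapply(kid_tips, has_both, TRUE)
    if (sum(qual) >= 2) {
      for (k in kids[qual]) descend(k)
    } else {
      clade_nodes <<- c(clade_nodes, node)
    }
  }
  descend(root)
  clades <- lapply(clade_nodes, function(nd) {
    leaves <- tr$tip.label[.tips_under(tr, nd)]
    list(node = nd, leaves = leaves,
         n_core = sum(groups[leaves] == "core_dino"))
  })
  # only clades containing both groups are major clades; every leaf not
  # under a major clade (e.g. under a sibling lineage skipped during the
  # descent) is reported unplaced
  keep <- vapply(clades, function(cl) has_both(cl$leaves), TRUE)
  clades <- clades[keep]
  ord <- order(-vapply(clades, `[[`, 0, "n_core"), seq_along(clades))
  clades <- clades[ord]
  for (i in seq_along(clades)) clades[[i]]$name <- sprintf("eIF4E-%d", i)
  placed <- unlist(lapply(clades, `[[`, "leaves"))
  structure(list(tree = tr, clades = clades,
                 unplaced = setdiff(tr$tip.label, placed),
                 subclades = NULL, groups = groups),
            class = "clade_partition")
}

#' @export
print.clade_partition <- function(x, ...) {
  cat(sprintf("clade partition: %d major clades, %d unplaced leaves\n",
              length(x$clades), length(x$unplaced)))
  for (cl in x$clades) {
    g <- table(x$groups[cl$leaves])
    cat(sprintf("  %s: %d leaves (%s)\n", cl$name, length(cl$leaves),
                paste(sprintf("%s %d", names(g), g), collapse = ", ")))
  }
  if (!is.null(x$subclades))
    cat(sprintf("  %d sub-clades: %s\n", length(x$subclades),
                paste(vapply(x$subclades, `[[`, "", "name"),
                      collapse = " ")))
  invisible(x)
}

#' Lettered core-dinoflagellate sub-clades of a major clade
#'
#' Finds maximal monophyletic groups of core-dinoflagellate leaves inside
#' each major clade. Syndinean and Perkinsus leaves are masked (ignored for
#' monophyly) and reported separately. Groups need at least `min_members`
#' leaves, except a single-leaf lineage attached directly at the
#' major-clade root, which is retained so one-copy-per-species sub-clades
#' are not lost. Letters a, b, c, ... are assigned in decreasing species
#' count, ties by decreasing leaf count then traversal order.
#'
#' @param partition A `clade_partition`.
#' @param species Named character vector mapping leaf ids to species.
#' @param min_members Minimum leaves per sub-clade (default 2).
#' @return The partition with `subclades` filled: list of
#'   name/major/node/leaves/species/n_species.
#' @export
find_subclades <- function(partition, species, min_members = 2L) {
  stopifnot(inherits(partition, "clade_partition"))
  tr <- partition$tree
  groups <- partition$groups
  ntip <- length(tr$tip.label)
  masked <- c("syndinean", "perkinsus")
  out <- list()
  for (cl in partition$clades) {
    if (is.na(cl$node)) next
    found <- list()
    pure_core <- function(tips) {
      tips <- tips[!(groups[tips] %in% masked)]
      length(tips) > 0 && all(groups[tips] == "core_dino")
    }
    recurse <- function(node, at_clade_root) {
      tips <- tr$tip.label[.tips_under(tr, node)]
      live <- tips[!(groups[tips] %in% masked)]
      if (pure_core(tips) &&
          (length(live) >= min_members ||
           (at_clade_root && length(live) >= 1))) {
        found[[length(found) + 1L]] <<- list(node = node, leaves = live)
        return(invisible())
      }
      if (node <= ntip) return(invisible())
      for (k in tr$edge[tr$edge[, 1] == node, 2])
        recurse(k, at_clade_root = FALSE)
    }
    if (cl$node <= ntip) {
      if (pure_core(tr$tip.label[cl$node]))
        found[[1]] <- list(node = cl$node, leaves = tr$tip.label[cl$node])
    } else {
      for (k in tr$edge[tr$edge[, 1] == cl$node, 2])
        recurse(k, at_clade_root = TRUE)
    }
    if (!length(found)) next
    sp <- lapply(found, function(f) unique(species[f$leaves]))
    ord <- order(-lengths(sp),
                 -vapply(found, function(f) length(f$leaves), 0),
                 seq_along(found))
    found <- found[ord]; sp <- sp[ord]
    num <- sub("eIF4E-", "", cl$name)
    for (i in seq_along(found)) {
      out[[length(out) + 1L]] <-
        list(name = sprintf("%s%s", num, letters[i]),
             major = cl$name, node = found[[i]]$node,
             leaves = found[[i]]$leaves,
             species = sort(unname(sp[[i]])), n_species = length(sp[[i]]))
    }
  }
  partition$subclades <- out
  partition
}

#' Species-representation table over sub-clades
#'
#' Counts census members per sub-clade and species, flags sub-clades with a
#' member in every species of the universe ("full representation"), and
#' totals members per species.
#'
#' @param partition A `clade_partition` with sub-clades (see
#'   [find_subclades()]).
#' @param census A `census_table` covering every sub-clade leaf.
#' @param species_universe Species defining full representation; defaults
#'   to all core-dinoflagellate species in the census.
#' @return Object of class `rep_table`: `counts` (sub-clade x species
#'   matrix), `n_species`, `full` (logical), `species_totals`.
#' @export
representation_table <- function(partition, census, species_universe = NULL) {
  stopifnot(inherits(partition, "clade_partition"))
  subclades <- partition$subclades
  if (is.null(subclades)) stop("run find_subclades() first")
  cen_sp <- stats::setNames(census$species, census$member_id)
  if (is.null(species_universe))
    species_universe <-
      sort(unique(census$species[census$group == "core_dino"]))
  leaves <- unlist(lapply(subclades, `[[`, "leaves"))
  missing <- setdiff(leaves, names(cen_sp))
  if (length(missing))
    stop("leaf absent from census: ", missing[1])
  counts <- matrix(0L, length(subclades), length(species_universe),
                   dimnames = list(vapply(subclades, `[[`, "", "name"),
                                   species_universe))
  for (i in seq_along(subclades)) {
    tab <- table(cen_sp[subclades[[i]]$leaves])
    tab <- tab[names(tab) %in% species_universe]
    counts[i, names(tab)] <- as.integer(tab)
  }
  n_species <- rowSums(counts > 0)
  structure(list(counts = counts, n_species = n_species,
                 full = n_species == length(species_universe),
                 species_totals = colSums(counts)),
            class = "rep_table")
}

#' @export
print.rep_table <- function(x, ...) {
  cat(sprintf("representation: %d sub-clades x %d species; %d fully represented\n",
              nrow(x$counts), ncol(x$counts), sum(x$full)))
  df <- data.frame(n_members = rowSums(x$counts), n_species = x$n_species,
                   full = x$full)
  print(df)
  invisible(x)
}
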