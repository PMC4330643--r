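mk_groups <- function(...) {
  v <- c(...)
  setNames(v, names(v))
}

test_that("major clades follow the joint-representation descent rule", {
  tr <- read_newick("((d1:1,h1:1):1,(d2:1,h2:1):1);")
  g <- mk_groups(d1 = "core_dino", h1 = "heterokont",
                 d2 = "core_dino", h2 = "heterokont")
  part <- partition_major_clades(tr, g, rooting = "none")
  expect_length(part$clades, 2)
  expect_setequal(part$clades[[1]]$leaves, c("d1", "h1"))

  # only one both-group child: the node itself is the single major clade
  tr2 <- read_newick("(d1:1,(d2:1,(h1:1,h2:1):1):1);")
  part2 <- partition_major_clades(tr2, g, rooting = "none")
  expect_length(part2$clades, 1)
  expect_setequal(part2$clades[[1]]$leaves, c("d1", "d2", "h1", "h2"))
})

test_that("clades are numbered by decreasing core-dinoflagellate count", {
  tr <- read_newick("((d1:1,h1:1):1,((d2:1,d3:1):1,h2:1):1);")
  g <- mk_groups(d1 = "core_dino", d2 = "core_dino", d3 = "core_dino",
                 h1 = "heterokont", h2 = "heterokont")
  part <- partition_major_clades(tr, g, rooting = "none")
  expect_equal(part$clades[[1]]$name, "eIF4E-1")
  expect_true(all(c("d2", "d3") %in% part$clades[[1]]$leaves))
})

test_that("a tree without both groups warns and returns unresolved", {
  tr <- read_newick("((a:1,b:1):1,c:1);")
  g <- mk_groups(a = "core_dino", b = "core_dino", c = "ciliate")
  expect_warning(part <- partition_major_clades(tr, g), "unresolved")
  expect_equal(part$clades[[1]]$name, "unresolved")
})

test_that("leaves outside every major clade are reported unplaced", {
  # a root polytomy with two qualifying children and one stray lineage
  tr <- read_newick("((d1:1,h1:1):1,(d2:1,h2:1):1,x1:3);")
  g <- mk_groups(d1 = "core_dino", h1 = "heterokont", d2 = "core_dino",
                 h2 = "heterokont", x1 = "apicomplexan")
  part <- partition_major_clades(tr, g, rooting = "none")
  expect_length(part$clades, 2)
  expect_equal(part$unplaced, "x1")
  # with only one qualifying child the whole root is a single clade and
  # nothing is unplaced
  tr2 <- read_newick("(((d1:1,h1:1):1,(d2:1,h2:1):1):1,x1:3);")
  part2 <- partition_major_clades(tr2, g, rooting = "none")
  expect_length(part2$clades, 1)
  expect_length(part2$unplaced, 0)
})

test_that("sub-clades split where non-core lineages interleave", {
  tr <- read_newick(
    "(((d1:1,d2:1):1,(a1:1,(d3:1,d4:1):1):1):1,(h1:1,h2:1):1);")
  g <- mk_groups(d1 = "core_dino", d2 = "core_dino", d3 = "core_dino",
                 d4 = "core_dino", a1 = "apicomplexan",
                 h1 = "heterokont", h2 = "heterokont")
  sp <- setNames(c("s1", "s2", "s1", "s2", "sa", "sh", "sh"),
                 names(g))
  part <- partition_major_clades(tr, g, rooting = "none")
  part <- find_subclades(part, sp)
  expect_length(part$subclades, 2)
  expect_setequal(part$subclades[[1]]$leaves, c("d1", "d2"))
  expect_setequal(part$subclades[[2]]$leaves, c("d3", "d4"))
})

test_that("masked syndinean/Perkinsus leaves never break monophyly", {
  tr <- read_newick(
    "(((d1:1,(syn:1,d2:1):1):1,a1:2):1,(h1:1,h2:1):1);")
  g <- mk_groups(d1 = "core_dino", d2 = "core_dino", syn = "syndinean",
                 a1 = "apicomplexan", h1 = "heterokont", h2 = "heterokont")
  sp <- setNames(c("s1", "s2", "sy", "sa", "sh", "sh"), names(g))
  part <- partition_major_clades(tr, g, rooting = "none")
  part <- find_subclades(part, sp)
  expect_length(part$subclades, 1)
  expect_setequal(part$subclades[[1]]$leaves, c("d1", "d2"))
})

test_that("a singleton lineage at the major-clade root is retained", {
  tr <- read_newick(
    "((d0:2,((d1:1,d2:1):1,(h1:1,h2:1):1):1):1,(d3:1,h3:1):2);")
  g <- mk_groups(d0 = "core_dino", d1 = "core_dino", d2 = "core_dino",
                 d3 = "core_dino", h1 = "heterokont", h2 = "heterokont",
                 h3 = "heterokont")
  sp <- setNames(c("s0", "s1", "s2", "s3", "sh", "sh", "sh"), names(g))
  part <- partition_major_clades(tr, g, rooting = "none")
  expect_length(part$clades, 2)
  part <- find_subclades(part, sp)
  expect_length(part$subclades, 3)
  nm <- vapply(part$subclades, function(s) length(s$leaves), 0L)
  expect_true(any(nm == 1L))   # the d0 lineage survives as a sub-clade
  # but a deep singleton does not
  tr2 <- read_newick("(((d1:1,d2:1):1,(d0:1,a1:1):1):1,(h1:1,h2:1):1);")
  g2 <- mk_groups(d0 = "core_dino", d1 = "core_dino", d2 = "core_dino",
                  a1 = "apicomplexan", h1 = "heterokont",
                  h2 = "heterokont")
  part2 <- find_subclades(partition_major_clades(tr2, g2, rooting = "none"),
                          sp)
  expect_length(part2$subclades, 1)
})

test_that("sub-clade letters order by species count and survive permutation", {
  nwk <- "(((d1:1,d2:1):1,(a1:1,(d3:1,(d4:1,d5:1):1):1):1):1,(h1:1,h2:1):1);"
  tr <- read_newick(nwk)
  g <- mk_groups(d1 = "core_dino", d2 = "core_dino", d3 = "core_dino",
                 d4 = "core_dino", d5 = "core_dino", a1 = "apicomplexan",
                 h1 = "heterokont", h2 = "heterokont")
  sp <- setNames(c("s1", "s1", "s2", "s3", "s4", "sa", "sh", "sh"),
                 names(g))
  part <- find_subclades(partition_major_clades(tr, g, rooting = "none"), sp)
  # {d3,d4,d5}: 3 species -> letter a; {d1,d2}: 1 species -> letter b
  expect_setequal(part$subclades[[1]]$leaves, c("d3", "d4", "d5"))
  expect_equal(part$subclades[[1]]$name, "1a")
  expect_equal(part$subclades[[2]]$name, "1b")
  # permuting tip order leaves letters unchanged
  tr_rot <- ape::rotateConstr(tr, rev(tr$tip.label))
  part2 <- find_subclades(partition_major_clades(tr_rot, g,
                                                 rooting = "none"), sp)
  lv <- lapply(part2$subclades, function(s) sort(s$leaves))
  expect_equal(lv[[1]], c("d3", "d4", "d5"))
  expect_equal(part2$subclades[[1]]$name, "1a")
})

test_that("representation tables count members per sub-clade and species", {
  fam <- simulate_family(small_sim_config(seed = 2))
  cen <- structure(data.frame(member_id = fam$truth$id,
                              species = fam$truth$species,
                              group = fam$truth$group),
                   class = c("census_table", "data.frame"))
  groups <- setNames(fam$truth$group, fam$truth$id)
  species <- setNames(fam$truth$species, fam$truth$id)
  part <- find_subclades(partition_major_clades(fam$tree, groups), species)
  rt <- representation_table(part, cen)
  expect_true(all(rowSums(rt$counts) ==
                    vapply(part$subclades, function(s) length(s$leaves), 0L)))
  expect_equal(unname(rt$n_species),
               unname(vapply(part$subclades, `[[`, 0L, "n_species")))
  expect_true(any(rt$full))
  # a sub-clade leaf missing from the census is an error naming the leaf
  victim <- part$subclades[[1]]$leaves[1]
  cen2 <- cen[cen$member_id != victim, ]
  class(cen2) <- class(cen)
  expect_error(representation_table(part, cen2), victim, fixed = TRUE)
})

test_that("the partition recovers generating clades on the true tree", {
  fam <- simulate_family(small_sim_config(seed = 4))
  groups <- setNames(fam$truth$group, fam$truth$id)
  species <- setNames(fam$truth$species, fam$truth$id)
  part <- find_subclades(partition_major_clades(fam$tree, groups), species)
  expect_length(part$clades, 3)
  expect_length(part$subclades, 9)
  expect_equal(subclade_accuracy(part, fam$truth), 100)
})
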