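test_that("sequence evolution: identity at t = 0, determinism, expectation", {
  mod <- substitution_model("LG")
  s <- random_protein(200, prob = mod$pi)
  expect_identical(evolve_sequence(s, 0, mod), s)
  set.seed(10); a <- evolve_sequence(s, 0.4, mod)
  set.seed(10); b <- evolve_sequence(s, 0.4, mod)
  expect_identical(a, b)
  expect_equal(nchar(a), nchar(s))

  # observed p-distance within 3 s.e. of the closed-form expectation
  set.seed(11)
  long <- random_protein(10000, prob = mod$pi)
  der <- evolve_sequence(long, 0.5, mod)
  P <- transition_prob(mod, 0.5)
  p_exp <- 1 - sum(mod$pi * diag(P))
  p_obs <- mean(strsplit(long, "")[[1]] != strsplit(der, "")[[1]])
  se <- sqrt(p_exp * (1 - p_exp) / 10000)
  expect_lt(abs(p_obs - p_exp), 3 * se)
})

test_that("clade signatures force states, insertions and the motif", {
  anch <- reference_anchors()
  core <- eif4e_reference(core = TRUE)
  sig <- clade_signature(states = c("56" = "Y", "112" = "H", "162" = "R"),
                         insertions = list(
                           list(window = c(73L, 102L), length = 10L),
                           list(window = c(130L, 166L), length = 8L)),
                         motif = "TVQEFW")
  set.seed(12)
  out <- apply_clade_signature(core$residues, anch$positions, sig)
  expect_equal(nchar(out$res), 139 + 18)
  for (p in c(56, 112, 162)) {
    i <- match(p, out$pos)
    expect_equal(substr(out$res, i, i),
                 unname(sig$states[[as.character(p)]]))
  }
  i73 <- match(73L, out$pos)
  expect_equal(substr(out$res, i73 - 5, i73), "TVQEFW")
  # idempotence
  again <- apply_clade_signature(out$res, out$pos, sig)
  expect_identical(again, out)
  # unmapped anchor errors
  expect_error(apply_clade_signature("MKW", c(1L, 2L, 3L), sig), "unmapped")
})

test_that("signature carriers classify to the generating clade end-to-end", {
  anch <- reference_anchors()
  core <- eif4e_reference(core = TRUE)
  set.seed(13)
  sig1 <- sim_config()$signatures[[1]]
  out <- apply_clade_signature(core$residues, anch$positions, sig1)
  a <- trim_core(align_to_reference(seq_record("c1", out$res)))
  st <- residue_states(a)
  expect_equal(st$p56, "Y"); expect_equal(st$p112, "H")
  expect_gte(st$ins_73_102, 5); expect_gte(st$ins_130_166, 5)
  expect_equal(classify_diagnostics(st)$label, "clade1_like")
})

test_that("zero-length branches give clade members identical up to signatures", {
  cfg <- small_sim_config(seed = 14, clade_stem = 0, subclade_stem = 0,
                          hk_stem = 0, hk_tip = 0, spine = 0,
                          copy_branch = 0,
                          divergence = rep(list(c(0, 0, 0)), 3))
  cfg$bias <- list(n = 0L, weight = 0, target = NULL, stem = 0, tip = 0)
  fam <- simulate_family(cfg)
  for (cl in unique(fam$truth$clade)) {
    ids <- fam$truth$id[fam$truth$clade == cl]
    seqs <- vapply(fam$records[ids], `[[`, "", "residues")
    expect_length(unique(seqs), 1L)
  }
})

test_that("simulation is deterministic per seed and truth is complete", {
  f1 <- simulate_family(small_sim_config(seed = 20))
  f2 <- simulate_family(small_sim_config(seed = 20))
  expect_identical(vapply(f1$records, `[[`, "", "residues"),
                   vapply(f2$records, `[[`, "", "residues"))
  expect_identical(write_newick(f1$tree), write_newick(f2$tree))
  f3 <- simulate_family(small_sim_config(seed = 21))
  expect_false(identical(vapply(f1$records, `[[`, "", "residues"),
                         vapply(f3$records, `[[`, "", "residues")))
  expect_setequal(f1$truth$id, names(f1$records))
  expect_setequal(f1$truth$id, f1$tree$tip.label)
  expect_equal(sort(unique(f1$truth$clade)), paste0("eIF4E-", 1:3))
  expect_equal(length(unique(na.omit(f1$truth$subclade))), 9L)
})

test_that("higher divergence scalars lower within-sub-clade identity", {
  levels <- c(0.03, 0.10, 0.22)
  means <- vapply(levels, function(s) {
    fam <- simulate_family(small_sim_config(
      seed = 30, divergence = rep(list(c(s, s, s)), 3)))
    m <- anchor_stack(fam$records)
    rows <- apply(m$matrix, 1, paste, collapse = "")
    ids <- fam$truth$id[fam$truth$subclade %in% "1a"]
    ids <- intersect(ids, names(rows))
    combos <- utils::combn(ids, 2)
    mean(vapply(seq_len(ncol(combos)), function(j)
      percent_identity(rows[[combos[1, j]]], rows[[combos[2, j]]]), 0))
  }, 0)
  expect_true(all(diff(means) < 0))
})

test_that("composition-biased lineages shift toward the target frequencies", {
  cfg <- small_sim_config(seed = 33)
  fam <- simulate_family(cfg)
  cil <- fam$truth$id[fam$truth$group == "ciliate"]
  expect_length(cil, 2L)
  target <- cfg$bias$target
  enriched <- names(sort(target, decreasing = TRUE))[1:4]
  frac <- function(id) {
    r <- strsplit(fam$records[[id]]$residues, "")[[1]]
    mean(r %in% enriched)
  }
  cil_frac <- mean(vapply(cil, frac, 0))
  core_frac <- mean(vapply(sample(fam$truth$id[fam$truth$group ==
                                                 "core_dino"], 10), frac, 0))
  expect_gt(cil_frac, core_frac + 0.05)
})
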