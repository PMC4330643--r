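ref <- eif4e_reference()
ref_aln <- trim_core(align_to_reference(ref, ref))

test_that("murine reference reports the canonical cap-binding states", {
  st <- residue_states(ref_aln)
  expect_equal(st$p43, "W"); expect_equal(st$p46, "W")
  expect_equal(st$p56, "W"); expect_equal(st$p73, "W")
  expect_equal(st$p102, "W"); expect_equal(st$p103, "E")
  expect_equal(st$p112, "R"); expect_equal(st$p157, "R")
  expect_equal(st$p162, "K"); expect_equal(st$p166, "W")
  expect_equal(st$ins_73_102, 0); expect_equal(st$ins_130_166, 0)
  expect_equal(st$cterm_ext, 41)
})

# helper: murine core with forced states / insertions, via the simulator's
# signature machinery
signed_core <- function(sig) {
  anch <- reference_anchors()
  core <- eif4e_reference(core = TRUE)
  s <- apply_clade_signature(core$residues, anch$positions, sig)
  seq_record("sig", s$res)
}

test_that("clade-2 style substitutions are reported at 112 and 162", {
  rec <- signed_core(clade_signature(states = c("112" = "C", "162" = "V")))
  st <- residue_states(trim_core(align_to_reference(rec, ref)))
  expect_equal(st$p112, "C")
  expect_equal(st$p162, "V")
})

test_that("an all-gap row reports gaps everywhere and zero insertions", {
  m <- as_multi_alignment(
    matrix("-", 1, 139, dimnames = list("empty", NULL)),
    positions = 38:176)
  st <- residue_states(m)
  expect_true(all(unlist(st[paste0("p", c(43, 56, 102, 112, 162))]) == "-"))
  expect_equal(st$ins_73_102, 0)
})

test_that("eIF4G motif variants classify by the charge of the x positions", {
  mk <- function(hex) {
    mat <- matrix("A", 1, 139, dimnames = list("m", NULL))
    mat[1, match(68:73, 38:176)] <- strsplit(hex, "")[[1]]
    scan_eif4g_motif(as_multi_alignment(mat, positions = 38:176))
  }
  expect_equal(mk("TVEEFW")$variant_class, "acidic_1c")
  expect_true(mk("TVEEFW")$matches_consensus)
  expect_equal(mk("TVKGFW")$variant_class, "basic_1d")
  expect_equal(mk("TVQEFW")$variant_class, "polar_1a1b")
  expect_equal(mk("SVGSFW")$variant_class, "canonical")
  expect_equal(mk("AAAAAA")$variant_class, "other")
  expect_false(mk("AAAAAA")$matches_consensus)
  # partially gapped window
  g <- mk("TV--FW")
  expect_false(g$matches_consensus)
  expect_equal(g$variant_class, "other")
})

test_that("diagnostic rules fire in order with first match winning", {
  rules_case <- function(sig) {
    rec <- signed_core(sig)
    a <- trim_core(align_to_reference(rec, ref))
    classify_diagnostics(residue_states(a))$label
  }
  # Class II aromatic replacement dominates everything else
  expect_equal(rules_case(clade_signature(states = c("43" = "Y"))),
               "metazoan_classII_like")
  # clade 1: both window insertions >= 5 plus H112
  expect_equal(rules_case(clade_signature(
    states = c("56" = "Y", "112" = "H"),
    insertions = list(list(window = c(73L, 102L), length = 10L),
                      list(window = c(130L, 166L), length = 10L)))),
    "clade1_like")
  # clade 2
  expect_equal(rules_case(clade_signature(states = c("112" = "C",
                                                     "162" = "V"))),
               "clade2_like")
  # murine itself satisfies the canonical rule set: a known artifact of
  # the rule design
  expect_equal(classify_diagnostics(residue_states(ref_aln))$label,
               "clade3_like")
  # one insertion only + H112 does not make clade 1; falls through
  expect_equal(rules_case(clade_signature(
    states = c("112" = "H"),
    insertions = list(list(window = c(73L, 102L), length = 10L)))),
    "unclassified")
})

test_that("classification is a pure function of the report", {
  rec <- signed_core(clade_signature(states = c("112" = "C", "162" = "A")))
  a <- trim_core(align_to_reference(rec, ref))
  st <- residue_states(a)
  expect_identical(classify_diagnostics(st), classify_diagnostics(st))
})

test_that("noise-free signature carriers all classify to their clade", {
  cfg <- sim_config(seed = 3,
                    species = capclade_species()[1:3],
                    clade_stem = 0, subclade_stem = 0, hk_stem = 0,
                    hk_tip = 0, spine = 0, copy_branch = 0,
                    divergence = rep(list(c(0, 0, 0)), 3),
                    copies = rep(list(list(c(1L, 1L), c(1L, 1L),
                                           c(1L, 1L))), 3),
                    presence = rep(list(c(3L, 3L, 3L)), 3),
                    bias = list(n = 0L, weight = 0, target = NULL,
                                stem = 0, tip = 0))
  fam <- simulate_family(cfg)
  m <- anchor_stack(fam$records)
  ann <- annotate_alignment(m)
  lab <- ann$label
  truth_clade <- fam$truth$clade[match(ann$seq_id, fam$truth$id)]
  expected <- c("eIF4E-1" = "clade1_like", "eIF4E-2" = "clade2_like",
                "eIF4E-3" = "clade3_like")
  expect_equal(unname(expected[truth_clade]), lab)
})

test_that("sub-clade-level characters land in evidence, not the label", {
  rec <- signed_core(clade_signature(states = c("102" = "R")))
  a <- trim_core(align_to_reference(rec, ref))
  cls <- classify_diagnostics(residue_states(a))
  expect_match(cls$evidence, "W102R")
  expect_false(cls$label == "clade2_like")
})
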