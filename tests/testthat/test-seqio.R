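test_that("FASTA parsing honors the id|species|group header convention", {
  f <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">s1|SpA|core_dino", "mkw",
               ">s2", "MKWR*",
               ">s3|SpB|not_a_group", "MK"), f)
  recs <- read_fasta(f)
  expect_length(recs, 3)
  expect_equal(recs$s1$residues, "MKW")
  expect_equal(recs$s1$group, "core_dino")
  expect_equal(recs$s1$species, "SpA")
  expect_equal(recs$s2$residues, "MKWR")   # terminal * stripped
  expect_equal(recs$s2$group, "other")
  expect_equal(recs$s3$group, "other")     # unknown group falls back
})

test_that("FASTA edge cases: empty file, wrapping, duplicates, bad residues", {
  f <- withr::local_tempfile(fileext = ".faa")
  file.create(f)
  expect_length(read_fasta(f), 0)

  set.seed(1)
  long <- random_protein(210)
  # hand-built wrapped fixture: 70-column lines
  writeLines(c(">w|Sp|other", substr(long, 1, 70), substr(long, 71, 140),
               substr(long, 141, 210)), f)
  rec <- read_fasta(f)$w
  expect_equal(nchar(rec$residues), 210)
  expect_equal(rec$residues, long)

  writeLines(c(">dup", "MK", ">dup", "MW"), f)
  expect_error(read_fasta(f), "dup")
  writeLines(c(">bad", "MK9Z"), f)
  expect_error(read_fasta(f), "bad")
})

test_that("FASTA round-trips through write_fasta, sidecar overrides headers", {
  recs <- seq_set(list(seq_record("a", "MKWLY", "Sp one", "heterokont"),
                       seq_record("b", random_protein(150))))
  f <- withr::local_tempfile(fileext = ".faa")
  write_fasta(recs, f, width = 60)
  back <- read_fasta(f)
  expect_equal(back$a$residues, "MKWLY")
  expect_equal(back$a$group, "heterokont")
  expect_equal(back$b$residues, recs$b$residues)

  side <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_table(data.frame(id = "b", species = "SpB", group = "ciliate"),
                  side)
  back2 <- read_fasta(f, sidecar = side)
  expect_equal(back2$b$species, "SpB")
  expect_equal(back2$b$group, "ciliate")
})

test_that("newick reading keeps lengths and internal support labels", {
  tr <- read_newick("(A:1,B:2);")
  expect_equal(sort(tr$tip.label), c("A", "B"))
  expect_equal(sort(tr$edge.length), c(1, 2))
  tr2 <- read_newick("((A:1,B:1)90:0.5,C:2);")
  expect_true("90" %in% tr2$node.label)
  # absent branch lengths default to zero
  tr3 <- read_newick("((A,B),C);")
  expect_equal(tr3$edge.length, rep(0, nrow(tr3$edge)))
})

test_that("newick parse errors carry position information", {
  expect_error(read_newick("((A:1,B:2);"), "unclosed")
  expect_error(read_newick("(A:1,B:2));"), "position")
})

test_that("newick round-trip is lossless on canonical forms", {
  set.seed(42)
  for (k in 1:50) {
    tr <- ape::rtree(sample(4:12, 1))
    tr$edge.length <- round(tr$edge.length, 6)
    s <- write_newick(tr)
    expect_equal(write_newick(read_newick(s)), s)
  }
})

nexus_lines_seq <- c(
  "#NEXUS",
  "[ generated fixture ]",
  "BEGIN DATA;",
  "DIMENSIONS NTAX=2 NCHAR=8;",
  "FORMAT DATATYPE=PROTEIN GAP=-;",
  "MATRIX",
  "tax1 ACDEGHIK",
  "tax2 ACD-GHIL",
  ";",
  "END;",
  "BEGIN TREES;",
  "TRANSLATE 1 tax1, 2 tax2;",
  "TREE t1 = ((1:1,2:2):0);",
  "END;")

nexus_lines_int <- c(
  "#NEXUS",
  "BEGIN DATA;",
  "DIMENSIONS NTAX=2 NCHAR=8;",
  "FORMAT DATATYPE=PROTEIN GAP=- INTERLEAVE=YES;",
  "MATRIX",
  "tax1 ACDE", "tax2 ACD-",
  "[ second block ]",
  "tax1 GHIK", "tax2 GHIL",
  ";",
  "END;")

test_that("NEXUS matrix and trees blocks parse, translate honored", {
  f <- withr::local_tempfile(fileext = ".nex")
  writeLines(nexus_lines_seq, f)
  nx <- read_nexus(f)
  expect_equal(length(nx$alignment), 2)
  expect_equal(unname(nchar(nx$alignment)), c(8L, 8L))
  expect_equal(nx$alignment[["tax2"]], "ACD-GHIL")
  expect_length(nx$trees, 1)
  expect_setequal(nx$trees[[1]]$tip.label, c("tax1", "tax2"))
})

test_that("interleaved and sequential NEXUS matrices compare equal", {
  f1 <- withr::local_tempfile(fileext = ".nex")
  f2 <- withr::local_tempfile(fileext = ".nex")
  writeLines(nexus_lines_seq, f1)
  writeLines(nexus_lines_int, f2)
  expect_equal(read_nexus(f1)$alignment, read_nexus(f2)$alignment)
})

test_that("NEXUS errors: truncation, missing blocks", {
  f <- withr::local_tempfile(fileext = ".nex")
  writeLines(nexus_lines_seq[1:7], f)   # cut inside MATRIX
  expect_error(read_nexus(f), "truncated|terminated")
  writeLines(nexus_lines_int, f)
  expect_error(read_nexus(f, require = "trees"), "TREES")
  writeLines(c("#NEXUS", "BEGIN TREES;", "TREE t=(A:1,B:1);", "END;"), f)
  expect_error(read_nexus(f, require = "alignment"), "DATA")
})

test_that("sequence records validate ids, groups and residues", {
  expect_error(seq_record("", "MK"), "non-empty")
  expect_error(seq_record("x", "MKU2"), "non-amino-acid")
  expect_equal(seq_record("x", "mkx*")$residues, "MKX")
  expect_error(seq_set(list(seq_record("a", "M"), seq_record("a", "K"))),
               "duplicate")
})
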