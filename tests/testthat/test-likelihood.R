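test_that("substitution models are proper normalized reversible models", {
  for (nm in c("LG", "WAG", "JTT")) {
    mod <- substitution_model(nm, gamma_shape = 0.9)
    expect_equal(sum(mod$pi), 1, tolerance = 1e-12)
    expect_equal(max(abs(rowSums(mod$Q))), 0, tolerance = 1e-10)
    expect_equal(-sum(mod$pi * diag(mod$Q)), 1, tolerance = 1e-10)
    P <- transition_prob(mod, 0.37)
    expect_equal(rowSums(P), rep(1, 20), tolerance = 1e-12,
                 ignore_attr = TRUE)
    # detailed balance (reversibility)
    F <- mod$pi * P
    expect_equal(max(abs(F - t(F))), 0, tolerance = 1e-12)
  }
  expect_equal(mean(discrete_gamma_rates(0.42, 4)), 1)
  expect_equal(discrete_gamma_rates(Inf, 4), rep(1, 4))
})

test_that("two-taxon pruning equals the matrix-exponential closed form", {
  mod <- substitution_model("LG", gamma_shape = 0.7, n_categories = 4L)
  tr <- read_newick("(A:0.2,B:0.3);")
  cols <- list(c("A", "A"), c("A", "R"), c("W", "C"), c("N", "N"))
  m <- as_multi_alignment(c(A = paste(vapply(cols, `[`, "", 1), collapse = ""),
                            B = paste(vapply(cols, `[`, "", 2), collapse = "")))
  got <- tree_log_likelihood(tr, m, mod)
  # independent oracle: scaling-and-squaring matrix exponential of Q
  cf <- 0
  for (cc in cols) {
    a <- match(cc[1], AA); b <- match(cc[2], AA)
    lik <- mean(vapply(mod$rates, function(r)
      mod$pi[a] * expm_oracle(mod$Q, 0.5 * r)[a, b], 0))
    cf <- cf + log(lik)
  }
  expect_equal(got, cf, tolerance = 1e-9)
})

test_that("lnL tends to log pi at vanishing branch length", {
  mod <- substitution_model("LG")
  tr <- read_newick("(A:1e-10,B:1e-10);")
  m <- as_multi_alignment(c(A = "W", B = "W"))
  expect_equal(tree_log_likelihood(tr, m, mod), log(mod$pi[["W"]]),
               tolerance = 1e-6)
})

test_that("likelihood is invariant under rerooting (pulley principle)", {
  set.seed(77)
  mod <- substitution_model("LG", gamma_shape = 1.2)
  for (k in 1:20) {
    tr <- ape::rtree(sample(4:7, 1))
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.8)
    seqs <- setNames(replicate(length(tr$tip.label),
                               random_protein(40, prob = mod$pi)),
                     tr$tip.label)
    m <- as_multi_alignment(seqs)
    l0 <- tree_log_likelihood(tr, m, mod)
    og <- sample(tr$tip.label, 1)
    tr2 <- ape::root(ape::unroot(tr), outgroup = og, resolve.root = TRUE)
    expect_equal(tree_log_likelihood(tr2, m, mod), l0, tolerance = 1e-8)
  }
})

test_that("pruning agrees with an independent implementation (phangorn pml)", {
  set.seed(55)
  mod <- substitution_model("LG", gamma_shape = 0.7)
  tr <- ape::rtree(6)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.6)
  seqs <- setNames(replicate(6, random_protein(60, prob = mod$pi)),
                   tr$tip.label)
  m <- as_multi_alignment(seqs)
  pd <- phangorn::phyDat(t(vapply(strsplit(seqs, ""), identity,
                                  character(60))), type = "AA")
  fit <- phangorn::pml(tr, pd, model = "LG", k = 4, shape = 0.7,
                       bf = mod$pi)
  expect_equal(tree_log_likelihood(tr, m, mod), fit$logLik,
               tolerance = 1e-6)
})

test_that("gaps are missing data: all-gap columns contribute nothing", {
  mod <- substitution_model("LG")
  tr <- read_newick("(A:0.2,B:0.3);")
  m1 <- as_multi_alignment(c(A = "AR", B = "AQ"))
  # appended columns observe nothing (gap or X in every row)
  m2 <- as_multi_alignment(c(A = "AR-X", B = "AQ--"))
  expect_equal(tree_log_likelihood(tr, m1, mod),
               tree_log_likelihood(tr, m2, mod))
  # a half-observed column contributes the marginal of its single residue
  m3 <- as_multi_alignment(c(A = "AR-", B = "AQW"))
  expect_equal(tree_log_likelihood(tr, m3, mod),
               tree_log_likelihood(tr, m1, mod) + log(mod$pi[["W"]]))
  expect_error(tree_log_likelihood(read_newick("(A:1,Z:1);"), m1, mod),
               "Z")
})

test_that("gamma-shape estimation finds an interior optimum on simulated data", {
  set.seed(101)
  truth <- 0.5
  mod <- substitution_model("LG", gamma_shape = truth, n_categories = 4L)
  tr <- ape::rtree(6)
  tr$edge.length <- runif(nrow(tr$edge), 0.1, 0.5)
  # simulate with per-site gamma rates down the tree
  n <- 400
  rates <- mod$rates[sample.int(4, n, replace = TRUE)]
  root <- random_protein(n, prob = mod$pi)
  seqs <- list()
  descend <- function(node, seq) {
    for (child in tr$edge[tr$edge[, 1] == node, 2]) {
      e <- which(tr$edge[, 1] == node & tr$edge[, 2] == child)
      t_e <- tr$edge.length[e]
      res <- strsplit(seq, "")[[1]]
      out <- vapply(seq_len(n), function(i) {
        P <- transition_prob(mod, t_e * rates[i])
        sample(AA, 1, prob = P[match(res[i], AA), ])
      }, "")
      s2 <- paste(out, collapse = "")
      if (child <= length(tr$tip.label)) seqs[[tr$tip.label[child]]] <<- s2
      else descend(child, s2)
    }
  }
  descend(length(tr$tip.label) + 1L, root)
  m <- as_multi_alignment(unlist(seqs))
  est <- estimate_gamma_shape(tr, m, mod)
  expect_gt(est$alpha, 0.1)
  expect_lt(est$alpha, 3)
  # the estimate should beat a very wrong shape
  bad <- substitution_model("LG", gamma_shape = 10)
  expect_gte(est$logLik, tree_log_likelihood(tr, m, bad) - 1e-6)
})

test_that("model frequencies beat contaminated empirical frequencies", {
  # families with composition-biased lineages distort the pooled empirical
  # frequencies; the model-frequency likelihood then wins, the direction
  # used to select LG frequencies for the survey phylogeny
  # full-size families: at this scale the distortion dominates the noise
  wins <- 0L
  for (sd in c(1, 7)) {
    fam <- simulate_family(sim_config(seed = sd))
    m <- anchor_stack(fam$records)
    tr <- suppressWarnings(nj_tree(distance_matrix(m)))
    cmp <- compare_frequencies(tr, m, "LG", gamma_shape = 1)
    wins <- wins + cmp$model_preferred
  }
  expect_gte(wins, 2L)
})
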