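test_that("pairwise distance corrections evaluate correctly", {
  expect_equal(pairwise_distance("MKLV", "MKLV", "p"), 0)
  expect_equal(pairwise_distance("MKLV", "MKLV", "kimura"), 0)
  expect_equal(pairwise_distance("MKLV", "MKLV", "ml-poisson"), 0)
  # p = 0.5 -> kimura d = -ln(0.45)
  expect_equal(pairwise_distance("AAAA", "AACC", "kimura"), -log(1 - 0.5 - 0.05))
  # gap columns excluded pairwise
  expect_equal(pairwise_distance("A-CD", "AB-D", "p"), 0)
  expect_error(pairwise_distance("--AB", "AB--", "p"), "no shared")
  # ml-poisson reduces to kimura-like behaviour at small p
  for (p in seq(0.01, 0.1, by = 0.01)) {
    d1 <- phyloroot:::correct_p(p, "kimura")
    d2 <- phyloroot:::correct_p(p, "ml-poisson")
    expect_lt(abs(d1 - d2), 0.01)
  }
})

test_that("ml-poisson distance recovers the generating branch length", {
  m <- substitution_model(alpha = 0.7, n_categories = 6L)
  tr <- parse_newick("(a:0.15,b:0.15);")
  fam <- evolve_alignment(tr, m, 50000, seed = 8)
  # inversion consistent with the generator's 6-category discretization
  d <- pairwise_distance(fam$seqs[["a"]], fam$seqs[["b"]], "ml-poisson",
                         alpha = 0.7, n_categories = 6L)
  # delta-method standard error of the corrected distance
  cc <- 19 / 20
  p <- pairwise_distance(fam$seqs[["a"]], fam$seqs[["b"]], "p")
  dd_dp <- (1 - p / cc)^(-1 / 0.7 - 1)
  se <- sqrt(p * (1 - p) / 50000) * dd_dp
  expect_lt(abs(d - 0.3), 3 * se)
  # continuous-gamma closed form stays close to the exact inversion
  d_cont <- pairwise_distance(fam$seqs[["a"]], fam$seqs[["b"]], "ml-poisson",
                              alpha = 0.7)
  expect_lt(abs(d_cont - d), 0.02)
})

test_that("saturated pairs get the flagged ceiling distance", {
  seqs <- c(a = strrep("A", 40), b = strrep("C", 40),
            c = paste0(strrep("A", 36), "CCCC"))
  d <- distance_matrix(seqs, "kimura")
  expect_true(nrow(attr(d, "saturated")) >= 1L)
  finite_max <- d["a", "c"]
  expect_equal(d["a", "b"], finite_max * 1.05)
})

test_that("neighbor joining is exact on additive matrices", {
  # worked quartet
  tt <- parse_newick("((A:1,B:2):1,C:3,D:4);")
  njt <- neighbor_joining(ape::cophenetic.phylo(tt))
  expect_setequal(names(bipartition_set(njt)), names(bipartition_set(tt)))
  expect_equal(sort(njt$edge.length), c(1, 1, 2, 3, 4))
  # 3-taxon closed form
  m3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- neighbor_joining(m3)
  expect_equal(sort(t3$edge.length), c((3 + 4 - 5) / 2, (3 + 5 - 4) / 2,
                                       (4 + 5 - 3) / 2))
  # random additive matrices, 5-30 leaves
  withr::with_seed(11, {
    for (i in 1:20) {
      n <- sample(5:30, 1)
      tr <- ape::rtree(n)
      tr$edge.length <- runif(nrow(tr$edge), 0.1, 2)
      rec <- neighbor_joining(ape::cophenetic.phylo(tr))
      expect_setequal(names(bipartition_set(rec)),
                      names(bipartition_set(ape::unroot(tr))))
      expect_equal(sort(rec$edge.length),
                   sort(ape::unroot(tr)$edge.length), tolerance = 1e-6)
    }
  })
  expect_error(neighbor_joining(matrix(0, 2, 2)), "at least 3")
})

test_that("pruning likelihood matches brute-force state summation", {
  m <- model4(alpha = 0.6, k = 3L)
  withr::with_seed(4, {
    for (i in 1:5) {
      tr <- ape::rtree(sample(3:5, 1))
      tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.8)
      tr <- ape::unroot(tr)
      nsit <- 6L
      fam <- evolve_alignment(tr, m, nsit, seed = i)
      seqs <- fam$seqs
      if (i == 3) substr(seqs[[1]], 2, 3) <- "--"  # gaps as missing data
      expect_equal(tree_log_likelihood(tr, seqs, m),
                   brute_log_likelihood(tr, seqs, m), tolerance = 1e-10)
    }
  })
})

test_that("site likelihoods sum to one over all leaf patterns", {
  m <- model4()
  tr <- parse_newick("(a:0.2,b:0.4,c:0.3);")
  states <- m$states
  pats <- expand.grid(a = states, b = states, c = states,
                      stringsAsFactors = FALSE)
  tot <- sum(vapply(seq_len(nrow(pats)), function(i) {
    exp(tree_log_likelihood(tr, c(a = pats$a[i], b = pats$b[i],
                                  c = pats$c[i]), m))
  }, numeric(1)))
  expect_equal(tot, 1, tolerance = 1e-10)
})

test_that("likelihood is invariant to re-rooting", {
  w <- tiny_world()
  m <- substitution_model()
  fam <- evolve_alignment(w$tree, m, 60, seed = 3)
  base <- tree_log_likelihood(w$tree, fam$seqs, m)
  for (og in c("og_p2_s1", "kA_c1_s2", "kB_c2_s1")) {
    rr <- ape::root(w$tree, outgroup = og, resolve.root = TRUE)
    expect_lt(abs(tree_log_likelihood(rr, fam$seqs, m) - base), 1e-8)
  }
})

test_that("likelihood agrees with an independent implementation", {
  skip_if_not_installed("phangorn")
  w <- tiny_world()
  m <- substitution_model(alpha = Inf, n_categories = 1L)
  fam <- evolve_alignment(w$tree, m, 120, seed = 13)
  pd <- phangorn::phyDat(t(sapply(strsplit(fam$seqs, ""), identity)),
                         type = "AA")
  fit <- phangorn::pml(ape::unroot(w$tree), pd, bf = rep(1 / 20, 20),
                       Q = rep(1, 190), k = 1)
  expect_equal(tree_log_likelihood(w$tree, fam$seqs, m), fit$logLik,
               tolerance = 1e-8)
})

test_that("branch-length optimization ascends and recovers true lengths", {
  m <- substitution_model(alpha = 0.7, n_categories = 6L)
  tr <- parse_newick("((A:0.12,B:0.08):0.1,(C:0.3,D:0.06):0.15,E:0.4);")
  fam <- evolve_alignment(tr, m, 20000, seed = 10)
  start <- neighbor_joining(distance_matrix(fam$seqs, "ml-poisson",
                                            alpha = 0.7))
  opt <- optimize_branch_lengths(start, fam$seqs, m)
  trace <- attr(opt, "lnL_sweeps")
  expect_true(all(diff(trace) >= -1e-9))
  # same topology as truth here, so compare per-split branch lengths
  expect_setequal(names(bipartition_set(opt)), names(bipartition_set(tr)))
  true_sorted <- sort(tr$edge.length)
  opt_sorted <- sort(opt$edge.length)
  big <- true_sorted >= 0.05
  expect_true(all(abs(opt_sorted[big] - true_sorted[big]) /
                    true_sorted[big] < 0.10))
  # already-optimal tree is a fixed point (no further gain)
  opt2 <- optimize_branch_lengths(opt, fam$seqs, m)
  expect_lt(attr(opt2, "lnL") - attr(opt, "lnL"), 1e-2)
  expect_equal(opt2$edge.length, opt$edge.length, tolerance = 1e-3)
})

test_that("bootstrap supports are percentages and strong signal is supported", {
  w <- tiny_world()
  fam <- evolve_alignment(w$tree, substitution_model(), 2000, seed = 21)
  bt <- bootstrap_support(fam$seqs, B = 30, seed = 5)
  sup <- bt$node.label[!is.na(bt$node.label)]
  expect_true(all(sup >= 0 & sup <= 100))
  og <- w$taxonomy$leaf[w$taxonomy$domain == "outgroup"]
  s <- split_bootstrap_support(fam$seqs, og, B = 30, seed = 5)
  expect_true(attr(s, "in_original"))
  expect_gte(as.numeric(s), 95)
  # determinism
  s2 <- split_bootstrap_support(fam$seqs, og, B = 30, seed = 5)
  expect_identical(as.numeric(s), as.numeric(s2))
})
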