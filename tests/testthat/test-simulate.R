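test_that("world construction: counts, splits, scaling, determinism", {
  cfg <- world_config(n_classes_per_kingdom = 2L, n_species_per_class = 2L,
                      n_outgroup_phyla = 3L, stem_length = 0.5)
  w <- sample_species_tree(cfg)
  expect_equal(length(w$tree$tip.label), 11L)  # 2*2*2 ingroup + 3 outgroup
  og <- w$taxonomy$leaf[w$taxonomy$domain == "outgroup"]
  expect_true(is_monophyletic(w$tree, og))
  expect_equal(interdomain_stem_length(w$tree,
                                       setdiff(w$tree$tip.label, og), og), 0.5)
  # every class and phylum monophyletic
  for (cl in unique(w$taxonomy$class)) {
    expect_true(is_monophyletic(w$tree,
                                w$taxonomy$leaf[w$taxonomy$class == cl]))
  }
  # determinism
  expect_identical(write_newick(sample_species_tree(cfg)$tree),
                   write_newick(w$tree))
  # rate multiplier scales every edge inside the clade exactly
  w8 <- sample_species_tree(world_config(
    n_classes_per_kingdom = 2L, n_species_per_class = 2L,
    n_outgroup_phyla = 3L, stem_length = 0.5,
    fast_clades = list(list(clade = "kA_c1", rate = 8))))
  leaves <- w$taxonomy$leaf[w$taxonomy$class == "kA_c1"]
  mrca <- ape::getMRCA(w$tree, match(leaves, w$tree$tip.label))
  inside <- phyloroot:::edges_below(w$tree, mrca)
  expect_equal(w8$tree$edge.length[inside], w$tree$edge.length[inside] * 8)
  outside_other_kingdom <- phyloroot:::edges_below(
    w$tree, ape::getMRCA(w$tree, match(w$taxonomy$leaf[w$taxonomy$phylum == "kB"],
                                       w$tree$tip.label)))
  expect_equal(w8$tree$edge.length[outside_other_kingdom],
               w$tree$edge.length[outside_other_kingdom])
  expect_error(world_config(n_species_per_class = 0), "counts")
})

test_that("evolve_alignment limits: zero branch lengths and determinism", {
  w <- tiny_world()
  m <- substitution_model()
  tr0 <- w$tree
  tr0$edge.length[] <- 0
  fam <- evolve_alignment(tr0, m, 50, seed = 3)
  expect_equal(length(unique(unname(fam$seqs))), 1L)
  f1 <- evolve_alignment(w$tree, m, 100, seed = 5)
  f2 <- evolve_alignment(w$tree, m, 100, seed = 5)
  expect_identical(f1$seqs, f2$seqs)
  expect_error(evolve_alignment(w$tree, m, 0), "n_sites")
})

test_that("observed divergence matches the matrix-exponential expectation", {
  # Poisson model: closed-form p(t) = c * (1 - exp(-t/c)), c = 19/20
  m <- substitution_model(alpha = Inf, n_categories = 1L)
  tr <- parse_newick("(a:0.05,b:0.05);")
  fam <- evolve_alignment(tr, m, 50000, seed = 7)
  p_obs <- pairwise_distance(fam$seqs[["a"]], fam$seqs[["b"]], "p")
  cc <- 19 / 20
  p_exp <- cc * (1 - exp(-0.1 / cc))
  expect_lt(abs(p_obs - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 50000))
})

test_that("very large gamma shape converges to the homogeneous model", {
  m_inf <- substitution_model(alpha = Inf, n_categories = 1L)
  m_big <- substitution_model(alpha = 5000, n_categories = 6L)
  expect_equal(m_big$rates, rep(1, 6), tolerance = 0.05)
  tr <- parse_newick("(a:0.1,b:0.1);")
  p1 <- pairwise_distance(evolve_alignment(tr, m_inf, 30000, seed = 1)$seqs[["a"]],
                          evolve_alignment(tr, m_inf, 30000, seed = 1)$seqs[["b"]],
                          "p")
  p2 <- pairwise_distance(evolve_alignment(tr, m_big, 30000, seed = 1)$seqs[["a"]],
                          evolve_alignment(tr, m_big, 30000, seed = 1)$seqs[["b"]],
                          "p")
  expect_lt(abs(p1 - p2), 3 * sqrt(p1 * (1 - p1) / 30000) + 1e-9)
})

test_that("leaf residue frequencies are stationary at equilibrium", {
  m <- substitution_model()  # equal frequencies
  tr <- parse_newick("(a:0.4,b:0.4);")
  fam <- evolve_alignment(tr, m, 50000, seed = 11)
  counts <- table(factor(strsplit(fam$seqs[["b"]], "")[[1]],
                         levels = m$states))
  expect_gt(stats::chisq.test(counts, p = m$freqs)$p.value, 0.01)
})

test_that("inject_hgt replaces the recipient and logs the event", {
  w <- tiny_world()
  m <- substitution_model()
  fam <- evolve_alignment(w$tree, m, 400, seed = 2)
  f0 <- inject_hgt(fam, w$tree, "og_p1_s1", "kA_c1_s1", divergence = 0)
  expect_identical(f0$seqs[["kA_c1_s1"]], f0$seqs[["og_p1_s1"]])
  expect_length(f0$truth, 1L)
  f1 <- inject_hgt(fam, w$tree, "kB_c2_s1", "kA_c1_s1", divergence = 0.02,
                   seed = 9)
  d <- distance_matrix(f1$seqs, "p")
  nn <- names(which.min(d["kA_c1_s1", -match("kA_c1_s1", colnames(d))]))
  expect_identical(nn, "kB_c2_s1")
  expect_error(inject_hgt(fam, w$tree, "nope", "kA_c1_s1"), "not in family")
})

test_that("inject_paralogy adds a diverged copy resolving to the species", {
  w <- tiny_world()
  fam <- evolve_alignment(w$tree, substitution_model(), 400, seed = 4)
  n0 <- length(fam$seqs)
  f <- inject_paralogy(fam, "kA_c2_s1", divergence = 0)
  expect_length(f$seqs, n0 + 1L)
  expect_identical(f$seqs[["kA_c2_s1#2"]], f$seqs[["kA_c2_s1"]])
  f2 <- inject_paralogy(fam, "kA_c2_s1", divergence = 0.03, seed = 5)
  d <- distance_matrix(f2$seqs, "p")
  nn <- names(which.min(d["kA_c2_s1#2", -match("kA_c2_s1#2", colnames(d))]))
  expect_identical(nn, "kA_c2_s1")
  expect_error(inject_paralogy(fam, "unknown_sp"), "no sequence")
})

test_that("degrade: truncation arithmetic, loss, mask fraction", {
  w <- tiny_world()
  fam <- evolve_alignment(w$tree, substitution_model(), 100, seed = 6)
  tr <- degrade(fam, "kA_c1_s1", "truncate", fraction = 0.4)
  ch <- strsplit(tr$seqs[["kA_c1_s1"]], "")[[1]]
  expect_equal(sum(ch == "-"), 60L)
  expect_true(tr$is_partial[["kA_c1_s1"]])
  # kept block is contiguous
  resid <- range(which(ch != "-"))
  expect_equal(diff(resid) + 1L, 40L)
  lost <- degrade(fam, "og_p1_s1", "loss")
  expect_false("og_p1_s1" %in% names(lost$seqs))
  expect_error(degrade(fam, "absent_leaf", "loss"), "not in family")
  big <- evolve_alignment(parse_newick("(a:0.1,b:0.1);"),
                          substitution_model(), 10000, seed = 8)
  mk <- degrade(big, "a", "mask", fraction = 0.5, seed = 3)
  gapped <- mean(strsplit(mk$seqs[["a"]], "")[[1]] == "-")
  expect_lt(abs(gapped - 0.5), 0.015)
  expect_error(degrade(fam, "kA_c1_s1", "mask", fraction = 1.2), "fraction")
})

test_that("make_benchmark labels follow the event rates", {
  cfg <- world_config(n_classes_per_kingdom = 2L, n_species_per_class = 2L,
                      n_outgroup_phyla = 3L)
  clean <- make_benchmark(cfg, n_families = 10L, event_rates = c(0, 0, 0),
                          n_sites_range = c(60L, 80L), seed = 2)
  expect_true(all(clean$truth$clean))
  allhgt <- make_benchmark(cfg, n_families = 10L, event_rates = c(1, 0, 0),
                           n_sites_range = c(60L, 80L), seed = 2)
  expect_true(all(allhgt$truth$hgt))
  mixed <- make_benchmark(cfg, n_families = 400L,
                          event_rates = c(0.2, 0.1, 0.1),
                          n_sites_range = c(30L, 40L), seed = 3)
  for (ev in c("hgt", "paralog", "partial")) {
    rate <- c(hgt = 0.2, paralog = 0.1, partial = 0.1)[[ev]]
    obs <- mean(mixed$truth[[ev]])
    expect_lt(abs(obs - rate), 3 * sqrt(rate * (1 - rate) / 400))
  }
  # determinism: same config and seed give identical sequences
  again <- make_benchmark(cfg, n_families = 3L, event_rates = c(0.5, 0.5, 0.5),
                          n_sites_range = c(60L, 80L), seed = 9)
  again2 <- make_benchmark(cfg, n_families = 3L, event_rates = c(0.5, 0.5, 0.5),
                           n_sites_range = c(60L, 80L), seed = 9)
  expect_identical(lapply(again$families, `[[`, "seqs"),
                   lapply(again2$families, `[[`, "seqs"))
})
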