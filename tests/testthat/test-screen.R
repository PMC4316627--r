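test_that("bipartition sets enumerate internal edges", {
  q <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  bs <- bipartition_set(q)
  expect_length(bs, 1L)
  # canonicalized to the side not containing the reference leaf "A"
  expect_setequal(bs[[1]], c("C", "D"))
  star <- parse_newick("(A:1,B:1,C:1,D:1);")
  expect_length(bipartition_set(star), 0L)
  withr::with_seed(5, {
    for (i in 1:20) {
      tr <- ape::unroot(ape::rtree(sample(5:12, 1)))
      n_internal <- sum(tr$edge[, 2] > length(tr$tip.label))
      expect_length(bipartition_set(tr), n_internal)
    }
  })
})

test_that("monophyly matches brute-force enumeration on random trees", {
  tr <- parse_newick("((A1:1,A2:1):1,(B1:1,B2:1):1);")
  expect_true(is_monophyletic(tr, c("A1", "A2")))
  tr2 <- parse_newick("((A1:1,B1:1):1,(A2:1,B2:1):1);")
  expect_false(is_monophyletic(tr2, c("A1", "A2")))
  expect_error(is_monophyletic(tr, "nope"), "not in tree")
  withr::with_seed(8, {
    for (i in 1:200) {
      tr <- ape::rtree(sample(4:10, 1))
      if (i %% 2 == 0) tr <- ape::unroot(tr)
      k <- sample(seq_len(length(tr$tip.label)), 1)
      leaves <- sample(tr$tip.label, k)
      expect_identical(is_monophyletic(tr, leaves),
                       brute_monophyletic(tr, leaves),
                       info = paste(write_newick(tr),
                                    paste(leaves, collapse = ",")))
    }
  })
})

test_that("class monophyly report reflects planted HGT", {
  w <- tiny_world()
  m <- substitution_model()
  clean <- evolve_alignment(w$tree, m, 500, seed = 4)
  rep_clean <- class_monophyly_report(gene_tree(clean), w$taxonomy,
                                      scope = c("ingroup-A", "ingroup-B"))
  expect_true(all(rep_clean))
  hgt <- inject_hgt(clean, w$tree, "kB_c1_s1", "kA_c1_s1",
                    divergence = 0.02, seed = 2)
  rep_hgt <- class_monophyly_report(gene_tree(hgt), w$taxonomy,
                                    scope = c("ingroup-A", "ingroup-B"))
  expect_true(any(!rep_hgt[c("kA_c1", "kB_c1")]))
  # single-member class is vacuously monophyletic
  pruned <- ape::drop.tip(gene_tree(clean), "kA_c1_s2")
  rep_p <- class_monophyly_report(pruned, w$taxonomy,
                                  scope = c("ingroup-A", "ingroup-B"))
  expect_true(rep_p[["kA_c1"]])
})

test_that("inter-domain HGT detection flags the transferred leaf", {
  w <- tiny_world()
  m <- substitution_model()
  clean <- evolve_alignment(w$tree, m, 500, seed = 6)
  d0 <- detect_interdomain_hgt(gene_tree(clean), w$taxonomy)
  expect_true(d0$applicable)
  expect_false(d0$flag)
  moved <- inject_hgt(clean, w$tree, "og_p1_s1", "kA_c2_s1",
                      divergence = 0.05, seed = 3)
  d1 <- detect_interdomain_hgt(gene_tree(moved), w$taxonomy)
  expect_true(d1$flag)
  expect_true("kA_c2_s1" %in% d1$candidates)
  # quartet with correct split
  q <- parse_newick("((i1:1,i2:1):1,(o1:1,o2:1):1);")
  tq <- taxonomy_map(c("i1", "i2", "o1", "o2"), c("i1", "i2", "o1", "o2"),
                     c("c1", "c1", "p1", "p2"), c("ph", "ph", "p1", "p2"),
                     c("ingroup-A", "ingroup-A", "outgroup", "outgroup"))
  expect_false(detect_interdomain_hgt(q, tq)$flag)
})

test_that("within-outgroup HGT is detected on the outgroup-restricted tree", {
  w <- tiny_world()  # 2 species per outgroup phylum
  m <- substitution_model()
  clean <- evolve_alignment(w$tree, m, 500, seed = 7)
  expect_false(detect_outgroup_internal_hgt(gene_tree(clean), w$taxonomy)$flag)
  moved <- inject_hgt(clean, w$tree, "og_p1_s1", "og_p2_s1",
                      divergence = 0.02, seed = 4)
  d <- detect_outgroup_internal_hgt(gene_tree(moved), w$taxonomy)
  expect_true(d$flag)
  expect_setequal(d$violated_phyla, c("og_p1", "og_p2"))
  # singleton phyla are vacuously clean
  w1 <- sample_species_tree(world_config(2, 2, 3,
                                         species_per_outgroup_phylum = 1L))
  f1 <- evolve_alignment(w1$tree, m, 300, seed = 8)
  expect_false(detect_outgroup_internal_hgt(gene_tree(f1), w1$taxonomy)$flag)
})

test_that("paralogy flags require copy-number evidence", {
  w <- tiny_world()
  m <- substitution_model()
  clean <- evolve_alignment(w$tree, m, 400, seed = 9)
  expect_false(detect_paralogy(clean, gene_tree(clean), w$taxonomy)$flag)
  dup <- inject_paralogy(clean, "kA_c1_s1", divergence = 0.05, seed = 2)
  d <- detect_paralogy(dup, gene_tree(dup), w$taxonomy)
  expect_true(d$flag)
  expect_identical(d$offending_species, "kA_c1_s1")
  # single-copy family with a class split is charged to monophyly, not paralogy
  hgt <- inject_hgt(clean, w$tree, "kB_c1_s1", "kA_c1_s1",
                    divergence = 0.02, seed = 3)
  expect_false(detect_paralogy(hgt, gene_tree(hgt), w$taxonomy)$flag)
})

test_that("screen_family verdicts and reasons are consistent", {
  w <- tiny_world()
  m <- substitution_model()
  crit <- filter_criteria(min_outgroup_phyla = 3L)
  clean <- evolve_alignment(w$tree, m, 500, seed = 10)
  r0 <- screen_family(clean, gene_tree(clean), w$taxonomy, crit)
  expect_identical(r0$verdict, "retain")
  expect_length(r0$reasons, 0L)
  hgt <- inject_hgt(clean, w$tree, "kB_c2_s2", "kA_c1_s1",
                    divergence = 0.02, seed = 5)
  r1 <- screen_family(hgt, gene_tree(hgt), w$taxonomy, crit)
  expect_identical(r1$verdict, "reject")
  expect_true(any(grepl("class_monophyly|interdomain_hgt", r1$reasons)))
  # coverage-only failure yields a single coverage reason
  crit24 <- filter_criteria(min_outgroup_phyla = 4L)  # world has only 3
  r2 <- screen_family(clean, gene_tree(clean), w$taxonomy, crit24)
  expect_identical(r2$verdict, "reject")
  expect_identical(r2$reasons, "min_outgroup_phyla")
  expect_identical(select_markers(list(r0, r1, r2)), clean$id)
})

test_that("screening is invariant to leaf order and input rooting", {
  w <- tiny_world()
  m <- substitution_model()
  fam <- evolve_alignment(w$tree, m, 400, seed = 12)
  fam <- inject_hgt(fam, w$tree, "og_p3_s1", "kB_c1_s2",
                    divergence = 0.03, seed = 6)
  tr <- gene_tree(fam)
  crit <- filter_criteria(min_outgroup_phyla = 3L)
  base <- screen_family(fam, tr, w$taxonomy, crit)
  perm <- fam
  ord <- withr::with_seed(2, sample(names(fam$seqs)))
  perm$seqs <- fam$seqs[ord]
  perm$is_partial <- fam$is_partial[ord]
  r_perm <- screen_family(perm, gene_tree(perm), w$taxonomy, crit)
  expect_identical(r_perm$verdict, base$verdict)
  expect_identical(sort(r_perm$reasons), sort(base$reasons))
  rerooted <- ape::root(tr, outgroup = "og_p1_s1", resolve.root = TRUE)
  r_root <- screen_family(fam, rerooted, w$taxonomy, crit)
  expect_identical(r_root$verdict, base$verdict)
  expect_identical(sort(r_root$reasons), sort(base$reasons))
})

test_that("clean benchmark with generous thresholds retains everything", {
  cfg <- world_config(n_classes_per_kingdom = 2L, n_species_per_class = 2L,
                      n_outgroup_phyla = 4L)
  bench <- make_benchmark(cfg, n_families = 8L, event_rates = c(0, 0, 0),
                          n_sites_range = c(300L, 400L), seed = 5)
  res <- run_benchmark(bench = bench,
                       config = list(screen = list(min_outgroup_phyla = 4L)))
  expect_equal(res$retain_recall, 1)
  expect_equal(res$retain_precision, 1)
})
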