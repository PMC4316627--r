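test_that("local alignment: identity, floor, and symmetry", {
  a <- "MKLVINSGHW"
  al <- local_align(a, a)
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  B62 <- get("BLOSUM62", envir = e)
  ch <- strsplit(a, "")[[1]]
  expect_equal(al$score, sum(B62[cbind(ch, ch)]))
  expect_equal(al$a_span, c(1L, 10L))
  # no positively scoring pair -> score 0, empty span
  none <- local_align("W", "C")
  expect_equal(none$score, 0)
  expect_equal(none$a_span, c(0L, 0L))
  # symmetric matrix -> symmetric score
  b <- "MKLWINAGH"
  expect_equal(local_align(a, b)$score, local_align(b, a)$score)
  expect_error(local_align("", "MK"), "empty")
})

test_that("local alignment equals brute-force enumeration on short pairs", {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  B62 <- get("BLOSUM62", envir = e)
  withr::with_seed(17, {
    for (i in 1:25) {
      a <- paste(sample(phyloroot:::AA_STATES, sample(3:6, 1),
                        replace = TRUE), collapse = "")
      b <- paste(sample(phyloroot:::AA_STATES, sample(3:6, 1),
                        replace = TRUE), collapse = "")
      expect_equal(local_align(a, b, gap_open = -5, gap_extend = -2)$score,
                   brute_local_score(a, b, B62, -5, -2),
                   info = paste(a, b))
    }
  })
})

test_that("E-value model: monotone in score, linear in lengths, sane tail", {
  decoys <- withr::with_seed(3, rnorm(500, mean = 25, sd = 4))
  cal <- calibrate_evalue(decoys, 200, 250)
  s <- seq(20, 60, by = 5)
  evs <- vapply(s, estimate_evalue, numeric(1), len_a = 200, len_b = 250,
                calibration = cal)
  expect_true(all(diff(evs) < 0))
  expect_equal(estimate_evalue(30, 400, 250, cal) /
                 estimate_evalue(30, 200, 250, cal), 2)
  # fitted tail at the 90th percentile within a small factor of empirical 10%
  q90 <- stats::quantile(decoys, 0.9)
  p_fit <- estimate_evalue(q90, 200, 250, cal) / (cal$K * 200 * 250) *
    exp(cal$lambda * 0) # = exp(-lambda q90 + mu/beta) term folded in
  p_fit <- exp(-(q90 - cal$mu) / cal$beta)
  expect_gt(p_fit, 0.1 / 3)
  expect_lt(p_fit, 0.1 * 3)
  expect_error(calibrate_evalue(rep(5, 300), 10, 10), "degenerate")
  expect_error(calibrate_evalue(rnorm(50), 10, 10), "at least 200")
})

test_that("search and family building recover planted families", {
  m <- substitution_model()
  w <- tiny_world()
  f1 <- evolve_alignment(w$tree, m, 150, seed = 1, id = "f1")
  f2 <- evolve_alignment(w$tree, m, 150, seed = 999, id = "f2")
  db <- c(setNames(as.character(f1$seqs), paste0("f1_", names(f1$seqs))),
          setNames(as.character(f2$seqs), paste0("f2_", names(f2$seqs))))
  qs <- db[c(1, 12)]  # one member of each planted family
  hits <- search_homologs(qs, db, seed = 3)
  # self-hit exclusion
  expect_false(any(hits$query == hits$subject))
  # all hits stay within the planted family
  expect_true(all(substr(hits$query, 1, 2) == substr(hits$subject, 1, 2)))
  fams <- build_families(hits, names(qs), sequences = db)
  # every planted family is fully recovered from any of its members as seed
  expect_equal(unname(lengths(lapply(fams, `[[`, "seqs"))), c(14L, 14L))
  expect_true(all(startsWith(names(fams[[1]]$seqs), "f1_")))
  # database of only the query itself -> no hits, family of size 1
  solo <- search_homologs(qs[1], db[1], seed = 3)
  expect_equal(nrow(solo), 0L)
  expect_length(build_families(solo, names(qs)[1])[[1]]$seqs, 1L)
  expect_error(search_homologs(qs, character(0)), "empty database")
})

test_that("partial-length members are removed at the median-fraction rule", {
  fam <- phyloroot:::new_gene_family(
    "f", c(a = strrep("M", 100), b = strrep("K", 100),
           c = strrep("L", 100), d = strrep("V", 45)), aligned = FALSE)
  out <- flag_partials(fam, 0.5)
  expect_setequal(names(out$seqs), c("a", "b", "c"))
  expect_identical(attr(out, "removed_partials"), "d")
  same <- flag_partials(phyloroot:::new_gene_family(
    "g", c(a = strrep("M", 80), b = strrep("K", 80)), aligned = FALSE), 0.5)
  expect_length(same$seqs, 2L)
  expect_warning(flag_partials(phyloroot:::new_gene_family(
    "h", c(a = "MK"), aligned = FALSE)), "fewer than 2")
  # truncate(0.4)-degraded synthetic member is removed at default settings
  w <- tiny_world()
  f <- evolve_alignment(w$tree, substitution_model(), 200, seed = 2)
  f <- degrade(f, "kB_c1_s1", "truncate", fraction = 0.4)
  out2 <- flag_partials(f, 0.5)
  expect_false("kB_c1_s1" %in% names(out2$seqs))
  expect_equal(sort(attr(out2, "removed_partials")), "kB_c1_s1")
})

test_that("coverage filters behave exactly at their boundaries", {
  mk_tax <- function(n_in, n_out_phyla) {
    taxonomy_map(
      leaf = c(sprintf("i%d", seq_len(n_in)), sprintf("o%d", seq_len(n_out_phyla))),
      species = c(sprintf("i%d", seq_len(n_in)), sprintf("o%d", seq_len(n_out_phyla))),
      class_ = c(rep("cl1", n_in), sprintf("op%d", seq_len(n_out_phyla))),
      phylum = c(rep("ph1", n_in), sprintf("op%d", seq_len(n_out_phyla))),
      domain = c(rep("ingroup-A", n_in), rep("outgroup", n_out_phyla)))
  }
  mk_fam <- function(tax) {
    phyloroot:::new_gene_family("f", setNames(rep("MKLV", nrow(tax)),
                                              tax$leaf), aligned = FALSE)
  }
  tax <- mk_tax(3, 24)
  r <- apply_family_filters(mk_fam(tax), tax)
  expect_false(r$kept)
  expect_identical(r$reasons, "min_archaeal_members")
  tax2 <- mk_tax(4, 23)
  r2 <- apply_family_filters(mk_fam(tax2), tax2)
  expect_false(r2$kept)
  expect_identical(r2$reasons, "min_outgroup_phyla")
  tax3 <- mk_tax(4, 24)
  r3 <- apply_family_filters(mk_fam(tax3), tax3)
  expect_true(r3$kept)
  expect_length(r3$reasons, 0L)
  # filters are idempotent: same verdict when reapplied
  expect_identical(apply_family_filters(mk_fam(tax3), tax3), r3)
  # coverage not enforced when outgroup rule is off
  r4 <- apply_family_filters(mk_fam(tax2), tax2, require_outgroup = FALSE)
  expect_true(r4$kept)
})
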