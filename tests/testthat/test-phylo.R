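test_that("self-alignment is perfect and scoring is symmetric", {
  al <- align_global("MKV", "MKV")
  expect_equal(al$identity, 1)
  expect_false(grepl("-", al$aligned_a, fixed = TRUE))
  set.seed(2)
  for (i in 1:5) {
    a <- rand_peptide(sample(5:30, 1)); b <- rand_peptide(sample(5:30, 1))
    expect_equal(align_global(a, b)$score, align_global(b, a)$score)
  }
})

test_that("emitted alignments re-score to their reported score and restore inputs", {
  set.seed(4)
  for (i in 1:10) {
    a <- rand_peptide(sample(10:60, 1)); b <- rand_peptide(sample(10:60, 1))
    al <- align_global(a, b)
    expect_equal(score_alignment(al$aligned_a, al$aligned_b), al$score)
    expect_equal(gsub("-", "", al$aligned_a, fixed = TRUE), a)
    expect_equal(gsub("-", "", al$aligned_b, fixed = TRUE), b)
  }
})

test_that("the DP optimum matches brute-force enumeration on short sequences", {
  al <- align_global("MKV", "MV")
  expect_equal(sum(strsplit(al$aligned_a, "")[[1]] == "-") +
               sum(strsplit(al$aligned_b, "")[[1]] == "-"), 1)
  set.seed(6)
  for (i in 1:8) {
    a <- rand_peptide(sample(2:4, 1)); b <- rand_peptide(sample(2:4, 1))
    expect_equal(align_global(a, b)$score, brute_force_align_score(a, b))
  }
})

test_that("scores agree with an independent aligner implementation", {
  skip_if_not_installed("Biostrings")
  data(BLOSUM62, package = "Biostrings", envir = environment())
  set.seed(8)
  for (i in 1:6) {
    a <- rand_peptide(sample(10:50, 1)); b <- rand_peptide(sample(10:50, 1))
    ref <- Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = BLOSUM62, gapOpening = 11, gapExtension = 1,
      type = "global"))
    expect_equal(align_global(a, b)$score, ref)
  }
})

test_that("homology scores are self-normalised and monotone in panel size", {
  set.seed(10)
  q <- rand_peptide(80)
  panel3 <- reference_panel(
    protein_set(c("r1", "r2", "r3"), c(q, rand_peptide(80), rand_peptide(80))),
    c(r1 = "S-RNase", r2 = "Class-I", r3 = "Class-II"))
  expect_equal(homology_score(q, panel3), 1)
  panel1 <- reference_panel(
    protein_set(c("r2", "r3"), panel3$proteins$sequence[2:3]),
    c(r2 = "S-RNase", r3 = "Class-I"))
  expect_gte(homology_score(q, panel3), homology_score(q, panel1))
  # unrelated random sequences stay under the default gate
  for (i in 1:5)
    expect_lt(homology_score(rand_peptide(150), panel1), 0.25)
  expect_error(homology_score(q, panel1, class_filter = "SSK1"), "empty")
})

test_that("distances are symmetric with correct corrections", {
  ps <- protein_set(c("a", "b", "c"),
                    c("MKVLAGHE", "MKVLAGHE", "MKVLAGHD"))
  d <- distance_matrix(ps, correction = "p")
  expect_equal(unname(diag(d)), c(0, 0, 0))
  expect_equal(d, t(d))
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 1 / 8)
  dp <- distance_matrix(ps, correction = "poisson")
  expect_equal(dp["a", "c"], -log(1 - 1 / 8))
  # closed form: p = 0.5 gives ln 2 under the Poisson correction
  expect_equal(gsiScreen:::.correct_dist(0.5, "poisson"), log(2))
  expect_equal(gsiScreen:::.correct_dist(1 - exp(-10) + 1e-12, "poisson"), 10)
})

test_that("neighbor joining recovers a known additive 4-taxon tree exactly", {
  # distances generated by ((A:1,B:2):1,(C:3,D:1))
  d <- matrix(c(0, 3, 5, 3,
                3, 0, 6, 4,
                5, 6, 0, 4,
                3, 4, 4, 0), 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(d)
  expect_equal(cophenetic(tr)[LETTERS[1:4], LETTERS[1:4]], d)
  truth <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1));")
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(truth), tr)), 0)
})

test_that("neighbor joining matches the least-squares topology oracle", {
  set.seed(12)
  for (i in 1:10) {
    case <- random_additive_case(sample(4:6, 1))
    tr <- nj_tree(case$d)
    expect_equal(cophenetic(tr)[rownames(case$d), colnames(case$d)],
                 case$d, tolerance = 1e-8)
    oracle <- best_ls_topology(case$d)
    expect_equal(as.numeric(ape::dist.topo(tr, oracle)), 0)
  }
})

test_that("3-taxon trees use the closed-form star formulas", {
  d <- matrix(c(0, 3, 8, 3, 0, 9, 8, 9, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(bl, c(a = 1, b = 2, c = 7))
})

test_that("degenerate equal-distance input resolves deterministically", {
  d <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(d) <- 0
  t1 <- ape::write.tree(nj_tree(d))
  t2 <- ape::write.tree(nj_tree(d))
  expect_identical(t1, t2)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2,
                              dimnames = list(c("a", "b"), c("a", "b")))),
               "3 taxa")
  dbad <- matrix(c(0, 1, 2, 3, 0, 1, 2, 1, 0), 3,
                 dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(dbad), "symmetric")
})

test_that("clade assignment reads the sister group with majority support", {
  panel <- reference_panel(
    protein_set(paste0("r", 1:6), replicate(6, rand_peptide(30))),
    setNames(c("Class-I", "Class-I", "S-RNase", "S-RNase", "Class-II",
               "outgroup"), paste0("r", 1:6)))
  # query nested inside a pure Class-I subtree
  tr <- ape::read.tree(
    text = "(((q:1,r1:1):1,r2:1):2,((r3:1,r4:1):1,(r5:1,r6:3):1):2);")
  a <- assign_clade(tr, "q", panel)
  expect_equal(a$assigned_class, "Class-I")
  expect_equal(a$support_fraction, 1)

  # sister group of mixed composition: majority 2/3
  tr2 <- ape::read.tree(
    text = "((q:1,(r3:1,(r4:1,r1:1):1):1):1,((r2:1,r5:1):1,r6:3):1);")
  a2 <- assign_clade(tr2, "q", panel)
  expect_equal(a2$assigned_class, "S-RNase")
  expect_equal(a2$support_fraction, 2 / 3)
  expect_error(assign_clade(tr2, "nope", panel), "not a leaf")
})

test_that("ties stay unresolved and leaf order does not matter", {
  panel <- reference_panel(
    protein_set(paste0("r", 1:5), replicate(5, rand_peptide(30))),
    setNames(c("S-RNase", "Class-II", "S-RNase", "Class-II", "outgroup"),
             paste0("r", 1:5)))
  # 1:1 sister at both the parent and grandparent level
  tr <- ape::read.tree(
    text = "((q:1,(r1:1,r2:1):1):1,((r3:1,r4:1):1,r5:5):1);")
  a <- assign_clade(tr, "q", panel)
  expect_equal(a$assigned_class, "unresolved")

  set.seed(14)
  case <- random_additive_case(4)
  ids <- rownames(case$d)
  pan <- reference_panel(
    protein_set(ids[-1], replicate(3, rand_peptide(25))),
    setNames(c("S-RNase", "S-RNase", "Class-I"), ids[-1]))
  t0 <- nj_tree(case$d)
  perm <- sample(ids)
  t1 <- nj_tree(case$d[perm, perm])
  expect_equal(assign_clade(t0, ids[1], pan)$assigned_class,
               assign_clade(t1, ids[1], pan)$assigned_class)
})
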