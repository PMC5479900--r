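test_that("FPKM follows the closed-form definition", {
  em <- expression_matrix(matrix(100, 1, 1, dimnames = list("g", "t")),
                          "counts", lengths = c(g = 1000),
                          library_sizes = c(t = 1e6))
  expect_equal(unname(compute_fpkm(em)$values[1, 1]), 100)

  z <- expression_matrix(matrix(0, 2, 3, dimnames = list(c("a", "b"),
                                                         c("l", "p", "s"))),
                         "counts", lengths = c(a = 500, b = 900),
                         library_sizes = c(l = 1e6, p = 2e6, s = 3e6))
  expect_true(all(compute_fpkm(z)$values == 0))
  expect_error(compute_fpkm(compute_fpkm(em)), "counts")
})

test_that("FPKM is invariant to jointly scaling counts and library sizes", {
  set.seed(3)
  for (i in 1:5) {
    ng <- sample(3:10, 1); nt <- sample(2:4, 1)
    genes <- paste0("g", 1:ng); tissues <- paste0("t", 1:nt)
    counts <- matrix(rpois(ng * nt, 200), ng, nt,
                     dimnames = list(genes, tissues))
    L <- setNames(sample(300:3000, ng), genes)
    N <- setNames(runif(nt, 1e6, 1e7), tissues)
    f1 <- compute_fpkm(expression_matrix(counts, "counts", L, N))$values
    f2 <- compute_fpkm(expression_matrix(counts * 7, "counts", L,
                                         N * 7))$values
    expect_equal(f2, f1, tolerance = 1e-12)
  }
})

test_that("specificity calls identify restricted, broad and silent genes", {
  m <- rbind(style_only = c(0, 0, 50),
             broad = c(12, 30, 8),
             pollen_only = c(0, 40, 0),
             silent = c(0, 0, 0))
  colnames(m) <- c("leaf", "pollen", "style")
  calls <- call_specificity(expression_matrix(m, "FPKM"))
  expect_equal(calls$specific_to,
               c("style", NA, "pollen", NA))
  expect_equal(calls$broad, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(calls$leaf, c("absent", "expressed", "absent", "absent"))
})

test_that("ambiguous values block specificity claims conservatively", {
  m <- matrix(c(0.7, 0, 50), 1, dimnames = list("g", c("leaf", "pollen",
                                                       "style")))
  calls <- call_specificity(expression_matrix(m, "FPKM"))
  expect_equal(calls$leaf, "ambiguous")
  expect_true(is.na(calls$specific_to))
})

test_that("raising expressed_min only removes expressed statuses", {
  set.seed(13)
  m <- matrix(runif(60, 0, 5), 20, 3,
              dimnames = list(paste0("g", 1:20), c("leaf", "pollen", "style")))
  em <- expression_matrix(m, "FPKM")
  lo <- call_specificity(em, expressed_min = 1, absent_max = 0.5)
  hi <- call_specificity(em, expressed_min = 2, absent_max = 0.5)
  for (t in c("leaf", "pollen", "style")) {
    was <- lo[[t]] == "expressed"
    now <- hi[[t]] == "expressed"
    expect_true(all(which(now) %in% which(was)))
  }
  expect_error(call_specificity(em, expressed_min = 0.1, absent_max = 0.5),
               "expressed_min")
})

test_that("specificity is stable under joint count/library scaling", {
  set.seed(17)
  genes <- paste0("g", 1:8); tissues <- c("leaf", "pollen", "style")
  counts <- matrix(rpois(24, 50), 8, 3, dimnames = list(genes, tissues))
  L <- setNames(sample(500:2000, 8), genes)
  N <- setNames(runif(3, 1e6, 5e6), tissues)
  c1 <- call_specificity(compute_fpkm(expression_matrix(counts, "counts",
                                                        L, N)))
  c2 <- call_specificity(compute_fpkm(expression_matrix(counts * 3, "counts",
                                                        L, N * 3)))
  expect_identical(c1, c2)
})

test_that("replicates average (FPKM) or sum (counts) per tissue", {
  m <- matrix(c(1, 3, 2, 4), 1, 4,
              dimnames = list("g", c("leaf_r1", "leaf_r2", "pollen_r1",
                                     "pollen_r2")))
  avg <- average_replicates(expression_matrix(m, "FPKM"))
  expect_equal(unname(avg$values["g", ]), c(2, 3))
  expect_equal(colnames(avg$values), c("leaf", "pollen"))

  cm <- expression_matrix(m, "counts", lengths = c(g = 1000),
                          library_sizes = c(leaf_r1 = 1e6, leaf_r2 = 3e6,
                                            pollen_r1 = 2e6, pollen_r2 = 2e6))
  summed <- average_replicates(cm)
  expect_equal(unname(summed$values["g", ]), c(4, 6))
  expect_equal(unname(summed$library_sizes), c(4e6, 4e6))
})
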