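test_that("the generator is deterministic given a seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_dataset(small_generator_config(), d1)
  generate_dataset(small_generator_config(), d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  d3 <- withr::local_tempdir()
  generate_dataset(generator_config(n_genes = 40, seed = 8), d3)
  expect_false(identical(readLines(file.path(d1, "proteome.fasta")),
                         readLines(file.path(d3, "proteome.fasta"))))
})

test_that("planted features verify with the package's own extractors", {
  ds <- generate_dataset(small_generator_config())
  truth <- ds$truth
  seqs <- setNames(ds$proteome$sequence, ds$proteome$id)

  for (g in truth$gene_id[truth$class == "planted_srnase"]) {
    pI <- isoelectric_point(seqs[g])$pI
    expect_gte(pI, 8); expect_lte(pI, 10)
    expect_equal(classify_rnase_lineage(scan_patterns(seqs[g])),
                 "s_lineage_compatible")
    expect_lte(intron_count(ds$gene_models[[g]]), 2L)
  }
  for (g in truth$gene_id[truth$class == "s_like_rnase"]) {
    expect_equal(classify_rnase_lineage(scan_patterns(seqs[g])), "s_like")
    expect_lte(isoelectric_point(seqs[g])$pI, 7)
  }
  for (g in truth$gene_id[truth$class == "ssk1_like"]) {
    r <- analyze_skp1_cterm(seqs[g])
    expect_true(r$ssk1_consistent)
    expect_equal(r$type, "I")
  }
  for (g in truth$gene_id[truth$class == "skp1_type2"])
    expect_equal(classify_skp1_type(seqs[g]), "II")

  # truth-table intron counts match the emitted gene models
  got <- vapply(truth$gene_id, function(g) intron_count(ds$gene_models[[g]]),
                0L)
  expect_equal(unname(got), truth$intron_count)
})

test_that("every emitted file re-parses through the readers", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(small_generator_config(), dir)
  prot <- read_fasta(ds$paths[["proteome"]])
  expect_equal(prot$sequence, ds$proteome$sequence)
  pan <- read_panel(ds$paths[["panel"]], ds$paths[["panel_labels"]])
  expect_equal(pan$labels, ds$panel$labels)
  em <- read_expression(ds$paths[["counts"]], "counts",
                        ds$paths[["lengths"]], ds$paths[["library_sizes"]])
  expect_equal(em$values, ds$expression$values)
  expect_equal(em$library_sizes, ds$expression$library_sizes)
  gm <- read_gene_models(ds$paths[["gff"]])
  expect_setequal(names(gm), names(ds$gene_models))
})

test_that("an all-background dataset yields no candidates in either screen", {
  cfg <- generator_config(
    n_genes = 30,
    fractions = c(planted_srnase = 0, s_like_rnase = 0, ssk1_like = 0,
                  skp1_broad = 0, skp1_type2 = 0, background = 1),
    seed = 5)
  ds <- generate_dataset(cfg)
  fpkm <- compute_fpkm(ds$expression)
  sr <- screen_srnase(ds$proteome, ds$panel, ds$gene_models, fpkm)
  expect_true(all(sr$verdicts$final != "candidate"))
  sk <- screen_ssk1(ds$proteome, ds$panel, fpkm)
  expect_true(all(sk$verdicts$final != "candidate"))
})

test_that("recovery metrics follow confusion-matrix arithmetic", {
  truth <- data.frame(gene_id = c("a", "b", "c", "d"),
                      class = c("planted_srnase", "planted_srnase",
                                "background", "background"))
  mk <- function(final) data.frame(gene_id = truth$gene_id,
                                   role = "srnase_screen", final = final)
  perfect <- evaluate_recovery(mk(c("candidate", "candidate", "rejected",
                                    "rejected")), truth)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$precision, 1)

  none <- evaluate_recovery(mk(rep("rejected", 4)), truth)
  expect_equal(none$sensitivity, 0)
  expect_equal(none$specificity, 1)
  expect_true(is.na(none$precision))

  mixed <- evaluate_recovery(mk(c("candidate", "rejected", "candidate",
                                  "rejected")), truth)
  expect_equal(mixed$sensitivity, 0.5)
  expect_equal(mixed$specificity, 0.5)
  expect_equal(unname(mixed$confusion["positive", ]), c(1, 1))

  bad <- mk(rep("rejected", 4)); bad$gene_id[1] <- "zz"
  expect_error(evaluate_recovery(bad, truth), "zz")
})

test_that("generator configurations are validated", {
  expect_error(generator_config(fractions = c(planted_srnase = 1)),
               "setequal|fractions|sum")
  fr <- c(planted_srnase = 0.5, s_like_rnase = 0.2, ssk1_like = 0.1,
          skp1_broad = 0.1, skp1_type2 = 0.05, background = 0.1)
  expect_error(generator_config(fractions = fr), "sum")
})
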