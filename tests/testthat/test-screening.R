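ds_small <- generate_dataset(small_generator_config())
fpkm_small <- compute_fpkm(ds_small$expression)
split_panel <- function(panel, classes) {
  ids <- names(panel$labels)[panel$labels %in% classes]
  reference_panel(panel$proteins[panel$proteins$id %in% ids, ],
                  panel$labels[ids])
}
rnase_panel <- split_panel(ds_small$panel,
                           c("S-RNase", "Class-I", "Class-II", "outgroup"))
skp_panel <- split_panel(ds_small$panel, c("SSK1", "SKP1-other"))

test_that("screen configuration round-trips through YAML losslessly", {
  cfg <- screen_config(ip_threshold = 8, stringency = "permissive",
                       allow_E_terminal = TRUE)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_screen_config(cfg, f)
  expect_equal(read_screen_config(f), cfg)
  expect_error(screen_config(ip_threshold = 20), "ip_threshold")
})

test_that("the S-RNase screen applies all four criteria and the clade veto", {
  res <- screen_srnase(ds_small$proteome, rnase_panel,
                       ds_small$gene_models, fpkm_small)
  v <- res$verdicts
  truth <- ds_small$truth[match(v$gene_id, ds_small$truth$gene_id), ]

  # planted positives pass everything
  planted <- v[truth$class == "planted_srnase", ]
  expect_true(all(planted$final == "candidate"))
  expect_true(all(planted$pI > 7.5))
  expect_true(all(planted$clade == "S-RNase"))

  # S-like genes fail the pattern-4 criterion and land in Class-I
  slike <- v[truth$class == "s_like_rnase", ]
  expect_true(all(slike$pattern4_absent == "fail"))
  expect_true(all(slike$final == "rejected"))
  expect_true(all(slike$clade == "Class-I"))
  expect_true(all(grepl("pattern 4", slike$reasons)))

  # unrelated background fails the homology gate
  bg <- v[truth$class == "background", ]
  expect_true(all(bg$homology_ok == "fail"))

  # verdicts partition the gene set
  expect_true(all(v$final %in% c("candidate", "rejected", "inconclusive")))
  # every rejection carries at least one reason
  expect_true(all(nzchar(v$reasons[v$final == "rejected"])))
  # candidates never carry a failing criterion
  flag_cols <- c("homology_ok", "pattern4_absent", "ip_ok", "introns_ok",
                 "expression_ok")
  cand <- v[v$final == "candidate", flag_cols]
  expect_true(all(cand == "pass"))
})

test_that("broad expression rejects on the style-restriction criterion", {
  # style-expressed but leaf-expressed gene, everything else S-RNase-like
  planted_id <- ds_small$truth$gene_id[ds_small$truth$class ==
                                         "planted_srnase"][1]
  em <- fpkm_small
  em$values[planted_id, ] <- c(30, 25, 40)
  res <- screen_srnase(ds_small$proteome, rnase_panel, ds_small$gene_models,
                       em)
  row <- res$verdicts[res$verdicts$gene_id == planted_id, ]
  expect_equal(row$expression_ok, "fail")
  expect_equal(row$final, "rejected")
  expect_match(row$reasons, "criterion 4")
})

test_that("missing evidence degrades to unknown and inconclusive, not fail", {
  res <- screen_srnase(ds_small$proteome, rnase_panel,
                       gene_models = NULL, expr = NULL)
  v <- res$verdicts
  expect_true(all(v$introns_ok == "unknown"))
  expect_true(all(v$expression_ok == "unknown"))
  expect_true(all(v$final != "candidate"))
  truth <- ds_small$truth[match(v$gene_id, ds_small$truth$gene_id), ]
  expect_true(all(v$final[truth$class == "planted_srnase"] == "inconclusive"))
})

test_that("screen thresholds act monotonically on the candidate set", {
  cand_at <- function(thr)
    with(screen_srnase(ds_small$proteome, rnase_panel, ds_small$gene_models,
                       fpkm_small,
                       screen_config(ip_threshold = thr))$verdicts,
         gene_id[final == "candidate"])
  c_lo <- cand_at(7.0); c_mid <- cand_at(7.5); c_hi <- cand_at(8.0)
  expect_true(all(c_mid %in% c_lo))
  expect_true(all(c_hi %in% c_mid))
})

test_that("the SSK1 screen requires type I, the motif and pollen specificity", {
  res <- screen_ssk1(ds_small$proteome, skp_panel, fpkm_small)
  v <- res$verdicts
  truth <- ds_small$truth[match(v$gene_id, ds_small$truth$gene_id), ]

  expect_true(all(v$final[truth$class == "ssk1_like"] == "candidate"))
  # type-II chimerics are rejected regardless of their C-terminus
  t2 <- v[truth$class == "skp1_type2", ]
  expect_true(all(t2$type == "II" & t2$final == "rejected"))
  # broadly expressed SKP1 genes are rejected on expression
  broad <- v[truth$class == "skp1_broad", ]
  expect_true(all(broad$final == "rejected"))
  expect_true(all(grepl("pollen", broad$reasons)))
  cand <- v[v$final == "candidate", ]
  expect_true(all(cand$type == "I" & cand$motif_ok == "pass"))
  expect_true(all(nzchar(v$reasons[v$final == "rejected"])))
})

test_that("run_pipeline writes a complete, self-consistent report bundle", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(small_generator_config(), file.path(dir, "data"))
  out <- file.path(dir, "out")
  res <- run_pipeline(out, ds$paths[["proteome"]],
                      panel_fasta = ds$paths[["panel"]],
                      panel_labels = ds$paths[["panel_labels"]],
                      gff = ds$paths[["gff"]],
                      expression = ds$paths[["counts"]],
                      lengths = ds$paths[["lengths"]],
                      library_sizes = ds$paths[["library_sizes"]])
  expect_true(all(file.exists(file.path(out, c(
    "verdicts_srnase.tsv", "verdicts_ssk1.tsv", "features.tsv",
    "tree_srnase.nwk", "tree_ssk1.nwk", "run_config.yaml",
    "summary.json")))))
  # summary counts equal the generator's planted counts
  s <- jsonlite::read_json(file.path(out, "summary.json"))
  expect_equal(s$srnase_screen$candidate,
               sum(ds$truth$class == "planted_srnase"))
  expect_equal(s$ssk1_screen$candidate, sum(ds$truth$class == "ssk1_like"))
  # feature table covers every gene and re-read trees parse
  feats <- read.delim(file.path(out, "features.tsv"))
  expect_setequal(feats$id, ds$truth$gene_id)
  expect_s3_class(ape::read.tree(file.path(out, "tree_srnase.nwk")), "phylo")
})

test_that("screens refuse empty inputs", {
  empty <- protein_set(character(0), character(0))
  expect_error(screen_srnase(empty, rnase_panel), "empty record set")
  expect_error(screen_ssk1(empty, skp_panel), "empty record set")
})
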