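test_that("pyro panel reader validates, round-trips, and ignores row order", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "sample_id,amplicon_id,cpg_1,cpg_2,cpg_3,cpg_4,cpg_5,cpg_6",
    "s1,NBL2,70,72.5,68,71,69,73",
    "s2,NBL2,55,60,58,57,61,59",
    "s1,LINE1,75,74,76,73,,"), f)
  panel <- read_pyro_panel(f)
  expect_s3_class(panel, "pyro_panel")
  p1 <- get_profile(panel, "s1", "NBL2")
  expect_equal(p1$n_cpgs, 6L)
  expect_equal(p1$cpg_values, c(70, 72.5, 68, 71, 69, 73))
  expect_equal(get_profile(panel, "s1", "LINE1")$n_cpgs, 4L)

  # empty file with a valid header -> empty collection, no error
  fe <- withr::local_tempfile(fileext = ".csv")
  writeLines("sample_id,amplicon_id,cpg_1,cpg_2,cpg_3,cpg_4,cpg_5,cpg_6", fe)
  expect_equal(nrow(read_pyro_panel(fe)), 0L)

  # out-of-range value -> rejection naming the file line
  fo <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,amplicon_id,cpg_1,cpg_2,cpg_3,cpg_4",
               "s1,LINE1,75,74,76,73",
               "s2,LINE1,103,74,76,73"), fo)
  expect_error(read_pyro_panel(fo), "range error.*line 3")

  # malformed numeric -> parse error naming the column
  fm <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,amplicon_id,cpg_1,cpg_2,cpg_3,cpg_4",
               "s1,LINE1,seventy,74,76,73"), fm)
  expect_error(read_pyro_panel(fm), "parse error.*cpg_1")

  # value beyond the declared panel size -> schema error
  fs <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,amplicon_id,cpg_1,cpg_2,cpg_3,cpg_4,cpg_5",
               "s1,LINE1,75,74,76,73,50"), fs)
  expect_error(read_pyro_panel(fs), "schema error")
  expect_error(read_pyro_panel(f, panel_spec = c(LINE1 = 4L)), "schema error")

  # round-trip (tab dialect) and row-order independence
  out <- withr::local_tempfile(fileext = ".tsv")
  write_pyro_panel(panel, out, sep = "\t")
  expect_equal(read_pyro_panel(out), panel)
  shuf <- withr::local_tempfile(fileext = ".csv")
  lines <- readLines(f)
  writeLines(c(lines[1], lines[c(4, 2, 3)]), shuf)
  expect_equal(read_pyro_panel(shuf), panel)
})

test_that("beta matrix reader enforces invariants and round-trips", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("probe_id,gene_symbol,sA_beta,sA_pval,sB_beta,sB_pval",
               "cg01,TP53,0.10,0.001,0.90,0.002",
               "cg02,BRCA1,0.55,0.004,0.52,0.001",
               "cg03,,0.30,0.020,0.35,0.003"), f)
  bm <- read_beta_matrix(f)
  expect_equal(dim(bm), c(3L, 2L))
  expect_equal(bm$gene_symbols, c("TP53", "BRCA1", ""))
  expect_false(is.null(bm$detection_p))

  # beta out of range -> range error naming the cell
  fb <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("probe_id,gene_symbol,sA_beta", "cg01,TP53,1.2"), fb)
  expect_error(read_beta_matrix(fb), "range error.*cg01.*sA")

  # duplicated probe id -> schema error
  fd <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("probe_id,gene_symbol,sA_beta", "cg01,TP53,0.2",
               "cg01,TP53,0.3"), fd)
  expect_error(read_beta_matrix(fd), "schema error.*cg01")

  # missing detection-p columns allowed, recorded as absent; round-trips
  fn <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("probe_id,gene_symbol,sA_beta,sB_beta",
               "cg01,TP53,0.10,0.90", "cg02,BRCA1,0.55,0.52"), fn)
  bm2 <- read_beta_matrix(fn)
  expect_null(bm2$detection_p)
  out <- withr::local_tempfile(fileext = ".csv")
  write_beta_matrix(bm2, out)
  expect_equal(read_beta_matrix(out), bm2)
  out2 <- withr::local_tempfile(fileext = ".csv")
  write_beta_matrix(bm, out2)
  expect_equal(read_beta_matrix(out2), bm)
})

test_that("cohort reader normalizes vocabulary and verifies donor linkage", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "sample_id,subject_id,role,timepoint_months,pair_id,chimerism,agvhd_grade",
    "d1,subjD,donor,,p1,unknown,unknown",
    "r1pre,subjR,recipient,-1,p1,complete,III",
    "r1m1,subjR,recipient,1,p1,complete,III",
    "r1m6,subjR,recipient,6,p1,complete,III"), f)
  ct <- read_cohort(f)
  expect_s3_class(ct, "cohort_table")
  expect_equal(nrow(ct), 4L)
  # raw grade III collapses into the severe group
  expect_true(all(ct$agvhd_grade[ct$role == "recipient"] == "II-V"))

  # recipient referencing an absent donor -> linkage error
  fo <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "sample_id,subject_id,role,timepoint_months,pair_id,chimerism,agvhd_grade",
    "r1,subjR,recipient,-1,p9,complete,0"), fo)
  expect_error(read_cohort(fo), "linkage error.*p9")

  # unknown chimerism token -> vocabulary error listing allowed values
  fv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "sample_id,subject_id,role,timepoint_months,pair_id,chimerism,agvhd_grade",
    "d1,subjD,donor,,p1,unknown,unknown",
    "r1,subjR,recipient,-1,p1,partial,0"), fv)
  expect_error(read_cohort(fv), "vocabulary error.*complete")

  out <- withr::local_tempfile(fileext = ".csv")
  write_cohort(ct, out)
  expect_equal(read_cohort(out), ct)
})

test_that("GEO series-matrix adapter flattens into the beta-matrix schema", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "!Series_title\t\"synthetic methylation series\"",
    "!Sample_geo_accession\t\"GSM1\"\t\"GSM2\"",
    "!series_matrix_table_begin",
    "ID_REF\tGSM1\tGSM2",
    "cg000002\t0.81\t0.12",
    "cg000001\t0.20\t0.25",
    "!series_matrix_table_end"), f)
  bm <- read_geo_series_matrix(
    f, gene_map = data.frame(probe_id = "cg000001", gene_symbol = "IFNG"))
  expect_s3_class(bm, "beta_matrix")
  expect_equal(dim(bm), c(2L, 2L))
  expect_equal(bm$probe_ids, c("cg000001", "cg000002"))  # canonical order
  expect_equal(bm$gene_symbols, c("IFNG", ""))
  expect_null(bm$detection_p)
  expect_equal(unname(bm$beta["cg000002", "GSM1"]), 0.81)
  expect_error(read_geo_series_matrix(withr::local_tempfile(lines = "x")),
               "parse error")
})

test_that("unit conversion bridges percent and beta scales", {
  expect_equal(convert_meth_units(c(0, 55, 100), "beta"), c(0, 0.55, 1))
  expect_equal(convert_meth_units(c(0, 0.55, 1), "percent"), c(0, 55, 100))
})
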