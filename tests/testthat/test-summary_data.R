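test_that("reading the packaged exposure panel preserves printed values", {
  hcy <- panel_table("hcy")
  expect_s3_class(hcy, "snp_assoc")
  expect_equal(nrow(hcy), 5)
  expect_equal(hcy$rsid[2], "rs1801133")
  expect_equal(hcy$beta[hcy$rsid == "rs1801133"], 0.16)
  expect_equal(hcy$se[hcy$rsid == "rs1801133"], 0.01)
  expect_equal(hcy$eaf, c(0.20, 0.34, 0.79, 0.55, 0.47))
  expect_identical(attr(hcy, "scale"), "linear")
  expect_identical(attr(hcy, "trait"), "exposure")
})

test_that("read errors name the offending column, row or rsid", {
  path <- withr::local_tempfile(fileext = ".tsv")

  writeLines(c("rsid\tgene\teffect_allele\teaf\tse\tp",
               "rs1\tX\tA\t0.2\t0.01\t0.5"), path)
  expect_error(read_summary_table(path), "beta")

  writeLines(c("rsid\teffect_allele\tbeta\tse",
               "rs1\tA\tnot_a_number\t0.01"), path)
  expect_error(read_summary_table(path), "row 1")

  writeLines(c("rsid\teffect_allele\tbeta\tse",
               "rs1\tA\t0.1\t0.01",
               "rs1\tA\t0.2\t0.01"), path)
  expect_error(read_summary_table(path), "rs1")

  writeLines(c("rsid\teffect_allele\tbeta\tse",
               "rs9\tA\t0.1\t0"), path)
  expect_error(read_summary_table(path), "rs9")

  writeLines(c("rsid\teffect_allele\teaf\tbeta\tse",
               "rs3\tA\t1.2\t0.1\t0.01"), path)
  expect_error(read_summary_table(path), "rs3")

  writeLines(c("rsid\teffect_allele\tbeta\tse",
               "rs4\tZ\t0.1\t0.01"), path)
  expect_error(read_summary_table(path), "rs4")
})

test_that("a header-only table yields an empty association set", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("rsid\tgene\teffect_allele\teaf\tbeta\tse\tp", path)
  empty <- read_summary_table(path)
  expect_equal(nrow(empty), 0)
  expect_s3_class(empty, "snp_assoc")
})

test_that("odds-ratio input is converted to lnOR at load time", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rsid\teffect_allele\tbeta\tse",
               sprintf("rs1\tA\t%.10f\t0.01", exp(0.02))), path)
  tab <- read_summary_table(path, scale = "lnor", or_input = TRUE)
  expect_equal(tab$beta, 0.02)
  expect_error(read_summary_table(path, scale = "linear", or_input = TRUE),
               "lnOR")
  writeLines(c("rsid\teffect_allele\tbeta\tse", "rs1\tA\t-0.5\t0.01"), path)
  expect_error(read_summary_table(path, scale = "lnor", or_input = TRUE),
               "positive")
})

test_that("write/read round trip preserves numeric fields to full precision", {
  set.seed(42)
  tab <- mini_assoc(betas = rnorm(4) / 3, ses = runif(4, 0.001, 0.2),
                    eafs = runif(4, 0.05, 0.95), scale = "lnor",
                    trait = "t2d")
  tab$p <- runif(4)
  tab$gene[2] <- NA_character_
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_table(tab, path)
  back <- read_summary_table(path, scale = "lnor", trait = "t2d")
  for (col in c("beta", "se", "eaf", "p")) {
    expect_identical(back[[col]], tab[[col]], label = col)
  }
  expect_identical(back$rsid, tab$rsid)
})

test_that("harmonization aligns exposure and outcomes to the increasing allele", {
  hcy <- panel_table("hcy")
  t2d <- panel_table("t2d")

  # already aligned: everything passes through unchanged
  iset <- harmonize(hcy, list(t2d = t2d))
  expect_equal(iset$snps, hcy$rsid)
  expect_equal(numeric_cols(iset$exposure), numeric_cols(hcy))
  expect_equal(numeric_cols(iset$outcomes$t2d), numeric_cols(t2d))
  expect_equal(nrow(iset$flips), 0)

  # exposure record re-expressed for the other allele flips back
  recoded <- snp_assoc(flip_record(as.data.frame(hcy), "rs1801133"),
                       scale = "linear", trait = "exposure")
  expect_equal(recoded$beta[recoded$rsid == "rs1801133"], -0.16)
  iset2 <- harmonize(recoded, list(t2d = t2d))
  row <- iset2$exposure[iset2$exposure$rsid == "rs1801133", ]
  expect_equal(row$beta, 0.16)
  expect_equal(row$eaf, 0.34)
  expect_identical(row$effect_allele, "other")
  # the outcome record reported for the original allele A already sits on
  # the increasing allele the recoded exposure was flipped onto, so it must
  # stay untouched (this is what makes harmonization coding-invariant)
  orow <- iset2$outcomes$t2d[iset2$outcomes$t2d$rsid == "rs1801133", ]
  expect_equal(orow$beta, 0.02)
  expect_equal(orow$eaf, 0.34)
  expect_true(all(iset2$exposure$beta >= 0))

  # an outcome missing one rsid drops it with a warning
  t2d4 <- snp_assoc(as.data.frame(t2d)[t2d$rsid != "rs234709", ],
                    scale = "lnor", trait = "t2d")
  expect_warning(iset3 <- harmonize(hcy, list(t2d = t2d4)), "rs234709")
  expect_equal(length(iset3$snps), 4)
  expect_true("rs234709" %in% iset3$flips$rsid)

  # empty intersection is an error
  alien <- mini_assoc(c(0.1), c(0.01), trait = "t2d", scale = "lnor")
  expect_warning(expect_error(harmonize(hcy, list(t2d = alien)), "shared"))
})

test_that("a complementary-base outcome allele warns and flips", {
  hcy <- panel_table("hcy")
  t2d <- as.data.frame(panel_table("t2d"))
  i <- which(t2d$rsid == "rs1801133")  # exposure allele A -> complement T
  t2d$effect_allele[i] <- "T"
  t2d$beta[i] <- -t2d$beta[i]
  t2d$eaf[i] <- 1 - t2d$eaf[i]
  t2d <- snp_assoc(t2d, scale = "lnor", trait = "t2d")
  expect_warning(iset <- harmonize(hcy, list(t2d = t2d)), "complement")
  orow <- iset$outcomes$t2d[iset$outcomes$t2d$rsid == "rs1801133", ]
  expect_equal(orow$beta, 0.02)
  expect_equal(orow$eaf, 0.34)
})

test_that("harmonization is idempotent and invariant to input allele coding", {
  hcy <- panel_table("hcy")
  outs <- list(t2d = panel_table("t2d"), glucose = panel_table("glucose"))
  base <- harmonize(hcy, outs)

  # idempotence: re-harmonizing the harmonized set changes nothing
  again <- harmonize(base)
  expect_equal(numeric_cols(again$exposure), numeric_cols(base$exposure))
  for (nm in names(base$outcomes)) {
    expect_equal(numeric_cols(again$outcomes[[nm]]),
                 numeric_cols(base$outcomes[[nm]]))
  }

  # flipping any subset of input records leaves the harmonized set unchanged
  set.seed(7)
  for (rep in 1:10) {
    hcy_f <- as.data.frame(hcy)
    outs_f <- lapply(outs, as.data.frame)
    for (rs in hcy$rsid[runif(5) < 0.5]) {
      hcy_f <- flip_record(hcy_f, rs)
    }
    for (nm in names(outs_f)) {
      for (rs in hcy$rsid[runif(5) < 0.5]) {
        outs_f[[nm]] <- flip_record(outs_f[[nm]], rs)
      }
    }
    iset <- harmonize(
      snp_assoc(hcy_f, scale = "linear", trait = "exposure"),
      lapply(outs_f, snp_assoc, scale = "linear"))
    expect_equal(numeric_cols(iset$exposure)[, c("eaf", "beta", "se")],
                 numeric_cols(base$exposure)[, c("eaf", "beta", "se")])
    for (nm in names(base$outcomes)) {
      expect_equal(numeric_cols(iset$outcomes[[nm]])[, c("eaf", "beta", "se")],
                   numeric_cols(base$outcomes[[nm]])[, c("eaf", "beta", "se")])
    }
  }
})
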