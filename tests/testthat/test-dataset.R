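test_that("pEC50 transform reproduces tabulated potencies and inverts cleanly", {
  # printed 3-dp values from the embedded benchmark
  expect_equal(round(pec50_from_ec50(7.6), 3), 5.119)
  expect_equal(round(pec50_from_ec50(42.4), 3), 4.373)
  expect_equal(round(pec50_from_ec50(9.3), 3), 5.032)
  expect_equal(pec50_from_ec50(1e6), 0)          # 1 M

  # strict monotone bijection; inverse recovers input
  ec <- 10^runif(50, -3, 6)
  expect_true(all(diff(pec50_from_ec50(sort(ec))) < 0))
  expect_equal(ec50_from_pec50(pec50_from_ec50(ec)), ec, tolerance = 1e-9)

  expect_error(pec50_from_ec50(0), class = "ermqsar_domain_error")
  expect_error(pec50_from_ec50(-3), class = "ermqsar_domain_error")
  expect_error(pec50_from_ec50(Inf), class = "ermqsar_domain_error")
})

test_that("activity residual is experimental minus predicted", {
  expect_equal(activity_residual(4.290, 3.399), 0.891)
  expect_equal(activity_residual(4.373, 4.372), 0.001, tolerance = 1e-12)
  x <- rnorm(10)
  expect_equal(activity_residual(x, x), rep(0, 10))
  expect_error(activity_residual(1, NA), class = "ermqsar_domain_error")
})

test_that("descriptor CSV round-trips bit-exactly and rejects malformed cells", {
  m <- matrix(c(rnorm(5), pi, exp(1), 1/3, sqrt(2), 2/7, 1e-300, 1e300),
              nrow = 3, dimnames = list(c("a", "b", "c"), paste0("d", 1:4)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_descriptor_csv(m, path)
  back <- read_descriptor_csv(path)
  expect_identical(back, m)    # bit-exact round trip

  writeLines(c("compound_id,d1,d2", "a,1.0,", "b,2.0,3.0"), path)
  expect_error(read_descriptor_csv(path), "row 1, column 'd2'",
               class = "ermqsar_parse_error")
  writeLines(c("compound_id,d1", "a,1.0", "a,2.0"), path)
  expect_error(read_descriptor_csv(path), "duplicate",
               class = "ermqsar_parse_error")
  writeLines(c("compound_id,d1", "a,1.0", "b,oops"), path)
  expect_error(read_descriptor_csv(path), "non-numeric value 'oops' at row 2",
               class = "ermqsar_parse_error")
})

test_that("activity CSV derives pEC50, validates splits, flags inconsistency", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound_id,ec50_uM,pec50,split",
               "c1,9.3,,train",
               "c2,,4.5,test",
               "c3,34.5,4.991,train"), path)
  recs <- read_activity_csv(path)
  expect_equal(round(recs$pec50[1], 3), 5.032)   # derived from EC50
  expect_false(recs$inconsistent[1])
  expect_false(recs$inconsistent[2])
  expect_true(recs$inconsistent[3])              # 4.991 vs -log10(34.5e-6) = 4.462

  writeLines(c("compound_id,ec50_uM,split", "c1,9.3,validation"), path)
  expect_error(read_activity_csv(path), "split",
               class = "ermqsar_validation_error")
  writeLines(c("compound_id,ec50_uM,split", "c1,-2,train"), path)
  expect_error(read_activity_csv(path), class = "ermqsar_validation_error")
})

test_that("embedded benchmark fixture matches its printed table", {
  f <- table4_fixture()
  expect_equal(nrow(f), 35)
  expect_equal(sum(f$split == "test"), 8)
  expect_setequal(f$compound_id[f$split == "test"],
                  c("1", "15", "20", "23", "25", "26", "29", "31"))

  r10a <- f[f$compound_id == "10a", ]
  expect_equal(r10a$ec50_uM, 7.6)
  expect_equal(r10a$pec50, 5.119)
  expect_equal(r10a$predicted, 5.245)
  expect_equal(r10a$residual, -0.126)
  expect_equal(r10a$split, "train")

  # printed pEC50 agrees with EC50 within 0.01 log units except where flagged
  expect_setequal(f$compound_id[f$inconsistent], c("11c", "14"))
  ok <- !f$inconsistent
  expect_true(all(abs(f$pec50[ok] - pec50_from_ec50(f$ec50_uM[ok])) <= 0.01))

  # printed residual = printed pEC50 - prediction at 3 dp, except compound 23
  recomputed <- round(activity_residual(f$pec50, f$predicted), 3)
  mismatch <- f$compound_id[recomputed != round(f$residual, 3)]
  expect_identical(mismatch, "23")
  expect_equal(round(f$pec50[f$compound_id == "23"] -
                       f$predicted[f$compound_id == "23"], 3), 0.127)
})

test_that("potency/efficacy fixture is complete", {
  t1 <- table1_fixture()
  expect_equal(nrow(t1), 10)
  expect_equal(t1$ec50_uM[t1$compound_id == "10a"], 7.6)
  expect_equal(t1$emax_pct[t1$compound_id == "10a"], 93.1)
  expect_equal(sum(is.na(t1$ec50_uM)), 4)  # not determined for 11a,b,f,g
})

test_that("dataset construction enforces strict compound alignment", {
  X <- matrix(rnorm(12), 4, 3,
              dimnames = list(paste0("c", 1:4), paste0("d", 1:3)))
  acts <- data.frame(compound_id = paste0("c", 1:4), pec50 = rnorm(4),
                     split = c("train", "train", "train", "test"))
  ds <- qsar_dataset(X, acts)
  expect_s3_class(ds, "qsar_dataset")

  expect_error(qsar_dataset(X, acts[1:3, ]), "only in descriptors",
               class = "ermqsar_validation_error")
  acts_bad <- rbind(acts, data.frame(compound_id = "c9", pec50 = 1, split = "train"))
  expect_error(qsar_dataset(X, acts_bad), "only in activities",
               class = "ermqsar_validation_error")
  # activity order is harmonised to descriptor row order
  ds2 <- qsar_dataset(X, acts[4:1, ])
  expect_identical(ds2$activities$compound_id, rownames(X))
})
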