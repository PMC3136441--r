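test_that("the bundled catalog loads and validates", {
  rec <- load_catalog()
  expect_s3_class(rec, "patient_catalog")
  expect_identical(nrow(rec), 44L)
  expect_false(anyDuplicated(rec$patient_id) > 0)
  expect_true(all(rec$del_size_bp > 0, na.rm = TRUE))
  # unit normalization: Mb rows stored as bp
  expect_identical(rec$del_size_bp[rec$patient_id == "P1"], 0.9e6)
  expect_identical(rec$del_size_bp[rec$patient_id == "P42"], 17626)
  # approximate sizes flagged
  expect_true(rec$approximate[rec$patient_id == "P35"])
  expect_identical(sum(rec$approximate), 1L)
  # mosaic percentages carried through
  expect_identical(rec$mosaic_percent[rec$patient_id == "P36"], 75L)
  expect_identical(rec$mosaic_percent[rec$patient_id == "P29"], 30L)
})

test_that("malformed catalogs are rejected with row context", {
  td <- withr::local_tempdir()
  raw <- readLines(catalog_path())
  # truncated header
  writeLines(raw[2:10], file.path(td, "t1.tsv"))
  expect_error(load_catalog(file.path(td, "t1.tsv")), "missing column")
  # unparseable size
  bad <- raw
  bad[3] <- sub("5.38 Mb", "5.38 parsecs", bad[3], fixed = TRUE)
  writeLines(bad, file.path(td, "t2.tsv"))
  expect_error(load_catalog(file.path(td, "t2.tsv")), "row 2")
  # unknown class
  bad <- raw
  bad[2] <- sub("Terminal deletion", "Sideways deletion", bad[2], fixed = TRUE)
  writeLines(bad, file.path(td, "t3.tsv"))
  expect_error(load_catalog(file.path(td, "t3.tsv")), "row 1")
})

test_that("class counts are invariant under shuffling and sum to n", {
  rec <- load_catalog()
  cc <- class_counts(rec)
  expect_identical(unname(cc), c(30L, 5L, 6L, 3L))
  expect_identical(sum(cc), nrow(rec))
  withr::with_seed(1, {
    shuffled <- rec[sample(nrow(rec)), ]
  })
  expect_identical(class_counts(shuffled), cc)
  empty <- rec[0, ]
  expect_identical(sum(class_counts(empty)), 0L)
})

test_that("parental-origin tables reproduce the published cells", {
  rec <- load_catalog()
  tab <- parental_origin_summary(rec)
  del <- tab[tab$group == "del(22)", ]
  expect_identical(c(del$n_informative, del$n_paternal, del$n_maternal,
                     del$pct_paternal), c(25L, 19L, 6L, 76L))
  ring <- tab[tab$group == "ring 22", ]
  expect_identical(c(ring$n_informative, ring$n_paternal, ring$n_maternal,
                     ring$pct_paternal), c(5L, 3L, 2L, 60L))
  tot <- tab[tab$group == "total", ]
  expect_identical(c(tot$n_informative, tot$n_paternal, tot$pct_paternal),
                   c(30L, 22L, 73L))
  term <- parental_origin_table(rec, "terminal_deletion")
  expect_identical(c(term$n_paternal, term$n_informative), c(17L, 23L))
  int <- parental_origin_table(rec, "interstitial_deletion")
  expect_identical(c(int$n_paternal, int$n_informative), c(2L, 2L))
  # informative + unknown = class total
  expect_identical(term$n_informative +
                     sum(rec$rearrangement_class == "terminal_deletion" &
                           rec$parental_origin == "unknown"), 30L)
  expect_error(parental_origin_table(rec, "derivative"))
})

test_that("size summaries match the catalog extremes", {
  rec <- load_catalog()
  int <- size_summary(rec, "interstitial_deletion")
  expect_identical(c(int$min_bp, int$max_bp), c(17626, 73833))
  expect_identical(int$n, 5L)
  term <- size_summary(rec, "terminal_deletion")
  expect_identical(term$min_bp, 122388)
  expect_identical(term$n, 30L)
  expect_error(size_summary(rec, "inverted_duplication"), "unknown")
})

test_that("the cohort report aggregates everything and is stable", {
  rec <- load_catalog()
  rep1 <- cohort_report(rec)
  rep2 <- cohort_report(rec)
  expect_identical(rep1, rep2)
  expect_identical(rep1$n_records, 44L)
  expect_identical(rep1$class_counts$terminal_deletion, 30L)
  expect_identical(rep1$parental_origin$pct_paternal[3], 73L)
  expect_identical(rep1$size_ranges$interstitial_deletion$min_bp, 17626)
  txt <- format(rep1)
  expect_match(txt, "44 subjects")
  expect_match(txt, "73%")
  # recomputed vs as-published class percentages shown side by side
  rep3 <- cohort_report(rec, printed_class_percent = c(
    terminal_deletion = 72, ring22 = 14, derivative = 7,
    interstitial_deletion = 9))
  expect_match(format(rep3), "as-published")
  expect_identical(rep3$class_percent_recomputed$terminal_deletion, 68.2)
  json <- jsonlite::toJSON(unclass(rep1), auto_unbox = TRUE)
  expect_true(jsonlite::validate(json))
})
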