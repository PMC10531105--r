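test_that("corpus JSON-lines round-trip preserves every record field", {
  co <- generate_corpus(3, seed = 5)[1:10, ]
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(co, path)
  expect_length(readLines(path), 10L)
  back <- read_corpus(path)
  for (f in c("report_id", "patient_id", "conclusion_text", "label", "split",
              "provenance")) {
    expect_identical(back[[f]], co[[f]], info = f)
  }
  expect_identical(lapply(back$roles, as.character),
                   lapply(co$roles, as.character))
})

test_that("malformed corpus lines are reported with line numbers", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"report_id":"a","patient_id":"p1","conclusion_text":"Stable disease.","label":"SD"}',
    '{"report_id":"b","patient_id":"p1","conclusion_text":"No change."}'
  ), path)
  expect_error(read_corpus(path), "line 2.*label")

  writeLines(c(
    '{"report_id":"a","patient_id":"p1","conclusion_text":"Stable disease.","label":"SD"}',
    '{"report_id":"a","patient_id":"p2","conclusion_text":"New lesion.","label":"PD"}'
  ), path)
  expect_error(read_corpus(path), "duplicate report_id")
})

test_that("labels parse case-insensitively and from integer codes", {
  expect_identical(as_response_label(c("ned", "Pr", "SD", "3")),
                   c("NED", "PR", "SD", "PD"))
  expect_identical(label_code(c("NED", "PD")), c(0L, 3L))
  expect_error(as_response_label("complete response"), "unknown")
})

test_that("patient-level split follows largest-remainder apportionment", {
  co <- corpus(paste0("r", 1:20), rep(paste0("p", 1:10), 2),
               rep("Stable disease.", 20), rep("SD", 20))
  sp <- split_by_patient(co, c(0.8, 0.1, 0.1), seed = 3)
  per_pat <- tapply(sp$split, sp$patient_id, unique)
  expect_identical(as.integer(table(factor(per_pat, c("train", "dev", "test")))),
                   c(8L, 1L, 1L))
  # same seed twice: identical assignment
  sp2 <- split_by_patient(co, c(0.8, 0.1, 0.1), seed = 3)
  expect_identical(sp$split, sp2$split)
})

test_that("splits are patient-disjoint and exact at 1000 patients", {
  co <- corpus(paste0("r", 1:1000), paste0("p", 1:1000),
               rep("No new lesion.", 1000), rep("NED", 1000))
  sp <- split_by_patient(co, seed = 7)
  pats <- split(sp$patient_id, sp$split)
  expect_identical(lengths(pats)[c("train", "dev", "test")],
                   c(train = 800L, dev = 100L, test = 100L))
  expect_length(intersect(pats$train, pats$dev), 0L)
  expect_length(intersect(pats$train, pats$test), 0L)
  expect_length(intersect(pats$dev, pats$test), 0L)
  expect_error(split_by_patient(co[1:2, ], seed = 1), "at least 3 patients")
})

test_that("class distribution reproduces the reference population percentages", {
  counts <- c(NED = 4133L, PR = 1204L, SD = 1531L, PD = 3734L)
  lab <- rep(names(counts), counts)
  co <- corpus(paste0("r", seq_along(lab)), paste0("p", seq_along(lab)),
               rep("Stable disease.", length(lab)), lab)
  cd <- class_distribution(co)
  tot <- cd[cd$split == "total", ]
  expect_identical(sum(tot$count), 10602L)
  expect_equal(tot$percent[tot$label == "NED"], 39.0)
  expect_equal(tot$percent[tot$label == "PD"], 35.2)
  expect_lt(abs(sum(tot$percent) - 100), 0.2)
})

test_that("class distribution is uniform for one record per class", {
  co <- corpus(paste0("r", 1:4), paste0("p", 1:4),
               rep("Stable disease.", 4), c("NED", "PR", "SD", "PD"))
  cd <- class_distribution(co)
  expect_true(all(cd$percent[cd$split == "total"] == 25.0))
  expect_error(class_distribution(co[0, ]), "empty")
})

test_that("per-split percentages sum to 100 within rounding slack", {
  co <- shared_corpus()
  cd <- class_distribution(co)
  sums <- tapply(cd$percent, cd$split, sum)
  expect_true(all(abs(sums - 100) <= 0.2))
})

test_that("patients spanning two splits are rejected", {
  expect_error(
    corpus(c("r1", "r2"), c("p1", "p1"), c("Stable disease.", "New lesion."),
           c("SD", "PD"), split = c("train", "test")),
    "span multiple splits"
  )
})
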