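test_that("SampleTable construction enforces the basic contract", {
  st <- makeTinyTable()
  expect_s4_class(st, "SampleTable")
  expect_setequal(parameterIds(st), c("p1", "p2"))
  expect_error(SampleTable(matrix(1:4, 2, 2,
                                  dimnames = list(NULL, c("p1", "p2"))),
                           c("a", "b"), c("treated", "x")),
               "treated")
  expect_error(SampleTable(matrix(1:4, 2, 2), c("a", "b"),
                           c("treated", "control")),
               "column names")
  expect_error(SampleTable(matrix(1:4, 2, 2,
                                  dimnames = list(NULL, c("p", "p"))),
                           c("a", "b"), c("treated", "control")),
               "duplicate")
})

test_that("validateSampleTable reports each violated rule with the offender", {
  st <- makeTinyTable()
  expect_identical(nrow(validateSampleTable(st)), 0L)

  # subject s3 loses its control arm
  keep <- !(subjectIds(st) == "s3" & armLabels(st) == "control")
  broken <- SampleTable(t(SummarizedExperiment::assay(st))[keep, ],
                        subjectIds(st)[keep],
                        as.character(armLabels(st))[keep],
                        as.character(SummarizedExperiment::colData(st)$timepoint)[keep])
  v <- validateSampleTable(broken)
  expect_identical(v$rule, "incomplete_subject")
  expect_identical(v$offender, "s3")
  expect_identical(nrow(validateSampleTable(broken, crossover = FALSE)), 0L)

  # duplicated (subject, arm, timepoint) observation
  dup_idx <- c(seq_len(ncol(st)), 1L)
  dup <- SampleTable(t(SummarizedExperiment::assay(st))[dup_idx, ],
                     subjectIds(st)[dup_idx],
                     as.character(armLabels(st))[dup_idx],
                     as.character(SummarizedExperiment::colData(st)$timepoint)[dup_idx])
  expect_true("duplicate_observation" %in% validateSampleTable(dup)$rule)
})

test_that("buildFeatureMatrix computes baseline and mean-over-time features", {
  # one subject, treated values 2 (t0) and 4 (t1), control 1 and 3
  st <- SampleTable(matrix(c(2, 4, 1, 3), 4, 1, dimnames = list(NULL, "p")),
                    subject_id = rep("s1", 4),
                    arm = rep(c("treated", "control"), each = 2),
                    timepoint = rep(c("t0", "t1"), 2))
  fm <- buildFeatureMatrix(st, AxisDefinition("ax", "p", "both"))
  expect_equal(unname(fm@design["s1.treated", ]), c(2, 3))
  expect_equal(unname(fm@design["s1.control", ]), c(1, 2))

  # single timepoint: baseline and mean coincide
  st1 <- makeTinyTable(timepoints = "t0")
  fm1 <- buildFeatureMatrix(st1, AxisDefinition("ax", c("p1", "p2"), "both"))
  expect_equal(fm1@design[, "p1.baseline"], fm1@design[, "p1.mean_over_time"])
})

test_that("feature matrix rows are arm-major, treated first", {
  st <- makeTinyTable(n_subjects = 3)
  fm <- buildFeatureMatrix(st, AxisDefinition("ax", c("p1", "p2")))
  expect_equal(dim(fm@design), c(6L, 2L))
  expect_equal(fm@y, c(0, 0, 0, 1, 1, 1))
  expect_equal(fm@subjectIds, rep(c("s1", "s2", "s3"), 2))
})

test_that("buildFeatureMatrix is invariant to sample-row permutation", {
  st <- makeTinyTable(n_subjects = 5, seed = 3)
  ax <- AxisDefinition("ax", c("p1", "p2"), "both")
  ref <- buildFeatureMatrix(st, ax)
  for (s in 1:5) {
    set.seed(s)
    perm <- sample(ncol(st))
    shuffled <- SampleTable(t(SummarizedExperiment::assay(st))[perm, ],
                            subjectIds(st)[perm],
                            as.character(armLabels(st))[perm],
                            as.character(SummarizedExperiment::colData(st)$timepoint)[perm])
    expect_equal(buildFeatureMatrix(shuffled, ax)@design, ref@design)
  }
})

test_that("feature matrix dimensions follow the axis definition", {
  st <- makeTinyTable(n_subjects = 4)
  ax_both <- AxisDefinition("ax", c("p1", "p2"), "both")
  fm <- buildFeatureMatrix(st, ax_both)
  expect_equal(ncol(fm@design), nrow(ax_both@features))
  expect_equal(nrow(fm@design), 2L * 4L)
})

test_that("unknown parameters and missing data are handled as specified", {
  st <- makeTinyTable()
  expect_error(buildFeatureMatrix(st, AxisDefinition("ax", "CRP")), "CRP")

  # > 20% missing in p1 -> dropped with warning; sporadic NA imputed arm-wise
  v <- t(SummarizedExperiment::assay(st))
  v[1:6, "p1"] <- NA           # 6/16 = 37.5% missing
  v[2, "p2"] <- NA             # 1/16 tolerated
  stna <- SampleTable(v, subjectIds(st), as.character(armLabels(st)),
                      as.character(SummarizedExperiment::colData(st)$timepoint))
  expect_warning(fm <- buildFeatureMatrix(stna, AxisDefinition("ax", c("p1", "p2"))),
                 "p1")
  expect_equal(colnames(fm@design), "p2.mean_over_time")
  expect_false(anyNA(fm@design))
})

test_that("axis definitions validate and expand 'both'", {
  ax <- AxisDefinition("oxidation", c("a", "b"), kind = c("both", "baseline"))
  expect_equal(nrow(ax@features), 3L)
  expect_error(AxisDefinition("x", "a", kind = "bogus"), "bogus")
  expect_error(methods::new("AxisDefinition", name = "x",
                            features = data.frame(parameter = c("a", "a"),
                                                  kind = c("baseline", "baseline"))),
               "duplicated")
})

test_that("axis config round-trips through JSON and YAML with 'both' shorthand", {
  doc <- list(axes = list(
    list(name = "oxidation",
         features = list(list(parameter = "uric_acid", kind = "both"),
                         list(parameter = "vitE")))))
  for (ext in c("json", "yaml")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    if (ext == "json") jsonlite::write_json(doc, path, auto_unbox = TRUE)
    else yaml::write_yaml(doc, path)
    axes <- readAxisDefinitions(path)
    expect_named(axes, "oxidation")
    expect_equal(nrow(axes$oxidation@features), 3L)
    expect_equal(sort(unique(axes$oxidation@features$kind)),
                 c("baseline", "mean_over_time"))
  }
  # write -> read round trip
  out <- withr::local_tempfile(fileext = ".json")
  writeAxisDefinitions(list(AxisDefinition("m", c("a", "b"))), out)
  expect_equal(readAxisDefinitions(out)$m@features$parameter, c("a", "b"))
})

test_that("sample tables round-trip through wide CSV/TSV", {
  st <- makeTinyTable()
  for (ext in c(".csv", ".tsv")) {
    path <- withr::local_tempfile(fileext = ext)
    writeSampleTable(st, path)
    back <- readSampleTable(path)
    expect_equal(t(SummarizedExperiment::assay(back)),
                 t(SummarizedExperiment::assay(st)), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(subjectIds(back), subjectIds(st))
  }
})
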