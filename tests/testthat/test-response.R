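makeScoreSet <- function(mat_treated, mat_control, axes = NULL) {
  n <- nrow(mat_treated)
  if (is.null(axes)) axes <- paste0("ax", seq_len(ncol(mat_treated)))
  subj <- sprintf("s%02d", seq_len(n))
  sc <- rbind(mat_treated, mat_control)
  dimnames(sc) <- list(c(paste0(subj, ".treated"), paste0(subj, ".control")),
                       axes)
  healthspace:::.scoreSet(sc, rep(subj, 2),
                          rep(c("treated", "control"), each = n))
}

makeResponseSet <- function(vectors, ids = sprintf("s%02d", seq_len(nrow(vectors)))) {
  colnames(vectors) <- paste0("ax", seq_len(ncol(vectors)))
  rownames(vectors) <- ids
  methods::new("ResponseSet", responses = vectors, subjectId = ids,
               cluster = rep(NA_integer_, nrow(vectors)),
               outlier = rep(FALSE, nrow(vectors)), dendrogram = NULL)
}

test_that("response vectors are the per-axis control - treated differences", {
  tr <- rbind(c(0, 0, 0), c(0.3, 0.3, 0.3), c(0.2, -0.1, 0.0))
  ct <- rbind(c(1, 1, 1), c(0.3, 0.3, 0.3), c(1.0, 0.4, -0.2))
  rs <- responseVectors(makeScoreSet(tr, ct))
  rm <- responseMatrix(rs)
  expect_equal(unname(rm[1, ]), c(1, 1, 1))       # anchor-mean subject
  expect_equal(unname(rm[2, ]), c(0, 0, 0))       # non-responder
  expect_equal(unname(rm[3, ]), c(0.8, 0.5, -0.2))
  # configurable sign convention
  rs2 <- responseVectors(makeScoreSet(tr, ct), sign = "treated_minus_control")
  expect_equal(responseMatrix(rs2), -rm)
})

test_that("incomplete subjects are dropped with a warning", {
  ss <- makeScoreSet(rbind(c(0, 0), c(1, 1)), rbind(c(1, 1), c(2, 2)))
  keep <- rownames(scoreMatrix(ss)) != "s02.control"
  ss_inc <- healthspace:::.scoreSet(scoreMatrix(ss)[keep, ],
                                    subjectIds(ss)[keep],
                                    as.character(armLabels(ss))[keep])
  expect_warning(rs <- responseVectors(ss_inc), "s02")
  expect_equal(subjectIds(rs), "s01")
})

test_that("UPGMA clustering reproduces the worked 3-point example", {
  rs <- makeResponseSet(rbind(c(0, 0, 0), c(1, 0, 0), c(10, 0, 0)))
  rs <- clusterResponses(rs, k = 2)
  hc <- responseDendrogram(rs)
  # first merge {1,2} at height 1; then {1,2} with {3} at (9 + 10)/2 = 9.5
  expect_equal(hc$height, c(1, 9.5))
  lab <- clusterLabels(rs)
  expect_equal(lab[["s01"]], lab[["s02"]])
  expect_false(lab[["s01"]] == lab[["s03"]])
})

test_that("identical vectors collapse to one cluster at height zero", {
  rs <- makeResponseSet(matrix(1, 5, 3))
  rs <- clusterResponses(rs, k = 1)
  expect_equal(responseDendrogram(rs)$height, rep(0, 4))
  expect_equal(unname(clusterLabels(rs)), rep(1L, 5))
})

test_that("merge heights match the brute-force UPGMA oracle", {
  set.seed(31)
  for (n in c(5, 6, 8)) {
    X <- matrix(rnorm(n * 3), n)
    rs <- clusterResponses(makeResponseSet(X), k = 2)
    expect_equal(responseDendrogram(rs)$height, bruteUpgma(X)$heights,
                 tolerance = 1e-10)
  }
})

test_that("clustering is invariant to subject order and translation", {
  set.seed(37)
  X <- matrix(rnorm(24), 8, 3)
  ref <- clusterResponses(makeResponseSet(X), k = 3)
  ref_lab <- clusterLabels(ref)
  for (i in 1:10) {
    perm <- sample(8)
    ids <- sprintf("s%02d", seq_len(8))[perm]
    shuf <- clusterResponses(makeResponseSet(X[perm, , drop = FALSE], ids), k = 3)
    lab <- clusterLabels(shuf)[names(ref_lab)]
    # same partition up to label permutation
    expect_equal(outer(lab, lab, "=="), outer(ref_lab, ref_lab, "=="),
                 ignore_attr = TRUE)
  }
  shifted <- clusterResponses(makeResponseSet(sweep(X, 2, c(5, -2, 100), "+")),
                              k = 3)
  expect_equal(responseDendrogram(shifted)$height,
               responseDendrogram(ref)$height, tolerance = 1e-10)
  expect_equal(clusterLabels(shifted), ref_lab)
})

test_that("the dendrogram-singleton outlier rule flags the extreme subject", {
  set.seed(41)
  X <- rbind(matrix(rnorm(15, sd = 0.5), 5, 3), c(100, 100, 100))
  rs <- flagOutliers(makeResponseSet(X))
  expect_equal(unname(isOutlier(rs)), c(rep(FALSE, 5), TRUE))
  # homogeneous cloud: nothing flagged
  rs2 <- flagOutliers(makeResponseSet(matrix(rnorm(30), 10, 3)))
  expect_false(any(isOutlier(rs2)))
  # too few subjects: warning, no flags
  expect_warning(rs3 <- flagOutliers(makeResponseSet(matrix(rnorm(9), 3, 3))),
                 "at least 4")
  expect_false(any(isOutlier(rs3)))
})

test_that("outlier false-positive rate is low on homogeneous clouds", {
  hits <- vapply(1:25, function(s) {
    set.seed(100 + s)
    any(isOutlier(flagOutliers(makeResponseSet(matrix(rnorm(33 * 3), 33)))))
  }, logical(1))
  expect_lte(mean(hits), 0.05)
})

test_that("explicit exclusion removes a subject from labels but not exports", {
  set.seed(43)
  rs <- makeResponseSet(matrix(rnorm(18), 6, 3))
  expect_message(rs <- flagOutliers(rs, exclude = "s03"), "s03")
  rs <- clusterResponses(rs, k = 2)
  expect_true(isOutlier(rs)[["s03"]])
  expect_true(is.na(clusterLabels(rs)[["s03"]]))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeResponses(rs, path)
  tab <- read.delim(path)
  expect_true("s03" %in% tab$subject_id)
  expect_error(flagOutliers(rs, exclude = "nobody"), "nobody")
})

test_that("outliers are excluded before the cut; k bounds are enforced", {
  set.seed(47)
  X <- rbind(matrix(rnorm(12, mean = 0, sd = 0.3), 4, 3),
             matrix(rnorm(12, mean = 5, sd = 0.3), 4, 3),
             c(500, 500, 500))
  rs <- flagOutliers(makeResponseSet(X))
  expect_true(isOutlier(rs)[["s09"]])
  rs <- clusterResponses(rs, k = 2)
  lab <- clusterLabels(rs)
  expect_true(is.na(lab[["s09"]]))
  expect_equal(length(unique(na.omit(lab))), 2L)
  expect_equal(unname(lab[1:4]), rep(lab[["s01"]], 4))
  expect_error(clusterResponses(rs, k = 50), "exceeds")
})

test_that("the automatic cut picks the largest relative height gap", {
  set.seed(53)
  X <- rbind(matrix(rnorm(12, 0, 0.2), 4, 3), matrix(rnorm(12, 8, 0.2), 4, 3))
  rs <- clusterResponses(makeResponseSet(X), k = "auto")
  expect_equal(length(unique(na.omit(clusterLabels(rs)))), 2L)
})

test_that("dendrograms export as Newick and merge-list TSV", {
  set.seed(59)
  rs <- clusterResponses(makeResponseSet(matrix(rnorm(15), 5, 3)), k = 2)
  nwk <- withr::local_tempfile(fileext = ".nwk")
  writeDendrogram(rs, nwk, format = "newick")
  tree <- ape::read.tree(nwk)
  expect_setequal(tree$tip.label, subjectIds(rs))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeDendrogram(rs, tsv, format = "tsv")
  ml <- read.delim(tsv)
  expect_equal(nrow(ml), 4L)
  expect_equal(ml$height, responseDendrogram(rs)$height)
  expect_equal(ml$size[4], 5L)
})
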