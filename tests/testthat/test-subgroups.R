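makeBalanced22 <- function(cell_means, n_per_cell = 3, sd = 0, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(cluster = c("c1", "c2"), treatment = c("t", "c"))
  v <- unlist(lapply(seq_len(4), function(i)
    cell_means[i] + rnorm(n_per_cell, sd = sd)))
  list(values = v,
       cluster = rep(grid$cluster, each = n_per_cell),
       treatment = rep(grid$treatment, each = n_per_cell))
}

test_that("additive cell means give zero interaction", {
  # cell means 1, 2, 3, 4 with (1+4) = (2+3): purely additive; within-cell
  # deviations sum to zero so the cell means are exact
  dev <- c(-0.3, 0, 0.3)
  values <- c(1 + dev, 2 + dev, 3 + dev, 4 + dev)
  cluster <- rep(rep(c("c1", "c2"), each = 3), 2)
  treatment <- rep(c("t", "c"), each = 6)
  res <- twoWayAnova(values, cluster, treatment)
  expect_lt(res$interaction[["F"]], 1e-20)
  expect_equal(res$interaction[["p"]], 1, tolerance = 1e-10)
  expect_gt(res$treatment[["F"]], 1)  # the main effects are real
})

test_that("a pure interaction pattern drives F towards infinity", {
  d <- makeBalanced22(c(0, 0, 0, 1), sd = 1e-4, seed = 5)
  res <- twoWayAnova(d$values, d$cluster, d$treatment)
  expect_gt(res$interaction[["F"]], 1e6)
  expect_lt(res$interaction[["p"]], 1e-12)
})

test_that("Type II F and p match the nested-least-squares oracle", {
  set.seed(7)
  for (i in 1:5) {
    n <- 24
    cluster <- sample(c("a", "b"), n, replace = TRUE, prob = c(0.7, 0.3))
    treatment <- rep(c("t", "c"), n / 2)
    values <- rnorm(n) + (cluster == "a") * 0.5 +
      (treatment == "t") * (cluster == "b") * 0.8
    if (any(table(cluster, treatment) == 0)) next
    got <- twoWayAnova(values, cluster, treatment)
    want <- nestedOlsAnova(values, cluster, treatment)
    for (eff in c("interaction", "cluster", "treatment")) {
      expect_equal(got[[eff]][["F"]], want[[eff]][["F"]], tolerance = 1e-8)
      expect_equal(got[[eff]][["p"]], want[[eff]][["p"]], tolerance = 1e-8)
    }
  }
})

test_that("on balanced designs Type II equals the classical decomposition", {
  set.seed(9)
  for (i in 1:5) {
    d <- makeBalanced22(rnorm(4), n_per_cell = 4, sd = 1, seed = 10 + i)
    got <- twoWayAnova(d$values, d$cluster, d$treatment)
    cls <- summary(aov(d$values ~ factor(d$cluster) * factor(d$treatment)))[[1]]
    expect_equal(got$cluster[["F"]], cls$`F value`[1], tolerance = 1e-10)
    expect_equal(got$treatment[["F"]], cls$`F value`[2], tolerance = 1e-10)
    expect_equal(got$interaction[["F"]], cls$`F value`[3], tolerance = 1e-10)
  }
})

test_that("degenerate ANOVA inputs are rejected or flagged", {
  d <- makeBalanced22(c(1, 2, 3, 4), sd = 1)
  drop <- !(d$cluster == "c2" & d$treatment == "c")
  expect_error(twoWayAnova(d$values[drop], d$cluster[drop], d$treatment[drop]),
               "empty design cell")
  expect_warning(
    res <- twoWayAnova(c(1, 2, 3, 4)[as.integer(interaction(d$cluster, d$treatment))],
                       d$cluster, d$treatment),
    "zero residual")
  expect_true(is.nan(res$interaction[["p"]]))
  expect_error(twoWayAnova(d$values, rep("a", 12), d$treatment), "2 levels")
})

test_that("characterizeClusters applies the interaction-first verdict logic", {
  # planted pattern: p_int responds to treatment in cluster 1 only;
  # p_clu differs between clusters; p_none is noise
  set.seed(13)
  n <- 24
  subj <- sprintf("s%02d", seq_len(n))
  cl <- rep(1:2, each = n / 2)
  make_vals <- function(f) {
    vals <- matrix(NA_real_, 2 * n, 3,
                   dimnames = list(NULL, c("p_int", "p_clu", "p_none")))
    arm <- rep(c("treated", "control"), n)
    for (i in seq_len(n)) for (a in 1:2) {
      r <- (i - 1) * 2 + a
      treated <- arm[r] == "treated"
      vals[r, "p_int"] <- 3 * treated * (cl[i] == 1) + rnorm(1, sd = 0.3)
      vals[r, "p_clu"] <- 3 * (cl[i] == 1) + rnorm(1, sd = 0.3)
      vals[r, "p_none"] <- rnorm(1, sd = 0.3)
    }
    SampleTable(vals, rep(subj, each = 2), arm)
  }
  st <- make_vals()
  rs <- methods::new("ResponseSet",
                     responses = matrix(0, n, 1,
                                        dimnames = list(subj, "ax1")),
                     subjectId = subj, cluster = as.integer(cl),
                     outlier = rep(FALSE, n), dendrogram = NULL)
  rec <- characterizeClusters(st, rs, alpha = 0.05)
  verd <- setNames(rec$verdict, rec$parameter_id)
  expect_equal(verd[["p_int"]], "interaction")
  expect_equal(verd[["p_clu"]], "cluster_main")
  expect_equal(verd[["p_none"]], "none")
  expect_true(all(rec$q_interaction >= rec$p_interaction, na.rm = TRUE))
  # main-effect q values exist only where the interaction was not significant
  expect_true(is.na(rec$q_cluster[rec$parameter_id == "p_int"]))

  # verdicts are invariant to cluster relabeling
  rs2 <- rs; rs2@cluster <- 3L - rs2@cluster
  rec2 <- characterizeClusters(st, rs2, alpha = 0.05)
  expect_equal(rec2$verdict, rec$verdict)
})

test_that("constant parameters and single clusters are handled", {
  n <- 8
  subj <- sprintf("s%d", 1:n)
  vals <- matrix(rnorm(2 * n), 2 * n, 1, dimnames = list(NULL, "p1"))
  st <- SampleTable(cbind(vals, const = 5), rep(subj, each = 2),
                    rep(c("treated", "control"), n))
  rs <- methods::new("ResponseSet",
                     responses = matrix(0, n, 1, dimnames = list(subj, "a")),
                     subjectId = subj,
                     cluster = rep(c(1L, 2L), each = n / 2),
                     outlier = rep(FALSE, n), dendrogram = NULL)
  expect_warning(rec <- characterizeClusters(st, rs), "untestable")
  expect_equal(rec$verdict[rec$parameter_id == "const"], "none")
  rs1 <- rs; rs1@cluster <- rep(1L, n)
  expect_error(characterizeClusters(st, rs1), "at least 2 clusters")
})
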