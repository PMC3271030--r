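# In-code fixtures and independent oracles shared across the suite.

# A minimal cross-over table: values[s, arm, tp, param] laid out explicitly.
makeTinyTable <- function(n_subjects = 4, params = c("p1", "p2"),
                          timepoints = c("t0", "t1"), seed = 1) {
  set.seed(seed)
  subj <- sprintf("s%d", seq_len(n_subjects))
  grid <- expand.grid(timepoint = timepoints, arm = c("treated", "control"),
                      subject = subj, stringsAsFactors = FALSE)
  vals <- matrix(rnorm(nrow(grid) * length(params)), nrow(grid),
                 dimnames = list(NULL, params))
  SampleTable(vals, grid$subject, grid$arm, grid$timepoint)
}

# Brute-force UPGMA: O(n^3) agglomeration with explicit all-pairs average
# distances; merges returned as heights in merge order.
bruteUpgma <- function(X) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  sizes <- integer(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)) for (j in seq_len(i - 1L)) {
      d <- mean(D[clusters[[i]], clusters[[j]], drop = FALSE])
      if (d < bestd - 1e-12) { bestd <- d; best <- c(j, i) }
    }
    heights <- c(heights, bestd)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    sizes <- c(sizes, length(merged))
    clusters[[best[1]]] <- merged
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, sizes = sizes)
}

# Type II two-way ANOVA by nested least-squares model comparison:
# each effect's SS is the residual-SS drop between the relevant nested fits.
nestedOlsAnova <- function(values, cluster, treatment) {
  df <- data.frame(v = values, a = factor(cluster), b = factor(treatment))
  rss <- function(fml) sum(residuals(lm(fml, data = df))^2)
  full <- lm(v ~ a * b, data = df)
  rss_full <- sum(residuals(full)^2)
  df_res <- full$df.residual
  ms_res <- rss_full / df_res
  ss_a <- rss(v ~ b) - rss(v ~ a + b)
  ss_b <- rss(v ~ a) - rss(v ~ a + b)
  ss_ab <- rss(v ~ a + b) - rss_full
  df_a <- nlevels(df$a) - 1L
  df_b <- nlevels(df$b) - 1L
  df_ab <- df_a * df_b
  out <- function(ss, d) {
    F <- (ss / d) / ms_res
    c(F = F, p = pf(F, d, df_res, lower.tail = FALSE))
  }
  list(cluster = out(ss_a, df_a), treatment = out(ss_b, df_b),
       interaction = out(ss_ab, df_ab))
}

# small simulation used where a full-size study would be wasteful
smallConfig <- function(...) {
  simulationConfig(nSubjects = 16,
                   blocks = c(oxidation = 4, inflammation = 6, metabolism = 10),
                   ...)
}
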