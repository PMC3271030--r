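#' Two-way fixed-effects ANOVA (cluster x treatment)
#'
#' Fits `values ~ cluster * treatment` and returns F and p for the
#' interaction and both main effects.  Unbalanced designs (responder
#' clusters rarely have equal sizes) use Type II sums of squares via
#' [car::Anova()] — each main effect adjusted for the other, the
#' interaction adjusted for both — matching the interaction-first logic;
#' Type III is available as an option.  On balanced designs Type II reduces
#' to the classical balanced ANOVA decomposition.
#'
#' @param values numeric response, one per sample.
#' @param cluster,treatment factors (>= 2 levels each); every cluster x
#'   treatment cell must contain at least one sample.
#' @param type sums-of-squares type, 2 (default) or 3.
#' @return list with elements `interaction`, `cluster`, `treatment`, each
#'   `c(F = , p = )`, plus `residual_df`.  Zero residual variance yields
#'   `NaN` p values with a warning.
#' @export
twoWayAnova <- function(values, cluster, treatment, type = 2) {
  cluster <- droplevels(as.factor(cluster))
  treatment <- droplevels(as.factor(treatment))
  stopifnot(length(values) == length(cluster),
            length(values) == length(treatment))
  if (nlevels(cluster) < 2L || nlevels(treatment) < 2L)
    stop("both factors need at least 2 levels")
  cells <- table(cluster, treatment)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)[1L, ]
    stop("empty design cell: cluster '", rownames(cells)[empty[1]],
         "' x treatment '", colnames(cells)[empty[2]], "'")
  }
  df <- data.frame(values = as.numeric(values), cluster = cluster,
                   treatment = treatment)
  contr <- if (type == 3)
    list(cluster = "contr.sum", treatment = "contr.sum") else NULL
  fit <- stats::lm(values ~ cluster * treatment, data = df, contrasts = contr)
  if (fit$df.residual < 1L)
    stop("no residual degrees of freedom (need within-cell replicates)")
  rss <- sum(stats::residuals(fit)^2)
  if (rss < .Machine$double.eps * sum(df$values^2 + 1)) {
    warning("zero residual variance; F undefined (p = NaN)")
    nanrow <- c(F = NaN, p = NaN)
    return(list(interaction = nanrow, cluster = nanrow, treatment = nanrow,
                residual_df = fit$df.residual))
  }
  a <- car::Anova(fit, type = type)
  pick <- function(term) c(F = a[term, "F value"], p = a[term, "Pr(>F)"])
  list(interaction = pick("cluster:treatment"),
       cluster = pick("cluster"),
       treatment = pick("treatment"),
       residual_df = fit$df.residual)
}

#' Characterize responder clusters parameter-by-parameter
#'
#' For every parameter, runs [twoWayAnova()] on the per-subject-arm mean
#' values (one value per subject per arm, so timepoints are never
#' pseudo-replicated) with factors cluster and treatment arm, then applies
#' interaction-first screening with BH FDR control: interaction p values
#' form one family across parameters; for parameters whose interaction is
#' *not* significant, each main effect is adjusted within its own family.
#' The verdict is `interaction` when the interaction q value is `<= alpha`;
#' otherwise the more significant main effect (if any) gives `cluster_main`
#' or `treatment_main`; else `none`.  This is the screen that surfaces
#' patterns like a metabolite responding to treatment in one responder
#' group but not the other (a significant cluster x treatment interaction).
#'
#' @param table the [SampleTable-class] of raw parameter values.
#' @param responses a clustered [ResponseSet-class]; outliers and
#'   unclustered subjects are excluded.
#' @param alpha FDR level (default 0.05).
#' @param type sums-of-squares type (default 2).
#' @return a `data.frame`, one row per parameter, with F/p/q per effect and
#'   a `verdict` column; analysis settings are attached as attributes.
#'   Untestable (e.g. constant) parameters get verdict `none` with a
#'   warning.  Cluster label permutations leave all verdicts unchanged.
#' @export
characterizeClusters <- function(table, responses, alpha = 0.05, type = 2) {
  stopifnot(methods::is(table, "SampleTable"),
            methods::is(responses, "ResponseSet"))
  lab <- responses@cluster
  names(lab) <- responses@subjectId
  lab <- lab[!is.na(lab)]
  if (length(unique(lab)) < 2L)
    stop("need at least 2 clusters to characterize (got ",
         length(unique(lab)), ")")
  am <- .subjectArmMeans(table)
  subjects <- intersect(am$subjects, names(lab))
  if (length(subjects) < 4L)
    stop("too few clustered subjects with data (", length(subjects), ")")
  cl <- factor(lab[subjects])
  treatment <- factor(rep(c("treated", "control"), each = length(subjects)),
                      levels = c("treated", "control"))
  cluster_f <- factor(rep(cl, 2L))
  params <- rownames(table)

  res <- lapply(params, function(pm) {
    v <- c(am$treated[subjects, pm], am$control[subjects, pm])
    if (anyNA(v) || stats::sd(v) == 0) {
      warning("parameter '", pm, "' untestable (constant or missing); ",
              "verdict 'none'")
      return(data.frame(parameter_id = pm,
                        F_interaction = NA_real_, p_interaction = NA_real_,
                        F_cluster = NA_real_, p_cluster = NA_real_,
                        F_treatment = NA_real_, p_treatment = NA_real_))
    }
    aov2 <- twoWayAnova(v, cluster_f, treatment, type = type)
    data.frame(parameter_id = pm,
               F_interaction = unname(aov2$interaction["F"]),
               p_interaction = unname(aov2$interaction["p"]),
               F_cluster = unname(aov2$cluster["F"]),
               p_cluster = unname(aov2$cluster["p"]),
               F_treatment = unname(aov2$treatment["F"]),
               p_treatment = unname(aov2$treatment["p"]))
  })
  res <- do.call(rbind, res)

  res$q_interaction <- NA_real_
  ok <- !is.na(res$p_interaction)
  res$q_interaction[ok] <- bhAdjust(res$p_interaction[ok])
  int_sig <- !is.na(res$q_interaction) & res$q_interaction <= alpha

  res$q_cluster <- res$q_treatment <- NA_real_
  main_fam <- ok & !int_sig
  res$q_cluster[main_fam] <- bhAdjust(res$p_cluster[main_fam])
  res$q_treatment[main_fam] <- bhAdjust(res$p_treatment[main_fam])

  verdict <- rep("none", nrow(res))
  verdict[int_sig] <- "interaction"
  cl_sig <- main_fam & !is.na(res$q_cluster) & res$q_cluster <= alpha
  tr_sig <- main_fam & !is.na(res$q_treatment) & res$q_treatment <= alpha
  both <- cl_sig & tr_sig
  verdict[cl_sig & !both] <- "cluster_main"
  verdict[tr_sig & !both] <- "treatment_main"
  verdict[both] <- ifelse(res$q_cluster[both] <= res$q_treatment[both],
                          "cluster_main", "treatment_main")
  res$verdict <- verdict
  attr(res, "alpha") <- alpha
  attr(res, "ss_type") <- type
  attr(res, "fdr_families") <-
    "interaction: one family across parameters; each main effect: own family over parameters with non-significant interaction"
  res
}

#' Export ANOVA records as TSV
#'
#' @param records result of [characterizeClusters()].
#' @param path output path.
#' @export
writeAnovaRecords <- function(records, path) {
  utils::write.table(records, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Top discriminating parameters of the cluster characterization
#'
#' Orders the ANOVA records by their smallest q value across the three
#' effect families and returns the head — the parameters primarily
#' responsible for the subgroup separation.
#'
#' @param records result of [characterizeClusters()].
#' @param n number of parameters to return (default 10).
#' @return the `n` top rows with an added `min_q` column.
#' @export
topDiscriminators <- function(records, n = 10L) {
  q <- pmin(records$q_interaction, records$q_cluster, records$q_treatment,
            na.rm = TRUE)
  q[!is.finite(q)] <- Inf
  out <- records[order(q), , drop = FALSE]
  out$min_q <- sort(q)
  utils::head(out, n)
}
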