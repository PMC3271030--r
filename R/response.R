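#' Per-subject treatment-response vectors
#'
#' The individual response is the per-axis difference between a subject's
#' two arms in the health space.  With the default sign convention
#' (`control - treated`) a positive value means the treatment moved the
#' subject toward the healthy origin (the treated-group mean at 0).  No
#' rescaling is applied to the vectors — they are clustered as-is.
#'
#' @param scores a [ScoreSet-class]; subjects lacking one arm are dropped
#'   with a warning.
#' @param sign `"control_minus_treated"` (default) or
#'   `"treated_minus_control"`.
#' @return a [ResponseSet-class] (clusters unassigned, no outliers flagged),
#'   subjects in sorted order.
#' @export
responseVectors <- function(scores,
                            sign = c("control_minus_treated",
                                     "treated_minus_control")) {
  sign <- match.arg(sign)
  stopifnot(methods::is(scores, "ScoreSet"))
  subj <- scores@subjectId
  arm <- as.character(scores@arm)
  subjects <- sort(unique(subj))
  complete <- vapply(subjects, function(s)
    all(c("treated", "control") %in% arm[subj == s]), TRUE)
  if (any(!complete))
    warning("dropping subject(s) without both arms: ",
            paste(subjects[!complete], collapse = ", "))
  subjects <- subjects[complete]
  if (!length(subjects))
    stop("no complete subjects: response vectors need both arms per subject")
  resp <- t(vapply(subjects, function(s) {
    ct <- colMeans(scores@scores[subj == s & arm == "control", , drop = FALSE])
    tr <- colMeans(scores@scores[subj == s & arm == "treated", , drop = FALSE])
    if (sign == "control_minus_treated") ct - tr else tr - ct
  }, numeric(ncol(scores@scores))))
  dimnames(resp) <- list(subjects, colnames(scores@scores))
  methods::new("ResponseSet", responses = resp, subjectId = subjects,
               cluster = rep(NA_integer_, length(subjects)),
               outlier = rep(FALSE, length(subjects)), dendrogram = NULL)
}

# average-linkage tree of the non-outlier rows, leaves named by subject
.responseTree <- function(responses, method = "average") {
  keep <- !responses@outlier
  stats::hclust(stats::dist(responses@responses[keep, , drop = FALSE],
                            method = "euclidean"), method = method)
}

#' Flag outlier subjects from the response dendrogram
#'
#' Automated stand-in for a manual exclusion: a subject is flagged when it
#' sits alone on one side of the dendrogram's top split *and* its merge
#' height exceeds `heightFactor` times the median pairwise distance.  The
#' rule is applied repeatedly (re-clustering after each removal) until no
#' subject qualifies.  Flagged subjects are excluded from cluster labels by
#' [clusterResponses()] but kept in all exports.  An explicit `exclude` list
#' overrides or supplements the rule; both paths are reported via messages.
#'
#' @param responses a [ResponseSet-class] with at least 4 subjects (fewer:
#'   warning, nothing flagged).
#' @param heightFactor multiplier of the median pairwise distance (default 3).
#' @param exclude character vector of subject ids to flag unconditionally.
#' @return the [ResponseSet-class] with updated outlier flags.
#' @export
flagOutliers <- function(responses, heightFactor = 3, exclude = NULL) {
  stopifnot(methods::is(responses, "ResponseSet"))
  out <- responses
  if (length(exclude)) {
    unknown <- setdiff(exclude, out@subjectId)
    if (length(unknown))
      stop("exclude names unknown subject(s): ", paste(unknown, collapse = ", "))
    out@outlier[out@subjectId %in% exclude] <- TRUE
    message("excluded by request: ", paste(exclude, collapse = ", "))
  }
  repeat {
    n_active <- sum(!out@outlier)
    if (n_active < 4L) {
      if (nrow(out@responses) < 4L)
        warning("outlier rule needs at least 4 subjects; nothing flagged")
      break
    }
    hc <- .responseTree(out)
    d <- stats::dist(out@responses[!out@outlier, , drop = FALSE])
    med <- stats::median(d)
    top <- hc$merge[nrow(hc$merge), ]
    top_height <- hc$height[length(hc$height)]
    singleton <- top[top < 0]
    if (length(singleton) != 1L || med == 0 ||
        top_height <= heightFactor * med)
      break
    id <- hc$labels[-singleton]
    out@outlier[out@subjectId == id] <- TRUE
    message("flagged dendrogram-singleton outlier: ", id,
            " (merge height ", format(top_height, digits = 3),
            " > ", heightFactor, " x median distance ",
            format(med, digits = 3), ")")
  }
  methods::validObject(out)
  out
}

#' Cluster response vectors into responder subgroups
#'
#' Agglomerative clustering of the raw response vectors — Euclidean
#' distance, average (UPGMA) linkage, no additional scaling — exactly the
#' stock procedure, via [stats::hclust()].  Labels come from cutting the
#' tree at `k` clusters after outlier removal; outliers keep `NA` labels.
#' `k = "auto"` picks the cut with the largest relative merge-height gap
#' (never overriding an explicitly given `k`).
#'
#' @param responses a [ResponseSet-class] (flag outliers first with
#'   [flagOutliers()] if desired); needs >= 3 non-outlier subjects.
#' @param k integer number of clusters (default 2, the two main responder
#'   groups), or `"auto"`.
#' @param method linkage passed to [stats::hclust()] (default `"average"`;
#'   alternatives are passed through untested against the reference
#'   procedure).
#' @return the [ResponseSet-class] with cluster labels and the `hclust`
#'   tree stored (see [responseDendrogram()]).
#' @export
clusterResponses <- function(responses, k = 2L, method = "average") {
  stopifnot(methods::is(responses, "ResponseSet"))
  keep <- !responses@outlier
  n <- sum(keep)
  if (n < 3L) stop("clustering needs at least 3 non-outlier subjects")
  hc <- .responseTree(responses, method = method)
  if (identical(k, "auto")) {
    k <- .autoK(hc$height)
  } else {
    k <- as.integer(k)
    if (k > n) stop("k = ", k, " exceeds the ", n, " non-outlier subjects")
  }
  labels <- if (k == 1L) rep(1L, n) else stats::cutree(hc, k = k)
  out <- responses
  out@cluster <- rep(NA_integer_, length(out@subjectId))
  out@cluster[match(hc$labels, out@subjectId)] <- as.integer(labels)
  out@dendrogram <- hc
  out
}

# Largest relative gap between successive merge heights; cutting between
# merge i and i+1 yields n - i clusters.
.autoK <- function(heights) {
  n <- length(heights) + 1L
  if (n <= 2L) return(n)
  pos <- which(heights[-length(heights)] > 0)
  if (!length(pos)) return(1L)
  ratio <- heights[pos + 1L] / heights[pos]
  i <- pos[which.max(ratio)]
  as.integer(n - i)
}

#' Retrieve the response dendrogram
#'
#' @param responses a [ResponseSet-class] after [clusterResponses()].
#' @return the `hclust` object of the non-outlier subjects.
#' @export
responseDendrogram <- function(responses) {
  if (is.null(responses@dendrogram))
    stop("no dendrogram stored; run clusterResponses() first")
  responses@dendrogram
}

#' Export a ResponseSet as TSV
#'
#' Columns: `subject_id`, one per axis, `cluster`, `outlier`.  Outliers are
#' retained (with `NA` cluster).
#'
#' @param responses a [ResponseSet-class].
#' @param path output path.
#' @export
writeResponses <- function(responses, path) {
  df <- data.frame(subject_id = responses@subjectId, responses@responses,
                   cluster = responses@cluster, outlier = responses@outlier,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export the response dendrogram
#'
#' `format = "tsv"` writes the merge list (`node_a`, `node_b`, `height`,
#' `size`; negative entries are leaves, positive ones earlier merges, as in
#' [stats::hclust()]).  `format = "newick"` writes a Newick tree (leaf
#' names = subject ids, branch lengths from the UPGMA heights) via
#' [ape::write.tree()].
#'
#' @param responses a clustered [ResponseSet-class].
#' @param path output path.
#' @param format `"newick"` or `"tsv"`.
#' @export
writeDendrogram <- function(responses, path, format = c("newick", "tsv")) {
  format <- match.arg(format)
  hc <- responseDendrogram(responses)
  if (format == "newick") {
    ape::write.tree(ape::as.phylo(hc), file = path)
  } else {
    sizes <- integer(nrow(hc$merge))
    size_of <- function(x) if (x < 0) 1L else sizes[x]
    for (i in seq_len(nrow(hc$merge)))
      sizes[i] <- size_of(hc$merge[i, 1]) + size_of(hc$merge[i, 2])
    df <- data.frame(node_a = hc$merge[, 1], node_b = hc$merge[, 2],
                     height = hc$height, size = sizes)
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
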