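#' Construct a SampleTable
#'
#' @param values numeric matrix or data.frame of parameter values with one row
#'   per sample (a (subject, arm, timepoint) observation) and one column per
#'   parameter.  Column names are the parameter ids.
#' @param subject_id character vector, one per sample.
#' @param arm character/factor, `"treated"` or `"control"`, one per sample.
#' @param timepoint optional character/factor of within-period timepoints; if
#'   omitted, a single timepoint `"t1"` is assumed.
#' @return a [SampleTable-class] object (parameters in rows, samples in
#'   columns, metadata in `colData`).
#' @examples
#' st <- SampleTable(matrix(rnorm(8), 4, 2, dimnames = list(NULL, c("CRP", "IL6"))),
#'                   subject_id = c("s1", "s1", "s2", "s2"),
#'                   arm = c("treated", "control", "treated", "control"))
#' validateSampleTable(st)
#' @export
SampleTable <- function(values, subject_id, arm, timepoint = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values)))
    stop("'values' must have parameter ids as column names")
  n <- nrow(values)
  if (length(subject_id) != n || length(arm) != n)
    stop("subject_id and arm must have one entry per sample row")
  if (is.null(timepoint)) timepoint <- rep("t1", n)
  if (length(timepoint) != n)
    stop("timepoint must have one entry per sample row")
  tp_lev <- if (is.factor(timepoint)) levels(timepoint) else
    sort(unique(as.character(timepoint)))
  cd <- S4Vectors::DataFrame(
    subject_id = as.character(subject_id),
    arm = factor(as.character(arm), levels = c("treated", "control")),
    timepoint = factor(as.character(timepoint), levels = tp_lev, ordered = TRUE))
  if (anyNA(cd$arm))
    stop("arm values must be 'treated' or 'control'")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(values = t(values)), colData = cd)
  colnames(se) <- paste(cd$subject_id, cd$arm, cd$timepoint, sep = ".")
  methods::new("SampleTable", se)
}

#' Validate a SampleTable against the cross-over design rules
#'
#' Reporting operation: checks the structural invariants and returns one
#' record per violation instead of failing.  Rules checked:
#' `duplicate_parameter` (parameter ids unique), `duplicate_observation`
#' (each subject at most once per (arm, timepoint)), and `incomplete_subject`
#' (cross-over mode: every subject has samples in both arms).
#'
#' @param table a [SampleTable-class].
#' @param crossover logical; check both-arms completeness (default TRUE).
#' @return a `data.frame` with columns `rule`, `offender`, `detail`; zero
#'   rows when all invariants hold.
#' @export
validateSampleTable <- function(table, crossover = TRUE) {
  stopifnot(methods::is(table, "SampleTable"))
  out <- list()
  pid <- rownames(table)
  dup <- unique(pid[duplicated(pid)])
  for (p in dup)
    out[[length(out) + 1L]] <- data.frame(
      rule = "duplicate_parameter", offender = p,
      detail = "parameter id appears more than once")
  cd <- SummarizedExperiment::colData(table)
  key <- paste(cd$subject_id, cd$arm, cd$timepoint, sep = "\r")
  dupk <- unique(key[duplicated(key)])
  for (k in dupk) {
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    out[[length(out) + 1L]] <- data.frame(
      rule = "duplicate_observation", offender = parts[1],
      detail = sprintf("subject '%s' has multiple samples for (%s, %s)",
                       parts[1], parts[2], parts[3]))
  }
  if (crossover) {
    arms_by_subj <- split(as.character(cd$arm), cd$subject_id)
    for (s in names(arms_by_subj)) {
      missing_arm <- setdiff(c("treated", "control"), unique(arms_by_subj[[s]]))
      for (a in missing_arm)
        out[[length(out) + 1L]] <- data.frame(
          rule = "incomplete_subject", offender = s,
          detail = sprintf("subject '%s' has no samples in the %s arm", s, a))
    }
  }
  if (!length(out))
    return(data.frame(rule = character(), offender = character(),
                      detail = character()))
  do.call(rbind, out)
}

#' Read / write a SampleTable as a wide delimited file
#'
#' The wide layout has leading metadata columns `subject_id`, `arm` and
#' (optionally) `timepoint`, followed by one column per parameter.  Field
#' separator is inferred from the extension (`.tsv` = tab, otherwise comma);
#' missing values may be empty cells or `NA`.
#'
#' @param path file path.
#' @param table a [SampleTable-class] (for writing).
#' @return `readSampleTable` returns a [SampleTable-class];
#'   `writeSampleTable` returns `path` invisibly.
#' @export
readSampleTable <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          na.strings = c("", "NA"), check.names = FALSE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("subject_id", "arm")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("sample table lacks required column(s): ", paste(miss, collapse = ", "))
  meta_cols <- intersect(c("subject_id", "arm", "timepoint"), colnames(df))
  vals <- as.matrix(df[, setdiff(colnames(df), meta_cols), drop = FALSE])
  storage.mode(vals) <- "double"
  SampleTable(vals, subject_id = df$subject_id, arm = df$arm,
              timepoint = if ("timepoint" %in% meta_cols) df$timepoint else NULL)
}

#' @rdname readSampleTable
#' @export
writeSampleTable <- function(table, path) {
  stopifnot(methods::is(table, "SampleTable"))
  cd <- SummarizedExperiment::colData(table)
  df <- data.frame(subject_id = as.character(cd$subject_id),
                   arm = as.character(cd$arm),
                   timepoint = as.character(cd$timepoint),
                   t(SummarizedExperiment::assay(table, "values")),
                   check.names = FALSE)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

# samples x parameters view used internally by the feature builder
.sampleValues <- function(table) t(SummarizedExperiment::assay(table, "values"))
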