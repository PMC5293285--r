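#' Read an abundance (OTU) table
#'
#' Reads tab- or comma-separated tables with a header row and a leading label
#' column, or BIOM files (format 1.0 JSON or 2.x HDF5, via the `biomformat`
#' package). Counts must be non-negative integers; tables of relative
#' abundances are rejected because MaxRank normalization draws individuals
#' (pre-scale such tables to counts first).
#'
#' Orientation is auto-detected by a simple heuristic: feature (OTU) axes are
#' almost always longer than sample axes, so the longer axis is taken as
#' features. Override with `orientation` when the heuristic is wrong.
#'
#' @param path path to a `.tsv`/`.txt`/`.csv` table or a `.biom` file.
#' @param orientation `"auto"`, `"samples_as_rows"` or `"samples_as_cols"`.
#' @return object of class `"abundance_table"`: list with `counts` (integer
#'   matrix, samples in rows), `sample_labels`, `feature_labels`,
#'   `orientation` (as stored in the source file).
#' @export
read_abundance_table <- function(path,
                                 orientation = c("auto", "samples_as_rows",
                                                 "samples_as_cols")) {
  orientation <- match.arg(orientation)
  if (grepl("\\.biom$", path, ignore.case = TRUE)) {
    return(read_biom_table(path))
  }
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      quote = "\"", comment.char = "#",
                      stringsAsFactors = FALSE),
    error = function(e) {
      stop("failed to parse table '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (ncol(df) < 2L) stop("table needs a label column and at least one count column",
                          call. = FALSE)
  row_labels <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("count columns must be numeric", call. = FALSE)
  check_integer_counts(m)
  storage.mode(m) <- "integer"
  rownames(m) <- row_labels

  samples_in_rows <- switch(orientation,
    samples_as_rows = TRUE,
    samples_as_cols = FALSE,
    auto = nrow(m) <= ncol(m)  # feature axis is almost always the longer one
  )
  if (!samples_in_rows) m <- t(m)
  structure(
    list(counts = m, sample_labels = rownames(m),
         feature_labels = colnames(m),
         orientation = if (samples_in_rows) "samples_as_rows" else "samples_as_cols"),
    class = "abundance_table"
  )
}

check_integer_counts <- function(m) {
  if (anyNA(m)) stop("table contains missing values", call. = FALSE)
  if (any(m < 0)) stop("table contains negative counts", call. = FALSE)
  if (any(m != round(m))) {
    stop(paste0(
      "table contains non-integer values; MaxRank normalization requires ",
      "integer counts. If these are relative abundances, rescale them to ",
      "counts before import."
    ), call. = FALSE)
  }
  invisible(TRUE)
}

read_biom_table <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    stop("reading BIOM files requires the 'biomformat' package",
         call. = FALSE)
  }
  b <- biomformat::read_biom(path)
  m <- as.matrix(biomformat::biom_data(b))  # features x samples
  check_integer_counts(m)
  storage.mode(m) <- "integer"
  m <- t(m)
  structure(
    list(counts = m, sample_labels = rownames(m),
         feature_labels = colnames(m), orientation = "samples_as_cols"),
    class = "abundance_table"
  )
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("Abundance table: %d samples x %d features\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Write an abundance table as TSV (features in rows)
#'
#' @param tbl an `"abundance_table"`.
#' @param path output file path.
#' @export
write_abundance_table <- function(tbl, path) {
  stopifnot(inherits(tbl, "abundance_table"))
  m <- t(tbl$counts)  # features x samples, the common OTU-table layout
  df <- data.frame(feature = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert an abundance table to a list of RADs
#'
#' One RAD per sample; species labels are discarded by design, only the
#' abundance structure is kept.
#'
#' @param tbl an `"abundance_table"`.
#' @return named list of [rad()] objects.
#' @export
as_rads <- function(tbl) {
  stopifnot(inherits(tbl, "abundance_table"))
  out <- lapply(seq_len(nrow(tbl$counts)), function(i) {
    rad(tbl$counts[i, ], label = tbl$sample_labels[i])
  })
  names(out) <- tbl$sample_labels
  out
}

reproducibility_header <- function(x) {
  c(
    sprintf("# radnorm %s", as.character(utils::packageVersion("radnorm"))),
    sprintf("# R=%d n_reps=%d seed=%s", x$R, x$n_reps,
            ifelse(is.na(x$seed), "NA", as.character(x$seed)))
  )
}

#' Write one NRAD as TSV
#'
#' Columns `rank`, `mean`, `ci_low`, `ci_high`, preceded by comment lines
#' recording R, the number of repetitions, the seed and the tool version, so
#' the output is reproducible from its header.
#'
#' @param nrad an `"nrad"` object.
#' @param path output file path.
#' @export
write_nrad <- function(nrad, path) {
  stopifnot(is_nrad(nrad))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(reproducibility_header(nrad),
               sprintf("# label=%s", nrad$label)), con)
  utils::write.table(as.data.frame(nrad), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an NRAD written by [write_nrad()]
#'
#' @param path input file path.
#' @return an `"nrad"` object.
#' @export
read_nrad <- function(path) {
  hdr <- grep("^#", readLines(path, n = 10L), value = TRUE)
  meta <- regmatches(hdr, regexec("R=(\\d+) n_reps=(\\d+) seed=(\\S+)", hdr))
  meta <- Filter(function(m) length(m) == 4L, meta)
  label <- sub("^# label=", "", grep("^# label=", hdr, value = TRUE))
  df <- utils::read.delim(path, comment.char = "#")
  new_nrad(df$mean, nrow(df), df$ci_low, df$ci_high,
           n_reps = if (length(meta)) as.integer(meta[[1L]][3L]) else 0L,
           seed = if (length(meta) && meta[[1L]][4L] != "NA")
             as.integer(meta[[1L]][4L]) else NULL,
           label = if (length(label)) label else "sample")
}

#' Write a set of NRADs as a wide matrix TSV
#'
#' One row per sample, one column per rank (mean abundances only).
#'
#' @param nrads list of `"nrad"` objects sharing `R`.
#' @param path output file path.
#' @export
write_nrad_matrix <- function(nrads, path) {
  stopifnot(all(vapply(nrads, is_nrad, logical(1))))
  A <- do.call(rbind, lapply(nrads, function(x) x$abundances))
  df <- data.frame(
    sample = vapply(nrads, function(x) x$label, character(1)),
    A, check.names = FALSE
  )
  colnames(df)[-1L] <- paste0("rank", seq_len(ncol(A)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(reproducibility_header(nrads[[1L]]), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an entropy/evenness table as TSV
#'
#' @param tab data.frame from [entropy_table()].
#' @param path output file path.
#' @export
write_entropy_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
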