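#' Read a delimited expression-style matrix and labels file
#'
#' Reads a TSV/CSV matrix (header row required, IDs in the first column)
#' and a two-column labels file (`sample_id`, `class`), aligns them on the
#' intersection of sample IDs, and returns a dataset ready for [habic()].
#' Samples present in only one of the files are dropped with a warning;
#' no overlap at all is an error. Duplicate feature names and non-numeric
#' matrix cells are errors reporting the offending names/coordinates.
#'
#' @param matrix_path path to the delimited matrix (delimiter
#'   auto-detected).
#' @param labels_path path to the delimited labels file.
#' @param layout `"samples_by_features"` (samples in rows, default) or
#'   `"features_by_samples"` (genes in rows, as expression matrices are
#'   usually shipped; the matrix is transposed on read).
#' @param positive optional class name to code as the positive (second)
#'   level.
#' @return A list of class `"habic_dataset"` with `x` (samples x
#'   features) and `y` (two-level factor).
#' @export
read_dataset <- function(matrix_path, labels_path,
                         layout = c("samples_by_features",
                                    "features_by_samples"),
                         positive = NULL) {
  layout <- match.arg(layout)
  dt <- data.table::fread(matrix_path, header = TRUE, data.table = FALSE)
  if (ncol(dt) < 2L)
    stop("matrix file must have an ID column plus at least one data column",
         call. = FALSE)
  ids <- as.character(dt[[1L]])
  raw_names <- colnames(dt)[-1L]   # before data.frame name repair
  body <- dt[, -1L, drop = FALSE]
  colnames(body) <- raw_names
  for (j in seq_along(body)) {
    if (!is.numeric(body[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(body[[j]]))) |
                     !grepl("^\\s*[-+0-9.eE]+\\s*$", as.character(body[[j]])))[1L]
      stop(sprintf("non-numeric value in matrix file at row %d, column '%s'",
                   bad, colnames(body)[j]), call. = FALSE)
    }
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  if (layout == "features_by_samples") m <- t(m)
  feats <- colnames(m)
  dup <- unique(feats[duplicated(feats)])
  if (length(dup) > 0L)
    stop(sprintf("duplicate feature name(s): %s",
                 paste(head(dup, 5L), collapse = ", ")), call. = FALSE)
  if (anyDuplicated(rownames(m)))
    stop("duplicate sample IDs in matrix file", call. = FALSE)

  lab <- data.table::fread(labels_path, header = TRUE, data.table = FALSE)
  if (ncol(lab) < 2L)
    stop("labels file must have columns (sample_id, class)", call. = FALSE)
  lab_ids <- as.character(lab[[1L]])
  common <- intersect(rownames(m), lab_ids)
  if (length(common) == 0L)
    stop("no overlapping sample IDs between matrix and labels files",
         call. = FALSE)
  dropped <- (nrow(m) - length(common)) + (length(lab_ids) - length(common))
  if (dropped > 0L)
    warning(sprintf("%d sample ID(s) present in only one file were dropped; %d retained",
                    dropped, length(common)), call. = FALSE)
  keep <- rownames(m)[rownames(m) %in% common]
  m <- m[keep, , drop = FALSE]
  y <- as_binary_factor(lab[[2L]][match(keep, lab_ids)], positive = positive)
  if (!all(is.finite(m)))
    stop("matrix contains missing or non-finite values", call. = FALSE)
  structure(list(x = m, y = y,
                 spec = list(source = matrix_path, layout = layout)),
            class = "habic_dataset")
}

#' Write a dataset as TSV files (plus a sidecar JSON)
#'
#' Writes `<prefix>_X.tsv` (samples in rows, sample IDs in the first
#' column), `<prefix>_labels.tsv` (`sample_id`, `label`) and, when the
#' dataset records its generating parameters, `<prefix>_spec.json`.
#'
#' @param dataset a `"habic_dataset"` (e.g. from
#'   [generate_classification()] or [read_dataset()]).
#' @param prefix output path prefix.
#' @return The paths written, invisibly.
#' @export
write_dataset <- function(dataset, prefix) {
  stopifnot(inherits(dataset, "habic_dataset"))
  xp <- paste0(prefix, "_X.tsv")
  lp <- paste0(prefix, "_labels.tsv")
  ids <- rownames(dataset$x)
  if (is.null(ids)) ids <- paste0("sample_", seq_len(nrow(dataset$x)))
  data.table::fwrite(
    data.frame(sample_id = ids, dataset$x, check.names = FALSE),
    xp, sep = "\t")
  data.table::fwrite(data.frame(sample_id = ids, label = dataset$y), lp,
                     sep = "\t")
  paths <- c(xp, lp)
  if (!is.null(dataset$spec)) {
    sp <- paste0(prefix, "_spec.json")
    jsonlite::write_json(dataset$spec, sp, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, sp)
  }
  invisible(paths)
}

#' Save / load a fitted model
#'
#' Serializes a fitted [habic()] model (supports, potentials, threshold,
#' orientation, seeds and any reducer or ensemble members) to a single
#' portable file. The round trip is bit-exact: a reloaded model produces
#' identical scores.
#'
#' @param model a fitted `"habic"` model.
#' @param path file path.
#' @return `write_habic`: `path`, invisibly. `read_habic`: the model.
#' @export
write_habic <- function(model, path) {
  stopifnot(inherits(model, "habic"))
  saveRDS(model, path, version = 3L)
  invisible(path)
}

#' @rdname write_habic
#' @export
read_habic <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "habic"))
    stop(sprintf("'%s' does not contain a habic model", path), call. = FALSE)
  model
}

#' Write a cross-validation report as TSV and JSON
#'
#' `<prefix>_cv.tsv` holds one row per split plus a `summary` row (means
#' and sds); `<prefix>_cv.json` is the full report including protocol and
#' seed.
#'
#' @param report a `"habic_cv"` object.
#' @param prefix output path prefix.
#' @return The paths written, invisibly.
#' @export
write_cv_report <- function(report, prefix) {
  stopifnot(inherits(report, "habic_cv"))
  tp <- paste0(prefix, "_cv.tsv")
  jp <- paste0(prefix, "_cv.json")
  d <- report$per_split
  d$split <- as.character(d$split)
  d <- rbind(d, data.frame(split = "mean", auc = report$auc_mean,
                           mcc = report$mcc_mean),
             data.frame(split = "sd", auc = report$auc_sd,
                        mcc = report$mcc_sd))
  data.table::fwrite(d, tp, sep = "\t")
  jsonlite::write_json(unclass(report), jp, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(tp, jp))
}
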