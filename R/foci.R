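#' Construct a foci dataset
#'
#' A foci dataset is the unit of coordinate-based meta-analysis: an ordered
#' table of activation peaks, one row per peak, each carrying a study
#' identifier, a contrast identifier, a class label (e.g. \code{"intention"},
#' \code{"self_agency"}, \code{"external_agency"}), and an MNI coordinate in
#' millimetres. All coordinates are normalised to MNI RAS mm on construction;
#' Talairach rows are converted with \code{\link{tal2mni}}.
#'
#' @param foci data frame with columns \code{study}, \code{contrast},
#'   \code{label}, \code{x}, \code{y}, \code{z} and optionally \code{space}
#'   (\code{"MNI"} or \code{"Talairach"}; default MNI).
#' @param label_set character vector of admissible labels; defaults to the
#'   labels present.
#' @param provenance free-text note on where the table came from.
#' @return An object of class \code{foci_dataset}: a data frame of foci (all
#'   in MNI space) with attributes \code{label_set} and \code{provenance}.
#' @export
foci_dataset <- function(foci, label_set = NULL, provenance = "") {
  foci <- as.data.frame(foci)
  required <- c("study", "contrast", "label", "x", "y", "z")
  missing_cols <- setdiff(required, names(foci))
  if (length(missing_cols) > 0L)
    stop("foci table is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(foci) == 0L)
    stop("foci dataset is empty")
  if (is.null(foci$space)) foci$space <- "MNI"
  bad_space <- setdiff(unique(foci$space), c("MNI", "Talairach"))
  if (length(bad_space) > 0L)
    stop("unknown coordinate space tag(s): ", paste(bad_space, collapse = ", "))
  xyz <- as.matrix(foci[, c("x", "y", "z")])
  storage.mode(xyz) <- "double"
  if (any(!is.finite(xyz)))
    stop("non-finite coordinates in foci table")
  tal <- foci$space == "Talairach"
  if (any(tal)) xyz[tal, ] <- tal2mni(xyz[tal, , drop = FALSE])
  foci$x <- xyz[, 1]; foci$y <- xyz[, 2]; foci$z <- xyz[, 3]
  foci$space <- "MNI"
  if (is.null(label_set)) label_set <- sort(unique(as.character(foci$label)))
  if (!all(foci$label %in% label_set))
    stop("label(s) outside the declared label set: ",
         paste(setdiff(unique(foci$label), label_set), collapse = ", "))
  foci$label <- as.character(foci$label)
  out_of_bounds <- abs(foci$x) > 100 | abs(foci$y) > 100 |
    foci$z < -80 | foci$z > 120
  if (any(out_of_bounds))
    warning(sum(out_of_bounds), " focus/foci outside sanity bounds ",
            "(|x|,|y| <= 100 mm, -80 <= z <= 120 mm) after MNI normalisation")
  structure(foci,
            label_set = label_set,
            provenance = provenance,
            class = c("foci_dataset", "data.frame"))
}

#' @export
print.foci_dataset <- function(x, ...) {
  cat(sprintf("foci_dataset: %d foci, %d studies, %d contrasts\n",
              nrow(x), length(unique(x$study)),
              length(unique(paste(x$study, x$contrast)))))
  tab <- table(factor(x$label, levels = attr(x, "label_set")))
  cat("labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Read a delimited foci table
#'
#' Reads a TSV/CSV of activation peaks into a \code{\link{foci_dataset}}.
#' Column names are remapped through \code{dialect}, so tables using e.g.
#' \code{Study}/\code{X}/\code{Y}/\code{Z} headers can be ingested without
#' editing. Rows with non-numeric coordinates are rejected and recorded in the
#' ingestion log rather than aborting the read.
#'
#' @param source path to a delimited text file (or a connection).
#' @param dialect named character vector mapping canonical names
#'   (\code{study}, \code{contrast}, \code{label}, \code{x}, \code{y},
#'   \code{z}, \code{space}) to the file's column names. Unmapped canonical
#'   names are looked up verbatim.
#' @param sep field separator; default tab.
#' @param label_set,provenance passed to \code{\link{foci_dataset}}.
#' @return A \code{foci_dataset}; the per-row ingestion log (row number,
#'   status, message) is attached as attribute \code{"ingestion_log"}.
#' @export
read_foci_table <- function(source, dialect = NULL, sep = "\t",
                            label_set = NULL, provenance = NULL) {
  raw <- utils::read.table(source, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  canonical <- c("study", "contrast", "label", "x", "y", "z", "space")
  colmap <- stats::setNames(canonical, canonical)
  if (!is.null(dialect)) colmap[names(dialect)] <- dialect
  mandatory <- c("study", "contrast", "label", "x", "y", "z")
  for (cn in mandatory)
    if (!colmap[[cn]] %in% names(raw))
      stop("foci table is missing mandatory column '", colmap[[cn]],
           "' (maps to '", cn, "')")
  has_space <- colmap[["space"]] %in% names(raw)
  n <- nrow(raw)
  if (n == 0L) stop("foci table has no data rows")
  coord <- suppressWarnings(cbind(
    x = as.numeric(raw[[colmap[["x"]]]]),
    y = as.numeric(raw[[colmap[["y"]]]]),
    z = as.numeric(raw[[colmap[["z"]]]])))
  ok <- stats::complete.cases(coord)
  log <- data.frame(row = seq_len(n),
                    status = ifelse(ok, "ok", "rejected"),
                    message = ifelse(ok, "", "non-numeric coordinate"),
                    stringsAsFactors = FALSE)
  if (!any(ok)) stop("no ingestible rows in foci table")
  df <- data.frame(study = as.character(raw[[colmap[["study"]]]][ok]),
                   contrast = as.character(raw[[colmap[["contrast"]]]][ok]),
                   label = as.character(raw[[colmap[["label"]]]][ok]),
                   x = coord[ok, "x"], y = coord[ok, "y"], z = coord[ok, "z"],
                   space = if (has_space) as.character(raw[[colmap[["space"]]]][ok]) else "MNI",
                   stringsAsFactors = FALSE)
  ds <- foci_dataset(df, label_set = label_set,
                     provenance = provenance %||% paste("read from",
                                                        if (is.character(source)) source else "connection"))
  attr(ds, "ingestion_log") <- log
  ds
}

#' Write a foci dataset to a delimited table
#'
#' @param ds a \code{\link{foci_dataset}}.
#' @param path output file path.
#' @param sep field separator; default tab.
#' @return \code{path}, invisibly.
#' @export
write_foci_table <- function(ds, path, sep = "\t") {
  df <- as.data.frame(ds)[, c("study", "contrast", "label",
                              "x", "y", "z", "space")]
  ## full-precision coordinates so a write/read round trip is bit-exact
  for (cn in c("x", "y", "z")) df[[cn]] <- sprintf("%.17g", df[[cn]])
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read foci in the Sleuth/GingerALE text dialect
#'
#' Parses the plain-text foci format used by Sleuth/GingerALE: blocks headed
#' by \code{// <study>: <contrast>} comment lines followed by whitespace-
#' separated \code{x y z} rows, blocks separated by blank lines. An optional
#' \code{// Reference=MNI} (or Talairach) header sets the space for the whole
#' file.
#'
#' @param path text file in the Sleuth dialect.
#' @param label label assigned to every focus in the file (the dialect does
#'   not carry class labels).
#' @return A \code{\link{foci_dataset}}.
#' @export
read_sleuth_foci <- function(path, label = "focus") {
  lines <- readLines(path)
  space <- "MNI"
  ref <- grep("^//\\s*Reference\\s*=", lines, value = TRUE)
  if (length(ref) > 0 && grepl("tal", ref[1], ignore.case = TRUE))
    space <- "Talairach"
  study <- contrast <- NA_character_
  rows <- list()
  block <- 0L
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "") next
    if (startsWith(ln, "//")) {
      body <- trimws(sub("^//", "", ln))
      if (grepl("^Reference\\s*=", body)) next
      if (grepl("Subjects\\s*=", body)) next
      block <- block + 1L
      parts <- strsplit(body, ":", fixed = TRUE)[[1]]
      study <- trimws(parts[1])
      contrast <- if (length(parts) > 1) trimws(paste(parts[-1], collapse = ":"))
                  else paste0("c", block)
      next
    }
    vals <- suppressWarnings(as.numeric(strsplit(ln, "[\\s,]+", perl = TRUE)[[1]]))
    if (length(vals) >= 3 && all(is.finite(vals[1:3])))
      rows[[length(rows) + 1L]] <- data.frame(
        study = study %||% "unknown", contrast = contrast %||% "c0",
        label = label, x = vals[1], y = vals[2], z = vals[3], space = space,
        stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("no foci found in ", path)
  foci_dataset(do.call(rbind, rows), provenance = paste("Sleuth dialect:", path))
}

#' Dataset-level label priors
#'
#' Returns, for each label in the dataset's label set, its exact proportion of
#' the total focus count. These proportions are the success probabilities of
#' the per-cluster binomial composition tests: a cluster is compared against
#' the expectation that its members are an exchangeable draw from the whole
#' dataset.
#'
#' @param ds a \code{\link{foci_dataset}}.
#' @return Named numeric vector of proportions summing to 1, with attribute
#'   \code{"counts"} (the integer counts) and \code{"total"}.
#' @export
dataset_priors <- function(ds) {
  stopifnot(inherits(ds, "foci_dataset"))
  label_set <- attr(ds, "label_set")
  if (!all(ds$label %in% label_set))
    stop("label(s) outside the declared label set")
  counts <- table(factor(ds$label, levels = label_set))
  p <- as.numeric(counts) / nrow(ds)
  structure(stats::setNames(p, label_set),
            counts = as.integer(counts), total = nrow(ds))
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
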