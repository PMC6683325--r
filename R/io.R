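# Readers and writers binding the pipeline stages together. TSV is the
# canonical interchange (samples in rows, first column sample_id); BIOM-JSON
# is optional. Every writer emits a header comment with the package version
# and seed, and writes atomically (temp file + rename) so a failed run leaves
# no partial output behind.

gm_header <- function(seed = NULL) {
  c(paste0("# gutmaturity ", as.character(utils::packageVersion("gutmaturity"))),
    if (!is.null(seed)) paste0("# seed: ", seed))
}

# Atomic TSV write with comment header.
write_gm_tsv <- function(df, path, seed = NULL) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(gm_header(seed), tmp)
  readr::write_tsv(df, tmp, append = TRUE, col_names = TRUE)
  if (!file.rename(tmp, path)) {
    abort(paste0("could not move temporary file onto ", path))
  }
  invisible(path)
}

read_gm_tsv <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path),
          class = "gutmaturity_validation_error")
  }
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' Read an abundance table from TSV or BIOM-JSON
#'
#' TSV tables carry samples in rows with a header row of feature ids and the
#' sample id in the first column; `#` lines are comments. If `meta` is
#' supplied, orientation is cross-checked against its sample ids and the
#' table is transposed when samples are found in columns. Rows are validated
#' as compositions: entries non-negative, each row summing to 1 (deviations
#' up to 1e-3 are renormalized with a message; larger ones are an error
#' naming the offending samples).
#'
#' @param path File path.
#' @param format `"tsv"` or `"biom-json"` (requires the biomformat package).
#' @param meta Optional sample metadata used to auto-detect orientation.
#'
#' @return A validated abundance tibble.
#' @export
read_abundance_table <- function(path, format = c("tsv", "biom-json"),
                                 meta = NULL) {
  format <- match.arg(format)
  if (format == "biom-json") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      abort("the biomformat package is required for BIOM-JSON input")
    }
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")  # features x samples
    table <- matrix_to_table(t(m))
  } else {
    raw <- read_gm_tsv(path)
    names(raw)[1] <- "sample_id"
    raw$sample_id <- as.character(raw$sample_id)
    table <- tibble::as_tibble(raw)
    if (!is.null(meta)) {
      in_rows <- mean(table$sample_id %in% meta$sample_id)
      in_cols <- mean(feature_ids(table) %in% meta$sample_id)
      if (in_cols > in_rows) {
        inform("samples found in columns; transposing the table")
        m <- abundance_matrix(table)
        table <- matrix_to_table(t(m))
      }
    }
  }
  validate_abundance_table(table)
}

#' Write an abundance table as TSV or BIOM-JSON
#'
#' @param table Abundance tibble.
#' @param path Output path.
#' @param format `"tsv"` or `"biom-json"`.
#' @param seed Seed recorded in the TSV header comment.
#' @return The path, invisibly.
#' @export
write_abundance_table <- function(table, path, format = c("tsv", "biom-json"),
                                  seed = NULL) {
  format <- match.arg(format)
  table <- validate_abundance_table(table)
  if (format == "biom-json") {
    # written directly (BIOM 1.0 dense JSON) rather than through an external
    # serializer so relative abundances keep full double precision; readable
    # by any BIOM 1.0 parser
    m <- t(abundance_matrix(table))  # biom stores features x samples
    doc <- list(
      id = NULL,
      format = "Biological Observation Matrix 1.0.0",
      format_url = "http://biom-format.org",
      type = "OTU table",
      generated_by = paste0("gutmaturity ",
                            utils::packageVersion("gutmaturity")),
      date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
      matrix_type = "dense",
      matrix_element_type = "float",
      shape = dim(m),
      rows = lapply(rownames(m),
                    function(id) list(id = id, metadata = NULL)),
      columns = lapply(colnames(m),
                       function(id) list(id = id, metadata = NULL)),
      data = m
    )
    tmp <- paste0(path, ".tmp", Sys.getpid())
    on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
    jsonlite::write_json(doc, tmp, auto_unbox = TRUE, digits = NA,
                         null = "null", matrix = "rowmajor")
    if (!file.rename(tmp, path)) abort(paste0("could not write ", path))
    return(invisible(path))
  }
  write_gm_tsv(table, path, seed = seed)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Requires a `sample_id` column; duplicate sample ids are an error.
#'
#' @param path File path.
#' @return A metadata tibble.
#' @export
read_sample_metadata <- function(path) {
  meta <- read_gm_tsv(path)
  if (!"sample_id" %in% names(meta)) {
    names(meta)[1] <- "sample_id"
  }
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id)) {
    abort(paste0("duplicated sample ids in metadata: ",
                 paste(unique(meta$sample_id[duplicated(meta$sample_id)]),
                       collapse = ", ")),
          class = "gutmaturity_validation_error")
  }
  meta
}

#' Read a proteome panel from TSV
#'
#' Samples in rows, proteins in columns, first column the sample id. Values
#' are expected on the log2 scale; set `log2_transform = TRUE` to transform
#' linear-scale (RFU-like) values on load.
#'
#' @param path File path.
#' @param log2_transform Apply `log2` to the values on load.
#' @return A panel tibble.
#' @export
read_proteome_panel <- function(path, log2_transform = FALSE) {
  raw <- read_gm_tsv(path)
  names(raw)[1] <- "sample_id"
  raw$sample_id <- as.character(raw$sample_id)
  m <- abundance_matrix(raw)
  if (any(!is.finite(m))) {
    abort("panel values must be finite", class = "gutmaturity_validation_error")
  }
  if (log2_transform) {
    if (any(m <= 0)) {
      abort("cannot log2-transform non-positive panel values",
            class = "gutmaturity_validation_error")
    }
    m <- log2(m)
  }
  matrix_to_table(m)
}

#' Read a GMT annotation-category file
#'
#' Standard GMT: one category per line, tab-separated as
#' `name<TAB>description<TAB>id1<TAB>id2...`.
#'
#' @param path File path.
#' @return A named list mapping category name to character vector of ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) {
    abort(paste0("malformed GMT line(s): ", paste(which(bad), collapse = ", ")),
          class = "gutmaturity_validation_error")
  }
  setNames(lapply(parts, function(p) unique(p[-(1:2)])),
           vapply(parts, `[[`, character(1), 1))
}

#' Save / load a fitted maturity model
#'
#' The model is serialized as a versioned JSON descriptor (features,
#' importance ranking, sparse set, calibration bins, hyperparameters, seed)
#' plus a binary sidecar (`<path>.rds`) holding the fitted forest and
#' training data.
#'
#' @param model A `maturity_model`.
#' @param path Path of the JSON descriptor; the sidecar is written next to
#'   it.
#' @return `path`, invisibly (`save_maturity_model`); the model
#'   (`load_maturity_model`).
#' @export
save_maturity_model <- function(model, path) {
  stopifnot(inherits(model, "maturity_model"))
  desc <- list(
    format = "gutmaturity_maturity_model",
    format_version = 1L,
    package_version = as.character(utils::packageVersion("gutmaturity")),
    seed = model$seed,
    hyper = model$hyper,
    features = model$features,
    full_importances = model$full_importances,
    sparse_features = model$sparse_features,
    cv_curve = model$cv_curve,
    calibration_bins = if (!is.null(model$calibration)) model$calibration$bins,
    sidecar = paste0(basename(path), ".rds")
  )
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  jsonlite::write_json(desc, tmp, auto_unbox = TRUE, digits = NA, null = "null")
  saveRDS(model, paste0(path, ".rds"))
  if (!file.rename(tmp, path)) abort(paste0("could not write ", path))
  invisible(path)
}

#' @rdname save_maturity_model
#' @export
load_maturity_model <- function(path) {
  desc <- jsonlite::read_json(path)
  if (!identical(desc$format, "gutmaturity_maturity_model")) {
    abort("not a maturity-model descriptor",
          class = "gutmaturity_validation_error")
  }
  model <- readRDS(file.path(dirname(path), desc$sidecar))
  stopifnot(inherits(model, "maturity_model"))
  model
}
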