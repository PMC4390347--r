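#' Assemble a screen dataset from well-level records
#'
#' A `screen_dataset` holds one row per assayed well: clone, trapped gene,
#' absorbed dose (Gy), duplicate index, dead-cell and total-cell luminescence
#' (RLU) from the cytotoxicity assay, beta-gal reporter luminescence (absent
#' for wild-type wells, which carry no trap construct), and a wild-type flag.
#' Live-cell signal is always derived as `total_rlu - dead_rlu`: the assay
#' chemistry measures the dead-cell protease signal first and the total signal
#' after lysis, so dead and total are the stored measurements.
#'
#' Wells violating `dead_rlu <= total_rlu` are excluded with a QC flag (kept
#' in `attr(x, "excluded")`) and reported via a message. Every clone must have
#' a 0-Gy reference record.
#'
#' @param records Data frame with columns `clone_id`, `gene_symbol`,
#'   `dose_gy`, `replicate`, `dead_rlu`, `total_rlu`, `betagal_rlu`,
#'   `is_wildtype`.
#' @param dose_set Optional ordered numeric vector of doses; defaults to the
#'   sorted distinct doses present.
#' @param require_betagal If `TRUE` (default), non-wild-type wells with a
#'   missing `betagal_rlu` raise a validation error naming the clones.
#'
#' @return An object of class `screen_dataset`: list with `records` (validated
#'   data frame), `dose_set`, and `background_genes` (distinct non-wild-type
#'   gene symbols). Excluded wells are attached as attribute `"excluded"`.
#' @seealso [read_plate_table()], [simulate_screen()]
#' @export
screen_dataset <- function(records, dose_set = NULL, require_betagal = TRUE) {
  required <- c("clone_id", "gene_symbol", "dose_gy", "replicate",
                "dead_rlu", "total_rlu", "betagal_rlu", "is_wildtype")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    ts_error("schema_error",
             paste("missing required column(s):",
                   paste(missing_cols, collapse = ", ")))
  }
  records <- as.data.frame(records)[required]
  records$clone_id <- as.character(records$clone_id)
  records$gene_symbol <- as.character(records$gene_symbol)
  records$dose_gy <- as.numeric(records$dose_gy)
  records$replicate <- as.integer(records$replicate)
  records$is_wildtype <- as.logical(records$is_wildtype)

  if (anyNA(records$dose_gy) || any(records$dose_gy < 0)) {
    ts_error("validation_error", "doses must be non-negative numbers")
  }
  if (any(records$replicate < 1L, na.rm = TRUE)) {
    ts_error("validation_error", "replicate indices must be positive integers")
  }
  key <- paste(records$clone_id, records$dose_gy, records$replicate)
  if (anyDuplicated(key)) {
    ts_error("validation_error",
             paste("duplicated (clone_id, dose, replicate) key(s):",
                   paste(head(unique(key[duplicated(key)]), 5), collapse = "; ")))
  }

  # QC: dead signal cannot exceed total signal; flag and exclude such wells.
  bad <- !is.na(records$dead_rlu) & !is.na(records$total_rlu) &
    records$dead_rlu > records$total_rlu
  excluded <- records[bad, , drop = FALSE]
  if (nrow(excluded) > 0) {
    excluded$qc_reason <- "dead_rlu > total_rlu"
    message(sprintf("excluding %d well(s) failing dead_rlu <= total_rlu QC: %s",
                    nrow(excluded),
                    paste(head(excluded$clone_id, 5), collapse = ", ")))
    records <- records[!bad, , drop = FALSE]
  }

  if (require_betagal && nrow(records) > 0) {
    no_bg <- !records$is_wildtype & is.na(records$betagal_rlu)
    if (any(no_bg)) {
      ts_error("validation_error",
               paste("non-wild-type clone(s) lacking betagal_rlu:",
                     paste(head(unique(records$clone_id[no_bg]), 5),
                           collapse = ", ")))
    }
  }

  if (nrow(records) > 0) {
    has_ref <- tapply(records$dose_gy == 0, records$clone_id, any)
    if (!all(has_ref)) {
      ts_error("validation_error",
               paste("clone(s) with no 0-Gy reference record:",
                     paste(head(names(has_ref)[!has_ref], 5), collapse = ", ")))
    }
  }

  if (is.null(dose_set)) dose_set <- sort(unique(records$dose_gy))
  background <- sort(unique(records$gene_symbol[!records$is_wildtype]))
  structure(list(records = records,
                 dose_set = as.numeric(dose_set),
                 background_genes = background),
            class = "screen_dataset",
            excluded = if (nrow(excluded) > 0) excluded else NULL)
}

#' @export
print.screen_dataset <- function(x, ...) {
  cat(sprintf(paste0("Screen dataset: %d wells, %d clones (%d genes), ",
                     "%d wild-type wells, doses %s Gy\n"),
              nrow(x$records),
              length(unique(x$records$clone_id[!x$records$is_wildtype])),
              length(x$background_genes),
              sum(x$records$is_wildtype),
              paste(x$dose_set, collapse = "/")))
  ex <- attr(x, "excluded")
  if (!is.null(ex)) cat(sprintf("  (%d wells QC-excluded)\n", nrow(ex)))
  invisible(x)
}

#' Read a plate-level assay table
#'
#' Reads a delimited text file with one row per well and the columns of
#' [screen_dataset()], validates it, and returns the dataset. The delimiter
#' is sniffed from the header line unless given.
#'
#' @param path Path to a CSV or TSV file.
#' @param sep Field delimiter; `"auto"` (default) chooses tab if the header
#'   contains tabs, otherwise comma.
#' @param require_betagal Passed to [screen_dataset()].
#' @return A `screen_dataset`.
#' @export
read_plate_table <- function(path, sep = c("auto", "\t", ","),
                             require_betagal = TRUE) {
  if (!file.exists(path)) ts_error("io_error", paste("no such file:", path))
  sep <- match.arg(sep)
  if (sep == "auto") {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                           check.names = FALSE)
  screen_dataset(raw, require_betagal = require_betagal)
}

#' Write a screen dataset back to a plate table
#'
#' @param x A `screen_dataset`.
#' @param path Output path; tab-delimited.
#' @return `path`, invisibly.
#' @export
write_plate_table <- function(x, path) {
  stopifnot(inherits(x, "screen_dataset"))
  utils::write.table(x$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene-set annotations in GMT format
#'
#' Standard GMT: one term per line, tab-separated fields
#' `term_id<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within a
#' line are collapsed to a set.
#'
#' @param path Path to a GMT file.
#' @return An object of class `gene_set_collection`: a named list of character
#'   vectors of member genes, with term descriptions in
#'   `attr(x, "descriptions")`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) ts_error("io_error", paste("no such file:", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  descs <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      ts_error("parse_error",
               sprintf("GMT line %d has %d field(s); need term, description, >=1 gene",
                       i, length(fields)))
    }
    term <- fields[[1]]
    if (term %in% names(sets)) {
      ts_error("parse_error", sprintf("duplicate term id '%s' (line %d)", term, i))
    }
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) {
      ts_error("parse_error", sprintf("GMT line %d has an empty member set", i))
    }
    sets[[term]] <- genes
    descs[[term]] <- fields[[2]]
  }
  structure(sets, descriptions = descs, class = "gene_set_collection")
}

#' Write a result table to delimited text
#'
#' Writes any of the pipeline result data frames as TSV with a stable column
#' order. Columns named `p`, `q` or ending in `_p`/`_q` are rendered in
#' scientific notation with at least 3 significant figures; values below
#' 1e-300 are written as the sentinel `"<1e-300"`, never as a silent `0`.
#'
#' @param results A data frame (possibly empty; the header is still written).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  if (is.null(results)) ts_error("validation_error", "results must be non-null")
  results <- as.data.frame(results)
  pcols <- grep("(^|_)[pq]$", names(results), value = TRUE)
  for (col in pcols) {
    if (is.numeric(results[[col]])) {
      results[[col]] <- format_pvalue(results[[col]])
    }
  }
  con <- tryCatch(file(path, "w"), error = function(e) {
    ts_error("io_error", paste("cannot open for writing:", path))
  })
  on.exit(close(con))
  utils::write.table(results, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a result table written by [write_results()]
#'
#' Restores the numeric p/q columns, mapping the `"<1e-300"` underflow
#' sentinel to 0 with a `log10_p` column left intact where present.
#'
#' @param path Path to a TSV written by [write_results()].
#' @return A data frame.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) ts_error("io_error", paste("no such file:", path))
  out <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  pcols <- grep("(^|_)[pq]$", names(out), value = TRUE)
  for (col in pcols) {
    if (is.character(out[[col]])) {
      sentinel <- out[[col]] == "<1e-300"
      vals <- suppressWarnings(as.numeric(out[[col]]))
      vals[sentinel] <- 0
      out[[col]] <- vals
    }
  }
  out
}
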