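AMPLITUDE_HEADER <- "Ch1 Amplitude,Ch2 Amplitude"

#' Read and write per-well droplet amplitude CSV
#'
#' The on-disk format mirrors droplet-reader exports: a header line
#' `Ch1 Amplitude,Ch2 Amplitude` followed by one numeric row per droplet.
#' Malformed rows are reported with their file line numbers. An optional
#' truth sidecar CSV (`truth_wt,truth_hdr,truth_nhej`) carries simulation
#' ground truth.
#'
#' @param path Amplitude CSV path.
#' @param well_id,sample_id Identifiers for the returned well (default:
#'   file name without extension).
#' @param truth_path Optional sidecar CSV path to read/write.
#' @return `read_amplitude_csv()` returns a [well_data()];
#'   `write_amplitude_csv()` returns `path` invisibly.
#' @export
read_amplitude_csv <- function(path, well_id = NULL, sample_id = NULL,
                               truth_path = NULL) {
  if (!file.exists(path)) stop("amplitude CSV not found: ", path)
  lines <- readLines(path)
  lines <- lines[!(seq_along(lines) > 1 & lines == "")]
  if (length(lines) == 0L) stop("empty amplitude file: ", path)
  if (trimws(lines[1]) != AMPLITUDE_HEADER)
    stop("bad header in ", path, ": expected '", AMPLITUDE_HEADER, "'")
  if (length(lines) < 2L) stop("no droplet rows in ", path)
  parts <- strsplit(lines[-1], ",", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop(sprintf("malformed row at line %d of %s (expected 2 fields)",
                 bad[1] + 1L, path))
  ch1 <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  ch2 <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  bad <- which(is.na(ch1) | is.na(ch2))
  if (length(bad))
    stop(sprintf("non-numeric amplitude at line %d of %s",
                 bad[1] + 1L, path))
  d <- data.frame(ch1_amplitude = ch1, ch2_amplitude = ch2)
  if (!is.null(truth_path)) {
    tr <- utils::read.csv(truth_path)
    if (!all(c("truth_wt", "truth_hdr", "truth_nhej") %in% names(tr)) ||
        nrow(tr) != nrow(d))
      stop("truth sidecar must have truth_wt/truth_hdr/truth_nhej and ",
           "one row per droplet")
    d <- cbind(d, tr[c("truth_wt", "truth_hdr", "truth_nhej")])
  }
  base <- sub("\\.[^.]*$", "", basename(path))
  well_data(d, well_id = well_id %||% base, sample_id = sample_id %||% base)
}

#' @rdname read_amplitude_csv
#' @param well A [well_data()] to write.
#' @export
write_amplitude_csv <- function(well, path, truth_path = NULL) {
  stopifnot(inherits(well, "well_data"))
  d <- well$droplets
  fmt <- function(x) formatC(x, format = "g", digits = 15)
  writeLines(c(AMPLITUDE_HEADER,
               paste(fmt(d$ch1_amplitude), fmt(d$ch2_amplitude), sep = ",")),
             path)
  if (!is.null(truth_path)) {
    if (!well$has_truth) stop("well carries no truth occupancy to write")
    utils::write.csv(d[c("truth_wt", "truth_hdr", "truth_nhej")],
                     truth_path, row.names = FALSE)
  }
  invisible(path)
}

#' Read and write cluster-count tables
#'
#' One row per well with columns `n_empty,n_nhej,n_wt_plus,n_hdr_plus`
#' (optional `n_anomalous` and identifier columns, which are preserved).
#'
#' @param path CSV path.
#' @return `read_cluster_counts_csv()` returns a named list of
#'   [cluster_counts()] (names from a `well_id` column when present).
#' @export
read_cluster_counts_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("n_empty", "n_nhej", "n_wt_plus", "n_hdr_plus")
  if (!all(need %in% names(df)))
    stop("cluster-count CSV must have columns ",
         paste(need, collapse = ", "))
  if (!"n_anomalous" %in% names(df)) df$n_anomalous <- 0L
  out <- lapply(seq_len(nrow(df)), function(i)
    cluster_counts(df$n_empty[i], df$n_nhej[i], df$n_wt_plus[i],
                   df$n_hdr_plus[i], df$n_anomalous[i]))
  names(out) <- if ("well_id" %in% names(df)) as.character(df$well_id)
                else as.character(seq_len(nrow(df)))
  out
}

#' @rdname read_cluster_counts_csv
#' @param counts A [cluster_counts()], a list of them, or a list of
#'   [assign_clusters()] results.
#' @export
write_cluster_counts_csv <- function(counts, path) {
  if (inherits(counts, c("cluster_counts", "gated_well")))
    counts <- list(counts)
  rows <- lapply(seq_along(counts), function(i) {
    x <- counts[[i]]
    wid <- names(counts)[i] %||% ""
    if (inherits(x, "gated_well")) {
      wid <- x$well_id
      x <- x$counts
    }
    cbind(data.frame(well_id = if (nzchar(wid)) wid else as.character(i)),
          as.data.frame(x))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write a quantification results table
#'
#' @param results A [quantify_classes()] estimate, or a named list of them
#'   (names become the `sample` column).
#' @param path Output path; format chosen by extension (`.csv` or
#'   `.json`).
#' @return The assembled data frame, invisibly.
#' @export
write_results <- function(results, path) {
  if (inherits(results, "quant_estimate")) results <- list(sample = results)
  df <- do.call(rbind, lapply(names(results), function(nm) {
    cbind(data.frame(sample = nm), as.data.frame(results[[nm]]))
  }))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(df)
}

#' Read a structured run configuration
#'
#' Configurations are YAML mappings; see [run_pipeline()] for the
#' recognized keys.
#'
#' @param path YAML file path.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping")
  cfg
}
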