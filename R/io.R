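#' Write an effect table to CSV with a metadata sidecar
#'
#' One row per effect (\code{effect_id, r, p, n, label,
#' is_true_effect}); generation parameters go to a plain key-value
#' sidecar at \code{<path>.meta.txt}.
#'
#' @param tab An [effect_table()].
#' @param path Output CSV path.
#' @param meta Named list of metadata values (seed, generator settings,
#'   scenario parameters, ...).
#' @return \code{path}, invisibly.
#' @export
write_effect_table <- function(tab, path, meta = list()) {
  stopifnot(inherits(tab, "effect_table"))
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  if (length(meta)) {
    writeLines(paste0(names(meta), "=",
                      vapply(meta, function(v)
                        paste(format(v, digits = 15), collapse = ","),
                        character(1))),
               paste0(path, ".meta.txt"))
  }
  invisible(path)
}

#' Read an effect table written by [write_effect_table()]
#'
#' @param path CSV path.
#' @return An [effect_table()]; the sidecar, if present, is attached as
#'   attribute \code{"meta"} (named character vector).
#' @export
read_effect_table <- function(path) {
  d <- utils::read.csv(path)
  mask <- if (all(is.na(d$is_true_effect))) NULL else as.logical(d$is_true_effect)
  tab <- effect_table(r = d$r, p = d$p, n = d$n[1], label = d$label[1],
                      effect_id = d$effect_id, is_true_effect = mask)
  side <- paste0(path, ".meta.txt")
  if (file.exists(side)) {
    kv <- strsplit(readLines(side), "=", fixed = TRUE)
    meta <- vapply(kv, `[`, character(1), 2)
    names(meta) <- vapply(kv, `[`, character(1), 1)
    attr(tab, "meta") <- meta
  }
  tab
}

# Write a record data frame as CSV with a versioned comment header.
write_records_csv <- function(df, path, config) {
  ver <- as.character(utils::packageVersion("rwrbias"))
  header <- sprintf("# rwrbias %s config_hash=%s", ver,
                    config_hash(config))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, qmethod = "double")
  invisible(path)
}

#' Read a record CSV written by the pipeline
#'
#' @param path CSV path (with a leading \code{#} header line).
#' @return Data frame of records.
#' @export
read_records_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}
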