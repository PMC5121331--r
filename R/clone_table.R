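#' Clone tables
#'
#' The clone table is the input boundary of the package: one row per
#' (clone, generation, quiescence state, timepoint) with a cell count, as
#' produced upstream by multiplex division-tracking flow cytometry after
#' gating.  Columns:
#'
#' * `experiment_id` -- experiment label,
#' * `condition` -- stimulation condition label,
#' * `timepoint_h` -- harvest time in hours (> 0),
#' * `clone_id` -- clonal family identifier (maps to exactly one condition),
#' * `generation` -- 0-based division number (founder = 0),
#' * `n_cells` -- positive integer count of cells in the row,
#' * `quiescent` -- 1 if the cells have reached division destiny (small cell
#'   size), 0 if still dividing.
#'
#' Two attributes carry assay metadata: `sampling_prob`, a named vector of
#' per-condition cell recovery probabilities r in (0, 1\], and
#' `founder_input`, a named vector of founder cells plated per condition.
#'
#' @param records data frame with the columns above (`experiment_id`
#'   optional).
#' @param sampling_prob named numeric vector, condition -> recovery
#'   probability r.
#' @param founder_input named numeric vector, condition -> founder count.
#' @return a `clone_table` (a validated data frame).
#' @export
clone_table <- function(records, sampling_prob = NULL, founder_input = NULL) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (is.null(records$experiment_id)) records$experiment_id <- "exp1"
  req <- c("experiment_id", "condition", "timepoint_h", "clone_id",
           "generation", "n_cells", "quiescent")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("clone table is missing columns: ", paste(miss, collapse = ", "))
  records <- records[req]
  records$quiescent <- as.integer(records$quiescent)
  bad <- which(
    !is.finite(records$generation) | records$generation < 0 |
      records$generation != round(records$generation) |
      !is.finite(records$n_cells) | records$n_cells < 1 |
      records$n_cells != round(records$n_cells) |
      !is.finite(records$timepoint_h) | records$timepoint_h <= 0 |
      !(records$quiescent %in% c(0L, 1L)))
  if (length(bad))
    stop("invalid clone-table rows (generation must be a non-negative integer, ",
         "n_cells a positive integer, timepoint_h > 0, quiescent 0/1) at row(s): ",
         paste(utils::head(bad, 20), collapse = ", "))
  cond_per_clone <- tapply(records$condition, records$clone_id,
                           function(z) length(unique(z)))
  if (any(cond_per_clone > 1))
    stop("clone_id must map to exactly one condition; offending clone(s): ",
         paste(utils::head(names(cond_per_clone)[cond_per_clone > 1], 5),
               collapse = ", "))
  if (!is.null(sampling_prob)) {
    if (any(sampling_prob <= 0 | sampling_prob > 1))
      stop("sampling probabilities r must lie in (0, 1]")
  }
  structure(records,
            sampling_prob = sampling_prob,
            founder_input = founder_input,
            class = c("clone_table", "data.frame"))
}

#' Read and write clone tables as TSV
#'
#' The on-disk dialect is UTF-8 tab-separated values with a mandatory header
#' row and '.' as decimal mark.  Leading comment lines prefixed `#` embed the
#' assay metadata (`# sampling_prob <condition>=<r>` and
#' `# founder_input <condition>=<n>`) so a written table round-trips through
#' `read_clone_table` unchanged.  Malformed rows are reported with their line
#' numbers.
#'
#' @param path file path.
#' @return `read_clone_table` returns a [clone_table()].
#' @export
read_clone_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  is_comment <- grepl("^#", lines)
  meta <- lines[is_comment]
  body <- lines[!is_comment]
  if (length(body) < 1) stop("clone-table file has no header row: ", path)
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          stringsAsFactors = FALSE)
  parse_meta <- function(tag) {
    rows <- grep(paste0("^#\\s*", tag, "\\s"), meta, value = TRUE)
    if (!length(rows)) return(NULL)
    kv <- sub(paste0("^#\\s*", tag, "\\s+"), "", rows)
    vals <- as.numeric(sub("^.*=", "", kv))
    names(vals) <- sub("=.*$", "", kv)
    vals
  }
  # map data-frame rows back to physical line numbers for error reporting
  body_line_no <- which(!is_comment)[-1L]  # first body line is the header
  tab <- tryCatch(
    clone_table(df, sampling_prob = parse_meta("sampling_prob"),
                founder_input = parse_meta("founder_input")),
    error = function(e) {
      msg <- conditionMessage(e)
      m <- regmatches(msg, regexec("row\\(s\\): ([0-9, ]+)", msg))[[1]]
      if (length(m) == 2) {
        rows <- as.integer(strsplit(m[2], ",\\s*")[[1]])
        stop("in ", path, ": ", sub("at row\\(s\\):.*$", "", msg),
             "at line(s): ", paste(body_line_no[rows], collapse = ", "),
             call. = FALSE)
      }
      stop("in ", path, ": ", msg, call. = FALSE)
    })
  tab
}

#' @rdname read_clone_table
#' @param x a [clone_table()].
#' @export
write_clone_table <- function(x, path) {
  stopifnot(inherits(x, "clone_table"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  fmt <- function(tag, v) {
    if (is.null(v)) return(character(0))
    paste0("# ", tag, " ", names(v), "=", format(v, digits = 15, trim = TRUE))
  }
  writeLines(c(fmt("sampling_prob", attr(x, "sampling_prob")),
               fmt("founder_input", attr(x, "founder_input"))), con)
  utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
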