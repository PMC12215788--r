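# Tab-separated interchange. All tables travel as TSV with a header row so
# every stage's inputs and outputs are language-neutral and diff-able.

#' Write a table as TSV
#'
#' @param x data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a TSV with required columns
#'
#' @param path Input path.
#' @param required Column names that must be present.
#' @return data.frame.
#' @export
read_tsv <- function(path, required = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                  check.names = FALSE)
  if (!is.null(required)) {
    missing <- setdiff(required, names(x))
    if (length(missing)) {
      stop("file ", path, " is missing column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  x
}

#' Read a long-format time-series panel TSV
#'
#' @param path Panel TSV with columns `subject`, `video`, `region`,
#'   `timepoint`, `value`.
#' @return `ts_panel`.
#' @export
read_panel_tsv <- function(path) {
  as_ts_panel(read_tsv(path, c("subject", "video", "region", "timepoint",
                               "value")))
}

#' Validate the pipeline's input files
#'
#' Runs per-file schema and range checks plus cross-file consistency checks
#' (every panel subject has attributes; every rated subject appears in the
#' panel), and returns one pass/fail line per check.
#'
#' @param paths Named list/vector with any of `panel`, `ratings`,
#'   `attributes` paths.
#' @return data.frame of class `validation_report`: `file`, `check`,
#'   `pass`, `detail`.
#' @export
validate_inputs <- function(paths) {
  lines <- list()
  note <- function(file, check, pass, detail = "") {
    lines[[length(lines) + 1L]] <<- data.frame(
      file = file, check = check, pass = pass, detail = detail,
      stringsAsFactors = FALSE)
  }
  read_checked <- function(name, required) {
    path <- paths[[name]]
    if (is.null(path)) return(NULL)
    if (!file.exists(path)) {
      stop("unreadable file for '", name, "': ", path, call. = FALSE)
    }
    x <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    missing <- setdiff(required, names(x))
    note(name, "schema: required columns", length(missing) == 0L,
         if (length(missing)) paste("missing:", paste(missing,
                                                      collapse = ", "))
         else "")
    if (length(missing)) return(NULL)
    x
  }

  panel <- read_checked("panel", c("subject", "video", "region",
                                   "timepoint", "value"))
  ratings <- read_checked("ratings", c("subject", "video", "rating"))
  attrs <- read_checked("attributes", c("subject", "age", "gender",
                                        "country"))

  if (!is.null(panel)) {
    note("panel", "values finite", all(is.finite(panel$value)), "")
    len <- aggregate(timepoint ~ subject + video + region, data = panel,
                     FUN = length)
    eq <- all(unlist(lapply(split(len$timepoint, len$video),
                            function(l) length(unique(l)) == 1L)))
    note("panel", "equal series lengths within video", eq, "")
  }
  if (!is.null(ratings)) {
    ok <- all(ratings$rating %in% 1:5)
    note("ratings", "ratings are integers in 1..5", ok,
         if (!ok) paste("offending values:",
                        paste(unique(ratings$rating[
                          !ratings$rating %in% 1:5]), collapse = ", "))
         else "")
    note("ratings", "unique (subject, video)",
         !anyDuplicated(ratings[c("subject", "video")]), "")
  }
  if (!is.null(attrs)) {
    note("attributes", "unique subjects", !anyDuplicated(attrs$subject), "")
    note("attributes", "positive ages",
         all(!is.na(attrs$age) & attrs$age > 0), "")
  }
  if (!is.null(panel) && !is.null(attrs)) {
    missing <- setdiff(unique(panel$subject), attrs$subject)
    note("attributes", "covers all panel subjects", length(missing) == 0L,
         if (length(missing)) paste("missing:",
                                    paste(missing, collapse = ", "))
         else "")
  }
  if (!is.null(panel) && !is.null(ratings)) {
    missing <- setdiff(unique(ratings$subject), unique(panel$subject))
    note("panel", "covers all rated subjects", length(missing) == 0L,
         if (length(missing)) paste("absent from panel:",
                                    paste(missing, collapse = ", "))
         else "")
  }
  report <- do.call(rbind, lines)
  class(report) <- c("validation_report", class(report))
  report
}

#' @export
print.validation_report <- function(x, ...) {
  for (i in seq_len(nrow(x))) {
    cat(sprintf("[%s] %s: %s%s\n", if (x$pass[i]) "PASS" else "FAIL",
                x$file[i], x$check[i],
                if (nzchar(x$detail[i])) paste0(" (", x$detail[i], ")")
                else ""))
  }
  invisible(x)
}
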