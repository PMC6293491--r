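#' Read a DREAM4-layout time-series expression file
#'
#' Tab-delimited text: a header row whose first field is a time label
#' followed by gene identifiers, then one row per measurement. Several
#' independent perturbation series may be stacked in one file; a new
#' series starts at a blank line or wherever the time value resets to at
#' most the previous row's time (both dialects occur in the wild).
#'
#' @param path file path.
#' @return An [expression_dataset].
#' @export
read_timeseries <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty file: ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L)
    stop("line 1: header must hold a time label plus gene identifiers")
  genes <- header[-1L]
  if (anyDuplicated(genes))
    stop("line 1: duplicate gene identifiers: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  nfield <- length(header)
  series <- list(); times <- list()
  cur <- NULL; cur_t <- numeric(0)
  flush <- function() {
    if (!is.null(cur) && nrow(cur) > 0L) {
      series[[length(series) + 1L]] <<- cur
      times[[length(times) + 1L]] <<- cur_t
    }
    cur <<- NULL; cur_t <<- numeric(0)
  }
  for (ln in seq_along(lines)[-1L]) {
    raw <- lines[ln]
    if (!nzchar(trimws(raw))) { flush(); next }
    fields <- strsplit(raw, "\t", fixed = TRUE)[[1L]]
    if (length(fields) != nfield)
      stop("line ", ln, ": expected ", nfield, " fields, found ",
           length(fields))
    vals <- suppressWarnings(as.numeric(fields))
    if (any(is.na(vals)))
      stop("line ", ln, ": non-numeric value '",
           fields[which(is.na(vals))[1L]], "'")
    t <- vals[1L]
    if (length(cur_t) > 0L && t <= cur_t[length(cur_t)]) flush()
    cur <- rbind(cur, vals[-1L])
    cur_t <- c(cur_t, t)
  }
  flush()
  if (length(series) == 0L) stop("no data rows in ", path)
  series <- lapply(series, function(m) { colnames(m) <- genes; m })
  expression_dataset(series, genes = genes, times = times)
}

#' Read a DREAM4-layout gold-standard edge list
#'
#' Three tab-delimited columns `regulator  target  indicator`: indicator 1
#' declares a directed edge, 0 an explicit non-edge (recorded, treated in
#' scoring like any absent pair). Contradictory duplicate rows are an
#' error.
#'
#' @param path file path.
#' @return A [gene_network]; explicit non-edges are kept in its
#'   `known_absent` element.
#' @export
read_gold_standard <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  reg <- tgt <- character(length(lines)); ind <- integer(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("line ", i, ": expected 3 tab-delimited fields")
    v <- suppressWarnings(as.integer(f[3L]))
    if (is.na(v) || !(v %in% c(0L, 1L)))
      stop("line ", i, ": edge indicator must be 0 or 1, found '",
           f[3L], "'")
    reg[i] <- f[1L]; tgt[i] <- f[2L]; ind[i] <- v
  }
  key <- paste(reg, tgt, sep = "\r")
  for (k in unique(key[duplicated(key)])) {
    if (length(unique(ind[key == k])) > 1L)
      stop("contradictory duplicate rows for pair ",
           sub("\r", " -> ", k, fixed = TRUE))
  }
  first <- !duplicated(key)
  reg <- reg[first]; tgt <- tgt[first]; ind <- ind[first]
  genes <- sort(unique(c(reg, tgt)))
  gene_network(data.frame(regulator = reg[ind == 1L],
                          target = tgt[ind == 1L],
                          stringsAsFactors = FALSE),
               genes = genes,
               known_absent = data.frame(regulator = reg[ind == 0L],
                                         target = tgt[ind == 0L],
                                         stringsAsFactors = FALSE))
}

#' Write a directed network as a gold-standard-style edge list
#'
#' Emits `regulator<TAB>target<TAB>1` lines, edges sorted lexicographically
#' by (regulator, target), newline-terminated; round-trips through
#' [read_gold_standard()]. An empty network yields an empty file.
#'
#' @param network a [gene_network].
#' @param path output file path.
#' @param header write a header line (off by default, matching the DREAM4
#'   dialect).
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, header = FALSE) {
  e <- network$edges
  e <- e[order(e$regulator, e$target), , drop = FALSE]
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (header) writeLines("regulator\ttarget\tedge", con)
  if (nrow(e))
    writeLines(paste(e$regulator, e$target, "1", sep = "\t"), con)
  invisible(path)
}

#' Write a time-series dataset in the DREAM4 layout
#'
#' Inverse of [read_timeseries()]: header `Time` + gene names, series
#' separated by a blank line, values formatted with full precision.
#'
#' @param dataset an [expression_dataset].
#' @param path output file path.
#' @param digits significant digits for expression values (default 6).
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(dataset, path, digits = 6) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("Time", dataset$genes), collapse = "\t"), con)
  for (s in seq_along(dataset$series)) {
    m <- dataset$series[[s]]
    rows <- vapply(seq_len(nrow(m)), function(i)
      paste(c(format(dataset$times[[s]][i]),
              formatC(m[i, ], digits = digits, format = "g")),
            collapse = "\t"), character(1))
    writeLines(rows, con)
    if (s < length(dataset$series)) writeLines("", con)
  }
  invisible(path)
}
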