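#' File format codecs
#'
#' Readers and writers for the plain-text interchange formats the pipeline
#' consumes and emits: BED3/BED6, narrowPeak (10 column), JASPAR-style PFM,
#' FASTA (via Biostrings), expression/count matrices as TSV, and survival
#' tables as CSV. Readers tolerate `track` and `browser` lines; malformed
#' lines raise an error naming the line number. Writers emit sorted,
#' tab-delimited, newline-terminated output.
#'
#' @name chromstrat-io
NULL

bed_data_lines <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  list(lines = lines[keep], numbers = which(keep))
}

parse_bed_fields <- function(path, min_fields) {
  dl <- bed_data_lines(path)
  fields <- strsplit(dl$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < min_fields)) {
    bad <- dl$numbers[which(nf < min_fields)[1]]
    abort(sprintf("malformed line %d in %s: expected >= %d tab-separated fields",
                  bad, path, min_fields))
  }
  starts <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  ends <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(!is.finite(starts) | !is.finite(ends))
  if (length(bad)) {
    abort(sprintf("malformed line %d in %s: non-numeric coordinates",
                  dl$numbers[bad[1]], path))
  }
  list(fields = fields, starts = starts, ends = ends, numbers = dl$numbers)
}

#' Read / write BED intervals
#'
#' @param path file path.
#' @return `read_bed()` returns a tibble with `chrom`, `start`, `end`
#'   (0-based half-open) and, when present, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  p <- parse_bed_fields(path, 3L)
  out <- tibble(
    chrom = vapply(p$fields, `[`, "", 1L),
    start = as.integer(p$starts),
    end = as.integer(p$ends)
  )
  nf <- lengths(p$fields)
  if (all(nf >= 6L)) {
    out$name <- vapply(p$fields, `[`, "", 4L)
    out$score <- suppressWarnings(as.numeric(vapply(p$fields, `[`, "", 5L)))
    out$strand <- vapply(p$fields, `[`, "", 6L)
  }
  out
}

#' @rdname read_bed
#' @param x interval tibble with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @export
write_bed <- function(x, path) {
  x <- x[radix_order(x$chrom, x$start, x$end), , drop = FALSE]
  cols <- c("chrom", "start", "end")
  if (all(c("name", "score", "strand") %in% names(x))) {
    cols <- c(cols, "name", "score", "strand")
  }
  data.table::fwrite(x[cols], path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write narrowPeak summit calls
#'
#' The 10-column ENCODE narrowPeak layout; column 10 is the summit offset
#' from `start` (-1 means missing and is mapped to `NA` with a warning).
#'
#' @param path file path.
#' @return tibble with `chrom`, `start`, `end`, `name`, `score`, `strand`,
#'   `signal`, `pvalue`, `qvalue`, `summit` (absolute 0-based position).
#' @export
read_narrowpeak <- function(path) {
  p <- parse_bed_fields(path, 10L)
  f <- p$fields
  offset <- as.integer(vapply(f, `[`, "", 10L))
  if (any(offset < 0)) {
    warn(sprintf("%d narrowPeak records in %s have summit offset -1; summit set to NA",
                 sum(offset < 0), path))
  }
  start <- as.integer(p$starts)
  tibble(
    chrom = vapply(f, `[`, "", 1L),
    start = start,
    end = as.integer(p$ends),
    name = vapply(f, `[`, "", 4L),
    score = as.numeric(vapply(f, `[`, "", 5L)),
    strand = vapply(f, `[`, "", 6L),
    signal = as.numeric(vapply(f, `[`, "", 7L)),
    pvalue = as.numeric(vapply(f, `[`, "", 8L)),
    qvalue = as.numeric(vapply(f, `[`, "", 9L)),
    summit = ifelse(offset < 0, NA_integer_, start + offset)
  )
}

#' @rdname read_narrowpeak
#' @param x summit tibble; needs `chrom`, `start`, `end`, `score`, `summit`.
#' @export
write_narrowpeak <- function(x, path) {
  x <- x[radix_order(x$chrom, x$start, x$end), , drop = FALSE]
  out <- data.table::data.table(
    chrom = x$chrom, start = x$start, end = x$end,
    name = col_or(x, "name", sprintf("peak_%d", seq_len(nrow(x)))),
    score = x$score,
    strand = col_or(x, "strand", "."),
    signal = col_or(x, "signal", x$score),
    pvalue = col_or(x, "pvalue", -1),
    qvalue = col_or(x, "qvalue", -1),
    offset = ifelse(is.na(x$summit), -1L, x$summit - x$start)
  )
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write JASPAR-style position frequency matrices
#'
#' Accepts records of the form `>name` followed by four rows (A, C, G, T),
#' with or without `A [ ... ]` brackets.
#'
#' @param path file path.
#' @return a named list of base x position count matrices
#'   (rows A, C, G, T).
#' @export
read_jaspar_pfm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (!length(heads)) abort(sprintf("no '>' records in %s", path))
  out <- list()
  for (i in seq_along(heads)) {
    from <- heads[i] + 1L
    to <- if (i < length(heads)) heads[i + 1] - 1L else length(lines)
    body <- lines[from:to]
    if (length(body) != 4L) {
      abort(sprintf("malformed PFM record at line %d in %s: expected 4 base rows",
                    heads[i], path))
    }
    rows <- lapply(seq_along(body), function(j) {
      clean <- gsub("^[ACGTacgt]?\\s*\\[?", "", body[j])
      clean <- gsub("\\]\\s*$", "", clean)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(clean), "\\s+")[[1]]))
      if (any(!is.finite(vals))) {
        abort(sprintf("malformed line %d in %s: non-numeric PFM counts",
                      from + j - 1L, path))
      }
      vals
    })
    if (length(unique(lengths(rows))) != 1L) {
      abort(sprintf("malformed PFM record at line %d in %s: ragged rows", heads[i], path))
    }
    m <- do.call(rbind, rows)
    rownames(m) <- c("A", "C", "G", "T")
    name <- sub("^>\\s*", "", lines[heads[i]])
    out[[strsplit(name, "\\s+")[[1]][1]]] <- m
  }
  out
}

#' @rdname read_jaspar_pfm
#' @param pfms named list of 4 x width count matrices.
#' @export
write_jaspar_pfm <- function(pfms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (name in names(pfms)) {
    m <- pfms[[name]]
    writeLines(paste0(">", name), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(sprintf("%s [ %s ]", b, paste(m[b, ], collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read / write FASTA sequences
#'
#' Thin wrappers over Biostrings handling multi-line records and N bases.
#'
#' @param path file path.
#' @return a [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname read_fasta
#' @param x a `DNAStringSet` (or named character vector of sequences).
#' @export
write_fasta <- function(x, path) {
  if (!methods::is(x, "DNAStringSet")) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read / write a numeric matrix as TSV
#'
#' First column holds row ids (regions or genes); the header row holds
#' sample ids.
#'
#' @param path file path.
#' @return a numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  m
}

#' @rdname read_matrix_tsv
#' @param x numeric matrix with dimnames.
#' @param id_name header for the row-id column.
#' @export
write_matrix_tsv <- function(x, path, id_name = "id") {
  dt <- data.table::data.table(id = rownames(x))
  data.table::setnames(dt, "id", id_name)
  dt <- cbind(dt, data.table::as.data.table(x))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read / write a survival table as CSV
#'
#' Columns: `sample` identifier, `time` (follow-up, arbitrary units),
#' `event` (1 death observed, 0 censored).
#'
#' @param path file path.
#' @return tibble with `sample`, `time`, `event`.
#' @export
read_survival_csv <- function(path) {
  dt <- data.table::fread(path, sep = ",", header = TRUE)
  need <- c("sample", "time", "event")
  if (!all(need %in% names(dt))) {
    abort(sprintf("survival table %s must have columns: %s",
                  path, paste(need, collapse = ", ")))
  }
  if (any(dt$time <= 0)) abort(sprintf("non-positive follow-up time in %s", path))
  if (!all(dt$event %in% c(0, 1))) abort(sprintf("event must be 0/1 in %s", path))
  as_tibble(dt[, need, with = FALSE])
}

#' @rdname read_survival_csv
#' @param x tibble with `sample`, `time`, `event`.
#' @export
write_survival_csv <- function(x, path) {
  data.table::fwrite(x[, c("sample", "time", "event")], path, sep = ",", quote = FALSE)
  invisible(path)
}
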