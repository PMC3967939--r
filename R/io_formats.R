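# Readers/writers for the external representations: TSV signal and call
# matrices, per-factor BED, model JSON, standards TSV. All coordinates
# are 0-based half-open.

#' Read a continuous signal matrix
#'
#' TSV dialect: header `chrom start end <factor...>`, one row per bin,
#' 0-based half-open coordinates, empty fields or `NA` for missing
#' values, optional `coverage` column. bedGraph dialect: a set of
#' per-factor bedGraph files mapped onto a user-supplied bin grid (each
#' track averaged over the overlap with each bin).
#'
#' @param path TSV file (tsv dialect) or named character vector of
#'   bedGraph paths, names = factor names (bedgraph-set dialect).
#' @param dialect `"tsv"` or `"bedgraph-set"`.
#' @param bins bin grid data.frame (`chrom`, `start`, `end`), required
#'   for the bedgraph-set dialect.
#' @return a [signal_matrix()] with rows sorted by (chrom, start).
#' @export
read_signal_matrix <- function(path, dialect = c("tsv", "bedgraph-set"),
                               bins = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "bedgraph-set") {
    return(read_bedgraph_set(path, bins))
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 4 ||
      !identical(tolower(names(tab)[1:3]), c("chrom", "start", "end"))) {
    stop("expected header 'chrom start end <factor...>' in ", path)
  }
  fac_cols <- setdiff(names(tab)[-(1:3)], "coverage")
  if (anyDuplicated(fac_cols)) {
    stop("duplicated factor names in header of ", path)
  }
  if (!is.numeric(tab$start) || !is.numeric(tab$end) ||
      anyNA(tab$start) || anyNA(tab$end)) {
    bad <- which(is.na(suppressWarnings(as.numeric(tab$start))) |
                   is.na(suppressWarnings(as.numeric(tab$end))))[1]
    stop("malformed coordinates at data line ", bad, " of ", path)
  }
  bad <- which(tab$start >= tab$end)
  if (length(bad)) {
    stop("start >= end at data line ", bad[1], " of ", path)
  }
  for (f in fac_cols) {
    if (!is.numeric(tab[[f]]) && !all(is.na(tab[[f]]))) {
      bad <- which(!is.na(tab[[f]]) &
                     is.na(suppressWarnings(as.numeric(tab[[f]]))))[1]
      stop("non-numeric value for factor '", f, "' at data line ", bad,
           " of ", path)
    }
  }
  key <- paste(tab$chrom, tab$start)
  if (anyDuplicated(key)) {
    stop("duplicated bin at data line ", which(duplicated(key))[1],
         " of ", path)
  }
  ord <- order(tab$chrom, tab$start)
  tab <- tab[ord, , drop = FALSE]
  vals <- as.matrix(tab[, fac_cols, drop = FALSE])
  signal_matrix(tab[, 1:3], vals,
                coverage = if ("coverage" %in% names(tab)) tab$coverage)
}

read_bedgraph_set <- function(paths, bins) {
  if (is.null(bins)) stop("bedgraph-set dialect needs a bin grid")
  if (is.null(names(paths)) || any(names(paths) == "")) {
    stop("bedgraph paths must be named by factor")
  }
  bins <- bins[order(bins$chrom, bins$start), , drop = FALSE]
  vals <- matrix(NA_real_, nrow(bins), length(paths),
                 dimnames = list(NULL, names(paths)))
  for (f in names(paths)) {
    bg <- utils::read.delim(paths[[f]], header = FALSE,
                            comment.char = "#",
                            col.names = c("chrom", "start", "end",
                                          "value"))
    for (ch in unique(bins$chrom)) {
      bi <- which(bins$chrom == ch)
      gi <- which(bg$chrom == ch)
      if (!length(gi)) next
      for (b in bi) {
        ov <- pmin(bg$end[gi], bins$end[b]) -
          pmax(bg$start[gi], bins$start[b])
        use <- ov > 0
        if (any(use)) {
          vals[b, f] <- sum(bg$value[gi][use] * ov[use]) / sum(ov[use])
        }
      }
    }
  }
  signal_matrix(bins, vals)
}

#' Write a signal matrix as TSV
#'
#' @param signal a [signal_matrix()].
#' @param path output file.
#' @export
write_signal_matrix <- function(signal, path) {
  tab <- cbind(signal$bins,
               as.data.frame(signal$values, check.names = FALSE))
  if (any(signal$coverage != 1)) tab$coverage <- signal$coverage
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write binary calls: per-factor BED plus a combined TSV
#'
#' One BED file per factor (named `<prefix><factor>.bed`, 0-based
#' half-open, rows with call = 1; created even when empty) plus a
#' combined `chrom start end <factor...>` TSV at `<prefix>calls.tsv`.
#'
#' @param code a [chromatin_code()].
#' @param prefix output path prefix (directory must exist).
#' @return invisibly, the vector of files written.
#' @export
write_binary_calls <- function(code, prefix) {
  files <- character(0)
  for (f in code$factors) {
    p <- paste0(prefix, gsub("[^A-Za-z0-9._-]", "_", f), ".bed")
    on_rows <- code$calls[, f] == 1L
    bed <- code$bins[on_rows, , drop = FALSE]
    # write an empty file too, so every factor leaves an artifact
    utils::write.table(bed, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    files <- c(files, p)
  }
  p <- paste0(prefix, "calls.tsv")
  tab <- cbind(code$bins, as.data.frame(code$calls, check.names = FALSE))
  utils::write.table(tab, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(files, p))
}

#' Read a combined binary-call TSV
#'
#' @param path a file written by [write_binary_calls()] (the combined
#'   TSV).
#' @return a [chromatin_code()].
#' @export
read_binary_calls <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE,
                           stringsAsFactors = FALSE)
  chromatin_code(tab[, 1:3],
                 as.matrix(tab[, -(1:3), drop = FALSE]))
}

#' Serialize a model to JSON / read it back
#'
#' The JSON document lists the factor names and the sparse nonzero
#' `h`/`J`/`K` entries keyed by (sorted) factor-name tuples, plus the
#' optional `logZ`. Keys are emitted in sorted order and zero-valued
#' entries are dropped, so output is byte-stable and canonical.
#'
#' @param model a [maxent_model()].
#' @param path JSON file path.
#' @return `write_maxent_model` invisibly returns `path`;
#'   `read_maxent_model` returns the [maxent_model()].
#' @export
write_maxent_model <- function(model, path) {
  f <- model$factors
  hs <- model$h[model$h != 0]
  hs <- hs[order(names(hs))]
  jkey <- paste(f[model$J$i], f[model$J$j], sep = "|")
  kkey <- paste(f[model$K$i], f[model$K$j], f[model$K$k], sep = "|")
  # sort member names inside each key, then the keys themselves
  sort_key <- function(keys) {
    vapply(strsplit(keys, "|", fixed = TRUE),
           function(p) paste(sort(p), collapse = "|"), character(1))
  }
  jkey <- sort_key(jkey)
  kkey <- sort_key(kkey)
  jo <- order(jkey)
  ko <- order(kkey)
  doc <- list(
    factors = f,
    order = model$order,
    hierarchy = model$hierarchy_flag,
    h = as.list(hs),
    J = stats::setNames(as.list(model$J$value[jo]), jkey[jo]),
    K = stats::setNames(as.list(model$K$value[ko]), kkey[ko]))
  if (!is.null(model$logZ)) doc$logZ <- model$logZ
  # I(17) significant digits: doubles survive the round-trip bit-exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_maxent_model
#' @export
read_maxent_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  f <- unlist(doc$factors)
  split_key <- function(keys, n_members, what) {
    if (!length(keys)) {
      return(matrix(integer(0), 0, n_members))
    }
    parts <- strsplit(keys, "|", fixed = TRUE)
    idx <- t(vapply(parts, function(p) {
      m <- match(p, f)
      if (anyNA(m)) {
        stop(what, " entry references unknown factor: ",
             paste(p[is.na(m)], collapse = ", "))
      }
      sort(m)
    }, integer(n_members)))
    idx
  }
  hn <- names(doc$h)
  if (length(hn) && anyNA(match(hn, f))) {
    stop("h entry references unknown factor")
  }
  ji <- split_key(names(doc$J), 2L, "J")
  ki <- split_key(names(doc$K), 3L, "K")
  maxent_model(
    f,
    h = stats::setNames(unlist(doc$h), hn),
    J = if (nrow(ji)) data.frame(i = ji[, 1], j = ji[, 2],
                                 value = unlist(doc$J, use.names = FALSE)),
    K = if (nrow(ki)) data.frame(i = ki[, 1], j = ki[, 2], k = ki[, 3],
                                 value = unlist(doc$K, use.names = FALSE)),
    logZ = doc$logZ,
    order = doc$order,
    hierarchy_flag = isTRUE(doc$hierarchy))
}

#' Read / write an interaction evaluation standard
#'
#' Two-column TSV of factor-name pairs (no header required; a header
#' line `factor_a factor_b` is tolerated and written).
#'
#' @param path TSV file.
#' @return an [evaluation_standard()].
#' @export
read_standards <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("^factor_a\tfactor_b", first)
  tab <- utils::read.delim(path, header = has_header, sep = "\t",
                           stringsAsFactors = FALSE)
  evaluation_standard(tab[, 1:2])
}

#' @rdname read_standards
#' @param standard an [evaluation_standard()].
#' @export
write_standards <- function(standard, path) {
  utils::write.table(standard$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
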