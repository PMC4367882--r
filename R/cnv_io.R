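#' Read per-sample CNV calls from a BED-like file
#'
#' Expected columns (tab-separated, no header): chrom, start, end (BED
#' 0-based half-open), sample_id, state (`loss`/`gain` or `del`/`dup`),
#' and optionally an algorithm label.  Records with `end <= start` are
#' rejected with a line-numbered diagnostic; exact duplicates (same
#' sample, coordinates and state) are collapsed with a warning.
#'
#' @param path Path to the BED-like file.
#' @param group Cohort group label for every call (`"case"`/`"control"`).
#' @param algorithm Calling-algorithm label applied when the file has no
#'   algorithm column.
#' @param build Genome build tag.
#' @return A data frame of class `cnv_calls` with columns `chrom`,
#'   `start`, `end`, `sample_id`, `state`, `algorithm`, `group`.
#' @export
read_cnv_calls <- function(path, group = "case", algorithm = "A",
                           build = "unknown") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  keep <- !grepl("^(#|track|browser)", lines)
  rows <- list()
  dropped <- 0L
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 5) {
      warning(sprintf("line %d: record rejected (need >= 5 columns)", i),
              call. = FALSE)
      next
    }
    start <- suppressWarnings(as.numeric(f[2]))
    end <- suppressWarnings(as.numeric(f[3]))
    if (is.na(start) || is.na(end) || end <= start) {
      warning(sprintf("line %d: record rejected (end <= start)", i),
              call. = FALSE)
      dropped <- dropped + 1L
      next
    }
    state <- c(loss = "loss", del = "loss", deletion = "loss",
               gain = "gain", dup = "gain", duplication = "gain")[tolower(f[5])]
    if (is.na(state)) {
      warning(sprintf("line %d: record rejected (unknown state '%s')",
                      i, f[5]), call. = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = norm_chrom(f[1]), start = start, end = end,
      sample_id = f[4], state = state,
      algorithm = if (length(f) >= 6) f[6] else algorithm,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               sample_id = character(0), state = character(0),
               algorithm = character(0), stringsAsFactors = FALSE)
  out$group <- rep(group, nrow(out))
  key <- paste(out$sample_id, out$chrom, out$start, out$end, out$state,
               out$algorithm)
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate CNV call(s) collapsed",
            call. = FALSE)
    out <- out[!duplicated(key), ]
  }
  rownames(out) <- NULL
  attr(out, "build") <- build
  class(out) <- c("cnv_calls", "data.frame")
  out
}

#' Write CNV calls in the BED-like dialect read by [read_cnv_calls()]
#'
#' @param calls A `cnv_calls` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cnv_calls <- function(calls, path) {
  utils::write.table(
    calls[, c("chrom", "start", "end", "sample_id", "state", "algorithm")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from a BED4 file
#'
#' Columns: chrom, start, end (BED convention), gene symbol.  When a
#' symbol appears on several records (multiple transcripts) the union span
#' per symbol is kept, since all downstream tests are gene-level.
#'
#' @param path Path to the BED4 file.
#' @param build Genome build tag.
#' @return Data frame with columns `symbol`, `chrom`, `start`, `end`.
#' @export
read_gene_models <- function(path, build = "unknown") {
  raw <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 4) stop("gene model BED must have 4 columns")
  g <- data.frame(symbol = raw[[4]], chrom = norm_chrom(raw[[1]]),
                  start = as.numeric(raw[[2]]), end = as.numeric(raw[[3]]),
                  stringsAsFactors = FALSE)
  if (any(g$end <= g$start)) stop("gene model with end <= start")
  out <- do.call(rbind, lapply(split(g, g$symbol), function(d) {
    if (length(unique(d$chrom)) > 1) d <- d[d$chrom == d$chrom[1], ]
    data.frame(symbol = d$symbol[1], chrom = d$chrom[1],
               start = min(d$start), end = max(d$end),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "build") <- build
  out
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then member gene symbols
#' (tab-separated).  Empty sets are dropped with a warning.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors of gene symbols.
#' @export
read_gene_sets <- function(path) {
  sets <- if (requireNamespace("fgsea", quietly = TRUE)) {
    fgsea::gmtPathways(path)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])),
                    vapply(parts, `[`, "", 1))
  }
  sets <- lapply(sets, function(s) unique(s[nzchar(s)]))
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warning("dropping empty gene set(s): ",
            paste(names(sets)[empty], collapse = ", "), call. = FALSE)
    sets <- sets[!empty]
  }
  sets
}

#' Write gene sets as GMT
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  writeLines(vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, ""), path)
  invisible(path)
}
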