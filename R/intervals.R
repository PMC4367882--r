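#' Genomic intervals
#'
#' All coordinates inside the package are 0-based half-open (BED
#' convention): `start` is the 0-based position of the first base, `end` is
#' one past the last base, and `end - start` is the length in bp.  Printed
#' human-genetics coordinates ("chr16:14,956,245-15,028,783") are 1-based
#' inclusive and are converted at I/O boundaries only.
#'
#' @param chrom Chromosome name; normalized to the "chr"-prefixed form.
#' @param start 0-based inclusive start (bp).
#' @param end 0-based exclusive end (bp); must exceed `start`.
#' @param build Genome build tag, a free-form string such as `"hg18"`.
#' @return An object of class `genomic_interval` with fields `chrom`,
#'   `start`, `end`, `build`.
#' @examples
#' gi <- genomic_interval("16", 14956244, 15028783, build = "hg18")
#' interval_length(gi)   # 72539
#' format(gi)            # printed 1-based inclusive form
#' @export
genomic_interval <- function(chrom, start, end, build = "unknown") {
  stopifnot(length(chrom) == 1L, length(start) == 1L, length(end) == 1L)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (is.na(start) || start < 0) stop("interval start must be >= 0")
  if (is.na(end) || end <= start) stop("interval end must exceed start")
  structure(
    list(chrom = norm_chrom(chrom), start = start, end = end,
         build = build),
    class = "genomic_interval"
  )
}

#' @rdname genomic_interval
#' @param x A `genomic_interval`.
#' @export
interval_length <- function(x) {
  stopifnot(inherits(x, "genomic_interval"))
  x$end - x$start
}

#' Convert printed 1-based inclusive coordinates to an internal interval
#'
#' @param chrom Chromosome name.
#' @param first,last 1-based inclusive bounds as printed in the literature.
#' @inheritParams genomic_interval
#' @return A `genomic_interval`; its length equals `last - first + 1`.
#' @export
interval_from_printed <- function(chrom, first, last, build = "unknown") {
  genomic_interval(chrom, first - 1, last, build = build)
}

#' @export
format.genomic_interval <- function(x, ...) {
  sprintf("%s:%s-%s [%s]", x$chrom,
          formatC(x$start + 1, format = "d", big.mark = ","),
          formatC(x$end, format = "d", big.mark = ","),
          x$build)
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat("<genomic_interval> ", format(x), "  (", interval_length(x),
      " bp)\n", sep = "")
  invisible(x)
}

#' Normalize chromosome names to the "chr"-prefixed form
#'
#' `"16"` and `"chr16"` both become `"chr16"`; mitochondrial aliases `"MT"`
#' and `"chrMT"` become `"chrM"`.
#'
#' @param chrom Character vector of chromosome names.
#' @return Character vector of normalized names.
#' @export
norm_chrom <- function(chrom) {
  chrom <- as.character(chrom)
  chrom <- ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))
  chrom[chrom == "chrMT"] <- "chrM"
  chrom
}

## shared helper: run `expr` under a private RNG stream seeded by `seed`,
## restoring the caller's RNG state afterwards.  Keeps every generator a
## pure function of (parameters, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

## comma-joined set columns <-> character vectors
split_field <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ",", fixed = TRUE)[[1]]
}
join_field <- function(x) {
  if (length(x) == 0) "" else paste(x, collapse = ",")
}
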