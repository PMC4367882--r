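#' Annotated variant sets
#'
#' A `variant_set` holds multi-sample SNV/indel calls together with the
#' annotations the prioritization cascade consumes: per-sample genotypes and
#' genotype qualities, population allele frequencies from up to several
#' sources, a functional-impact category, clinical evidence flags and gene
#' symbols.  It is a column-oriented container:
#'
#' * `info` — data frame, one row per (variant, alt allele): `id`, `chrom`,
#'   `start`, `end` (0-based half-open), `ref`, `alt`, `impact`,
#'   `splice_offset` (bp into the intron for splice variants, `NA`
#'   otherwise), `genes` and `clinical_flags` (comma-joined), `caller`.
#' * `gt` — integer matrix (variants x samples) of alternate-allele copy
#'   counts 0/1/2, `NA` for missing calls.
#' * `gq` — numeric matrix of genotype qualities, same shape as `gt`.
#' * `af` — numeric matrix (variants x frequency sources) of population
#'   allele frequencies in \[0, 1\]; `NA` means the variant was not
#'   observed in that source.
#'
#' Multi-allelic records are split into one row per alternate allele before
#' any filtering, so the frequency and impact logic is always per allele.
#'
#' @param info Data frame as described above (missing annotation columns
#'   are filled with defaults).
#' @param gt,gq Genotype and quality matrices; rows must match `info`.
#' @param af Optional allele-frequency matrix.
#' @param build Genome build tag.
#' @return An object of class `variant_set`.
#' @export
variant_set <- function(info, gt, gq, af = NULL, build = "unknown") {
  info <- as.data.frame(info, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "ref", "alt")
  miss <- setdiff(need, names(info))
  if (length(miss))
    stop("variant info is missing columns: ", paste(miss, collapse = ", "))
  info$chrom <- norm_chrom(info$chrom)
  if (is.null(info$id))
    info$id <- variant_key(info, rule = "position_alleles")
  info$id <- make.unique(as.character(info$id), sep = "#")
  if (is.null(info$impact)) info$impact <- "other"
  if (is.null(info$splice_offset)) info$splice_offset <- NA_real_
  if (is.null(info$genes)) info$genes <- ""
  if (is.null(info$clinical_flags)) info$clinical_flags <- ""
  if (is.null(info$caller)) info$caller <- "unknown"
  bad <- which(info$end <= info$start | info$start < 0)
  if (length(bad))
    stop("invalid variant span at row(s) ", paste(bad, collapse = ", "))
  canon <- c("id", "chrom", "start", "end", "ref", "alt", "impact",
             "splice_offset", "genes", "clinical_flags", "caller")
  info <- info[, c(canon, setdiff(names(info), canon)), drop = FALSE]

  gt <- as.matrix(gt)
  gq <- as.matrix(gq)
  if (nrow(gt) != nrow(info) || nrow(gq) != nrow(info))
    stop("genotype matrices must have one row per variant")
  if (!identical(dim(gt), dim(gq)))
    stop("gt and gq must have identical dimensions")
  if (is.null(colnames(gt)))
    stop("gt must carry sample ids as column names")
  if (anyDuplicated(colnames(gt)))
    stop("duplicate sample_id in genotype matrix")
  colnames(gq) <- colnames(gt)
  storage.mode(gt) <- "integer"
  storage.mode(gq) <- "double"
  if (any(gt < 0 | gt > 2, na.rm = TRUE))
    stop("allele counts must be 0, 1, 2 or NA")

  if (is.null(af)) {
    af <- matrix(NA_real_, nrow = nrow(info), ncol = 0)
  } else {
    af <- as.matrix(af)
    storage.mode(af) <- "double"
    if (nrow(af) != nrow(info))
      stop("af must have one row per variant")
    if (any(af < 0 | af > 1, na.rm = TRUE))
      stop("population allele frequencies must lie in [0, 1]")
  }
  rownames(gt) <- rownames(gq) <- info$id
  if (ncol(af) > 0) rownames(af) <- info$id
  rownames(info) <- NULL

  structure(list(info = info, gt = gt, gq = gq, af = af, build = build),
            class = "variant_set")
}

#' @rdname variant_set
#' @param x A `variant_set`.
#' @export
n_variants <- function(x) nrow(x$info)

#' @rdname variant_set
#' @export
variant_ids <- function(x) x$info$id

#' @rdname variant_set
#' @export
sample_ids <- function(x) colnames(x$gt)

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("<variant_set> %d variants x %d samples [%s], %d freq source(s)\n",
              n_variants(x), ncol(x$gt), x$build, ncol(x$af)))
  invisible(x)
}

#' Subset a variant set by row index, logical mask or variant id
#'
#' @param x A `variant_set`.
#' @param i Integer/logical index or character vector of variant ids.
#' @param ... Unused.
#' @export
`[.variant_set` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$info$id)
  out <- x
  out$info <- x$info[i, , drop = FALSE]
  rownames(out$info) <- NULL
  out$gt <- x$gt[i, , drop = FALSE]
  out$gq <- x$gq[i, , drop = FALSE]
  out$af <- x$af[i, , drop = FALSE]
  out
}

#' Zygosity label from an alternate-allele copy count
#'
#' @param allele_count Integer vector of alternate-allele copies (0, 1, 2)
#'   with `NA` for missing genotypes.
#' @return Character vector over `{"ref", "het", "hom", "missing"}`.
#' @export
zygosity <- function(allele_count) {
  out <- rep("missing", length(allele_count))
  out[!is.na(allele_count) & allele_count == 0] <- "ref"
  out[!is.na(allele_count) & allele_count == 1] <- "het"
  out[!is.na(allele_count) & allele_count == 2] <- "hom"
  out
}

## matching key used by consensus intersection and recurrence tallies
variant_key <- function(info, rule = c("position_alleles", "position")) {
  rule <- match.arg(rule)
  if (rule == "position_alleles")
    paste(info$chrom, info$start, info$ref, info$alt, sep = ":")
  else
    paste(info$chrom, info$start, sep = ":")
}

#' Dual-caller consensus intersection
#'
#' Variant callers differ sharply in their raw output; requiring a variant
#' to be reported by two independent callers is a strong error filter.
#' Returns the variants of `set_a` that are also present in `set_b` under
#' the chosen matching rule.  Annotations are taken from `set_a` and the
#' caller label of the result is set to `"consensus"`.
#'
#' @param set_a,set_b `variant_set` objects.
#' @param match_rule `"position_alleles"` (default) matches on chromosome,
#'   start, ref and alt; `"position"` matches on chromosome and start only.
#' @return A `variant_set`, a subset of `set_a`.
#' @export
intersect_callsets <- function(set_a, set_b,
                               match_rule = c("position_alleles", "position")) {
  match_rule <- match.arg(match_rule)
  stopifnot(inherits(set_a, "variant_set"), inherits(set_b, "variant_set"))
  ka <- variant_key(set_a$info, match_rule)
  kb <- variant_key(set_b$info, match_rule)
  out <- set_a[ka %in% kb]
  out$info$caller <- rep("consensus", nrow(out$info))
  out
}

# ---------------------------------------------------------------------------
# VCF dialect I/O
# ---------------------------------------------------------------------------

default_vcf_keys <- function() {
  list(af = c("AF_1KG", "AF_CG", "AF_ESP"),
       impact = "IMPACT", gene = "GENE", flag = "CLNFLAG",
       splice = "SPLICE_OFS")
}

impact_vocabulary <- function() {
  c("missense", "frameshift", "inframe_indel", "stop_change", "splice",
    "mirna_binding", "mirna_deleterious", "structural", "synonymous",
    "utr", "intronic", "other")
}

parse_info_field <- function(s) {
  if (is.na(s) || s == "." || !nzchar(s)) return(list())
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- lapply(kv, function(p) if (length(p) > 1) p[2] else "")
  names(vals) <- vapply(kv, `[`, "", 1)
  vals
}

#' Read an annotated multi-sample VCF
#'
#' Parses the VCF dialect used throughout the pipeline: annotation lives in
#' configurable INFO keys (population allele frequencies as fractions in
#' \[0, 1\], impact category, gene symbols, clinical flags, splice offset)
#' and genotypes in GT:GQ sample columns.  Multi-allelic records are split
#' into one variant per alternate allele; per-allele INFO values may be
#' comma-separated in allele order.  Records that cannot be interpreted
#' (e.g. a missing alternate allele) are rejected with a line-numbered
#' diagnostic.
#'
#' @param path Path to the VCF file.
#' @param caller_label Provenance label stored on every parsed variant.
#' @param keys Named list mapping annotation roles to INFO keys; see
#'   `default_vcf_keys()`.
#' @param build Genome build tag for the parsed coordinates.
#' @return A `variant_set`.  Coordinates are converted from the file's
#'   1-based positions to the internal 0-based half-open convention.
#' @export
read_variants <- function(path, caller_label = "unknown",
                          keys = default_vcf_keys(), build = "unknown") {
  if (!file.exists(path)) stop("no such VCF: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  gtm <- v@gt
  n_meta <- length(v@meta)
  if (is.null(fix) || nrow(fix) == 0) {
    return(variant_set(
      info = data.frame(chrom = character(0), start = numeric(0),
                        end = numeric(0), ref = character(0),
                        alt = character(0)),
      gt = matrix(integer(0), 0, 0,
                  dimnames = list(NULL, character(0))),
      gq = matrix(numeric(0), 0, 0), build = build))
  }
  samples <- colnames(gtm)[-1]
  vocab <- impact_vocabulary()

  rows <- list(); gts <- list(); gqs <- list(); afs <- list()
  unknown_impacts <- character(0)
  for (r in seq_len(nrow(fix))) {
    line_no <- n_meta + 1L + r
    alt_str <- fix[r, "ALT"]
    ref <- fix[r, "REF"]
    if (is.na(alt_str) || alt_str == "." || !nzchar(alt_str)) {
      warning(sprintf("line %d: record rejected (missing ALT allele)",
                      line_no), call. = FALSE)
      next
    }
    if (is.na(ref) || ref == "." || !nzchar(ref)) {
      warning(sprintf("line %d: record rejected (missing REF allele)",
                      line_no), call. = FALSE)
      next
    }
    alts <- strsplit(alt_str, ",", fixed = TRUE)[[1]]
    pos <- suppressWarnings(as.numeric(fix[r, "POS"]))
    if (is.na(pos)) {
      warning(sprintf("line %d: record rejected (bad POS)", line_no),
              call. = FALSE)
      next
    }
    info <- parse_info_field(fix[r, "INFO"])
    fmt <- strsplit(gtm[r, 1], ":", fixed = TRUE)[[1]]
    gt_i <- match("GT", fmt)
    gq_i <- match("GQ", fmt)
    sample_fields <- strsplit(gtm[r, -1, drop = TRUE], ":", fixed = TRUE)

    per_alt <- function(key, k) {
      val <- info[[key]]
      if (is.null(val)) return(NA_character_)
      parts <- strsplit(val, ",", fixed = TRUE)[[1]]
      if (length(parts) >= k) parts[k] else parts[1]
    }

    for (k in seq_along(alts)) {
      alt <- alts[k]
      if (alt == "." || !nzchar(alt)) {
        warning(sprintf("line %d: alt allele %d rejected (missing ALT)",
                        line_no, k), call. = FALSE)
        next
      }
      ac <- integer(length(samples)); qual <- numeric(length(samples))
      for (s in seq_along(samples)) {
        f <- sample_fields[[s]]
        gstr <- if (!is.na(gt_i) && length(f) >= gt_i) f[gt_i] else "."
        alleles <- strsplit(gstr, "[/|]")[[1]]
        if (any(alleles == ".") || length(alleles) == 0) {
          ac[s] <- NA_integer_
        } else {
          ac[s] <- sum(alleles == as.character(k))
        }
        qv <- if (!is.na(gq_i) && length(f) >= gq_i) f[gq_i] else NA
        qual[s] <- suppressWarnings(as.numeric(qv))
      }
      imp <- per_alt(keys$impact, k)
      if (is.na(imp) || !nzchar(imp)) imp <- "other"
      if (!imp %in% vocab) {
        unknown_impacts <- c(unknown_impacts, imp)
        imp <- "other"
      }
      af_row <- vapply(keys$af, function(key) {
        x <- per_alt(key, k)
        suppressWarnings(as.numeric(x))
      }, numeric(1))
      so <- suppressWarnings(as.numeric(per_alt(keys$splice, k)))
      idf <- fix[r, "ID"]
      vid <- if (!is.na(idf) && nzchar(idf) && idf != ".") {
        if (length(alts) == 1) idf else paste0(idf, "_", k)
      } else NA_character_
      rows[[length(rows) + 1L]] <- data.frame(
        id = vid,
        chrom = fix[r, "CHROM"], start = pos - 1,
        end = pos - 1 + nchar(ref), ref = ref, alt = alt,
        impact = imp, splice_offset = so,
        genes = {
          g <- per_alt(keys$gene, k)
          if (is.na(g)) "" else gsub("\\|", ",", g)
        },
        clinical_flags = {
          g <- per_alt(keys$flag, k)
          if (is.na(g)) "" else gsub("\\|", ",", g)
        },
        caller = caller_label, stringsAsFactors = FALSE)
      gts[[length(gts) + 1L]] <- ac
      gqs[[length(gqs) + 1L]] <- qual
      afs[[length(afs) + 1L]] <- af_row
    }
  }
  if (length(unknown_impacts))
    warning("unknown impact value(s) mapped to 'other': ",
            paste(unique(unknown_impacts), collapse = ", "), call. = FALSE)
  if (length(rows) == 0)
    stop("no parseable variant records in ", path)
  info_df <- do.call(rbind, rows)
  info_df$chrom <- norm_chrom(info_df$chrom)
  blank <- is.na(info_df$id)
  info_df$id[blank] <- variant_key(info_df, "position_alleles")[blank]
  gt <- do.call(rbind, gts); colnames(gt) <- samples
  gq <- do.call(rbind, gqs); colnames(gq) <- samples
  af <- do.call(rbind, afs); colnames(af) <- keys$af
  variant_set(info_df, gt, gq, af, build = build)
}

#' Write a variant set as VCF
#'
#' Inverse of [read_variants()]: annotations are serialized into the same
#' INFO keys, genotypes as GT:GQ.  `read_variants(write_variants(x))` is the
#' identity on the annotation fields the pipeline uses.
#'
#' @param x A `variant_set`.
#' @param path Output path.
#' @param keys INFO-key mapping, as in [read_variants()].
#' @return `path`, invisibly.
#' @export
write_variants <- function(x, path, keys = default_vcf_keys()) {
  stopifnot(inherits(x, "variant_set"))
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##reference=%s", x$build),
    vapply(keys$af, function(k) sprintf(
      "##INFO=<ID=%s,Number=A,Type=Float,Description=\"Population allele frequency\">", k), ""),
    sprintf("##INFO=<ID=%s,Number=A,Type=String,Description=\"Impact category\">", keys$impact),
    sprintf("##INFO=<ID=%s,Number=A,Type=String,Description=\"Gene symbols\">", keys$gene),
    sprintf("##INFO=<ID=%s,Number=A,Type=String,Description=\"Clinical flags\">", keys$flag),
    sprintf("##INFO=<ID=%s,Number=A,Type=Float,Description=\"Splice offset bp into intron\">", keys$splice),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Float,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids(x)), collapse = "\t")
  )
  num <- function(v) ifelse(is.na(v), NA_character_,
                            sub("\\.?0+$", "", sprintf("%.10f", v)))
  lines <- character(n_variants(x))
  for (i in seq_len(n_variants(x))) {
    inf <- x$info[i, ]
    info_parts <- character(0)
    if (ncol(x$af) > 0) {
      for (j in seq_len(ncol(x$af))) {
        if (!is.na(x$af[i, j]))
          info_parts <- c(info_parts,
                          sprintf("%s=%s", colnames(x$af)[j], num(x$af[i, j])))
      }
    }
    info_parts <- c(info_parts, sprintf("%s=%s", keys$impact, inf$impact))
    if (nzchar(inf$genes))
      info_parts <- c(info_parts,
                      sprintf("%s=%s", keys$gene, gsub(",", "|", inf$genes)))
    if (nzchar(inf$clinical_flags))
      info_parts <- c(info_parts,
                      sprintf("%s=%s", keys$flag,
                              gsub(",", "|", inf$clinical_flags)))
    if (!is.na(inf$splice_offset))
      info_parts <- c(info_parts,
                      sprintf("%s=%s", keys$splice, num(inf$splice_offset)))
    gt_str <- c("0/0", "0/1", "1/1")[x$gt[i, ] + 1L]
    gt_str[is.na(gt_str)] <- "./."
    gq_str <- num(x$gq[i, ])
    gq_str[is.na(gq_str)] <- "."
    lines[i] <- paste(c(inf$chrom, format(inf$start + 1, scientific = FALSE),
                        inf$id, inf$ref, inf$alt, ".", "PASS",
                        paste(info_parts, collapse = ";"), "GT:GQ",
                        paste(gt_str, gq_str, sep = ":")),
                      collapse = "\t")
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}
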