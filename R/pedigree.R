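#' Pedigrees
#'
#' A pedigree is a data frame with one row per member and columns
#' `sample_id`, `father_id`, `mother_id` (`NA` when unknown), `sex`
#' (`"male"`, `"female"` or `"unknown"`) and `affected` (`TRUE`, `FALSE`
#' or `NA` for unknown phenotype).  Parental ids must refer to members and
#' no member may be its own ancestor.
#'
#' @param members Data frame with the columns above (ids may be given as
#'   `0` or `""` for missing parents).
#' @return A validated data frame of class `pedigree`.
#' @export
pedigree <- function(members) {
  m <- as.data.frame(members, stringsAsFactors = FALSE)
  need <- c("sample_id", "father_id", "mother_id", "sex", "affected")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("pedigree is missing columns: ", paste(miss, collapse = ", "))
  m$sample_id <- as.character(m$sample_id)
  clean_parent <- function(p) {
    p <- as.character(p)
    p[p %in% c("0", "", ".") | is.na(p)] <- NA_character_
    p
  }
  m$father_id <- clean_parent(m$father_id)
  m$mother_id <- clean_parent(m$mother_id)
  if (anyDuplicated(m$sample_id))
    stop("duplicate sample_id in pedigree: ",
         paste(unique(m$sample_id[duplicated(m$sample_id)]), collapse = ", "))
  for (col in c("father_id", "mother_id")) {
    ref <- m[[col]]
    bad <- !is.na(ref) & !ref %in% m$sample_id
    if (any(bad))
      stop("unknown ", col, " referenced: ",
           paste(unique(ref[bad]), collapse = ", "))
  }
  # ancestry must be acyclic (a member can never be its own ancestor)
  parent_of <- function(id) {
    r <- m[m$sample_id == id, ]
    stats::na.omit(c(r$father_id, r$mother_id))
  }
  for (id in m$sample_id) {
    seen <- character(0)
    frontier <- parent_of(id)
    while (length(frontier)) {
      if (id %in% frontier)
        stop("cyclic parentage involving sample ", id)
      seen <- union(seen, frontier)
      frontier <- setdiff(unique(unlist(lapply(frontier, parent_of))), seen)
    }
  }
  class(m) <- c("pedigree", "data.frame")
  m
}

#' Read a 6-column PED file
#'
#' Columns: family id, individual id, father id, mother id, sex
#' (1 = male, 2 = female, other = unknown), phenotype (2 = affected,
#' 1 = unaffected, 0/-9 = unknown).
#'
#' @param path Path to the PED file.
#' @return A `pedigree`.
#' @export
read_pedigree <- function(path) {
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 6)
    stop("PED file must have 6 columns, found ", ncol(raw))
  pedigree(data.frame(
    sample_id = raw[[2]],
    father_id = raw[[3]],
    mother_id = raw[[4]],
    sex = c("1" = "male", "2" = "female")[raw[[5]]] |>
      (\(s) ifelse(is.na(s), "unknown", s))(),
    affected = c("2" = TRUE, "1" = FALSE)[raw[[6]]],
    stringsAsFactors = FALSE))
}

#' Write a pedigree as a 6-column PED file
#'
#' @param ped A `pedigree`.
#' @param path Output path.
#' @param family_id Family identifier written in column 1.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path, family_id = "FAM1") {
  stopifnot(inherits(ped, "pedigree"))
  sex <- c(male = "1", female = "2", unknown = "0")[ped$sex]
  phe <- ifelse(is.na(ped$affected), "0", ifelse(ped$affected, "2", "1"))
  out <- data.frame(family_id, ped$sample_id,
                    ifelse(is.na(ped$father_id), "0", ped$father_id),
                    ifelse(is.na(ped$mother_id), "0", ped$mother_id),
                    ifelse(is.na(sex), "0", sex), phe)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname pedigree
#' @param ped A `pedigree`.
#' @export
affected_ids <- function(ped) ped$sample_id[!is.na(ped$affected) & ped$affected]

#' @rdname pedigree
#' @export
unaffected_ids <- function(ped) ped$sample_id[!is.na(ped$affected) & !ped$affected]
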