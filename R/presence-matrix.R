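#' Phyletic presence/state matrix
#'
#' A `presence_matrix` is a character matrix with one row per gene family and
#' one column per taxon; each cell is one of `"absent"`, `"sec"`, `"cys"`,
#' `"other"` (a residue other than Sec/Cys aligned at the Sec position) or
#' `"missing"` (no usable evidence; never counted as a loss).
#'
#' @param x character matrix (families x taxa) with dimnames, or a long
#'   data.frame with columns `family`, `taxon`, `state`.
#' @param meta optional per-family metadata data.frame with columns
#'   `family`, `parent_family` (empty string when the family was not born by
#'   duplication of another family in the matrix), logical
#'   `selenoprotein_subfamily`, and free-text `notes`.
#' @return a `presence_matrix` object.
#' @export
presence_matrix <- function(x, meta = NULL) {
  if (is.data.frame(x)) {
    need <- c("family", "taxon", "state")
    if (!all(need %in% names(x)))
      stop("long-format input needs columns family, taxon, state")
    fams <- unique(x$family)
    taxa <- unique(x$taxon)
    m <- matrix(NA_character_, length(fams), length(taxa),
                dimnames = list(fams, taxa))
    m[cbind(match(x$family, fams), match(x$taxon, taxa))] <- x$state
    x <- m
  }
  if (!is.matrix(x) || is.null(rownames(x)) || is.null(colnames(x)))
    stop("presence matrix must have family rownames and taxon colnames")
  x[] <- normalize_state(x)
  if (anyNA(x)) stop("undefined cells in presence matrix")
  bad <- setdiff(unique(as.vector(x)), .selevo_states)
  if (length(bad)) stop("unknown state token(s): ", paste(bad, collapse = ", "))
  informative <- apply(x, 1, function(s) any(!s %in% c("absent", "missing")))
  if (any(!informative))
    stop("families with no observed presence: ",
         paste(rownames(x)[!informative], collapse = ", "))
  if (!is.null(meta)) {
    if (!all(c("family", "parent_family") %in% names(meta)))
      stop("meta needs columns family and parent_family")
    if (!all(rownames(x) %in% meta$family))
      stop("meta is missing families present in the matrix")
    known <- nzchar(meta$parent_family)
    unknown <- setdiff(meta$parent_family[known], meta$family)
    if (length(unknown))
      stop("parent_family references unknown families: ",
           paste(unknown, collapse = ", "))
    meta <- meta[match(rownames(x), meta$family), , drop = FALSE]
    rownames(meta) <- NULL
  }
  structure(x, class = c("presence_matrix", "matrix"), meta = meta)
}

# Case/spelling normalization for state tokens ("Sec" -> "sec", "U" -> "sec").
normalize_state <- function(s) {
  s <- tolower(trimws(s))
  map <- c(sec = "sec", u = "sec", cys = "cys", c = "cys",
           absent = "absent", "-" = "absent", other = "other",
           missing = "missing", "?" = "missing", na = "missing")
  out <- unname(map[s])
  unknown <- is.na(out) & !is.na(s)
  out[unknown] <- s[unknown]          # caught by the vocabulary check
  out
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat("presence_matrix:", nrow(x), "families x", ncol(x), "taxa\n")
  tab <- table(factor(as.vector(unclass(x)), levels = .selevo_states))
  cat(paste(names(tab), tab, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Family metadata of a presence matrix
#' @param x a `presence_matrix`.
#' @return the metadata data.frame, or `NULL`.
#' @export
family_meta <- function(x) attr(x, "meta")

#' Read / write a phyletic state matrix (long TSV)
#'
#' The on-disk format is a three-column TSV (`family`, `taxon`, `state`);
#' state tokens are case-normalized on read.  `write_state_matrix()` followed
#' by `read_state_matrix()` is a lossless round trip.
#'
#' @param path TSV file path.
#' @param meta optional metadata (see [presence_matrix()]).
#' @return a `presence_matrix`.
#' @export
read_state_matrix <- function(path, meta = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  presence_matrix(df, meta = meta)
}

#' @rdname read_state_matrix
#' @param x a `presence_matrix` to write.
#' @export
write_state_matrix <- function(x, path) {
  long <- data.frame(family = rep(rownames(x), each = ncol(x)),
                     taxon = rep(colnames(x), times = nrow(x)),
                     state = as.vector(t(unclass(x))),
                     stringsAsFactors = FALSE)
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read family metadata TSV
#' @param path TSV with columns family, parent_family, selenoprotein_subfamily, notes.
#' @return a data.frame.
#' @export
read_family_meta <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = c(parent_family = "character",
                                           notes = "character"))
  meta$parent_family[is.na(meta$parent_family)] <- ""
  meta$selenoprotein_subfamily <- as.logical(meta$selenoprotein_subfamily)
  meta
}

#' Number of selenoproteins encoded at a tip
#'
#' Counts families whose state at `taxon` is `sec`; Cys/other homologs and
#' missing data are not counted.
#'
#' @param x a `presence_matrix` or an `event_set`.
#' @param taxon tip name.
#' @return integer count.
#' @export
selenoproteome_size <- function(x, taxon) UseMethod("selenoproteome_size")

#' @export
selenoproteome_size.presence_matrix <- function(x, taxon) {
  if (!taxon %in% colnames(x)) stop("unknown taxon: ", taxon)
  sum(unclass(x)[, taxon] == "sec")
}

#' Group-level Sec presence census
#'
#' Recomputes the group-level presence table: a family is present in a taxon
#' group when at least one tip of the group carries it in the `sec` state.
#'
#' @param x a `presence_matrix`.
#' @param groups named list mapping group name to character vector of tips.
#' @param subfamilies_only restrict to rows flagged as selenoprotein
#'   subfamilies in the metadata (default `TRUE` when metadata is present).
#' @return logical matrix, families x groups.
#' @export
group_presence <- function(x, groups, subfamilies_only = !is.null(family_meta(x))) {
  m <- unclass(x)
  if (subfamilies_only) {
    meta <- family_meta(x)
    if (is.null(meta)) stop("no family metadata attached")
    m <- m[meta$selenoprotein_subfamily, , drop = FALSE]
  }
  out <- vapply(groups, function(tips) {
    tips <- intersect(tips, colnames(m))
    apply(m[, tips, drop = FALSE] == "sec", 1, any)
  }, logical(nrow(m)))
  rownames(out) <- rownames(m)
  out
}
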