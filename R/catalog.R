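#' Hairpin sequence catalogs
#'
#' A hairpin catalog is an ordered collection of named precursor-miRNA
#' stem-loop sequences over the RNA alphabet \{A, C, G, U\}, together with a
#' base-name index used to resolve human-readable miRNA names (see
#' \code{\link{resolve_name}}). Identifiers must be unique.
#'
#' @param records data frame with columns \code{identifier},
#'   \code{description}, \code{sequence}; \code{length} is derived.
#' @param allow_ambiguous keep records containing IUPAC ambiguity codes
#'   (N, R, Y, ...) instead of rejecting them. Ambiguous positions are
#'   excluded from distance scoring downstream.
#' @return An object of class \code{hairpin_catalog}.
#' @seealso \code{\link{read_hairpin_fasta}},
#'   \code{\link{generate_fixture_catalog}}
#' @export
hairpin_catalog <- function(records, allow_ambiguous = FALSE) {
  stopifnot(is.data.frame(records),
            all(c("identifier", "sequence") %in% names(records)))
  ids <- as.character(records$identifier)
  if (anyDuplicated(ids))
    stop2("duplicate identifiers in catalog: ",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- normalize_sequence(as.character(records$sequence))
  bad <- !grepl("^[ACGU]+$", seqs)
  ambiguous <- rep(FALSE, length(seqs))
  if (any(bad)) {
    iupac_ok <- grepl("^[ACGURYSWKMBDHVN]+$", seqs[bad])
    if (!all(iupac_ok))
      stop2("records with non-nucleotide symbols: ",
            paste(ids[bad][!iupac_ok], collapse = ", "))
    if (!allow_ambiguous)
      stop2("records contain IUPAC ambiguity codes (use allow_ambiguous ",
            "= TRUE to keep them): ", paste(ids[bad], collapse = ", "))
    ambiguous[bad] <- TRUE
  }
  if (any(nchar(seqs) < 1L)) stop2("empty sequences are not allowed")
  df <- data.frame(identifier = ids,
                   description = as.character(records$description %||% ""),
                   sequence = seqs,
                   length = nchar(seqs),
                   ambiguous = ambiguous,
                   stringsAsFactors = FALSE)
  structure(list(records = df, name_index = build_name_index(ids)),
            class = "hairpin_catalog")
}

# T -> U, upper case. The internal alphabet is RNA; miRBase distributes U,
# DNA-letter FASTA input is accepted.
normalize_sequence <- function(x) chartr("T", "U", toupper(x))

# Base-name keys: identifier with a trailing locus suffix ("-1", "-2", ...)
# and/or a trailing arm letter ("a".."z" directly after a digit) stripped.
strip_locus <- function(id) sub("-[0-9]+$", "", id)
strip_arm <- function(id) sub("(?<=[0-9])[a-z]$", "", id, perl = TRUE)

build_name_index <- function(ids) {
  lower <- tolower(ids)
  list(exact = lower,
       locus = strip_locus(lower),
       arm = strip_arm(lower),
       arm_locus = strip_arm(strip_locus(lower)))
}

#' @export
length.hairpin_catalog <- function(x) nrow(x$records)

#' @export
print.hairpin_catalog <- function(x, ...) {
  n <- length(x)
  cat(sprintf("Hairpin catalog: %d record%s, lengths %d-%d nt\n",
              n, if (n == 1) "" else "s",
              min(x$records$length), max(x$records$length)))
  if (any(x$records$ambiguous))
    cat(sprintf("  %d record(s) contain IUPAC ambiguity codes\n",
                sum(x$records$ambiguous)))
  cat("  identifiers: ", paste(head(x$records$identifier, 5), collapse = ", "),
      if (n > 5) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
`[.hairpin_catalog` <- function(x, i, ...) {
  if (is.character(i)) {
    pos <- match(i, x$records$identifier)
    if (anyNA(pos))
      stop2("unknown identifiers: ", paste(i[is.na(pos)], collapse = ", "))
    i <- pos
  }
  hairpin_catalog(x$records[i, , drop = FALSE],
                  allow_ambiguous = TRUE)
}

#' @export
as.data.frame.hairpin_catalog <- function(x, ...) x$records

catalog_ids <- function(catalog) catalog$records$identifier

catalog_sequences <- function(catalog) {
  setNames(catalog$records$sequence, catalog$records$identifier)
}

#' Read a hairpin FASTA catalog
#'
#' Reads a (possibly multi-line) FASTA file of precursor miRNA stem-loop
#' sequences, normalizes the sequences to the RNA alphabet (T mapped to U,
#' case folded to upper) and optionally restricts to one species by
#' identifier prefix, e.g. \code{"hsa-"} for human.
#'
#' The FASTA identifier is the first whitespace-delimited token of each
#' header; the remainder of the header is kept as the description.
#'
#' @param path path to a FASTA file.
#' @param species_prefix optional identifier prefix filter (e.g.
#'   \code{"hsa-"}); \code{NULL} keeps all records.
#' @param allow_ambiguous keep records with IUPAC ambiguity codes.
#' @return A \code{\link{hairpin_catalog}}.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">hsa-mir-21 example", "acgu"), fa)
#' read_hairpin_fasta(fa)
#' @export
read_hairpin_fasta <- function(path, species_prefix = NULL,
                               allow_ambiguous = FALSE) {
  if (!file.exists(path)) stop2("FASTA file not found: ", path)
  set <- tryCatch(readBStringSet(path),
                  error = function(e) stop2("malformed FASTA '", path, "': ",
                                            conditionMessage(e)))
  if (length(set) == 0L) stop2("no FASTA records in ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- sub("^\\S+\\s*", "", headers)
  seqs <- as.character(set)
  if (!is.null(species_prefix)) {
    keep <- startsWith(ids, species_prefix)
    if (!any(keep))
      stop2("no records with identifier prefix '", species_prefix, "'")
    ids <- ids[keep]; desc <- desc[keep]; seqs <- seqs[keep]
  }
  hairpin_catalog(data.frame(identifier = ids, description = desc,
                             sequence = seqs, stringsAsFactors = FALSE),
                  allow_ambiguous = allow_ambiguous)
}

#' Write a catalog to FASTA
#'
#' Sequences are written in the RNA alphabet, wrapped at 60 columns.
#' Re-reading the file with \code{\link{read_hairpin_fasta}} reproduces
#' identifiers and sequences exactly.
#'
#' @param catalog a \code{\link{hairpin_catalog}}.
#' @param path output file path.
#' @param width line-wrap width in characters.
#' @return \code{path}, invisibly.
#' @export
write_hairpin_fasta <- function(catalog, path, width = 60L) {
  stopifnot(inherits(catalog, "hairpin_catalog"))
  r <- catalog$records
  nm <- ifelse(nzchar(r$description),
               paste(r$identifier, r$description), r$identifier)
  set <- BStringSet(setNames(r$sequence, nm))
  writeXStringSet(set, filepath = path, width = as.integer(width))
  invisible(path)
}
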