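#' Resolve a miRNA name to catalog identifiers
#'
#' Biomarker panels are usually published with short names such as
#' \code{"miR-323"} or \code{"let-7a"}, without species prefix, arm letter
#' or locus suffix. \code{resolve_name} maps such a name to stem-loop
#' identifiers in a catalog: the query is case folded, the species prefix
#' (default \code{"hsa-"}) is prepended when absent, and candidates are
#' collected at the first matching level of
#' \enumerate{
#'   \item exact identifier match (\code{"hsa-mir-21"}),
#'   \item identifiers equal after stripping a trailing locus suffix
#'     (\code{"let-7a"} matches \code{hsa-let-7a-1/-2/-3}),
#'   \item identifiers equal after additionally stripping a trailing arm
#'     letter (\code{"miR-323"} matches \code{hsa-mir-323a/b}).
#' }
#' When several candidates exist the resolution policy decides:
#' \describe{
#'   \item{\code{"multi-locus-first"}}{pick the lexicographically first
#'     identifier and warn, listing all candidates (default; deterministic
#'     and auditable).}
#'   \item{\code{"exact"}}{fail on any ambiguity.}
#'   \item{\code{"all"}}{return all candidates.}
#' }
#' An explicit \code{name_map} (query to identifier, see
#' \code{\link{read_name_map}}) overrides the heuristics, so a known
#' locus choice can be injected once established.
#'
#' @param query miRNA name as printed (e.g. \code{"miR-323"}).
#' @param catalog a \code{\link{hairpin_catalog}}.
#' @param policy ambiguity policy, see Details.
#' @param species_prefix prefix prepended to unprefixed queries.
#' @param name_map optional named character vector mapping queries to
#'   identifiers.
#' @return A list of class \code{name_resolution} with elements
#'   \code{query}, \code{matches}, \code{policy_applied} (one of
#'   \code{exact}, \code{single-arm-letter}, \code{multi-locus-first},
#'   \code{explicit-map}) and \code{ambiguous} (TRUE iff more than one
#'   candidate existed before the policy was applied).
#' @examples
#' cat <- generate_fixture_catalog(3, c(60, 60), seed = 1)
#' resolve_name(toupper(catalog_names(cat)[1]), cat, species_prefix = "")
#' @export
resolve_name <- function(query, catalog,
                         policy = c("multi-locus-first", "exact", "all"),
                         species_prefix = "hsa-", name_map = NULL) {
  stopifnot(inherits(catalog, "hairpin_catalog"), length(catalog) > 0L,
            is.character(query), length(query) == 1L)
  policy <- match.arg(policy)
  key <- tolower(trimws(query))
  if (!is.null(name_map)) {
    hit <- match(key, tolower(names(name_map)))
    if (!is.na(hit)) {
      id <- unname(name_map[[hit]])
      if (!id %in% catalog_ids(catalog))
        stop2("name map sends '", query, "' to '", id,
              "', which is not in the catalog")
      return(structure(list(query = query, matches = id,
                            policy_applied = "explicit-map",
                            ambiguous = FALSE),
                       class = "name_resolution"))
    }
  }
  if (nzchar(species_prefix) && !startsWith(key, species_prefix))
    key <- paste0(species_prefix, key)
  idx <- catalog$name_index
  ids <- catalog_ids(catalog)
  level <- "exact"
  cand <- ids[idx$exact == key]
  if (length(cand) == 0L) {
    cand <- ids[idx$locus == key]
    level <- "multi-locus"
  }
  if (length(cand) == 0L) {
    cand <- ids[idx$arm == key | idx$arm_locus == key]
    level <- "single-arm-letter"
  }
  if (length(cand) == 0L)
    stop2("cannot resolve miRNA name '", query, "' (looked up as '", key,
          "') in the catalog")
  cand <- sort(cand)
  ambiguous <- length(cand) > 1L
  applied <- if (!ambiguous) {
    if (level == "exact") "exact" else level
  } else if (policy == "exact") {
    stop2("ambiguous name '", query, "': candidates ",
          paste(cand, collapse = ", "),
          " (policy = \"exact\" refuses to choose)")
  } else if (policy == "all") {
    level
  } else {
    warning("name '", query, "' is ambiguous; using first candidate '",
            cand[1], "' of: ", paste(cand, collapse = ", "), call. = FALSE)
    "multi-locus-first"
  }
  matches <- if (ambiguous && policy == "multi-locus-first") cand[1] else cand
  structure(list(query = query, matches = matches,
                 policy_applied = applied, ambiguous = ambiguous),
            class = "name_resolution")
}

#' @export
print.name_resolution <- function(x, ...) {
  cat(sprintf("'%s' -> %s [%s%s]\n", x$query,
              paste(x$matches, collapse = ", "), x$policy_applied,
              if (x$ambiguous) ", ambiguous" else ""))
  invisible(x)
}

#' Resolve a vector of panel names
#'
#' Applies \code{\link{resolve_name}} to each name, collecting all
#' failures into a single error so a panel can be fixed in one pass.
#'
#' @inheritParams resolve_name
#' @param names character vector of miRNA names.
#' @return data frame with columns \code{query}, \code{identifier},
#'   \code{ambiguous}, \code{policy}.
#' @export
resolve_panel <- function(names, catalog,
                          policy = c("multi-locus-first", "exact", "all"),
                          species_prefix = "hsa-", name_map = NULL) {
  policy <- match.arg(policy)
  res <- lapply(names, function(q) {
    tryCatch(resolve_name(q, catalog, policy = policy,
                          species_prefix = species_prefix,
                          name_map = name_map),
             error = function(e) structure(conditionMessage(e),
                                           class = "resolution_failure"))
  })
  failed <- vapply(res, inherits, logical(1), "resolution_failure")
  if (any(failed))
    stop2("unresolved panel names:\n  ",
          paste(unlist(res[failed]), collapse = "\n  "))
  do.call(rbind, lapply(res, function(r)
    data.frame(query = r$query, identifier = r$matches[1],
               ambiguous = r$ambiguous, policy = r$policy_applied,
               stringsAsFactors = FALSE)))
}

#' Read a name-map TSV
#'
#' Two tab-separated columns, \code{query} and \code{identifier};
#' lines starting with \code{#} are comments.
#'
#' @param path file path.
#' @return named character vector (names are queries).
#' @export
read_name_map <- function(path) {
  if (!file.exists(path)) stop2("name-map file not found: ", path)
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop2("name map must have two tab-separated columns")
  setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Read a plain-text biomarker panel
#'
#' One or more miRNA names per line, separated by commas and/or
#' whitespace; \code{#} starts a comment.
#'
#' @param path file path.
#' @return character vector of names.
#' @export
read_panel_names <- function(path) {
  if (!file.exists(path)) stop2("panel file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  nm <- unlist(strsplit(lines, "[,[:space:]]+"))
  nm <- nm[nzchar(nm)]
  if (length(nm) == 0L) stop2("no miRNA names in ", path)
  nm
}

#' Catalog identifiers
#'
#' @param catalog a \code{\link{hairpin_catalog}}.
#' @return character vector of identifiers in catalog order.
#' @export
catalog_names <- function(catalog) {
  stopifnot(inherits(catalog, "hairpin_catalog"))
  catalog_ids(catalog)
}
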