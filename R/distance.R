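#' Alignment scoring parameters
#'
#' Scoring for the pairwise global (end-to-end) alignment that precedes
#' the distance calculation. The defaults follow the classic
#' bioinformatics-toolbox nucleotide scheme: a NUC44-style substitution
#' core (match +5, mismatch -4) with gap-open and gap-extend magnitudes
#' of 8 (the cost of a length-k gap is
#' \code{gap_open + k * gap_extend}). All four values are configurable;
#' distances published for a given catalog are reproducible only under
#' the scoring they were computed with.
#'
#' \code{gap_columns} controls how alignment columns containing a gap
#' enter the p-distance: \code{"excluded"} (default) drops them from both
#' the compared-site count L and the mismatch count X, the standard
#' p-distance convention; \code{"counted-as-mismatch"} keeps every column
#' and scores gap columns as differences.
#'
#' @param match,mismatch substitution scores.
#' @param gap_open,gap_extend gap penalty magnitudes (nonnegative).
#' @param gap_columns gap-column policy, see Details.
#' @return An object of class \code{alignment_params}.
#' @export
alignment_params <- function(match = 5, mismatch = -4,
                             gap_open = 8, gap_extend = 8,
                             gap_columns = c("excluded",
                                             "counted-as-mismatch")) {
  gap_columns <- match.arg(gap_columns)
  stopifnot(gap_open >= 0, gap_extend >= 0, match > mismatch)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, gap_columns = gap_columns),
            class = "alignment_params")
}

#' @export
print.alignment_params <- function(x, ...) {
  cat(sprintf(paste0("Alignment params: match %+g, mismatch %+g, ",
                     "gap open %g, gap extend %g, gap columns %s\n"),
              x$match, x$mismatch, x$gap_open, x$gap_extend, x$gap_columns))
  invisible(x)
}

params_fingerprint <- function(params) {
  paste(params$match, params$mismatch, params$gap_open, params$gap_extend,
        params$gap_columns, sep = "/")
}

substitution_matrix <- function(params) {
  b <- c("A", "C", "G", "U")
  m <- matrix(params$mismatch, 4, 4, dimnames = list(b, b))
  diag(m) <- params$match
  m
}

# Vectorized batch alignment: each sequence in `patterns` against the single
# `subject`. Returns per-pair compared-site count L and mismatch count X
# under the gap-column policy. L for "excluded" is nmatch + nmismatch
# (gap-free columns); total columns are len_a + len_b - L_excluded (no
# column can be gap-over-gap in a pairwise alignment).
align_batch <- function(patterns, subject, params) {
  pa <- pairwiseAlignment(RNAStringSet(patterns), RNAStringSet(subject)[[1]],
                          type = "global",
                          substitutionMatrix = substitution_matrix(params),
                          gapOpening = params$gap_open,
                          gapExtension = params$gap_extend)
  nm <- nmatch(pa)
  nmm <- nmismatch(pa)
  L_ex <- nm + nmm
  if (params$gap_columns == "excluded") {
    data.frame(L = L_ex, X = nmm)
  } else {
    total <- nchar(patterns) + nchar(subject) - L_ex
    data.frame(L = total, X = total - nm)
  }
}

#' Align one pair of hairpin sequences
#'
#' Global end-to-end alignment of two sequences under
#' \code{\link{alignment_params}}, summarized as the compared-site count
#' L, the mismatch count X and the observed proportion of differing
#' nucleotides \code{p_hat = X / L}. The pair is put into a canonical
#' order internally before aligning, so the summary is symmetric in its
#' arguments by construction.
#'
#' @param a,b sequence strings (optionally named), or single-record
#'   \code{\link{hairpin_catalog}} objects.
#' @param params an \code{\link{alignment_params}} object.
#' @return A list of class \code{alignment_summary} with elements
#'   \code{id_a}, \code{id_b}, \code{L}, \code{X}, \code{p_hat}.
#' @examples
#' align_pair("ACGU", "ACGU")                    # L = 4, X = 0
#' align_pair("AAAA", "AAAU")$p_hat              # 0.25
#' @export
align_pair <- function(a, b, params = alignment_params()) {
  a <- as_named_sequence(a, "seq_a")
  b <- as_named_sequence(b, "seq_b")
  if (nchar(a) < 1L || nchar(b) < 1L) stop2("empty sequence")
  # canonical order: by sequence then name, so (L, X) is symmetric
  swap <- paste0(unname(b), names(b)) < paste0(unname(a), names(a))
  pair <- if (swap) c(b, a) else c(a, b)
  res <- align_batch(normalize_sequence(unname(pair[1])),
                     normalize_sequence(unname(pair[2])), params)
  structure(list(id_a = names(a), id_b = names(b),
                 L = res$L, X = res$X, p_hat = res$X / res$L),
            class = "alignment_summary")
}

as_named_sequence <- function(x, default_name) {
  if (inherits(x, "hairpin_catalog")) {
    stopifnot(length(x) == 1L)
    return(setNames(x$records$sequence, x$records$identifier))
  }
  stopifnot(is.character(x), length(x) == 1L)
  setNames(unname(x), if (is.null(names(x))) default_name else names(x))
}

#' @export
print.alignment_summary <- function(x, ...) {
  cat(sprintf("%s vs %s: L = %d, X = %d, p_hat = %.6g\n",
              x$id_a, x$id_b, x$L, x$X, x$p_hat))
  invisible(x)
}

#' Jukes-Cantor one-parameter distance
#'
#' Converts an observed proportion of differing nucleotides \code{p_hat}
#' into the expected number of substitutions per site
#' \deqn{K = -\frac{3}{4} \ln\!\left(1 - \frac{4}{3}\hat p\right),}
#' under the one-parameter model in which substitutions occur with equal
#' probability among the four nucleotides. The correction diverges at
#' \code{p_hat >= 3/4} (saturation); such inputs return \code{Inf}, never
#' a silently finite number. Values just below 3/4 map to large finite
#' distances - the heavy right tail of catalog-wide distance data.
#'
#' @param p_hat proportion(s) in [0, 1].
#' @return Numeric vector of distances (substitutions/site); \code{Inf}
#'   where saturated.
#' @examples
#' jukes_cantor(0)     # 0
#' jukes_cantor(0.30)  # 0.3831192...
#' jukes_cantor(0.75)  # Inf (saturated)
#' @export
jukes_cantor <- function(p_hat) {
  stopifnot(is.numeric(p_hat))
  if (any(p_hat < 0 | p_hat > 1, na.rm = TRUE))
    stop2("p_hat must lie in [0, 1]")
  K <- rep(Inf, length(p_hat))
  ok <- !is.na(p_hat) & p_hat < 0.75
  K[ok] <- -0.75 * log(1 - (4 / 3) * p_hat[ok])
  K[ok & K == 0] <- 0  # avoid IEEE negative zero at p_hat = 0
  K[is.na(p_hat)] <- NA_real_
  K
}

#' Number of unordered pairs
#'
#' @param n number of sequences.
#' @return \code{n * (n - 1) / 2}, as a double (exact for catalog sizes).
#' @examples
#' pair_count(1917)  # 1836486
#' @export
pair_count <- function(n) {
  stopifnot(n >= 0)
  n * (n - 1) / 2
}

new_condensed <- function(ids, values, saturated) {
  stopifnot(length(values) == pair_count(length(ids)),
            length(saturated) == length(values))
  structure(list(ids = ids, values = values, saturated = saturated),
            class = "condensed_dist")
}

#' @export
length.condensed_dist <- function(x) length(x$values)

#' @export
print.condensed_dist <- function(x, ...) {
  fin <- x$values[is.finite(x$values)]
  cat(sprintf("Condensed distances: %d sequences, %d pairs\n",
              length(x$ids), length(x$values)))
  if (length(fin))
    cat(sprintf("  finite range (%.5g, %.5g), mean %.6g\n",
                min(fin), max(fin), mean(fin)))
  if (any(x$saturated))
    cat(sprintf("  %d saturated pair(s) (p_hat >= 3/4)\n",
                sum(x$saturated)))
  invisible(x)
}

#' @export
as.matrix.condensed_dist <- function(x, ...) {
  n <- length(x$ids)
  m <- matrix(0, n, n, dimnames = list(x$ids, x$ids))
  m[upper.tri(m)] <- NA  # filled below in row-major pair order
  k <- 1L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    m[i, j] <- m[j, i] <- x$values[k]
    k <- k + 1L
  }
  m
}

#' @export
as.dist.condensed_dist <- function(m, ...) {
  stats::as.dist(as.matrix(m))
}

#' Extract the distance values of a condensed vector
#'
#' @param x a \code{condensed_dist} object.
#' @param finite drop non-finite (saturated) entries.
#' @return numeric vector in row-major pair order (i < j).
#' @export
distance_values <- function(x, finite = FALSE) {
  stopifnot(inherits(x, "condensed_dist"))
  v <- x$values
  if (finite) v[is.finite(v)] else v
}

# Core all-pairs engine over bare sequences. Row-major pair order over
# i < j: for i = 1 the pairs (1,2)...(1,n), then (2,3)..., matching the
# storage convention of stats::dist.
condensed_from_sequences <- function(ids, seqs, params, verbose = FALSE) {
  n <- length(seqs)
  stopifnot(n >= 2L, length(ids) == n)
  npairs <- pair_count(n)
  values <- numeric(npairs)
  saturated <- logical(npairs)
  pos <- 1L
  for (i in seq_len(n - 1L)) {
    res <- align_batch(seqs[(i + 1L):n], seqs[i], params)
    if (any(res$L < 1L))
      stop2("alignment of pair (", ids[i], ", ",
            ids[(i + 1L):n][which(res$L < 1L)[1]],
            ") has no scored columns")
    p <- res$X / res$L
    k <- jukes_cantor(p)
    idx <- pos:(pos + n - i - 1L)
    values[idx] <- k
    saturated[idx] <- p >= 0.75
    pos <- pos + (n - i)
    if (verbose && i %% 25L == 0L)
      message(sprintf("  aligned %d / %d sequences", i, n))
  }
  new_condensed(ids, values, saturated)
}

#' All-pairs Jukes-Cantor distances for a catalog
#'
#' Aligns every unordered pair of catalog sequences and applies the
#' Jukes-Cantor correction, returning the condensed vector of
#' \code{n(n-1)/2} distances in row-major pair order (i < j) over the
#' catalog order. Saturated pairs (\code{p_hat >= 3/4}) are \code{Inf}
#' and flagged in the \code{saturated} mask.
#'
#' With \code{cache} set, the result is written to a self-describing TSV
#' after computing; if the file already exists and records the same
#' identifiers and scoring parameters, it is read back instead of
#' recomputing (stale caches are detected and ignored).
#'
#' @param catalog a \code{\link{hairpin_catalog}} with at least 2 records.
#' @param params an \code{\link{alignment_params}} object.
#' @param cache optional path of a distance cache TSV.
#' @param verbose log progress.
#' @return A \code{condensed_dist} object.
#' @export
pairwise_distances <- function(catalog, params = alignment_params(),
                               cache = NULL, verbose = FALSE) {
  stopifnot(inherits(catalog, "hairpin_catalog"), length(catalog) >= 2L)
  ids <- catalog_ids(catalog)
  if (!is.null(cache) && file.exists(cache)) {
    hit <- tryCatch(read_distances(cache), error = function(e) NULL)
    if (!is.null(hit) && identical(hit$ids, ids) &&
        identical(attr(hit, "params_fingerprint"),
                  params_fingerprint(params))) {
      message("distance cache hit: ", cache)
      return(hit)
    }
    if (verbose) message("stale distance cache ignored: ", cache)
  }
  cd <- condensed_from_sequences(ids, catalog$records$sequence, params,
                                 verbose = verbose)
  if (!is.null(cache)) write_distances(cd, cache, params = params)
  cd
}

#' Pairwise distances for a biomarker panel
#'
#' Resolves the panel names against the catalog (see
#' \code{\link{resolve_panel}}), then computes the condensed distances
#' over exactly the resolved members, in input order; \code{m} names give
#' \code{m(m-1)/2} values. Unresolvable names abort with the full list of
#' failures. Two names resolving to the same stem-loop are kept as
#' distinct members (a warning is emitted); published pair counts assume
#' all listed names are members.
#'
#' @inheritParams resolve_panel
#' @param params an \code{\link{alignment_params}} object.
#' @return A \code{condensed_dist} over the resolved identifiers.
#' @export
panel_distances <- function(names, catalog, params = alignment_params(),
                            policy = "multi-locus-first",
                            species_prefix = "hsa-", name_map = NULL) {
  stopifnot(length(names) >= 2L)
  res <- resolve_panel(names, catalog, policy = policy,
                       species_prefix = species_prefix, name_map = name_map)
  if (anyDuplicated(res$identifier))
    warning("panel names resolve to duplicate stem-loops: ",
            paste(unique(res$identifier[duplicated(res$identifier)]),
                  collapse = ", "), call. = FALSE)
  seqs <- catalog_sequences(catalog)[res$identifier]
  cd <- condensed_from_sequences(res$identifier, unname(seqs), params)
  attr(cd, "queries") <- res$query
  cd
}

#' Write / read a distance cache TSV
#'
#' Plain-text, self-describing format: comment header lines
#' \code{#premirdist-distances}, \code{#ids: ...} (comma separated) and
#' \code{#params: ...} (scoring fingerprint), then one
#' \code{value<TAB>saturated} row per pair, pair indices implicit in
#' row-major order.
#'
#' @param x a \code{condensed_dist}.
#' @param path file path.
#' @param params the \code{\link{alignment_params}} used (stored in the
#'   header for staleness detection).
#' @return \code{path} (write) / a \code{condensed_dist} (read).
#' @export
write_distances <- function(x, path, params = alignment_params()) {
  stopifnot(inherits(x, "condensed_dist"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#premirdist-distances",
               paste0("#ids: ", paste(x$ids, collapse = ",")),
               paste0("#params: ", params_fingerprint(params)),
               "value\tsaturated"), con)
  write.table(data.frame(value = sprintf("%.17g", x$values),
                         saturated = as.integer(x$saturated)),
              con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_distances
#' @export
read_distances <- function(path) {
  if (!file.exists(path)) stop2("distance file not found: ", path)
  hdr <- readLines(path, n = 3L)
  if (!identical(hdr[1], "#premirdist-distances"))
    stop2("not a premirdist distance file: ", path)
  ids <- strsplit(sub("^#ids: ", "", hdr[2]), ",", fixed = TRUE)[[1]]
  fp <- sub("^#params: ", "", hdr[3])
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  vals <- as.numeric(df$value)
  cd <- new_condensed(ids, vals, as.logical(df$saturated))
  attr(cd, "params_fingerprint") <- fp
  cd
}
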