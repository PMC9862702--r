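# Shared fixtures and independent oracles, built in code at test time.

# A tiny hand-written catalog with miRBase-style identifiers.
mirbase_style_catalog <- function() {
  hairpin_catalog(data.frame(
    identifier = c("hsa-mir-21", "hsa-let-7a-1", "hsa-let-7a-2",
                   "hsa-let-7a-3", "hsa-mir-323a", "hsa-mir-323b",
                   "hsa-mir-10a"),
    description = "fixture",
    sequence = c("UAGCUUAUCAGACUGAUGUUGA",
                 "UGAGGUAGUAGGUUGUAUAGUU",
                 "UGAGGUAGUAGGUUGUAUAGUA",
                 "UGAGGUAGUAGGUUGUAUAGUG",
                 "CACAUUACACGGUCGACCUCU",
                 "CACAUUACACGGUCGACCUCA",
                 "UACCCUGUAGAUCCGAAUUUGUG"),
    stringsAsFactors = FALSE))
}

write_tmp_fasta <- function(catalog, width = 60L) {
  path <- tempfile(fileext = ".fa")
  write_hairpin_fasta(catalog, path, width = width)
  path
}

# Hamming distance between two equal-length sequence strings.
hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Independent L/X oracle: run the same Biostrings alignment but count
# columns from the aligned strings, rather than via the C accessors used
# by the package.
string_alignment_counts <- function(a, b, params = alignment_params()) {
  m <- matrix(params$mismatch, 4, 4,
              dimnames = list(c("A", "C", "G", "U"), c("A", "C", "G", "U")))
  diag(m) <- params$match
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::RNAString(a), Biostrings::RNAString(b), type = "global",
    substitutionMatrix = m, gapOpening = params$gap_open,
    gapExtension = params$gap_extend)
  x <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  y <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  keep <- x != "-" & y != "-"
  # no column is gap-over-gap, so "not a match" is simply x != y
  list(L_excluded = sum(keep), X_excluded = sum(x[keep] != y[keep]),
       columns = length(x), X_counted = sum(x != y))
}

# Exact two-sample KS statistic by direct enumeration of both step
# functions over the pooled points.
ks_stat_enumerated <- function(a, b) {
  z <- sort(unique(c(a, b)))
  Fa <- vapply(z, function(q) mean(a <= q), numeric(1))
  Fb <- vapply(z, function(q) mean(b <= q), numeric(1))
  max(abs(Fa - Fb))
}

# Location of an optional locally supplied human hairpin FASTA (the
# miRBase v22.1-era stem-loop file). Full-catalog reproduction checks
# require it; it is not redistributable inside the package.
reference_catalog_path <- function() {
  getOption("premirdist.hairpin_fasta", "")
}

# Memoized full-catalog distances for the reproduction checks.
.reference_env <- new.env(parent = emptyenv())
reference_distances <- function(path) {
  if (is.null(.reference_env$cd)) {
    cat <- read_hairpin_fasta(path, species_prefix = "hsa-")
    .reference_env$catalog <- cat
    .reference_env$cd <- pairwise_distances(
      cat, cache = file.path(tempdir(), "premirdist_ref_distances.tsv"))
  }
  .reference_env$cd
}
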