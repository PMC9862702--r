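#' Generate a synthetic hairpin catalog
#'
#' Draws \code{n} records with i.i.d. bases from \code{composition} and
#' lengths uniform on \code{length_range} (inclusive). Identical
#' \code{(n, length_range, composition, seed)} yield byte-identical
#' catalogs. Used as the deterministic fixture generator for tests and
#' desk-scale studies.
#'
#' @param n number of records.
#' @param length_range integer vector \code{c(min, max)} in nt.
#' @param composition base frequencies for A, C, G, U; must be
#'   nonnegative and sum to 1 (within 1e-9).
#' @param seed integer seed; \code{NULL} uses the current RNG stream.
#' @param prefix identifier prefix; records are numbered
#'   \code{<prefix>0001, ...}.
#' @return A \code{\link{hairpin_catalog}}.
#' @examples
#' generate_fixture_catalog(5, c(60, 60), seed = 1)
#' @export
generate_fixture_catalog <- function(n, length_range = c(50L, 180L),
                                     composition = c(A = 0.25, C = 0.25,
                                                     G = 0.25, U = 0.25),
                                     seed = NULL, prefix = "syn-mir-") {
  stopifnot(n >= 1)
  check_composition(composition)
  check_length_range(length_range)
  with_seed(seed, {
    lens <- sample_length(length_range, n)
    seqs <- vapply(lens, function(L)
      paste(sample(c("A", "C", "G", "U"), L, replace = TRUE,
                   prob = composition), collapse = ""), character(1))
    hairpin_catalog(data.frame(
      identifier = sprintf("%s%04d", prefix, seq_len(n)),
      description = "synthetic fixture",
      sequence = seqs, stringsAsFactors = FALSE))
  })
}

check_composition <- function(composition) {
  if (length(composition) != 4L || any(composition < 0) ||
      abs(sum(composition) - 1) > 1e-9)
    stop2("composition must be 4 nonnegative frequencies summing to 1")
  invisible(TRUE)
}

# Uniform integer lengths on [min, max]; safe when min == max (avoids the
# sample(x) scalar expansion).
sample_length <- function(length_range, n) {
  pool <- seq.int(length_range[1], length_range[2])
  if (length(pool) == 1L) rep(pool, n) else sample(pool, n, replace = TRUE)
}

check_length_range <- function(length_range) {
  if (length(length_range) != 2L || length_range[1] < 1 ||
      length_range[1] > length_range[2])
    stop2("length_range must be c(min, max) with 1 <= min <= max")
  invisible(TRUE)
}

#' Plant an exact number of substitutions into a sequence
#'
#' Substitutes exactly \code{round(fraction * nchar(x))} positions of
#' \code{x} (chosen without replacement) to a \emph{different} base, with
#' no indels, so the Hamming distance between input and output equals that
#' count exactly. This is the oracle for the observed proportion of
#' differing nucleotides: an equal-length pair built this way has a known
#' p-distance.
#'
#' @param x a sequence string over \{A, C, G, U\}.
#' @param fraction proportion of positions to substitute, in [0, 1].
#' @param seed integer seed; \code{NULL} uses the current RNG stream.
#' @return The mutated sequence string.
#' @examples
#' x <- strrep("ACGU", 25)
#' y <- plant_mutations(x, 0.3, seed = 1)
#' sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])  # exactly 30
#' @export
plant_mutations <- function(x, fraction, seed = NULL) {
  stopifnot(is.character(x), length(x) == 1L, nchar(x) >= 1L,
            fraction >= 0, fraction <= 1)
  bases <- c("A", "C", "G", "U")
  chars <- strsplit(normalize_sequence(x), "")[[1]]
  if (!all(chars %in% bases))
    stop2("plant_mutations requires a pure A/C/G/U sequence")
  L <- length(chars)
  k <- round(fraction * L)
  if (k == 0L) return(paste(chars, collapse = ""))
  with_seed(seed, {
    pos <- sample.int(L, k)
    for (p in pos) {
      alt <- bases[bases != chars[p]]
      chars[p] <- alt[sample.int(3L, 1L)]
    }
    paste(chars, collapse = "")
  })
}

#' Generate a family-structured synthetic catalog
#'
#' Emulates the paralog structure of a real precursor-miRNA catalog:
#' most hairpins are singletons, but a minority belong to families of
#' near-identical loci (in miRBase, e.g. the let-7 family or the large
#' C19MC mir-515 cluster). Each family starts from one random seed
#' sequence (\code{\link{generate_fixture_catalog}} conditions); further
#' members are copies with a planted substitution fraction drawn uniformly
#' from \code{divergence}. Multi-member families alternate between
#' arm-letter naming (\code{...-017a}, \code{...-017b}) and locus-suffix
#' naming (\code{...-018-1}, \code{...-018-2}) so that name-resolution
#' collisions occur, as they do for published panel names.
#'
#' Distances within families are small while distances between unrelated
#' families sit near the random-sequence background, giving the skewed,
#' sharply peaked, heavy-right-tailed distance distribution characteristic
#' of real hairpin catalogs.
#'
#' @param n_families number of families.
#' @param size_levels,size_probs family-size distribution; defaults make
#'   most families singletons with occasional large clusters.
#' @param divergence range of the within-family planted substitution
#'   fraction.
#' @param length_range,composition,seed,prefix as in
#'   \code{\link{generate_fixture_catalog}}; the default composition is
#'   mildly G-rich, as hairpin sequences are.
#' @return A \code{\link{hairpin_catalog}}.
#' @export
generate_family_catalog <- function(n_families = 70L,
                                    size_levels = c(1L, 2L, 3L, 4L, 8L, 12L),
                                    size_probs = c(0.55, 0.20, 0.10,
                                                   0.08, 0.05, 0.02),
                                    divergence = c(0.02, 0.35),
                                    length_range = c(50L, 180L),
                                    composition = c(A = 0.22, C = 0.26,
                                                    G = 0.30, U = 0.22),
                                    seed = NULL, prefix = "syn-mir-") {
  stopifnot(n_families >= 1, length(size_levels) == length(size_probs),
            all(size_levels >= 1), diff(divergence) >= 0,
            divergence[1] >= 0, divergence[2] <= 1)
  check_composition(composition)
  check_length_range(length_range)
  with_seed(seed, {
    ids <- character(0); seqs <- character(0); desc <- character(0)
    bases <- c("A", "C", "G", "U")
    sizes <- sample(size_levels, n_families, replace = TRUE,
                    prob = size_probs)
    for (f in seq_len(n_families)) {
      L <- sample_length(length_range, 1L)
      seed_seq <- paste(sample(bases, L, replace = TRUE,
                               prob = composition), collapse = "")
      m <- sizes[f]
      base_id <- sprintf("%s%03d", prefix, f)
      if (m == 1L) {
        ids <- c(ids, base_id); seqs <- c(seqs, seed_seq)
        desc <- c(desc, "synthetic singleton")
        next
      }
      arm_style <- f %% 2L == 0L
      fam_ids <- if (arm_style) paste0(base_id, letters[seq_len(m)])
                 else paste0(base_id, "a-", seq_len(m))
      fam_seqs <- c(seed_seq, vapply(seq_len(m - 1L), function(k)
        plant_mutations(seed_seq, runif(1, divergence[1], divergence[2])),
        character(1)))
      ids <- c(ids, fam_ids); seqs <- c(seqs, fam_seqs)
      desc <- c(desc, rep(sprintf("synthetic family %d", f), m))
    }
    hairpin_catalog(data.frame(identifier = ids, description = desc,
                               sequence = seqs, stringsAsFactors = FALSE))
  })
}
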