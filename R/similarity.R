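#' Percentile table of a fitted distance distribution
#'
#' Tabulates the \code{q}th percentiles of a fitted model for a vector of
#' percents, one row per \code{q}. By convention the \code{q = 100} row
#' is the maximum \emph{observed} distance rather than the model's 100\%
#' quantile: the KDE has unbounded support, so only the sample maximum
#' gives a finite, meaningful table entry.
#'
#' @param model a \code{\link[=fit_distance_distribution]{dist_fit}}.
#' @param qs percents in (0, 100], strictly increasing.
#' @return data frame of class \code{quantile_table} with columns
#'   \code{q} and \code{value}.
#' @export
quantile_table <- function(model, qs = seq(5, 100, by = 5)) {
  stopifnot(inherits(model, "dist_fit"),
            all(qs > 0 & qs <= 100), !is.unsorted(qs, strictly = TRUE))
  value <- dist_quantile(model, qs / 100)
  value[qs == 100] <- model$data_max
  structure(data.frame(q = qs, value = value),
            class = c("quantile_table", "data.frame"),
            source_family = model$family)
}

#' Load the packaged human reference percentile table
#'
#' The published percentile table of the human pre-miRNA Jukes-Cantor
#' distance distribution (1917 miRBase v22.1 stem-loops, 1,836,486
#' pairwise distances, Gaussian KDE at bandwidth 0.00973513), shipped as
#' plain text so panels can be ranked without recomputing the full
#' catalog model.
#'
#' @return A \code{\link{quantile_table}} with rows q = 5, 10, ..., 100.
#' @export
reference_percentile_table <- function() {
  path <- system.file("extdata", "hsa_premirna_percentiles.tsv",
                      package = "premirdist", mustWork = TRUE)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  structure(data.frame(q = as.numeric(df$q), value = as.numeric(df$value)),
            class = c("quantile_table", "data.frame"),
            source_family = "reference")
}

#' Percentile rank of a distance
#'
#' Two semantics are supported, both used in practice:
#' \describe{
#'   \item{\code{"continuous"}}{\code{100 * cdf(d)} under the fitted
#'     model - the default for scoring panel means.}
#'   \item{\code{"nearest-table"}}{the tabulated \code{q} whose value is
#'     closest to \code{d} (ties go to the smaller \code{q}) - the
#'     rank-lookup rule used with a printed percentile table.}
#' }
#'
#' @param d distance value(s).
#' @param model a \code{dist_fit} (required for continuous mode).
#' @param mode percentile semantics.
#' @param table a \code{\link{quantile_table}} (required for
#'   nearest-table mode).
#' @return percent value(s) in [0, 100].
#' @examples
#' percentile_of(0.81, mode = "nearest-table",
#'               table = reference_percentile_table())  # 15
#' @export
percentile_of <- function(d, model = NULL,
                          mode = c("continuous", "nearest-table"),
                          table = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(d))
  if (mode == "continuous") {
    if (is.null(model)) stop2("continuous mode requires a fitted model")
    return(100 * dist_cdf(model, d))
  }
  if (is.null(table)) stop2("nearest-table mode requires a quantile table")
  stopifnot(inherits(table, "quantile_table"))
  tab <- table[order(table$q), , drop = FALSE]
  vapply(d, function(di) tab$q[which.min(abs(tab$value - di))],
         numeric(1))
}

#' Similarity verdict at a percentile threshold
#'
#' A distance (or panel mean) at percentile rank \code{percentile} is
#' called similar when its rank is strictly below the chosen threshold
#' percentile \code{threshold_p}.
#'
#' @param percentile,threshold_p percents in (0, 100].
#' @return logical.
#' @export
is_similar <- function(percentile, threshold_p) {
  stopifnot(percentile >= 0, percentile <= 100,
            threshold_p > 0, threshold_p <= 100)
  percentile < threshold_p
}

#' Score a biomarker panel against a reference distribution
#'
#' Resolves the panel names, computes all pairwise distances among the
#' resolved stem-loops, and summarizes them: mean (finite pairs only;
#' saturated pairs are excluded with a warning), range, the percentile
#' rank of the mean under \code{model}, and - when \code{threshold_p} is
#' given - the similarity verdict.
#'
#' @inheritParams panel_distances
#' @param model a fitted \code{dist_fit} used as the reference
#'   distribution (continuous mode), or \code{NULL} when \code{mode =
#'   "nearest-table"}.
#' @param threshold_p optional threshold percentile in (0, 100].
#' @param mode percentile semantics (see \code{\link{percentile_of}}).
#' @param table quantile table for nearest-table mode.
#' @return An object of class \code{panel_report}: queries, resolved
#'   identifiers (with ambiguity flags), panel size \code{m},
#'   \code{pair_count}, the \code{condensed_dist}, \code{mean},
#'   \code{range}, \code{percentile_of_mean}, \code{threshold_p},
#'   \code{similar}, and the number of excluded saturated pairs.
#' @export
analyze_panel <- function(names, catalog, model,
                          params = alignment_params(),
                          policy = "multi-locus-first",
                          species_prefix = "hsa-", name_map = NULL,
                          threshold_p = NULL,
                          mode = c("continuous", "nearest-table"),
                          table = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(names) >= 2L)
  resolved <- resolve_panel(names, catalog, policy = policy,
                            species_prefix = species_prefix,
                            name_map = name_map)
  cd <- condensed_from_sequences(
    resolved$identifier,
    unname(catalog_sequences(catalog)[resolved$identifier]), params)
  vals <- cd$values
  n_sat <- sum(!is.finite(vals))
  if (n_sat > 0) {
    warning(n_sat, " saturated pair(s) excluded from the panel mean",
            call. = FALSE)
    vals <- vals[is.finite(vals)]
  }
  m <- nrow(resolved)
  mu <- mean(vals)
  pct <- percentile_of(mu, model = model, mode = mode, table = table)
  structure(list(queries = names, resolved = resolved, m = m,
                 pair_count = pair_count(m), distances = cd,
                 mean = mu, range = range(vals),
                 percentile_of_mean = pct,
                 threshold_p = threshold_p,
                 similar = if (!is.null(threshold_p))
                   is_similar(pct, threshold_p) else NULL,
                 n_saturated = n_sat),
            class = "panel_report")
}

#' @export
print.panel_report <- function(x, ...) {
  cat(sprintf("Biomarker panel: %d miRNAs, %d pairwise distances\n",
              x$m, length(x$distances)))
  if (any(x$resolved$ambiguous))
    cat("  ambiguous names: ",
        paste(x$resolved$query[x$resolved$ambiguous], collapse = ", "),
        "\n", sep = "")
  cat(sprintf("  mean distance  %.6g\n", x$mean))
  cat(sprintf("  range          (%.6g, %.6g)\n",
              x$range[1], x$range[2]))
  cat(sprintf("  percentile     %.4g\n", x$percentile_of_mean))
  if (x$n_saturated > 0)
    cat(sprintf("  excluded %d saturated pair(s)\n", x$n_saturated))
  if (!is.null(x$similar))
    cat(sprintf("  similar at p < %g: %s\n", x$threshold_p,
                if (x$similar) "yes" else "no"))
  invisible(x)
}
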