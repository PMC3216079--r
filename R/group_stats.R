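# Study-level statistics over per-hip damage tables.

#' Per-approach damage table
#'
#' Container for percentage muscle damage measured in a set of hips under
#' each surgical approach: a named list of numeric vectors, one per
#' approach, all values in `[0, 100]`.
#'
#' @param values named list of numeric vectors of damage percentages.
#' @return an object of class `"damage_table"`.
#' @export
damage_table <- function(values) {
  if (!is.list(values) || length(values) == 0L) {
    stop("'values' must be a non-empty list of numeric vectors", call. = FALSE)
  }
  if (is.null(names(values)) || any(!nzchar(names(values)))) {
    names(values) <- paste0("group", seq_along(values))
  }
  for (nm in names(values)) {
    v <- values[[nm]]
    if (!is.numeric(v) || length(v) == 0L) {
      stop(sprintf("group '%s' must be a non-empty numeric vector", nm),
           call. = FALSE)
    }
    if (anyNA(v) || any(v < 0 | v > 100)) {
      stop(sprintf("group '%s' has values outside [0, 100]", nm), call. = FALSE)
    }
  }
  structure(values, class = "damage_table")
}

#' @export
print.damage_table <- function(x, ...) {
  cat(sprintf("<damage_table> %d approaches: %s\n", length(x),
              paste(sprintf("%s (n=%d)", names(x), lengths(x)), collapse = ", ")))
  invisible(x)
}

#' Group medians and ranges
#'
#' Describes each approach by its median damage percentage and range,
#' matching the descriptive convention for small, skewed samples. Medians of
#' even-sized groups are the mean of the two central order statistics.
#'
#' @param table a [damage_table()].
#' @return a data frame with columns `approach`, `n`, `median`, `min`, `max`.
#' @export
summarize_groups <- function(table) {
  stopifnot(inherits(table, "damage_table"))
  data.frame(approach = names(table),
             n = unname(lengths(table)),
             median = vapply(table, stats::median, numeric(1), USE.NAMES = FALSE),
             min = vapply(table, min, numeric(1), USE.NAMES = FALSE),
             max = vapply(table, max, numeric(1), USE.NAMES = FALSE),
             row.names = NULL)
}

#' Joint Kruskal-Wallis test across all approaches
#'
#' Rank-based k-group test of identical distributions with mid-rank ties
#' correction and the chi-square approximation on k - 1 degrees of freedom
#' (computed by [stats::kruskal.test()]). When every observation is
#' identical the statistic is 0 and p = 1.
#'
#' @param table a [damage_table()] with at least 2 groups.
#' @return a list with `statistic` (ties-corrected H), `df` and `p_value`.
#' @export
kruskal_wallis <- function(table) {
  stopifnot(inherits(table, "damage_table"))
  if (length(table) < 2L) stop("need at least 2 groups", call. = FALSE)
  values <- unlist(table, use.names = FALSE)
  groups <- factor(rep(names(table), lengths(table)), levels = names(table))
  if (length(unique(values)) == 1L) {
    return(list(statistic = 0, df = length(table) - 1L, p_value = 1))
  }
  kt <- stats::kruskal.test(values, groups)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' Pairwise Kruskal-Wallis tests against a reference approach
#'
#' Two-group rank tests of each remaining approach against a reference
#' (conventional) approach; the caller applies a Bonferroni-adjusted
#' threshold from [bonferroni_threshold()].
#'
#' @param table a [damage_table()].
#' @param reference name or index of the reference group (default first).
#' @return a data frame with one row per comparison: `approach`,
#'   `statistic`, `df`, `p_value`.
#' @export
kruskal_wallis_pairwise <- function(table, reference = 1L) {
  stopifnot(inherits(table, "damage_table"))
  ref <- if (is.character(reference)) reference else names(table)[reference]
  if (!ref %in% names(table)) stop("unknown reference group", call. = FALSE)
  others <- setdiff(names(table), ref)
  rows <- lapply(others, function(nm) {
    kw <- kruskal_wallis(damage_table(table[c(ref, nm)]))
    data.frame(approach = nm, statistic = kw$statistic, df = kw$df,
               p_value = kw$p_value)
  })
  do.call(rbind, rows)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha family-wise significance level, in (0, 1).
#' @param m number of comparisons, `>= 1`.
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 5) # 0.01
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("'alpha' must lie in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(m) || m < 1 || m != floor(m)) {
    stop("'m' must be a positive integer", call. = FALSE)
  }
  alpha / m
}

#' Frequency table for dichotomous structure outcomes
#'
#' Tabulates counts of affected hips per anatomical structure and approach
#' (e.g. released external rotators, transected nerves), optionally split by
#' a categorical state (e.g. ligament released / partial / intact).
#'
#' @param records data frame with columns `structure`, `approach`, `count`
#'   and optionally `state`.
#' @param n_per_group hips per approach; counts must lie in
#'   `[0, n_per_group]`.
#' @return a matrix of counts with structures (x states) as rows and
#'   approaches as columns, plus a `total` column.
#' @export
tabulate_dichotomous <- function(records, n_per_group = 5L) {
  req <- c("structure", "approach", "count")
  if (!all(req %in% names(records))) {
    stop("records need columns: structure, approach, count", call. = FALSE)
  }
  if (any(records$count < 0 | records$count > n_per_group)) {
    stop(sprintf("counts must lie in [0, %d]", n_per_group), call. = FALSE)
  }
  rowvar <- if ("state" %in% names(records)) {
    paste(records$structure, records$state, sep = " / ")
  } else {
    records$structure
  }
  rowf <- factor(rowvar, levels = unique(rowvar))
  colf <- factor(records$approach, levels = unique(records$approach))
  tab <- stats::xtabs(count ~ rowf + colf, data =
                        data.frame(count = records$count, rowf, colf))
  out <- matrix(as.numeric(tab), nrow = nrow(tab),
                dimnames = list(rownames(tab), colnames(tab)))
  cbind(out, total = rowSums(out))
}
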