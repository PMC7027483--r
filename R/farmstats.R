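# Farm-neighbourhood statistics: zonal means of forest-carbon layers in
# circular buffers around farm centroids, Spearman correlations of farm
# indicators with those layers, and pairwise Wilcoxon rank-sum tests
# between farm types with Holm correction and a compact letter display.

#' Zonal means of forest-carbon layers around farms
#'
#' For each farm, the mean of each layer over valid (forest) pixels whose
#' centres fall within the circular buffer of the given radius. Farms with
#' no valid pixel in reach are flagged (`n_forest_pixels = 0`, stats `NA`)
#' and should be excluded from correlations.
#'
#' @param farms a `farm_survey` (needs `x`, `y`, `farm_id`).
#' @param layers named list of co-registered `grid_layer`s.
#' @param radius buffer radius in metres (default 5,000 m).
#' @return data.frame: `farm_id`, `n_forest_pixels`, one mean column per
#'   layer.
#' @export
neighbourhood_stats <- function(farms, layers, radius = 5000) {
  if (radius <= 0) stop("radius must be positive")
  l1 <- layers[[1]]
  if (grepl("deg|4326|longlat|geographic", l1$crs, ignore.case = TRUE))
    stop("neighbourhood buffers require projected coordinates in metres")
  for (l in layers) check_same_grid(l1, l)
  ctr <- pixel_centers(l1)
  px <- as.vector(ctr$x); py <- as.vector(ctr$y)
  out <- data.frame(farm_id = farms$farm_id,
                    n_forest_pixels = 0L)
  for (nm in names(layers)) out[[nm]] <- NA_real_
  vals <- lapply(layers, function(l) as.vector(l$values))
  for (k in seq_len(nrow(farms))) {
    inb <- (px - farms$x[k])^2 + (py - farms$y[k])^2 <= radius^2
    valid <- inb & !is.na(vals[[1]])
    out$n_forest_pixels[k] <- sum(valid)
    if (any(valid))
      for (nm in names(layers))
        out[[nm]][k] <- mean(vals[[nm]][inb & !is.na(vals[[nm]])])
  }
  out
}

#' Spearman correlations between farm indicators and forest-carbon stats
#'
#' Computes Spearman's rho with a two-sided p-value for every indicator x
#' layer pair, and flags indicator pairs that are themselves highly
#' rank-correlated (|rho| >= `collinearity_cutoff`) as collinear.
#'
#' @param survey a `farm_survey`.
#' @param stats output of [neighbourhood_stats()] (or any data.frame of
#'   per-farm layer statistics aligned by `farm_id`).
#' @param indicators character vector of survey columns to use.
#' @param collinearity_cutoff |rho| threshold for the collinearity flags.
#' @return list: `correlations` (indicator, layer, rho, p, n) and
#'   `collinear` (pairs of indicators above the cutoff).
#' @export
indicator_correlations <- function(survey, stats,
                                   indicators = names(default_effect_sizes()),
                                   collinearity_cutoff = 0.7) {
  layer_cols <- setdiff(names(stats), c("farm_id", "n_forest_pixels"))
  m <- merge(as.data.frame(survey), stats, by = "farm_id")
  if ("n_forest_pixels" %in% names(m))
    m <- m[m$n_forest_pixels > 0 | !length(layer_cols), , drop = FALSE]
  rows <- list()
  for (ind in indicators) for (lay in layer_cols) {
    ok <- stats::complete.cases(m[[ind]], m[[lay]])
    n <- sum(ok)
    if (n < 10) {
      rows[[length(rows) + 1]] <- data.frame(
        indicator = ind, layer = lay, rho = NA_real_, p = NA_real_, n = n)
      next
    }
    if (stats::sd(m[[ind]][ok]) == 0 || stats::sd(m[[lay]][ok]) == 0) {
      rows[[length(rows) + 1]] <- data.frame(
        indicator = ind, layer = lay, rho = NA_real_, p = NA_real_, n = n)
      next
    }
    ct <- suppressWarnings(stats::cor.test(m[[ind]][ok], m[[lay]][ok],
                                           method = "spearman"))
    rows[[length(rows) + 1]] <- data.frame(
      indicator = ind, layer = lay, rho = unname(ct$estimate),
      p = ct$p.value, n = n)
  }
  cors <- do.call(rbind, rows)
  coll <- list()
  if (length(indicators) > 1) {
    cm <- suppressWarnings(
      stats::cor(m[indicators], method = "spearman",
                 use = "pairwise.complete.obs"))
    pr <- which(abs(cm) >= collinearity_cutoff & upper.tri(cm),
                arr.ind = TRUE)
    if (nrow(pr))
      coll <- data.frame(indicator_a = indicators[pr[, 1]],
                         indicator_b = indicators[pr[, 2]],
                         rho = cm[pr])
  }
  list(correlations = cors,
       collinear = if (length(coll)) coll else
         data.frame(indicator_a = character(), indicator_b = character(),
                    rho = numeric()))
}

#' Pairwise Wilcoxon rank-sum tests between farm types
#'
#' For each forest-carbon statistic, all pairwise Wilcoxon rank-sum tests
#' between farm types with Holm-adjusted p-values (mid-ranks with normal
#' approximation and tie correction for larger groups, exact otherwise —
#' the default behaviour of the underlying test), plus a compact letter
#' display of significance groups. Types with fewer than `min_n` farms
#' are excluded with a warning.
#'
#' @param survey a `farm_survey` (needs `farm_type`).
#' @param stats output of [neighbourhood_stats()].
#' @param variables columns of `stats` to test; default: all layer means.
#' @param alpha significance level for the letter display.
#' @param min_n minimum farms per type.
#' @return list per variable: `pairs` (type_a, type_b, p_adj) and
#'   `letters` (named compact letter display).
#' @export
farm_type_tests <- function(survey, stats, variables = NULL,
                            alpha = 0.05, min_n = 5) {
  m <- merge(as.data.frame(survey), stats, by = "farm_id")
  if ("n_forest_pixels" %in% names(m)) m <- m[m$n_forest_pixels > 0, ]
  if (is.null(variables))
    variables <- setdiff(names(stats), c("farm_id", "n_forest_pixels"))
  counts <- table(m$farm_type)
  small <- names(counts)[counts < min_n]
  if (length(small)) {
    warning("excluding farm type(s) with < ", min_n, " farms: ",
            paste(small, collapse = ", "))
    m <- m[!m$farm_type %in% small, ]
  }
  types <- sort(unique(m$farm_type))
  if (length(types) < 2)
    stop("need at least two farm types with >= ", min_n, " farms")
  out <- list()
  for (v in variables) {
    pw <- suppressWarnings(
      stats::pairwise.wilcox.test(m[[v]], m$farm_type,
                                  p.adjust.method = "holm"))
    pm <- pw$p.value
    pairs <- data.frame(type_a = character(), type_b = character(),
                        p_adj = numeric())
    for (i in rownames(pm)) for (j in colnames(pm))
      if (!is.na(pm[i, j]))
        pairs <- rbind(pairs, data.frame(type_a = j, type_b = i,
                                         p_adj = pm[i, j]))
    means <- tapply(m[[v]], m$farm_type, mean, na.rm = TRUE)
    out[[v]] <- list(pairs = pairs,
                     letters = letter_display(pairs, names(means)[
                       order(means)], alpha = alpha))
  }
  out
}

#' Compact letter display from pairwise adjusted p-values
#'
#' Insert-and-absorb algorithm: groups ordered by mean share a letter iff
#' no pair within the letter differs significantly.
#'
#' @param pairs data.frame `type_a`, `type_b`, `p_adj`.
#' @param ordered_types type labels ordered (e.g. by group mean).
#' @param alpha significance level.
#' @return named character vector of letter codes.
#' @export
letter_display <- function(pairs, ordered_types, alpha = 0.05) {
  differs <- function(a, b) {
    hit <- (pairs$type_a == a & pairs$type_b == b) |
      (pairs$type_a == b & pairs$type_b == a)
    any(pairs$p_adj[hit] < alpha)
  }
  groups <- list()
  for (t in ordered_types) {
    placed <- FALSE
    for (g in seq_along(groups)) {
      if (!any(vapply(groups[[g]], differs, logical(1), b = t))) {
        groups[[g]] <- c(groups[[g]], t)
        placed <- TRUE
      }
    }
    if (!placed) groups[[length(groups) + 1]] <- t
  }
  out <- stats::setNames(rep("", length(ordered_types)), ordered_types)
  for (g in seq_along(groups))
    for (t in groups[[g]])
      out[t] <- paste0(out[t], letters[g])
  out
}
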