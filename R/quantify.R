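# Fractional distribution of each stain class across the base/middle/tip
# regions, cohort summaries, and region comparisons.

#' Fractional distribution of stain classes across leaflet regions
#'
#' For each stain class, the percent of that class's total pixels falling in
#' each region: `percent(region, class) = 100 * count(class & region) /
#' count(class)`. The denominator is the class total over the whole leaflet,
#' so the three percentages sum to 100 per class. A class with zero stained
#' pixels has an undefined distribution, reported as `NA` (never 0/0).
#'
#' @param stain_masks Named list of logical class masks (from
#'   [classify_stain()]), or a named list/vector structure of per-region
#'   counts (see [distribution_from_counts()]).
#' @param partition A `region_partition` of matching dimensions.
#' @return A `regional_distribution`: data.frame with columns `class`,
#'   `region` (base/middle/tip), `count`, `percent`.
#' @examples
#' distribution_from_counts(c(base = 264, middle = 207, tip = 529), "elastin")
#' @export
regional_fractions <- function(stain_masks, partition) {
  stopifnot(inherits(partition, "region_partition"), length(stain_masks) > 0,
            !is.null(names(stain_masks)))
  labels <- unclass(partition)
  rows <- lapply(names(stain_masks), function(cl) {
    m <- stain_masks[[cl]]
    if (!all(dim(m) == dim(labels))) {
      stop("stain mask '", cl, "' dimensions differ from the partition")
    }
    counts <- vapply(1:3, function(k) sum(m & labels == k), numeric(1))
    total <- sum(counts)
    data.frame(class = cl, region = factor(REGION_LEVELS, REGION_LEVELS),
               count = as.integer(counts),
               percent = if (total > 0) 100 * counts / total else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  undefined <- unique(out$class[is.na(out$percent)])
  if (length(undefined) > 0) {
    message("class(es) with zero stained pixels, distribution undefined: ",
            paste(undefined, collapse = ", "))
  }
  class(out) <- c("regional_distribution", class(out))
  out
}

#' Build a regional distribution directly from per-region counts
#'
#' @param counts Named numeric vector with elements `base`, `middle`, `tip`.
#' @param class Stain class name.
#' @return A `regional_distribution` (see [regional_fractions()]).
#' @export
distribution_from_counts <- function(counts, class = "stain") {
  stopifnot(all(REGION_LEVELS %in% names(counts)))
  counts <- counts[REGION_LEVELS]
  total <- sum(counts)
  out <- data.frame(class = class,
                    region = factor(REGION_LEVELS, REGION_LEVELS),
                    count = as.integer(counts),
                    percent = if (total > 0) 100 * counts / total else NA_real_,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("regional_distribution", class(out))
  out
}

cohort_long <- function(distributions) {
  stopifnot(length(distributions) >= 1)
  classes0 <- sort(unique(distributions[[1]]$class))
  for (i in seq_along(distributions)) {
    cl <- sort(unique(distributions[[i]]$class))
    if (!identical(cl, classes0)) {
      stop("leaflet ", i, " has class set {", paste(cl, collapse = ", "),
           "} but leaflet 1 has {", paste(classes0, collapse = ", "), "}")
    }
  }
  ids <- names(distributions) %||% as.character(seq_along(distributions))
  if (is.null(names(distributions))) {
    ids <- paste0("leaflet", seq_along(distributions))
  }
  do.call(rbind, Map(function(d, id) {
    cbind(leaflet = id, as.data.frame(d))
  }, distributions, ids))
}

#' Cohort summary: mean and SD of regional percentages
#'
#' Arithmetic mean and sample standard deviation (n-1 denominator) of the
#' per-leaflet percentages, per class and region. With a single leaflet the
#' SD is reported as `NA`.
#'
#' @param distributions List of `regional_distribution` (one per leaflet),
#'   all with the same class set.
#' @return data.frame with columns `class`, `region`, `n`, `mean_pct`,
#'   `sd_pct`, and `label` rendered as `"m ± s%"` to one decimal.
#' @export
summarize_cohort <- function(distributions) {
  long <- cohort_long(distributions)
  key <- interaction(long$class, long$region, drop = FALSE)
  rows <- lapply(split(long, key), function(d) {
    p <- d$percent[!is.na(d$percent)]
    n <- length(p)
    m <- if (n > 0) mean(p) else NA_real_
    s <- if (n > 1) stats::sd(p) else NA_real_
    data.frame(class = d$class[1], region = d$region[1], n = n,
               mean_pct = m, sd_pct = s,
               label = if (n > 1) sprintf("%.1f ± %.1f%%", m, s)
                       else sprintf("%.1f%%", m),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$class, out$region), , drop = FALSE]
  rownames(out) <- NULL
  out
}

signif_tier <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

# One-way F statistic across the three regions, computed from sums of
# squares; used by the permutation test so the statistic is identical for
# observed and permuted tables.
oneway_f <- function(values, groups) {
  gm <- mean(values)
  parts <- split(values, groups)
  ssb <- sum(vapply(parts, function(v) length(v) * (mean(v) - gm)^2, numeric(1)))
  ssw <- sum(vapply(parts, function(v) sum((v - mean(v))^2), numeric(1)))
  dfb <- length(parts) - 1
  dfw <- length(values) - length(parts)
  if (ssw == 0) return(if (ssb == 0) 0 else Inf)
  (ssb / dfb) / (ssw / dfw)
}

# All 6 orderings of the three region labels.
PERM3 <- rbind(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))

#' Compare regional percentages across base/middle/tip
#'
#' Per stain class, tests whether the fractional distribution differs across
#' the three leaflet regions. The default is a one-way ANOVA
#' ([stats::aov()]) with Tukey HSD pairwise follow-up. The alternative is a
#' permutation test that re-labels the three region values *within* each
#' leaflet (respecting the per-leaflet sum-to-100 constraint) and uses the
#' one-way F statistic; it enumerates all `6^n` label assignments
#' exhaustively when that is at most `max_exact`, otherwise samples `nperm`
#' random assignments (Monte-Carlo p with the +1 correction). Significance
#' tiers are `*` p < 0.05, `**` p < 0.01, `***` p < 0.001.
#'
#' @param distributions List of `regional_distribution`, one per leaflet
#'   (n >= 2).
#' @param method `"anova"` or `"permutation"`.
#' @param nperm Random permutations when not exhaustive.
#' @param max_exact Enumerate exhaustively while `6^n <= max_exact`.
#' @param seed Seed for the Monte-Carlo branch.
#' @return List with `overall` (class, method, statistic, p_value, tier,
#'   exact) and `pairwise` (ANOVA only: Tukey-adjusted region contrasts).
#' @export
compare_regions <- function(distributions,
                            method = c("anova", "permutation"),
                            nperm = 2000, max_exact = 46656, seed = 1) {
  method <- match.arg(method)
  if (length(distributions) < 2) {
    stop("need at least 2 leaflets for a region comparison (got ",
         length(distributions), ")")
  }
  long <- cohort_long(distributions)
  if (anyNA(long$percent)) {
    stop("undefined (zero-total) distributions present; drop those classes first")
  }
  classes <- unique(long$class)
  overall <- list(); pairwise <- list()
  for (cl in classes) {
    d <- long[long$class == cl, ]
    if (method == "anova") {
      fit <- stats::aov(percent ~ region, data = d)
      tab <- summary(fit)[[1]]
      fstat <- tab[["F value"]][1]
      p <- tab[["Pr(>F)"]][1]
      tk <- stats::TukeyHSD(fit)$region
      pairwise[[cl]] <- data.frame(class = cl,
                                   contrast = rownames(tk),
                                   diff = tk[, "diff"],
                                   p_adj = tk[, "p adj"],
                                   tier = signif_tier(tk[, "p adj"]),
                                   stringsAsFactors = FALSE)
      overall[[cl]] <- data.frame(class = cl, method = "one-way ANOVA",
                                  statistic = fstat, p_value = p,
                                  tier = signif_tier(p), exact = NA,
                                  stringsAsFactors = FALSE)
    } else {
      vals <- matrix(d$percent[order(d$leaflet, d$region)],
                     ncol = 3, byrow = TRUE) # one row per leaflet: b, m, t
      n <- nrow(vals)
      region_idx <- rep(1:3, times = n)
      obs <- oneway_f(as.vector(t(vals)), region_idx)
      exact <- (6^n) <= max_exact
      eps <- 1e-12
      if (exact) {
        grids <- rep(list(1:6), n)
        combos <- as.matrix(expand.grid(grids))
        stat <- apply(combos, 1, function(rowp) {
          permuted <- vapply(seq_len(n), function(i) vals[i, PERM3[rowp[i], ]],
                             numeric(3))
          oneway_f(as.vector(permuted), region_idx)
        })
        p <- mean(stat >= obs - eps)
      } else {
        stat <- with_seed(seed, vapply(seq_len(nperm), function(b) {
          permuted <- vapply(seq_len(n), function(i)
            vals[i, PERM3[sample.int(6, 1), ]], numeric(3))
          oneway_f(as.vector(permuted), region_idx)
        }, numeric(1)))
        p <- (1 + sum(stat >= obs - eps)) / (1 + nperm)
      }
      overall[[cl]] <- data.frame(class = cl,
                                  method = "within-leaflet permutation F",
                                  statistic = obs, p_value = p,
                                  tier = signif_tier(p), exact = exact,
                                  stringsAsFactors = FALSE)
    }
  }
  res <- list(overall = do.call(rbind, c(overall, make.row.names = FALSE)),
              pairwise = if (length(pairwise) > 0)
                do.call(rbind, c(pairwise, make.row.names = FALSE)) else NULL)
  res
}

#' Bar plot of a cohort summary (mean ± SD per class and region)
#'
#' @param summary Output of [summarize_cohort()].
#' @return A ggplot object.
#' @export
plot_cohort <- function(summary) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_cohort() needs the ggplot2 package")
  }
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = region, y = mean_pct)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = pmax(mean_pct - sd_pct, 0),
      ymax = mean_pct + sd_pct), width = 0.25) +
    ggplot2::facet_wrap(~class) +
    ggplot2::labs(x = NULL, y = "fraction of stain (%)") +
    ggplot2::theme_minimal()
}
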