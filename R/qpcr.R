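# Relative qPCR expression by the Livak 2^-ddCt method.

#' Read and validate a Ct table
#'
#' A Ct table holds one row per technical replicate with columns
#' `sample`, `group`, `gene`, `replicate`, `ct`. Ct values are cycle
#' thresholds and must lie in `[1, 45]`.
#'
#' @param x A data.frame with the columns above, or a path to such a CSV.
#' @return The validated data.frame (class `ct_table` prepended).
#' @export
ct_table <- function(x) {
  if (is.character(x)) x <- utils::read.csv(x, stringsAsFactors = FALSE)
  need <- c("sample", "group", "gene", "replicate", "ct")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    stop("Ct table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (!is.numeric(x$ct) || anyNA(x$ct)) stop("ct column must be numeric, no NA")
  if (any(x$ct < 1 | x$ct > 45)) {
    stop("Ct values outside [1, 45]: check the table")
  }
  class(x) <- unique(c("ct_table", class(x)))
  x
}

#' Collapse technical replicates to per-sample mean Ct
#'
#' Arithmetic mean of the replicate Ct values per (sample, group, gene).
#' With `outlier_policy = TRUE`, replicates farther than 0.5 Ct from the
#' within-well median are dropped before averaging (off by default).
#'
#' @param table A [ct_table()] (or coercible data.frame / CSV path).
#' @param outlier_policy Drop replicates > 0.5 Ct from the median first?
#' @return data.frame with columns `sample`, `group`, `gene`, `ct_mean`,
#'   `n_replicates`.
#' @export
collapse_replicates <- function(table, outlier_policy = FALSE) {
  table <- ct_table(table)
  key <- interaction(table$sample, table$gene, drop = TRUE)
  parts <- split(seq_len(nrow(table)), key)
  rows <- lapply(parts, function(idx) {
    ct <- table$ct[idx]
    if (outlier_policy && length(ct) >= 2) {
      keep <- abs(ct - stats::median(ct)) <= 0.5
      if (any(keep)) ct <- ct[keep]
    }
    data.frame(sample = table$sample[idx[1]],
               group = table$group[idx[1]],
               gene = table$gene[idx[1]],
               ct_mean = mean(ct),
               n_replicates = length(ct),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$sample, out$gene), , drop = FALSE]
}

#' Relative expression by 2^-ddCt
#'
#' Livak relative quantification: per sample,
#' `dCt = Ct(target) - Ct(reference)`; per group, `ddCt = mean dCt(group) -
#' mean dCt(control)`; relative expression `fold = 2^-ddCt`. The control
#' group's fold is exactly 1 by construction.
#'
#' @param table A [ct_table()] (or data.frame / CSV path). Technical
#'   replicates are collapsed with [collapse_replicates()] first.
#' @param reference_gene Housekeeping gene name (e.g. `"GAPDH"`).
#' @param target_gene Gene of interest (e.g. `"ELN"`).
#' @param control_group Name of the baseline group.
#' @param outlier_policy Passed to [collapse_replicates()].
#' @return data.frame with one row per group: `group`, `n`, `delta_ct_mean`,
#'   `delta_ct_sd`, `delta_delta_ct`, `fold_change`, `fold_sd`, `fold_sem`.
#'   `fold_sd`/`fold_sem` describe the spread of per-sample folds
#'   `2^-(dCt_i - mean dCt(control))`.
#' @examples
#' tab <- generate_ct_table(ct_design(fold_changes = c(WT = 1, KitWv = 0.58)),
#'                          seed = 1)
#' delta_delta_ct(tab, "GAPDH", "ELN", "WT")
#' @export
delta_delta_ct <- function(table, reference_gene, target_gene, control_group,
                           outlier_policy = FALSE) {
  collapsed <- collapse_replicates(table, outlier_policy = outlier_policy)
  if (!reference_gene %in% collapsed$gene) {
    stop("reference gene '", reference_gene, "' absent from table")
  }
  if (!target_gene %in% collapsed$gene) {
    stop("target gene '", target_gene, "' absent from table")
  }
  if (!control_group %in% collapsed$group) {
    stop("control group '", control_group, "' absent from table")
  }
  ref <- collapsed[collapsed$gene == reference_gene, ]
  tgt <- collapsed[collapsed$gene == target_gene, ]
  m <- merge(tgt[, c("sample", "group", "ct_mean")],
             ref[, c("sample", "ct_mean")],
             by = "sample", suffixes = c("_target", "_reference"))
  if (nrow(m) < nrow(tgt)) {
    bad <- setdiff(tgt$sample, ref$sample)
    stop("sample(s) missing the reference gene: ", paste(bad, collapse = ", "))
  }
  m$delta_ct <- m$ct_mean_target - m$ct_mean_reference

  groups <- unique(m$group)
  groups <- c(control_group, setdiff(groups, control_group))
  ctrl_mean <- mean(m$delta_ct[m$group == control_group])
  rows <- lapply(groups, function(g) {
    d <- m$delta_ct[m$group == g]
    ddct <- mean(d) - ctrl_mean
    folds_i <- 2^-(d - ctrl_mean)
    data.frame(group = g, n = length(d),
               delta_ct_mean = mean(d),
               delta_ct_sd = if (length(d) > 1) stats::sd(d) else NA_real_,
               delta_delta_ct = ddct,
               fold_change = 2^-ddct,
               fold_sd = if (length(d) > 1) stats::sd(folds_i) else NA_real_,
               fold_sem = if (length(d) > 1)
                 stats::sd(folds_i) / sqrt(length(d)) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
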