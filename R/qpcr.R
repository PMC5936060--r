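# Delta-Ct relative quantification for single-embryo qRT-PCR.
#
# Per embryo, delta-Ct = mean(target replicate Cts) - mean(housekeeping
# replicate Cts); the relative expression level is 2^-deltaCt.  Group
# comparison is a two-tailed t-test on the delta-Ct scale (Cts are the
# approximately normal quantity), with the fold change reported on the
# level scale.

#' Per-embryo delta-Ct
#'
#' @param target_ct Numeric vector of target-gene replicate Ct values.
#' @param housekeeping_ct Numeric vector of housekeeping replicate Cts.
#' @param max_spread Warn when a triplicate spans more than this many
#'   cycles (`NULL` disables the check).
#' @return `mean(target_ct) - mean(housekeeping_ct)`.
#' @export
delta_ct <- function(target_ct, housekeeping_ct, max_spread = NULL) {
  stopifnot(length(target_ct) >= 1L, length(housekeeping_ct) >= 1L,
            all(target_ct > 0), all(housekeeping_ct > 0))
  if (!is.null(max_spread)) {
    for (v in list(target = target_ct, housekeeping = housekeeping_ct))
      if (diff(range(v)) > max_spread)
        warning(sprintf("replicate Ct spread %.2f exceeds %.2f cycles",
                        diff(range(v)), max_spread), call. = FALSE)
  }
  mean(target_ct) - mean(housekeeping_ct)
}

#' Relative expression level from delta-Ct
#'
#' @param dct Delta-Ct value(s), cycles.
#' @return `2^-dct`; strictly decreasing in `dct`, 1 iff `dct = 0`.
#' @export
relative_level <- function(dct) 2^(-dct)

#' Compute delta-Ct and relative levels for a long Ct table
#'
#' The table has one row per embryo x gene with replicate columns
#' `ct1, ct2, ...` (the CSV interface of [read_ct_table()]).  Each embryo
#' must carry both the target and the housekeeping gene.
#'
#' @param ct_table data.frame with columns `embryo_id`, `gene`,
#'   `ct1..ctK`, optionally `group`.
#' @param target Target gene name.
#' @param housekeeping Housekeeping (reference) gene name
#'   (default `"eef1a1l1"`).
#' @param max_spread Optional replicate-spread warning threshold (cycles).
#' @return data.frame `embryo_id` (+ `group` if present), `delta_ct`,
#'   `rel_level`.
#' @export
quantify_qpcr <- function(ct_table, target, housekeeping = "eef1a1l1",
                          max_spread = NULL) {
  ctc <- grep("^ct[0-9]+$", names(ct_table), value = TRUE)
  if (length(ctc) == 0L) stop("no replicate columns ct1, ct2, ... found")
  ids <- unique(ct_table$embryo_id)
  rows <- lapply(ids, function(id) {
    sub <- ct_table[ct_table$embryo_id == id, , drop = FALSE]
    tg <- sub[sub$gene == target, ctc, drop = FALSE]
    hk <- sub[sub$gene == housekeeping, ctc, drop = FALSE]
    if (nrow(tg) != 1L || nrow(hk) != 1L)
      stop("embryo ", id, " must have exactly one row for each of '",
           target, "' and '", housekeeping, "'")
    dct <- delta_ct(as.numeric(tg[1, ]), as.numeric(hk[1, ]),
                    max_spread = max_spread)
    out <- data.frame(embryo_id = id, delta_ct = dct,
                      rel_level = relative_level(dct),
                      stringsAsFactors = FALSE)
    if ("group" %in% names(sub)) out$group <- sub$group[1]
    out
  })
  out <- do.call(rbind, rows)
  out[, intersect(c("embryo_id", "group", "delta_ct", "rel_level"),
                  names(out)), drop = FALSE]
}

#' Compare relative expression between two groups
#'
#' Two-tailed t-test on the chosen scale (default delta-Ct, where Ct noise
#' is closest to normal).  The percent change between groups is reported
#' on the 2^-deltaCt level scale under *both* conventions — from the
#' group-mean delta-Cts (`change_from_mean_dct`) and from the group means
#' of per-embryo levels (`change_from_mean_levels`) — because the two
#' generally differ and published numbers rarely say which was used.
#'
#' @param dct_a,dct_b Numeric per-embryo delta-Ct vectors (reference group
#'   first: a positive percent change means lower expression in `b`).
#' @param on_scale `"dct"` (default) or `"level"` — scale for the t-test.
#' @param var_equal Pooled (default) vs Welch t-test.
#' @return List: `test` (`"ish_test"`), `ratio_from_mean_dct`,
#'   `change_from_mean_dct`, `ratio_from_mean_levels`,
#'   `change_from_mean_levels` (changes as fractions; positive = decrease
#'   in group b).
#' @export
compare_expression <- function(dct_a, dct_b, on_scale = c("dct", "level"),
                               var_equal = TRUE) {
  on_scale <- match.arg(on_scale)
  xa <- if (on_scale == "dct") dct_a else relative_level(dct_a)
  xb <- if (on_scale == "dct") dct_b else relative_level(dct_b)
  tst <- if (var_equal)
    pooled_t(group_summary(xa, label = "a"), group_summary(xb, label = "b"))
  else
    welch_t(group_summary(xa, label = "a"), group_summary(xb, label = "b"))
  r_dct <- 2^(-(mean(dct_b) - mean(dct_a)))
  r_lvl <- mean(relative_level(dct_b)) / mean(relative_level(dct_a))
  list(test = tst,
       ratio_from_mean_dct = r_dct, change_from_mean_dct = 1 - r_dct,
       ratio_from_mean_levels = r_lvl, change_from_mean_levels = 1 - r_lvl)
}

#' Read a Ct table CSV
#'
#' Columns `embryo_id, gene, ct1, ct2, ct3` (any number of `ct*` replicate
#' columns; an optional `group` column is carried through).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_ct_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
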