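## Group-comparison statistics and delta-delta-Ct fold-change arithmetic.
## Reporting plumbing: standard tests only, no bespoke inference.

#' Holm-Sidak step-down adjusted p values
#'
#' Step-down multiple-comparison adjustment using the Sidak correction at
#' each step: the i-th smallest p value is adjusted to
#' `1 - (1 - p)^(m - i + 1)`, with the running maximum enforcing
#' monotonicity.
#'
#' @param p Numeric vector of raw p values.
#' @return Adjusted p values in the original order.
#' @export
holm_sidak <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p) | p < 0 | p > 1)) config_error("p values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  adj <- cummax(1 - (1 - p[o])^(m - seq_len(m) + 1))
  pmin(adj, 1)[order(o)]
}

#' Compare two groups (or a factorial design)
#'
#' Two-group design: two-tailed Student's t test (pooled variance) with
#' group means and SEM.  Factorial design (`levels_a`/`levels_b` given,
#' e.g. serial time points): two-way ANOVA on group x level plus
#' per-level two-tailed t tests with Holm-Sidak adjustment.
#'
#' @param values_a,values_b Numeric response vectors for the two groups.
#' @param design `"two_group"` or `"factorial"`.
#' @param labels Length-2 group labels.
#' @param levels_a,levels_b Factor giving each observation's level
#'   (required for the factorial design).
#' @return An object of class `group_result`: per-group `mean`, `sem`,
#'   `n`; `test`; `p_value` (two-group) or the ANOVA table plus a
#'   `comparisons` data frame with raw and adjusted p values (factorial).
#' @export
compare_groups <- function(values_a, values_b, design = c("two_group", "factorial"),
                           labels = c("A", "B"), levels_a = NULL, levels_b = NULL) {
  design <- match.arg(design)
  if (length(values_a) < 2 || length(values_b) < 2) {
    config_error("each group needs n >= 2")
  }
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  base <- list(
    labels = labels,
    mean = c(mean(values_a), mean(values_b)),
    sem = c(sem(values_a), sem(values_b)),
    n = c(length(values_a), length(values_b))
  )
  if (design == "two_group") {
    tt <- stats::t.test(values_a, values_b, var.equal = TRUE)
    out <- c(base, list(test = "two-tailed Student's t test",
                        statistic = unname(tt$statistic), p_value = tt$p.value))
  } else {
    if (is.null(levels_a) || is.null(levels_b)) {
      config_error("factorial design needs levels_a and levels_b")
    }
    df <- data.frame(
      value = c(values_a, values_b),
      group = factor(rep(labels, c(length(values_a), length(values_b)))),
      level = factor(c(levels_a, levels_b))
    )
    fit <- stats::aov(value ~ group * level, data = df)
    an <- summary(fit)[[1]]
    lv <- levels(df$level)
    cmp <- do.call(rbind, lapply(lv, function(l) {
      a <- df$value[df$group == labels[1] & df$level == l]
      b <- df$value[df$group == labels[2] & df$level == l]
      if (length(a) < 2 || length(b) < 2) return(NULL)
      data.frame(level = l, mean_a = mean(a), mean_b = mean(b),
                 p_raw = stats::t.test(a, b, var.equal = TRUE)$p.value)
    }))
    cmp$p_adj <- holm_sidak(cmp$p_raw)
    out <- c(base, list(test = "two-way ANOVA + Holm-Sidak", anova = an, comparisons = cmp,
                        p_value = an[["Pr(>F)"]][1]))
  }
  structure(out, class = "group_result")
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf("<group_result> %s: %.4g +/- %.3g (n=%d) vs %s: %.4g +/- %.3g (n=%d)\n",
              x$labels[1], x$mean[1], x$sem[1], x$n[1],
              x$labels[2], x$mean[2], x$sem[2], x$n[2]))
  cat(sprintf("  %s, p = %.4g\n", x$test, x$p_value))
  if (!is.null(x$comparisons)) {
    print(x$comparisons, row.names = FALSE)
  }
  invisible(x)
}

#' Relative qPCR quantification (delta-delta-Ct)
#'
#' Per sample `dCt = Ct_target - Ct_reference`; between groups
#' `ddCt = mean dCt(group_a) - mean dCt(group_b)`; fold change
#' `2^(-ddCt)`, i.e. expression of `group_a` relative to `group_b`.
#'
#' @param ct_table Long-format data frame with columns `sample_id`,
#'   `group`, `gene`, `ct` (see [generate_ct_table()]).
#' @param target Target gene name.
#' @param reference Reference (housekeeping) gene name.
#' @param group_a,group_b Group labels to contrast.
#' @return An object of class `fold_change`: `ddct`, `fold`, per-group
#'   mean dCt and n.
#' @export
fold_change <- function(ct_table, target, reference, group_a, group_b) {
  need <- c("sample_id", "group", "gene", "ct")
  if (!all(need %in% names(ct_table))) {
    format_error("ct_table must have columns %s", paste(need, collapse = ", "))
  }
  dct_group <- function(g) {
    tgt <- ct_table[ct_table$group == g & ct_table$gene == target, ]
    ref <- ct_table[ct_table$group == g & ct_table$gene == reference, ]
    if (!nrow(tgt)) config_error("target gene '%s' absent in group '%s'", target, g)
    if (!nrow(ref)) config_error("reference gene '%s' absent in group '%s'", reference, g)
    ref_ct <- ref$ct[match(tgt$sample_id, ref$sample_id)]
    if (anyNA(ref_ct)) config_error("reference gene '%s' missing for some samples of '%s'", reference, g)
    tgt$ct - ref_ct
  }
  da <- dct_group(group_a); db <- dct_group(group_b)
  ddct <- mean(da) - mean(db)
  structure(list(
    target = target, reference = reference,
    group_a = group_a, group_b = group_b,
    dct_a = mean(da), dct_b = mean(db), n_a = length(da), n_b = length(db),
    ddct = ddct, fold = 2^(-ddct)
  ), class = "fold_change")
}

#' @export
print.fold_change <- function(x, ...) {
  cat(sprintf("<fold_change> %s (%s vs %s, ref %s): ddCt = %.4g, fold = %.4g\n",
              x$target, x$group_a, x$group_b, x$reference, x$ddct, x$fold))
  invisible(x)
}
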