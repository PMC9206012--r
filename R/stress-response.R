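# Salt-stress response quantification: 2^-ddCt relative expression from CT
# tables and group t-tests for expression / root-length differences.

validate_ct_table <- function(table) {
  stopifnot(is.data.frame(table))
  need <- c("gene", "condition", "replicate", "ct")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols)) {
    stop("CT table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(table$ct <= 0)) stop("CT values must be > 0", call. = FALSE)
  invisible(table)
}

#' Relative expression by the 2^-ddCt method
#'
#' For each gene and condition, dCt = mean CT(gene) - mean CT(reference)
#' within the condition; ddCt = dCt(condition) - dCt(calibrator); fold
#' change = 2^-ddCt (amplification efficiency fixed at 2). Per-replicate
#' dCt values (gene CT minus reference CT matched by replicate index) are
#' kept and used for a two-sided equal-variance t-test of each condition
#' against the calibrator.
#'
#' @param table Data frame with columns `gene`, `condition`, `replicate`,
#'   `ct` (cycles, > 0). The reference gene must be measured in every
#'   condition.
#' @param reference_gene Reference (housekeeping) gene id, e.g. `"CYP"`.
#' @param calibrator_condition Condition whose expression is defined as 1,
#'   e.g. `"0mM"`.
#' @return Data frame with `gene`, `condition`, `delta_ct`,
#'   `delta_delta_ct`, `fold_change`, `p_value` (NA for the calibrator
#'   itself and the reference gene), `flag` (ns/p05/p01).
#' @export
ddct <- function(table, reference_gene, calibrator_condition) {
  validate_ct_table(table)
  conditions <- unique(table$condition)
  if (!calibrator_condition %in% conditions) {
    stop("calibrator condition '", calibrator_condition,
         "' absent from table", call. = FALSE)
  }
  ref_missing <- conditions[!vapply(conditions, function(cd) {
    any(table$gene == reference_gene & table$condition == cd)
  }, logical(1))]
  if (length(ref_missing)) {
    stop("reference gene '", reference_gene, "' missing in condition(s): ",
         paste(ref_missing, collapse = ", "), call. = FALSE)
  }
  genes <- setdiff(unique(table$gene), reference_gene)

  # per-replicate dCt for one gene in one condition
  rep_dct <- function(g, cd) {
    gt <- table[table$gene == g & table$condition == cd, ]
    rt <- table[table$gene == reference_gene & table$condition == cd, ]
    m <- match(gt$replicate, rt$replicate)
    ref_ct <- ifelse(is.na(m), mean(rt$ct), rt$ct[m])
    gt$ct - ref_ct
  }

  rows <- list()
  for (g in c(genes, reference_gene)) {
    dct_cal <- rep_dct(g, calibrator_condition)
    for (cd in conditions) {
      dct <- rep_dct(g, cd)
      ddct_val <- mean(dct) - mean(dct_cal)
      p <- NA_real_
      if (cd != calibrator_condition && g != reference_gene &&
          length(dct) >= 2 && length(dct_cal) >= 2) {
        p <- safe_ttest(dct, dct_cal, var_equal = TRUE)[["p"]]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, condition = cd,
        delta_ct = mean(dct), delta_delta_ct = ddct_val,
        fold_change = 2^(-ddct_val), p_value = p,
        flag = significance_flag(p), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

significance_flag <- function(p) {
  ifelse(is.na(p), "ns", ifelse(p <= 0.01, "p01",
                                ifelse(p <= 0.05, "p05", "ns")))
}

#' Two-group t-test with significance flags
#'
#' Two-sided two-sample t-test (equal-variance Student by default, Welch
#' via `kind = "welch"`), flagged at P <= 0.05 (`p05`) and P <= 0.01
#' (`p01`). Used both for relative-expression comparisons and for
#' root-length measurements.
#'
#' @param values_a,values_b Numeric vectors with >= 2 values each.
#' @param kind `"equal_var"` (default) or `"welch"`.
#' @return List with `t`, `p`, `flag`.
#' @export
group_ttest <- function(values_a, values_b, kind = c("equal_var", "welch")) {
  kind <- match.arg(kind)
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  res <- safe_ttest(values_a, values_b, var_equal = kind == "equal_var")
  list(t = res[["t"]], p = res[["p"]], flag = significance_flag(res[["p"]]))
}
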