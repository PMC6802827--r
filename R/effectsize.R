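#' Cohen's d with pooled standard deviation
#'
#' Standardized mean difference `d = (mean(x1) - mean(x2)) / s_pooled` with
#' `s_pooled = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))` (sample
#' variances, n-1 denominator). Antisymmetric in its arguments and invariant
#' to a common positive affine rescaling of both samples.
#'
#' @param x1,x2 Numeric vectors with at least two values each.
#' @return Signed effect size.
#' @export
#' @examples
#' cohens_d(c(2, 4), c(1, 3))  # 1/sqrt(2)
cohens_d <- function(x1, x2) {
  x1 <- x1[!is.na(x1)]
  x2 <- x2[!is.na(x2)]
  n1 <- length(x1)
  n2 <- length(x2)
  if (n1 < 2 || n2 < 2) {
    stop("need at least two values per group", call. = FALSE)
  }
  s <- sqrt(((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2))
  if (s == 0) stop("pooled standard deviation is zero", call. = FALSE)
  (mean(x1) - mean(x2)) / s
}

#' Rank baseline protein releases between two treatment groups
#'
#' Compares raw MFIs per protein between a treated group (one or more
#' tables, pooled) and a control group with an unpaired two-sided t-test,
#' computes Cohen's d with the treated-minus-control sign convention
#' (positive d = more release in the treated samples), retains proteins
#' significant at `alpha`, and sorts them by decreasing d.
#'
#' @param control_table MFI table of the control group.
#' @param treated_tables MFI table, or list of tables, of the treated
#'   group(s); multiple tables are pooled into one group.
#' @param alpha Significance level for retention (default 0.05, unadjusted).
#' @param var_equal Use the Student (pooled-variance) t-test, consistent
#'   with the pooled-sd effect size (default); `FALSE` gives Welch.
#' @param adjust Multiple-testing correction passed to [stats::p.adjust()];
#'   default `"none"` (retention at raw p-values).
#' @return Tibble of retained proteins sorted by decreasing `cohens_d`, with
#'   columns `protein`, `n_treated`, `n_control`, `mean_treated`,
#'   `mean_control`, `cohens_d`, `p_value`; the full per-protein table
#'   (including non-retained proteins, flagged by `retained`) is attached as
#'   attribute `all`. Proteins with fewer than two values in either group
#'   are excluded with a warning.
#' @export
rank_baseline_releases <- function(control_table, treated_tables,
                                   alpha = 0.05, var_equal = TRUE,
                                   adjust = "none") {
  if (is.data.frame(treated_tables)) treated_tables <- list(treated_tables)
  treated <- dplyr::bind_rows(treated_tables)
  proteins <- intersect(protein_cols(control_table), protein_cols(treated))
  stats_one <- function(j) {
    x_t <- treated[[j]][!is.na(treated[[j]])]
    x_c <- control_table[[j]][!is.na(control_table[[j]])]
    if (length(x_t) < 2 || length(x_c) < 2) return(NULL)
    tt <- t.test(x_t, x_c, var.equal = var_equal)
    tibble::tibble(protein = j, n_treated = length(x_t),
                   n_control = length(x_c),
                   mean_treated = mean(x_t), mean_control = mean(x_c),
                   cohens_d = cohens_d(x_t, x_c),
                   p_value = unname(tt$p.value))
  }
  res <- purrr::map(proteins, stats_one)
  dropped <- proteins[purrr::map_lgl(res, is.null)]
  if (length(dropped) > 0) {
    warning("excluded protein(s) with fewer than two values per group: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  all_tbl <- dplyr::bind_rows(res)
  if (nrow(all_tbl) == 0) stop("no testable proteins", call. = FALSE)
  all_tbl$p_adjusted <- p.adjust(all_tbl$p_value, method = adjust)
  all_tbl$retained <- all_tbl$p_adjusted < alpha
  out <- dplyr::arrange(dplyr::filter(all_tbl, .data$retained),
                        dplyr::desc(.data$cohens_d))
  out$retained <- NULL
  out$p_adjusted <- if (adjust == "none") NULL else out$p_adjusted
  attr(out, "all") <- dplyr::arrange(all_tbl, dplyr::desc(.data$cohens_d))
  attr(out, "alpha") <- alpha
  class(out) <- c("effect_size_tbl", class(out))
  out
}
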