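# The statistical battery: Shapiro-Wilk normality gating, Pearson or
# Spearman correlation per gated pair, Student's t or Mann-Whitney U
# group comparison, and block-wise correlation reports with significance
# stars and an |r| > 0.4 reporting filter. Raw (uncorrected) p-values by
# default, mirroring the reporting style of small-cohort imaging studies;
# an optional multiplicity correction switch is provided.

#' Normality gate for a continuous sample
#'
#' Shapiro-Wilk test at `alpha`; a sample is called normal iff
#' p >= alpha. Degenerate (constant) samples are non-normal. Samples
#' larger than 5000 are gated on their first 5000 values (the test's
#' implementation limit).
#'
#' @param x Numeric sample, n >= 3.
#' @param alpha Gate level.
#' @return `"normal"` or `"non_normal"`.
#' @export
normality_gate <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  assert_that(length(x) >= 3, "normality gate needs n >= 3")
  if (sd(x) == 0) return("non_normal")
  if (length(x) > 5000) x <- x[seq_len(5000)]
  p <- shapiro.test(x)$p.value
  if (p >= alpha) "normal" else "non_normal"
}

p_stars <- function(p) {
  dplyr::case_when(is.na(p) ~ "", p < 0.001 ~ "***", p < 0.01 ~ "**",
                   p < 0.05 ~ "*", TRUE ~ "")
}

#' Correlate a pair of continuous variables with normality gating
#'
#' Pearson's coefficient when both variables pass the normality gate,
#' Spearman's otherwise (two-sided p in both cases), with significance
#' stars at 0.05 / 0.01 / 0.001 and the |r| > 0.4 reporting flag.
#'
#' @param x,y Paired numeric samples, n >= 3.
#' @param method `"auto"` (normality-gated), `"pearson"` or `"spearman"`.
#' @param gates Optional character vector of length 2 with precomputed
#'   gate results for x and y (used by [build_correlation_report()] to
#'   gate once per variable).
#' @param r_threshold Absolute-coefficient reporting threshold.
#' @return One-row tibble: `r`, `method`, `p_value`, `stars`, `reported`,
#'   `flagged` (zero variance, coefficient undefined).
#' @export
correlate <- function(x, y, method = "auto", gates = NULL, r_threshold = 0.4) {
  assert_that(length(x) == length(y), "samples must be paired")
  assert_that(length(x) >= 3, "correlation needs n >= 3")
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble::tibble(r = NA_real_, method = NA_character_,
                          p_value = NA_real_, stars = "", reported = FALSE,
                          flagged = TRUE))
  }
  if (method == "auto") {
    gates <- gates %||% c(normality_gate(x), normality_gate(y))
    method <- if (all(gates == "normal")) "pearson" else "spearman"
  }
  ct <- suppressWarnings(cor.test(x, y, method = method,
                                  alternative = "two.sided"))
  r <- unname(ct$estimate)
  tibble::tibble(r = r, method = method, p_value = ct$p.value,
                 stars = p_stars(ct$p.value), reported = abs(r) > r_threshold,
                 flagged = FALSE)
}

#' Compare a continuous variable between two groups
#'
#' Student's t-test when the variable passes the normality gate in both
#' groups, Mann-Whitney's U test otherwise; two-sided. The U test is
#' exact for combined n <= 20 without ties and uses the normal
#' approximation with tie correction otherwise.
#'
#' @param values Numeric sample.
#' @param groups Two-level factor (or coercible) of the same length, each
#'   group of size >= 2.
#' @param method `"auto"` (normality-gated), `"student_t"` or
#'   `"mann_whitney_u"`.
#' @return Object of class `group_comparison`: a list with `method`,
#'   `statistic`, `p_value` and a per-group `summary` tibble with
#'   mean +/- SD formatting.
#' @export
group_compare <- function(values, groups,
                          method = c("auto", "student_t", "mann_whitney_u")) {
  method <- match.arg(method)
  groups <- as.factor(groups)
  assert_that(nlevels(groups) == 2, "groups must have exactly two levels")
  assert_that(length(values) == length(groups), "values and groups must align")
  split_v <- split(values, groups)
  assert_that(all(lengths(split_v) >= 2), "each group needs size >= 2")
  if (method == "auto") {
    gate <- vapply(split_v, function(v) {
      if (length(v) < 3) "non_normal" else normality_gate(v)
    }, character(1))
    method <- if (all(gate == "normal")) "student_t" else "mann_whitney_u"
  }
  n_tot <- length(values)
  has_ties <- anyDuplicated(values) > 0
  if (method == "student_t") {
    ht <- t.test(split_v[[1]], split_v[[2]], var.equal = TRUE)
  } else {
    ht <- suppressWarnings(
      wilcox.test(split_v[[1]], split_v[[2]],
                  exact = n_tot <= 20 && !has_ties, correct = TRUE))
  }
  smry <- tibble::tibble(
    group = names(split_v), n = lengths(split_v),
    mean = vapply(split_v, mean, numeric(1)),
    sd = vapply(split_v, sd, numeric(1)))
  smry$label <- sprintf("%.3g ± %.2g", smry$mean, smry$sd)
  structure(list(method = method, statistic = unname(ht$statistic),
                 p_value = ht$p.value, summary = smry),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>", x$method, "\n")
  cat("  statistic:", signif(x$statistic, 5), " p:", signif(x$p_value, 4), "\n")
  for (i in seq_len(nrow(x$summary)))
    cat(" ", x$summary$group[i], ": ", x$summary$label[i],
        " (n = ", x$summary$n[i], ")\n", sep = "")
  invisible(x)
}

#' Build block-wise correlation reports
#'
#' Correlates every imaging biomarker with every clinical variable of
#' each block (cineanthropometric, functional, respiratory by default),
#' gating normality once per variable, starring raw two-sided p-values
#' and flagging cells with |r| above the reporting threshold. Cells below
#' the threshold are retained with `reported = FALSE`.
#'
#' @param table Analysis-ready results table (one row per subject) with
#'   imaging biomarker and clinical columns.
#' @param blocks Named list of character vectors of clinical variables;
#'   defaults to [report_blocks()] intersected with the table.
#' @param imaging Character vector of imaging biomarker columns.
#' @param r_threshold Reporting threshold on |r|.
#' @param p_adjust `"none"` (default, raw p-values) or any method of
#'   [stats::p.adjust()] applied within each block.
#' @param gate `"variable"` (default) gates normality once per variable;
#'   `"pair"` gates within each pair (identical here, but kept explicit
#'   for pairwise-complete data).
#' @return Object of class `correlation_report`: a long tibble with
#'   columns `block`, `imaging`, `clinical`, `r`, `method`, `p_value`,
#'   `stars`, `reported`, `flagged`.
#' @export
build_correlation_report <- function(table, blocks = NULL,
                                     imaging = imaging_biomarker_names(),
                                     r_threshold = 0.4, p_adjust = "none",
                                     gate = c("variable", "pair")) {
  gate <- match.arg(gate)
  blocks <- blocks %||% lapply(report_blocks(), intersect, names(table))
  all_clin <- unique(unlist(blocks))
  missing_cols <- setdiff(c(imaging, all_clin), names(table))
  if (length(missing_cols))
    stop("unknown column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  gates <- if (gate == "variable") {
    vapply(c(imaging, all_clin), function(v) normality_gate(table[[v]]),
           character(1))
  } else NULL
  rows <- purrr::map_dfr(names(blocks), function(bl) {
    purrr::map_dfr(imaging, function(im) {
      purrr::map_dfr(blocks[[bl]], function(cl) {
        cell <- correlate(table[[im]], table[[cl]],
                          gates = if (!is.null(gates)) gates[c(im, cl)] else NULL,
                          r_threshold = r_threshold)
        dplyr::bind_cols(tibble::tibble(block = bl, imaging = im, clinical = cl),
                         cell)
      })
    })
  })
  if (p_adjust != "none") {
    rows <- rows |>
      dplyr::group_by(.data$block) |>
      dplyr::mutate(p_value = stats::p.adjust(.data$p_value, method = p_adjust),
                    stars = p_stars(.data$p_value)) |>
      dplyr::ungroup()
  }
  structure(rows, class = c("correlation_report", class(rows)),
            r_threshold = r_threshold)
}

#' Widen one block of a correlation report to the published matrix layout
#'
#' Rows are imaging biomarkers, columns clinical variables, cells
#' formatted as "r stars".
#'
#' @param report A `correlation_report`.
#' @param block Block name.
#' @return Tibble in wide layout.
#' @export
report_matrix <- function(report, block) {
  report |>
    dplyr::filter(.data$block == !!block) |>
    dplyr::mutate(cell = sprintf("%.2f%s", .data$r,
                                 ifelse(.data$stars == "", "",
                                        paste0(" ", .data$stars)))) |>
    dplyr::select("imaging", "clinical", "cell") |>
    tidyr::pivot_wider(names_from = "clinical", values_from = "cell")
}
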