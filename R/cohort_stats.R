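#' Classify responders by post-VLCD fasting glucose
#'
#' A participant whose fasting plasma glucose after the 8-week very low
#' calorie diet and return to a normal diet is strictly below 7 mmol/l is a
#' responder; 7.0 or above is a non-responder (the strict inequality
#' matters at the boundary). Missing values give `"unassigned"` with a
#' warning.
#'
#' @param fpg_post_vlcd numeric vector of week-8 fasting plasma glucose,
#'   mmol/l.
#' @param threshold diagnostic threshold, mmol/l (default 7).
#' @return character vector: `"responder"`, `"non_responder"` or
#'   `"unassigned"`.
#' @export
classify_responder <- function(fpg_post_vlcd, threshold = 7) {
  out <- ifelse(is.na(fpg_post_vlcd), "unassigned",
                ifelse(fpg_post_vlcd < threshold, "responder",
                       "non_responder"))
  if (any(!is.na(fpg_post_vlcd) & fpg_post_vlcd <= 0))
    stop("fasting glucose must be positive", call. = FALSE)
  if (any(is.na(fpg_post_vlcd)))
    warning(sprintf("%d missing glucose values left unassigned",
                    sum(is.na(fpg_post_vlcd))), call. = FALSE)
  out
}

new_stat_result <- function(method, statistic, p_value, n, estimate = NA_real_,
                            df = NA_real_, computable = TRUE,
                            note = NA_character_) {
  structure(list(method = method, statistic = statistic, p_value = p_value,
                 n = n, estimate = estimate, df = df,
                 computable = computable, note = note),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  if (!x$computable) {
    cat(sprintf("<stat_result> %s: not computable (%s), n = %s\n",
                x$method, x$note, paste(x$n, collapse = "/")))
    return(invisible(x))
  }
  cat(sprintf("<stat_result> %s: statistic = %.4g%s, p = %.4g, n = %s%s\n",
              x$method, x$statistic,
              if (is.na(x$df)) "" else sprintf(" (df %.3g)", x$df),
              x$p_value, paste(x$n, collapse = "/"),
              if (is.na(x$estimate)) "" else
                sprintf(", estimate = %.4g", x$estimate)))
  invisible(x)
}

#' Paired Student's t test
#'
#' Classical paired t on positionwise differences, two-sided. Pairs with a
#' missing member are dropped. Zero-variance differences yield a
#' not-computable result (with `statistic = 0` when the differences are all
#' zero) rather than a fabricated p-value.
#'
#' @param x,y numeric vectors, paired by position, length >= 2.
#' @return A `stat_result` with method `"paired_t"`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) stop("need at least 2 complete pairs", call. = FALSE)
  d <- x - y
  if (stats::sd(d) == 0) {
    return(new_stat_result("paired_t", statistic = if (mean(d) == 0) 0 else
      sign(mean(d)) * Inf, p_value = NA_real_, n = n,
      computable = FALSE, note = "zero-variance differences"))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  new_stat_result("paired_t", unname(tt$statistic), tt$p.value, n,
                  estimate = unname(tt$estimate), df = unname(tt$parameter))
}

#' Two-sample Student's t test
#'
#' Pooled-variance ("Student's") two-sample t by default, the classical
#' test; `welch = TRUE` drops the equal-variance assumption.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param welch use the Welch-Satterthwaite correction.
#' @return A `stat_result` with method `"unpaired_t"`.
#' @export
unpaired_t <- function(x, y, welch = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 values", call. = FALSE)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    return(new_stat_result("unpaired_t",
                           statistic = if (mean(x) == mean(y)) 0 else
                             sign(mean(x) - mean(y)) * Inf,
                           p_value = NA_real_, n = c(length(x), length(y)),
                           computable = FALSE, note = "both groups constant"))
  }
  tt <- stats::t.test(x, y, var.equal = !welch)
  new_stat_result("unpaired_t", unname(tt$statistic), tt$p.value,
                  c(length(x), length(y)),
                  estimate = mean(x) - mean(y), df = unname(tt$parameter))
}

#' Mann-Whitney U test
#'
#' Exact p by enumeration of the rank distribution when both samples have
#' 8 or fewer observations and there are no ties; otherwise the
#' tie-corrected normal approximation with continuity correction. The
#' reported statistic is U for the first sample (`U1 + U2 = n1 * n2`).
#'
#' @param x,y numeric vectors, each non-empty.
#' @return A `stat_result` with method `"mann_whitney_u"`.
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y))
    stop("both groups must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 8 && length(y) <= 8 && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  new_stat_result("mann_whitney_u", unname(wt$statistic), wt$p.value,
                  c(length(x), length(y)),
                  note = if (exact) "exact" else "normal approximation")
}

#' Pearson or Spearman correlation
#'
#' Pearson's r, or Spearman's rho on tie-corrected ranks, with a two-sided
#' p-value from the t transform `t = r * sqrt((n - 2) / (1 - r^2))`.
#'
#' @param x,y numeric vectors of equal length >= 3 (pairwise-complete).
#' @param method `"pearson"` or `"spearman"`.
#' @return A `stat_result` with the coefficient in `estimate`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(new_stat_result(method, NA_real_, NA_real_, n,
                           computable = FALSE, note = "zero variance"))
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         exact = FALSE))
  r <- unname(ct$estimate)
  # p via the t transform for both methods (cor.test does this for
  # pearson and for spearman with exact = FALSE)
  new_stat_result(method, unname(ct$statistic), ct$p.value, n,
                  estimate = r,
                  df = if (method == "pearson") unname(ct$parameter)
                       else n - 2)
}

#' Group/timepoint summary with the study's contrasts
#'
#' Builds a Table-1-style summary of a long cohort table (one row per
#' participant-timepoint): per variable, group and timepoint the mean, SEM
#' (`sd/sqrt(n)`) and contributing n, with missing values excluded per cell
#' and cells with fewer than 2 values omitted with a warning. Contrasts:
#'
#' * within group, baseline vs each later timepoint by paired t on
#'   participants present at both (`paired_t`);
#' * between groups at baseline and 6 months: Mann-Whitney U for fasting
#'   insulin, unpaired Student's t for age and diabetes duration
#'   (baseline only) and for all other variables.
#'
#' The choice of test per variable follows the reporting convention of the
#' source design; no multiple-testing correction is applied.
#'
#' @param records data.frame with columns `id`, `group`, `timepoint` and
#'   numeric variable columns (as from [generate_cohort()]).
#' @param variables variables to summarize; default all numeric columns.
#' @param insulin_var variable compared by Mann-Whitney U.
#' @param unpaired_vars baseline-only variables compared by unpaired t.
#' @return Object of class `group_summary`: `cells` (data.frame of
#'   mean/sem/n) and `contrasts` (data.frame with method, statistic, p).
#' @export
summarize_group <- function(records,
                            variables = NULL,
                            insulin_var = "insulin_pmol_l",
                            unpaired_vars = c("age_years",
                                              "duration_years")) {
  stopifnot(all(c("id", "group", "timepoint") %in% names(records)))
  if (is.null(variables)) {
    variables <- setdiff(names(records)[vapply(records, is.numeric,
                                               TRUE)],
                         c("id"))
  }
  tps <- intersect(c("baseline", "week8", "month6"),
                   unique(records$timepoint))
  groups <- unique(records$group)

  cells <- list()
  for (v in variables) for (g in groups) for (tp in tps) {
    x <- records[[v]][records$group == g & records$timepoint == tp]
    x <- x[!is.na(x)]
    if (length(x) == 0L) next
    if (length(x) < 2L) {
      warning(sprintf("cell %s/%s/%s has < 2 values; omitted", v, g, tp),
              call. = FALSE)
      next
    }
    cells[[length(cells) + 1L]] <-
      data.frame(variable = v, group = g, timepoint = tp, n = length(x),
                 mean = mean(x), sem = stats::sd(x) / sqrt(length(x)))
  }
  cells <- do.call(rbind, cells)

  contrasts <- list()
  add <- function(row) contrasts[[length(contrasts) + 1L]] <<- row
  srow <- function(v, contrast, s) {
    data.frame(variable = v, contrast = contrast, method = s$method,
               statistic = if (s$computable) s$statistic else NA_real_,
               p_value = s$p_value, n = paste(s$n, collapse = "/"),
               computable = s$computable)
  }
  # within-group change from baseline
  for (v in variables) for (g in groups) for (tp in setdiff(tps, "baseline")) {
    b <- records[records$group == g & records$timepoint == "baseline",
                 c("id", v)]
    f <- records[records$group == g & records$timepoint == tp, c("id", v)]
    m <- merge(b, f, by = "id")
    m <- m[stats::complete.cases(m), ]
    if (nrow(m) < 2 || v %in% unpaired_vars) next
    s <- paired_t(m[[2]], m[[3]])
    add(srow(v, sprintf("%s: baseline vs %s", g, tp), s))
  }
  # between-group at baseline and month6
  if (length(groups) == 2) {
    for (v in variables) {
      btp <- if (v %in% unpaired_vars) "baseline" else
        intersect(c("baseline", "month6"), tps)
      for (tp in btp) {
        x <- records[[v]][records$group == groups[1] &
                            records$timepoint == tp]
        y <- records[[v]][records$group == groups[2] &
                            records$timepoint == tp]
        x <- x[!is.na(x)]; y <- y[!is.na(y)]
        if (length(x) < 2 || length(y) < 2) next
        s <- if (v == insulin_var) mann_whitney_u(x, y) else unpaired_t(x, y)
        add(srow(v, sprintf("%s vs %s at %s", groups[1], groups[2], tp), s))
      }
    }
  }
  contrasts <- if (length(contrasts)) do.call(rbind, contrasts) else NULL
  structure(list(cells = cells, contrasts = contrasts),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, digits = 3, ...) {
  cat("Group/timepoint summary (mean ± SEM)\n")
  cl <- x$cells
  cl$value <- sprintf(paste0("%.", digits, "g ± %.", digits, "g (n=%d)"),
                      cl$mean, cl$sem, cl$n)
  wide <- stats::reshape(cl[, c("variable", "group", "timepoint", "value")],
                         idvar = c("variable", "group"),
                         timevar = "timepoint", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  print(wide, row.names = FALSE)
  if (!is.null(x$contrasts)) {
    cat("\nContrasts\n")
    ct <- x$contrasts
    ct$p_value <- signif(ct$p_value, 3)
    ct$statistic <- signif(ct$statistic, 4)
    print(ct, row.names = FALSE)
  }
  invisible(x)
}
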