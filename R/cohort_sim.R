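#' Default cohort distribution parameters
#'
#' Per-variable, per-group, per-timepoint means with their standard errors
#' and the group sizes they were reported at (responders n = 12,
#' non-responders n = 17), for a diabetes-reversal study design: weight,
#' BMI, fasting plasma glucose, fasting insulin, total body fat, pancreas
#' fat, HbA1c, triacylglycerol, age, diabetes duration, pancreas volume and
#' border fractal dimension at baseline, after the 8-week very low calorie
#' diet (VLCD), and at 6 months. Age and duration are baseline-only. The
#' per-individual standard deviation used by [generate_cohort()] is
#' `sem * sqrt(n_ref)`.
#'
#' @return data.frame with columns `variable`, `group`, `timepoint`,
#'   `mean`, `sem`, `n_ref`, `sd`.
#' @export
table1_parameters <- function() {
  tp <- c("baseline", "week8", "month6")
  row3 <- function(variable, group, means, sems, n_ref) {
    data.frame(variable = variable, group = group, timepoint = tp,
               mean = means, sem = sems, n_ref = n_ref)
  }
  row1 <- function(variable, group, m, s, n_ref) {
    data.frame(variable = variable, group = group, timepoint = "baseline",
               mean = m, sem = s, n_ref = n_ref)
  }
  R <- "responder"; N <- "non_responder"
  out <- rbind(
    row3("weight_kg", R, c(99.8, 84.1, 84.4), c(3.2, 3.1, 3.2), 12),
    row3("weight_kg", N, c(96.7, 83.8, 84.8), c(3.9, 3.4, 3.7), 17),
    row3("bmi", R, c(34.0, 28.6, 28.7), c(0.8, 0.8, 0.7), 12),
    row3("bmi", N, c(34.4, 29.8, 30.2), c(1.1, 1.1, 1.1), 17),
    row3("fpg_mmol_l", R, c(8.9, 5.1, 6.2), c(0.7, 0.2, 0.3), 12),
    row3("fpg_mmol_l", N, c(13.2, 8.5, 9.4), c(0.6, 0.8, 0.7), 17),
    row3("insulin_pmol_l", R, c(143.8, 63.2, 68.8), c(23.6, 7.6, 16.0), 12),
    row3("insulin_pmol_l", N, c(78.5, 47.9, 49.3), c(18.1, 8.3, 7.0), 17),
    row3("total_body_fat_pct", R, c(36.2, 30.1, 31.5), c(1.9, 2.0, 1.9), 12),
    row3("total_body_fat_pct", N, c(42.6, 37.2, 40.8), c(2.2, 2.0, 2.5), 17),
    row3("pancreas_fat_pct", R, c(4.5, 4.0, 3.7), c(0.3, 0.3, 0.3), 12),
    row3("pancreas_fat_pct", N, c(5.5, 5.5, 4.9), c(0.8, 0.7, 0.6), 17),
    row3("hba1c_mmol_mol", R, c(54.5, 39.8, 41.4), c(3.7, 2.2, 1.6), 12),
    row3("hba1c_mmol_mol", N, c(68.1, 62.8, 61.7), c(3.2, 4.3, 3.3), 17),
    row3("triacylglycerol_mmol_l", R, c(2.0, 1.0, 1.2), c(0.3, 0.1, 0.1), 12),
    row3("triacylglycerol_mmol_l", N, c(1.8, 1.0, 1.2), c(0.4, 0.1, 0.2), 17),
    row3("pancreas_volume_cm3", R, c(52.0, 51.9, 51.4), c(4.9, 5.3, 4.5), 12),
    row3("pancreas_volume_cm3", N, c(39.7, 41.4, 41.3), c(2.7, 2.6, 2.8), 17),
    row3("fd", R, c(1.143, 1.169, 1.130), c(0.013, 0.006, 0.012), 12),
    row3("fd", N, c(1.175, 1.176, 1.167), c(0.006, 0.005, 0.007), 17),
    row1("age_years", R, 52.0, 2.9, 12),
    row1("age_years", N, 59.9, 2.1, 17),
    row1("duration_years", R, 3.8, 1.0, 12),
    row1("duration_years", N, 9.8, 1.6, 17)
  )
  out$sd <- out$sem * sqrt(out$n_ref)
  rownames(out) <- NULL
  out
}

#' Analytic generating means of a simulated cohort
#'
#' For most cells the generating distribution is normal and the generating
#' mean equals the input mean. The post-VLCD (week-8) fasting glucose cells
#' are constrained — responders strictly below the diagnostic threshold,
#' non-responders at or above it — so their generating law is a truncated
#' normal; this returns the analytic mean of the distribution actually
#' generated from, which is what a consistent summary should recover.
#'
#' @param parameters parameter table as from [table1_parameters()].
#' @param glucose_threshold responder threshold, mmol/l (default 7).
#' @return `parameters` with an added `generating_mean` column.
#' @export
cohort_generating_means <- function(parameters = table1_parameters(),
                                    glucose_threshold = 7) {
  gm <- parameters$mean
  con <- parameters$variable == "fpg_mmol_l" & parameters$timepoint == "week8"
  for (i in which(con)) {
    mu <- parameters$mean[i]; s <- parameters$sd[i]
    if (s == 0) next
    a <- (glucose_threshold - mu) / s
    gm[i] <- if (parameters$group[i] == "responder")
      mu - s * stats::dnorm(a) / stats::pnorm(a)      # upper-truncated (< thr)
    else
      mu + s * stats::dnorm(a) / (1 - stats::pnorm(a)) # lower-truncated (>= thr)
  }
  parameters$generating_mean <- gm
  parameters
}

#' Simulate a two-group, three-timepoint cohort
#'
#' Draws per-participant values for every variable, group and timepoint in
#' `parameters`. Two sampling modes:
#'
#' * `stratified = TRUE` (default): within each group/timepoint cell the
#'   normal distribution is sampled by stratified inversion (one draw per
#'   equal-probability stratum, assigned to participants in seeded random
#'   order — a Latin-hypercube-style scheme). Cell sample means then match
#'   the generating means essentially exactly at any n, which makes
#'   simulated Table-1-style summaries stable for small cohorts; sample
#'   SDs are mildly shrunk at very small n.
#' * `stratified = FALSE`: plain iid normal draws.
#'
#' The responder definition is enforced on week-8 fasting glucose:
#' responder draws fall strictly below `glucose_threshold`, non-responder
#' draws at or above it. In stratified mode this uses exact truncated
#' inverse-CDF sampling; in iid mode, violating draws are resampled up to
#' `max_attempts` times (an infeasible specification, e.g. a mean many SDs
#' on the wrong side of the threshold with tiny SD, errors loudly).
#'
#' Age and diabetes duration are drawn once per participant and repeated
#' across timepoints; sex is assigned in the reported 8M:4F / 7M:10F
#' proportions.
#'
#' @param n_responders,n_non_responders group sizes (>= 2).
#' @param parameters parameter table as from [table1_parameters()].
#' @param stratified use stratified inversion sampling (see Details).
#' @param glucose_threshold responder threshold on week-8 fasting plasma
#'   glucose, mmol/l.
#' @param max_attempts resampling cap per cell in iid mode.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return data.frame, one row per participant-timepoint: `id`, `group`,
#'   `timepoint`, `sex`, then one column per variable.
#' @export
generate_cohort <- function(n_responders = 12, n_non_responders = 17,
                            parameters = table1_parameters(),
                            stratified = TRUE, glucose_threshold = 7,
                            max_attempts = 1000L, seed = 1L) {
  stopifnot(n_responders >= 2, n_non_responders >= 2,
            all(parameters$sd >= 0))
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))

  groups <- list(responder = n_responders, non_responder = n_non_responders)
  tps <- c("baseline", "week8", "month6")
  vars <- unique(parameters$variable)
  static_vars <- c("age_years", "duration_years")

  sex_split <- c(responder = 8 / 12, non_responder = 7 / 17)

  recs <- list()
  for (g in names(groups)) {
    n <- groups[[g]]
    ids <- sprintf("%s_%02d", ifelse(g == "responder", "R", "N"), seq_len(n))
    n_m <- round(sex_split[[g]] * n)
    sex <- sample(c(rep("M", n_m), rep("F", n - n_m)))
    df <- expand.grid(id = ids, timepoint = tps, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
    df <- df[order(match(df$id, ids), match(df$timepoint, tps)), ]
    df$group <- g
    df$sex <- sex[match(df$id, ids)]
    for (v in vars) {
      df[[v]] <- NA_real_
      for (tp in if (v %in% static_vars) "baseline" else tps) {
        p <- parameters[parameters$variable == v & parameters$group == g &
                          parameters$timepoint == tp, ]
        if (nrow(p) != 1L) next
        con <- v == "fpg_mmol_l" && tp == "week8"
        side <- if (!con) NULL else
          if (g == "responder") "upper" else "lower"
        x <- draw_cell(n, p$mean, p$sd, stratified, side,
                       glucose_threshold, max_attempts)
        df[[v]][df$timepoint == tp] <- x
      }
      if (v %in% static_vars) {
        base <- df[[v]][df$timepoint == "baseline"]
        df[[v]] <- base[match(df$id, df$id[df$timepoint == "baseline"])]
      }
    }
    recs[[g]] <- df
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out[, c("id", "group", "timepoint", "sex", vars)]
}

# one cell: n values from N(mu, sd), optionally truncated at `thr`
# (side = "upper": X < thr; "lower": X >= thr)
draw_cell <- function(n, mu, sd, stratified, side, thr, max_attempts) {
  if (sd == 0) {
    if (!is.null(side) &&
        ((side == "upper" && mu >= thr) || (side == "lower" && mu < thr)))
      stop(sprintf("infeasible glucose constraint: mean %.2f with sd 0", mu),
           call. = FALSE)
    return(rep(mu, n))
  }
  if (stratified) {
    u <- (sample.int(n) - stats::runif(n)) / n   # one draw per stratum
    if (is.null(side)) return(mu + sd * stats::qnorm(u))
    pa <- stats::pnorm((thr - mu) / sd)
    if (side == "upper") {
      if (pa <= 0) stop("infeasible glucose constraint (no mass below threshold)",
                        call. = FALSE)
      return(mu + sd * stats::qnorm(u * pa))
    }
    if (pa >= 1) stop("infeasible glucose constraint (no mass above threshold)",
                      call. = FALSE)
    return(mu + sd * stats::qnorm(pa + u * (1 - pa)))
  }
  x <- stats::rnorm(n, mu, sd)
  if (is.null(side)) return(x)
  bad <- if (side == "upper") x >= thr else x < thr
  attempts <- 0L
  while (any(bad)) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop(sprintf(paste0("glucose constraint unmet after %d resampling ",
                          "attempts (mean %.2f, sd %.2f): infeasible spec"),
                   max_attempts, mu, sd), call. = FALSE)
    x[bad] <- stats::rnorm(sum(bad), mu, sd)
    bad <- if (side == "upper") x >= thr else x < thr
  }
  x
}
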