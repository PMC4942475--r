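#' Global switch cost from trial-level records
#'
#' The global switch cost is the block-level response-time penalty of task
#' switching: mean RT over correct, responded trials in switch (dual-task)
#' blocks minus mean RT over correct, responded trials in single-task blocks.
#' Rest trials and no-go trials (`responded = FALSE`) never enter the
#' computation.
#'
#' @param trials data.frame with columns `block_type` (one of `"single"`,
#'   `"switch"`, `"rest"`), `rt` (response time in seconds), `correct`
#'   (logical) and `responded` (logical). A missing `responded` column is
#'   taken as all `TRUE`.
#' @return Global switch cost in seconds (a single numeric).
#' @examples
#' trials <- data.frame(
#'   block_type = c("single", "single", "switch", "switch"),
#'   rt = c(0.5, 0.5, 0.72, 0.72),
#'   correct = TRUE, responded = TRUE
#' )
#' compute_global_switch_cost(trials) # 0.22
#' @export
compute_global_switch_cost <- function(trials) {
  trials <- as.data.frame(trials)
  stopifnot(all(c("block_type", "rt", "correct") %in% names(trials)))
  if (is.null(trials$responded)) trials$responded <- TRUE
  ok <- trials$correct & trials$responded & trials$block_type != "rest"
  if (any(trials$rt[ok & !is.na(trials$rt)] <= 0)) {
    stop("responded trials must have positive response times")
  }
  rt_single <- trials$rt[ok & trials$block_type == "single"]
  rt_switch <- trials$rt[ok & trials$block_type == "switch"]
  if (length(rt_single) == 0L || length(rt_switch) == 0L) {
    stop("insufficient trials: need at least one correct, responded trial ",
         "in each of the single and switch conditions")
  }
  mean(rt_switch) - mean(rt_single)
}

#' Normalized whole-brain volume (nWBV)
#'
#' The intracranial brain fraction: (gray + white matter volume) divided by
#' the sum of gray, white, and CSF volume. Dimensionless, in (0, 1]; used as
#' a covariate in all mediation equations. Scale-invariant in the three
#' tissue volumes.
#'
#' @param gm,wm,csf tissue volumes (any common unit), all non-negative.
#' @return nWBV fraction(s); vectorized over subjects.
#' @export
compute_nwbv <- function(gm, wm, csf) {
  if (any(gm < 0 | wm < 0 | csf < 0)) stop("tissue volumes must be non-negative")
  tot <- gm + wm + csf
  if (any(tot <= 0)) stop("total tissue volume must be positive")
  (gm + wm) / tot
}

#' Construct a subject table
#'
#' @param group integer/numeric group indicator, 0 = young, 1 = old, so a
#'   positive total effect means higher (worse) switch costs in the old group.
#' @param switch_cost global switch cost in seconds.
#' @param sex binary covariate (0/1).
#' @param nwbv normalized whole-brain volume in (0, 1].
#' @param id optional subject labels.
#' @return data.frame with columns `id`, `group`, `sex`, `nwbv`,
#'   `switch_cost`, one row per subject.
#' @export
subject_table <- function(group, switch_cost, sex = NULL, nwbv = NULL,
                          id = NULL) {
  n <- length(group)
  stopifnot(length(switch_cost) == n)
  if (!all(group %in% c(0, 1))) stop("group must be coded 0 (young) / 1 (old)")
  if (sum(group == 0) == 0L || sum(group == 1) == 0L) {
    stop("both groups must be non-empty")
  }
  if (is.null(id)) id <- sprintf("sub-%03d", seq_len(n))
  if (is.null(sex)) sex <- rep(NA_real_, n)
  if (is.null(nwbv)) nwbv <- rep(NA_real_, n)
  if (any(!is.na(nwbv) & (nwbv <= 0 | nwbv > 1))) {
    stop("nwbv must lie in (0, 1]")
  }
  data.frame(id = as.character(id), group = as.numeric(group),
             sex = as.numeric(sex), nwbv = as.numeric(nwbv),
             switch_cost = as.numeric(switch_cost),
             stringsAsFactors = FALSE)
}

# Drop subjects with missing analyzed fields (complete-case analysis).
# Returns the table plus an attribute with the dropped count.
complete_subjects <- function(subjects, with_covariates = TRUE) {
  cols <- c("group", "switch_cost", if (with_covariates) c("sex", "nwbv"))
  keep <- stats::complete.cases(subjects[, cols, drop = FALSE])
  if (!all(keep)) {
    message(sum(!keep), " subject(s) dropped for missing values")
  }
  out <- subjects[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

# Design matrix shared by all mediation equations: intercept, group, and
# (optionally) z-scored sex and nWBV. Covariates are standardized to
# stabilize conditioning; the group coefficient is unaffected.
design_matrix <- function(subjects, with_covariates = TRUE) {
  X <- cbind(intercept = 1, group = subjects$group)
  if (with_covariates) {
    zs <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x - mean(x)
    X <- cbind(X, sex = zs(subjects$sex), nwbv = zs(subjects$nwbv))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient design matrix; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  X
}

#' Total effect of age group on switch costs
#'
#' Ordinary least squares of switch cost on an intercept and the group
#' indicator, optionally adjusting for sex and nWBV. Without covariates the
#' group coefficient equals the difference of group means and the t statistic
#' equals the pooled-variance two-sample t.
#'
#' @param subjects subject table (see [subject_table()]).
#' @param with_covariates include sex and nWBV as covariates.
#' @return list with `beta` (group coefficient, seconds), `t`, `df`, `p`
#'   (two-tailed).
#' @export
group_total_effect <- function(subjects, with_covariates = FALSE) {
  subjects <- complete_subjects(subjects, with_covariates)
  if (sum(subjects$group == 0) == 0L || sum(subjects$group == 1) == 0L) {
    stop("both groups must be non-empty")
  }
  X <- design_matrix(subjects, with_covariates)
  fit <- stats::lm.fit(X, subjects$switch_cost)
  df <- nrow(X) - ncol(X)
  rss <- sum(fit$residuals^2)
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(rss / df * XtXinv[2, 2])
  beta <- unname(fit$coefficients["group"])
  tstat <- if (se > 0) beta / se else 0
  list(beta = beta, t = tstat, df = df,
       p = 2 * stats::pt(-abs(tstat), df))
}

#' Levene's test for equality of switch-cost variance across groups
#'
#' One-way ANOVA on the absolute deviations of switch cost from each group's
#' center. The classical Levene test centers on the group mean (the default);
#' `center = "median"` gives the Brown-Forsythe variant.
#'
#' @param subjects subject table.
#' @param center `"mean"` (classical Levene) or `"median"` (Brown-Forsythe).
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
levene_test <- function(subjects, center = c("mean", "median")) {
  center <- match.arg(center)
  g <- factor(subjects$group)
  if (any(table(g) < 2L)) stop("both groups need at least 2 subjects")
  cfun <- if (center == "mean") mean else stats::median
  dev <- abs(subjects$switch_cost - stats::ave(subjects$switch_cost, g, FUN = cfun))
  n <- length(dev); k <- nlevels(g)
  gm <- tapply(dev, g, mean)
  ssb <- sum(table(g) * (gm - mean(dev))^2)
  ssw <- sum((dev - stats::ave(dev, g, FUN = mean))^2)
  df1 <- k - 1L; df2 <- n - k
  Fstat <- if (ssw > 0) (ssb / df1) / (ssw / df2) else if (ssb == 0) 0 else Inf
  list(F = Fstat, df1 = df1, df2 = df2,
       p = stats::pf(Fstat, df1, df2, lower.tail = FALSE))
}

#' Reconstruct two groups matching printed summary statistics
#'
#' Builds a subject table whose per-group sample means and standard
#' deviations equal the given values exactly, by affinely rescaling an
#' equally spaced score vector. Useful for reproducing summary-level
#' regression results when subject-level data are unavailable.
#'
#' @param n_young,n_old group sizes.
#' @param mean_young,mean_old group means of the switch cost (seconds).
#' @param sd_young,sd_old group standard deviations (seconds).
#' @return subject table with `sex`/`nwbv` missing.
#' @export
subjects_from_summary <- function(n_young = 63, mean_young = 0.22, sd_young = 0.083,
                                  n_old = 112, mean_old = 0.30, sd_old = 0.15) {
  fix_moments <- function(n, m, s) {
    x <- seq_len(n)
    m + s * (x - mean(x)) / stats::sd(x)
  }
  subject_table(group = rep(c(0, 1), c(n_young, n_old)),
                switch_cost = c(fix_moments(n_young, mean_young, sd_young),
                                fix_moments(n_old, mean_old, sd_old)))
}

#' Read / write subject tables and trial records
#'
#' Subject tables are tab-separated text with header columns `id`, `group`,
#' `sex`, `nwbv`, `switch_cost`; trial records are tab-separated with columns
#' `subject`, `block_type`, `rt`, `correct`, `responded`.
#'
#' @param path file path.
#' @param subjects,trials data.frames to write.
#' @name subject_io
#' @export
read_subject_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "group", "sex", "nwbv", "switch_cost")
  if (!all(need %in% names(x))) {
    stop("subject table must have columns: ", paste(need, collapse = ", "))
  }
  x[, need]
}

#' @rdname subject_io
#' @export
write_subject_table <- function(subjects, path) {
  utils::write.table(subjects, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname subject_io
#' @export
read_trials <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  x$correct <- as.logical(x$correct)
  x$responded <- as.logical(x$responded)
  x
}

#' @rdname subject_io
#' @export
write_trials <- function(trials, path) {
  utils::write.table(trials, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
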