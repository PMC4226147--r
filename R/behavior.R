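#' Intraclass correlation for session reliability
#'
#' Average-measure ICC from the two-way mean-squares decomposition of a
#' targets x raters table (here: subject x condition cells rated in two
#' sessions). The default is the consistency-type two-way mixed
#' average-measure coefficient, ICC(3,k) = (MS_rows − MS_error) / MS_rows;
#' `type = "agreement"` gives the absolute-agreement variant ICC(2,k).
#' The confidence interval and p-value come from the F distribution of
#' MS_rows / MS_error with (n−1, (n−1)(k−1)) degrees of freedom
#' (consistency case).
#'
#' @param session1,session2 numeric vectors or subject x condition matrices
#'   of the two ratings of the same targets, in matching order.
#' @param type `"consistency"` (default) or `"agreement"`.
#' @param conf_level confidence level for the interval.
#' @return List with `icc`, `ci` (length 2), `p`, `F`, `df1`, `df2`,
#'   mean squares, `type`. Zero between-target variance yields NA with a
#'   warning.
#' @export
icc_consistency_average <- function(session1, session2,
                                    type = c("consistency", "agreement"),
                                    conf_level = 0.95) {
  type <- match.arg(type)
  x <- cbind(as.vector(as.matrix(session1)), as.vector(as.matrix(session2)))
  if (anyNA(x)) stop("complete two-session table required")
  n <- nrow(x); k <- ncol(x)
  stopifnot(n >= 2)
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (msr < .Machine$double.eps * 100) {
    warning("zero between-target variance: ICC undefined")
    return(list(icc = NA_real_, ci = c(NA_real_, NA_real_), p = NA_real_,
                F = NA_real_, df1 = n - 1, df2 = (n - 1) * (k - 1),
                msr = msr, msc = msc, mse = mse, type = type))
  }
  icc <- if (type == "consistency") {
    (msr - mse) / msr
  } else {
    (msr - mse) / (msr + (msc - mse) * k / n)
  }
  Fv <- msr / mse
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  a <- 1 - (1 - conf_level) / 2
  fl <- Fv / stats::qf(a, df1, df2)
  fu <- Fv * stats::qf(a, df2, df1)
  ci <- c(1 - 1 / fl, 1 - 1 / fu)
  p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  list(icc = icc, ci = ci, p = p, F = Fv, df1 = df1, df2 = df2,
       msr = msr, msc = msc, mse = mse, type = type)
}

#' One-way repeated-measures ANOVA on ratings
#'
#' Classical within-subject F test of the condition effect,
#' F = MS_condition / MS_(condition x subject), with
#' df = (c−1, (c−1)(n−1)), computed via [stats::aov()] with a subject error
#' stratum. An optional Greenhouse–Geisser correction adjusts the degrees
#' of freedom for sphericity violations.
#'
#' @param ratings numeric subject x condition matrix (e.g.
#'   [mean_ratings()]), complete.
#' @param gg_correction apply the Greenhouse–Geisser epsilon.
#' @return List with `F`, `df1`, `df2`, `p` (and `epsilon` if corrected).
#' @export
rm_anova <- function(ratings, gg_correction = FALSE) {
  stopifnot(is.matrix(ratings), ncol(ratings) >= 2)
  if (anyNA(ratings)) stop("complete subject x condition table required")
  n <- nrow(ratings); cnd <- ncol(ratings)
  long <- data.frame(
    rating = as.vector(ratings),
    condition = factor(rep(colnames(ratings) %||% seq_len(cnd), each = n)),
    subject = factor(rep(rownames(ratings) %||% seq_len(n), cnd))
  )
  fit <- stats::aov(rating ~ condition + Error(subject), data = long)
  tab <- summary(fit)[["Error: Within"]][[1]]
  Fv <- tab["condition", "F value"]
  df1 <- tab["condition", "Df"]
  df2 <- tab["Residuals", "Df"]
  if (gg_correction) {
    # Greenhouse-Geisser epsilon from the double-centered covariance
    S <- stats::cov(ratings)
    Sc <- sweep(sweep(S, 1, rowMeans(S)), 2, colMeans(S)) + mean(S)
    eps <- sum(diag(Sc))^2 / ((cnd - 1) * sum(Sc^2))
    eps <- min(1, max(1 / (cnd - 1), eps))
    p <- stats::pf(Fv, df1 * eps, df2 * eps, lower.tail = FALSE)
    return(list(F = Fv, df1 = df1, df2 = df2, p = p, epsilon = eps))
  }
  list(F = Fv, df1 = df1, df2 = df2,
       p = stats::pf(Fv, df1, df2, lower.tail = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Paired t-test with explicit degenerate-case handling
#'
#' Dependent-samples t (two-tailed) of `a - b`. The order convention is
#' `a` minus `b`: t is positive when `a` exceeds `b` on average. A zero
#' difference variance is degenerate: identical vectors give t = 0, p = 1;
#' a constant non-zero difference gives infinite t with a warning.
#'
#' @param a,b equal-length (>= 2) paired observations.
#' @return List with `t`, `df`, `p`, `mean_diff`.
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  n <- length(d)
  if (stats::sd(d) < .Machine$double.eps * 100) {
    if (all(abs(d) < .Machine$double.eps * 100)) {
      return(list(t = 0, df = n - 1, p = 1, mean_diff = 0))
    }
    warning("zero difference variance with non-zero mean: t undefined (infinite)")
    return(list(t = sign(mean(d)) * Inf, df = n - 1, p = 0,
                mean_diff = mean(d)))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate))
}

#' Behavioral report: reliability, condition effect, paired contrasts
#'
#' Session reliability (ICC, two-way mixed, average measure, over all
#' subject x condition cells), one-way repeated-measures ANOVA of the
#' session-averaged ratings across conditions, and paired t-tests for the
#' requested contrasts (by the `a - b` convention of [paired_t()]).
#'
#' @param ratings a `ratings_table` with pre and post sessions.
#' @param contrasts list of condition pairs; default: adjacent-preference
#'   pairs and the extreme pair, mirroring the standard reporting of such
#'   designs.
#' @return A `behavioral_report` (list with `icc`, `anova`, `contrasts`
#'   data.frame) with a print method.
#' @export
behavioral_report <- function(ratings,
                              contrasts = list(c("F1", "F2"), c("F3", "F4"),
                                               c("F2", "F4"), c("F1", "F4"))) {
  validate_ratings(ratings)
  m <- mean_ratings(ratings)
  s1 <- mean_ratings_session(ratings, "pre")
  s2 <- mean_ratings_session(ratings, "post")
  icc <- icc_consistency_average(s1, s2)
  an <- rm_anova(m)
  ct <- do.call(rbind, lapply(contrasts, function(pr) {
    if (!all(pr %in% colnames(m))) return(NULL)
    r <- paired_t(m[, pr[1]], m[, pr[2]])
    data.frame(pair = paste(pr, collapse = " vs "),
               t = r$t, df = r$df, p = r$p, mean_diff = r$mean_diff,
               stringsAsFactors = FALSE)
  }))
  structure(list(icc = icc, anova = an, contrasts = ct,
                 n_subjects = nrow(m)),
            class = "behavioral_report")
}

mean_ratings_session <- function(ratings, session) {
  r <- ratings[ratings$session == session, , drop = FALSE]
  tab <- tapply(r$rating, list(r$subject, r$condition), mean)
  tab[, unique(ratings$condition), drop = FALSE]
}

#' @export
print.behavioral_report <- function(x, ...) {
  cat("Behavioral report\n")
  cat(sprintf("  ICC (two-way mixed, average measure, %s) = %.3f, 95%% CI [%.3f, %.3f], p = %.2g\n",
              x$icc$type, x$icc$icc, x$icc$ci[1], x$icc$ci[2], x$icc$p))
  cat(sprintf("  RM-ANOVA: F(%d, %d) = %.2f, p = %.2g\n",
              x$anova$df1, x$anova$df2, x$anova$F, x$anova$p))
  if (!is.null(x$contrasts)) {
    cat("  Paired contrasts (first minus second):\n")
    print(x$contrasts, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Write a behavioral report as JSON
#' @param report a `behavioral_report`.
#' @param path output path.
#' @export
write_behavioral_report <- function(report, path) {
  jsonlite::write_json(
    list(icc = report$icc, anova = report$anova,
         contrasts = report$contrasts, n_subjects = report$n_subjects),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
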