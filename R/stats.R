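#' Animals-by-days measure matrix
#'
#' The statistics layer works on one metric arranged as an animals x sessions
#' matrix with explicit `NA` for missing sessions (unusable acquisition
#' files are marked, never silently dropped).
#'
#' @param x Numeric matrix (animals in rows, days in columns) or a long
#'   data.frame with columns `animal`, `day` and `value`.
#' @param days Optional day labels (column names).
#' @param animals Optional animal ids (row names).
#' @param condition Optional condition label attached as an attribute.
#' @return A numeric matrix of class `measure_matrix`.
#' @export
measure_matrix <- function(x, days = NULL, animals = NULL, condition = NULL) {
  if (is.data.frame(x)) {
    stopifnot(all(c("animal", "day", "value") %in% names(x)))
    days <- days %||% unique(as.character(x$day))
    animals <- animals %||% unique(as.character(x$animal))
    m <- matrix(NA_real_, length(animals), length(days),
                dimnames = list(animals, days))
    ai <- match(as.character(x$animal), animals)
    di <- match(as.character(x$day), days)
    ok <- !is.na(ai) & !is.na(di)
    if (anyDuplicated(cbind(ai[ok], di[ok]))) {
      stop("duplicate animal x day cells in the input table")
    }
    m[cbind(ai[ok], di[ok])] <- x$value[ok]
  } else {
    m <- as.matrix(x)
    if (!is.null(days)) colnames(m) <- days
    if (!is.null(animals)) rownames(m) <- animals
    if (is.null(colnames(m))) colnames(m) <- paste0("T", seq_len(ncol(m)))
    if (is.null(rownames(m))) rownames(m) <- paste0("animal", seq_len(nrow(m)))
  }
  storage.mode(m) <- "double"
  structure(m, condition = condition,
            class = c("measure_matrix", "matrix", "array"))
}

as_measure_matrix <- function(m) {
  if (inherits(m, "measure_matrix")) m else measure_matrix(m)
}

#' Per-day group summary (mean, SEM, n)
#'
#' Mean and standard error of the mean (sd / sqrt(n)) per day over the
#' non-missing animals. With a single animal the SEM is `NA` (undefined by
#' convention). Days with no data are flagged, not zero-filled.
#'
#' @param matrix A [measure_matrix()] (or coercible matrix).
#' @return Data.frame with columns `day`, `mean`, `sem`, `n`; `mean` and
#'   `sem` are `NA` for empty days.
#' @examples
#' group_summary(measure_matrix(matrix(c(1, 2, 3), 3, 1, ,
#'                                     list(NULL, "D0"))))
#' @export
group_summary <- function(matrix) {
  m <- as_measure_matrix(matrix)
  data.frame(
    day = colnames(m),
    mean = apply(m, 2, function(v) if (all(is.na(v))) NA_real_ else
      mean(v, na.rm = TRUE)),
    sem = apply(m, 2, function(v) {
      n <- sum(!is.na(v))
      if (n < 2L) NA_real_ else stats::sd(v, na.rm = TRUE) / sqrt(n)
    }),
    n = apply(m, 2, function(v) sum(!is.na(v))),
    row.names = NULL
  )
}

#' One-way repeated-measures ANOVA (day as the within-subject factor)
#'
#' Classical univariate repeated-measures decomposition on the animals with
#' complete rows (listwise completion; animals missing any session are
#' dropped and the number used is reported). Sums of squares:
#' between-days, between-subjects and residual; `F = MS_day / MS_error` with
#' `df = (d - 1, (d - 1)(n - 1))`. The Greenhouse-Geisser epsilon is computed
#' and reported but not applied to the quoted p-value; `p_gg` carries the
#' corrected value for readers who want it.
#'
#' @param matrix A [measure_matrix()].
#' @param alpha Significance level used for the critical F value and the
#'   reject/retain decision. Required explicitly: the source protocol quotes
#'   an ambiguous level, so no silent default is taken.
#' @return A list of class `anova_result`: `F`, `df_effect`, `df_error`, `p`,
#'   `critical_value`, `decision` (`"reject"`/`"retain"`), `alpha`,
#'   `confidence` (implied confidence level), `gg_epsilon`, `p_gg`,
#'   `n_animals`, `n_days`.
#' @export
rm_anova <- function(matrix, alpha) {
  if (missing(alpha)) stop("alpha must be given explicitly (e.g. 0.05)")
  stopifnot(alpha > 0, alpha < 1)
  m <- as_measure_matrix(matrix)
  complete <- stats::complete.cases(m)
  m <- m[complete, , drop = FALSE]
  n <- nrow(m); d <- ncol(m)
  if (n < 2L) stop("need at least 2 animals with complete rows, got ", n)
  if (d < 2L) stop("need at least 2 days, got ", d)
  grand <- mean(m)
  day_means <- colMeans(m)
  subj_means <- rowMeans(m)
  ss_day <- n * sum((day_means - grand)^2)
  ss_subj <- d * sum((subj_means - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_err <- ss_total - ss_day - ss_subj
  df_day <- d - 1L
  df_err <- (d - 1L) * (n - 1L)
  ms_day <- ss_day / df_day
  ms_err <- ss_err / df_err
  F <- if (ss_day <= 1e-12 * max(ss_total, 1)) 0
       else if (ms_err <= 0) Inf
       else ms_day / ms_err
  p <- stats::pf(F, df_day, df_err, lower.tail = FALSE)
  # Greenhouse-Geisser sphericity estimate from the column covariance
  S <- stats::cov(m)
  k <- ncol(S)
  # eps = (tr C)^2 / ((k-1) sum C^2) on the double-centred covariance
  C <- S - matrix(rowMeans(S), k, k) -
    matrix(colMeans(S), k, k, byrow = TRUE) + mean(S)
  ev <- sum(diag(C))^2
  eps <- ev / ((k - 1) * sum(C^2))
  eps <- min(max(eps, 1 / (k - 1)), 1)
  p_gg <- stats::pf(F, eps * df_day, eps * df_err, lower.tail = FALSE)
  crit <- stats::qf(1 - alpha, df_day, df_err)
  structure(
    list(
      F = F, df_effect = df_day, df_error = df_err, p = p,
      critical_value = crit,
      decision = if (F > crit) "reject" else "retain",
      alpha = alpha, confidence = 1 - alpha,
      gg_epsilon = eps, p_gg = p_gg,
      n_animals = n, n_days = d,
      ss = c(day = ss_day, subject = ss_subj, error = ss_err)
    ),
    class = "anova_result"
  )
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf(
    paste0("Repeated-measures ANOVA (day within animal)\n",
           "  n = %d animals (complete rows), %d days\n",
           "  F(%d, %d) = %.4f, p = %.4g\n",
           "  critical F at alpha = %g (confidence %g%%): %.4f -> %s H0\n",
           "  Greenhouse-Geisser epsilon = %.3f (p_GG = %.4g, not applied)\n"),
    x$n_animals, x$n_days, x$df_effect, x$df_error, x$F, x$p,
    x$alpha, 100 * x$confidence, x$critical_value,
    if (x$decision == "reject") "reject" else "retain",
    x$gg_epsilon, x$p_gg
  ))
  invisible(x)
}

#' Tukey-Kramer multiple comparisons across days
#'
#' Pairwise studentized-range comparisons of day means with the Kramer
#' correction for unequal group sizes (each day uses its non-missing
#' animals; the pooled within-day mean square provides the error term). With
#' equal n this reduces to the classical Tukey HSD.
#'
#' @param matrix A [measure_matrix()].
#' @param day_pairs Optional list of length-2 character vectors naming the
#'   pairs to test; default all pairs.
#' @param alpha Significance level for the flags (explicit, no default).
#' @return Data.frame with columns `day1`, `day2`, `diff`, `q`, `p_adj`,
#'   `significant`, `n1`, `n2`.
#' @export
tukey_kramer <- function(matrix, day_pairs = NULL, alpha) {
  if (missing(alpha)) stop("alpha must be given explicitly (e.g. 0.05)")
  m <- as_measure_matrix(matrix)
  days <- colnames(m)
  ns <- colSums(!is.na(m))
  if (any(ns < 2L)) {
    stop("every day needs >= 2 non-missing animals; offending day(s): ",
         paste(days[ns < 2L], collapse = ", "))
  }
  means <- colMeans(m, na.rm = TRUE)
  k <- ncol(m)
  ss_within <- sum(vapply(seq_len(k), function(j) {
    v <- m[!is.na(m[, j]), j]
    sum((v - mean(v))^2)
  }, numeric(1)))
  df_err <- sum(ns) - k
  mse <- ss_within / df_err
  if (is.null(day_pairs)) {
    cmb <- utils::combn(days, 2L, simplify = FALSE)
  } else {
    cmb <- day_pairs
    stopifnot(all(vapply(cmb, length, integer(1)) == 2L),
              all(unlist(cmb) %in% days))
  }
  rows <- lapply(cmb, function(pr) {
    i <- pr[1]; j <- pr[2]
    diff <- means[[i]] - means[[j]]
    se <- sqrt(mse / 2 * (1 / ns[[i]] + 1 / ns[[j]]))
    q <- abs(diff) / se
    p <- stats::ptukey(q, nmeans = k, df = df_err, lower.tail = FALSE)
    data.frame(day1 = i, day2 = j, diff = diff, q = q, p_adj = p,
               significant = p < alpha, n1 = ns[[i]], n2 = ns[[j]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bonferroni-corrected pairwise comparisons (paired)
#'
#' Paired t-tests between the given days (animals missing either day of a
#' pair are dropped for that pair), with the Bonferroni correction over the
#' number of pairs: a pair is significant when its raw p-value is below
#' `alpha / n_pairs` (equivalently, `p_adj = min(1, p * n_pairs) < alpha`).
#' Used for the D0/D1/D21 barycenter comparisons.
#'
#' @param matrix A [measure_matrix()].
#' @param days Character vector of day labels to compare pairwise
#'   (default `c("D0", "D1", "D21")`).
#' @param alpha Significance level (explicit, no default).
#' @return Data.frame with `day1`, `day2`, `diff` (mean of paired
#'   differences), `t`, `df`, `p`, `p_adj`, `significant`, `n`.
#' @export
bonferroni_pairwise <- function(matrix, days = c("D0", "D1", "D21"), alpha) {
  if (missing(alpha)) stop("alpha must be given explicitly (e.g. 0.05)")
  m <- as_measure_matrix(matrix)
  missing_days <- setdiff(days, colnames(m))
  if (length(missing_days)) {
    stop("day(s) not present in the matrix: ",
         paste(missing_days, collapse = ", "))
  }
  cmb <- utils::combn(days, 2L, simplify = FALSE)
  n_pairs <- length(cmb)
  rows <- lapply(cmb, function(pr) {
    a <- m[, pr[1]]; b <- m[, pr[2]]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 2L) {
      stop("pair ", pr[1], "-", pr[2], " has fewer than 2 complete animals")
    }
    tt <- stats::t.test(a[ok], b[ok], paired = TRUE)
    p_adj <- min(1, tt$p.value * n_pairs)
    data.frame(
      day1 = pr[1], day2 = pr[2], diff = unname(tt$estimate),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value, p_adj = p_adj, significant = p_adj < alpha,
      n = sum(ok)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' F critical-value decision
#'
#' Rejects the null hypothesis when the observed F statistic exceeds the
#' F-distribution quantile at confidence `1 - alpha` for the given degrees
#' of freedom (the table look-up used in the original protocol).
#'
#' @param F Observed F statistic.
#' @param df_effect,df_error Degrees of freedom.
#' @param alpha Significance level (explicit, no default).
#' @return List with `critical_value`, `reject`, `alpha`, `confidence`.
#' @examples
#' critical_value_decision(3.491, 7, 56, alpha = 0.05)
#' @export
critical_value_decision <- function(F, df_effect, df_error, alpha) {
  if (missing(alpha)) stop("alpha must be given explicitly (e.g. 0.05)")
  if (df_effect <= 0 || df_error <= 0) {
    stop("degrees of freedom must be positive")
  }
  stopifnot(F >= 0, alpha > 0, alpha < 1)
  crit <- stats::qf(1 - alpha, df_effect, df_error)
  list(critical_value = crit, reject = F > crit, alpha = alpha,
       confidence = 1 - alpha)
}
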