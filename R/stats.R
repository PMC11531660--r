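# Cohort-level statistics: summary tables, normality, Student's t-tests and
# two-way intraclass correlation coefficients.

#' Column-wise mean and sample SD of a cohort table
#'
#' @param table data.frame, rows = specimens, numeric columns.
#' @return data.frame with columns `parameter`, `mean`, `sd`, `n`.
#' @export
cohort_summary <- function(table) {
  num <- table[vapply(table, is.numeric, logical(1))]
  if (nrow(num) < 2) stop("cohort summary needs at least 2 specimens", call. = FALSE)
  data.frame(parameter = names(num),
             mean = vapply(num, mean, numeric(1), na.rm = TRUE),
             sd = vapply(num, stats::sd, numeric(1), na.rm = TRUE),
             n = vapply(num, function(x) sum(!is.na(x)), numeric(1)),
             row.names = NULL)
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around [stats::shapiro.test()] with the degenerate constant
#' sample flagged instead of erroring.
#'
#' @param x numeric sample, 3 <= n <= 5000.
#' @return list with `W`, `p_value`, `degenerate`.
#' @export
shapiro_wilk <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || length(x) > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  if (stats::sd(x) == 0)
    return(list(W = NA_real_, p_value = NA_real_, degenerate = TRUE))
  s <- stats::shapiro.test(x)
  list(W = unname(s$statistic), p_value = s$p.value, degenerate = FALSE)
}

#' Two-sided Student's t-test
#'
#' Paired (the default for medial-vs-lateral offsets of the same specimens)
#' or two-sample with pooled variance. Zero variance of the paired
#' differences is flagged rather than erroring.
#'
#' @param x,y numeric samples.
#' @param paired logical.
#' @return list with `t`, `df`, `p_value`, `mean_diff`, `degenerate`.
#' @export
t_test <- function(x, y, paired = TRUE) {
  if (paired && stats::sd(x - y) == 0)
    return(list(t = ifelse(mean(x - y) == 0, 0, Inf), df = length(x) - 1,
                p_value = ifelse(mean(x - y) == 0, 1, 0),
                mean_diff = mean(x - y), degenerate = TRUE))
  tt <- stats::t.test(x, y, paired = paired, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value,
       mean_diff = if (paired) mean(x - y) else mean(x) - mean(y),
       degenerate = FALSE)
}

#' Intraclass correlation coefficient from a two-way layout
#'
#' Single-rater ICCs from the two-way ANOVA mean squares of a complete
#' subjects x raters table: ICC(2,1), two-way random effects, absolute
#' agreement; and ICC(3,1), two-way mixed effects, consistency. The p-value
#' is the one-sided F-test of the between-subjects effect,
#' `F = MSR / MSE` on (n - 1, (n - 1)(k - 1)) degrees of freedom.
#'
#' @param ratings n x k numeric matrix (rows = subjects/specimens, columns =
#'   raters or sessions), complete.
#' @param model `"ICC2"` or `"ICC3"`.
#' @return list with `icc`, `model`, `F`, `df1`, `df2`, `p_value`, and the
#'   mean squares `MSR`, `MSC`, `MSE`.
#' @export
icc <- function(ratings, model = c("ICC2", "ICC3")) {
  model <- match.arg(model)
  R <- as.matrix(ratings)
  if (any(is.na(R))) stop("ICC requires a complete two-way layout", call. = FALSE)
  n <- nrow(R); k <- ncol(R)
  if (n < 2 || k < 2) stop("ICC needs at least 2 subjects and 2 raters", call. = FALSE)
  gm <- mean(R)
  rm_ <- rowMeans(R); cm <- colMeans(R)
  SSR <- k * sum((rm_ - gm)^2)
  SSC <- n * sum((cm - gm)^2)
  SST <- sum((R - gm)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  val <- if (model == "ICC2") {
    (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  } else {
    (MSR - MSE) / (MSR + (k - 1) * MSE)
  }
  # degenerate perfect-agreement layouts: 0/0 -> 1 by continuity
  if (!is.finite(val)) val <- 1
  Fst <- MSR / MSE
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  p <- if (is.finite(Fst)) stats::pf(Fst, df1, df2, lower.tail = FALSE) else 0
  list(icc = val, model = model, F = Fst, df1 = df1, df2 = df2, p_value = p,
       MSR = MSR, MSC = MSC, MSE = MSE)
}

#' Observer-reliability ICC report for epicondyle coordinates
#'
#' Long-format rater table with columns `specimen`, `rater`, `session`,
#' `parameter`, `value` (the six parameters are the X/Y/Z coordinates of the
#' two epicondyles). Inter-observer ICC(2,1) is computed per parameter on
#' the specimen x rater table of session means; intra-observer ICC(3,1) per
#' rater and parameter on the specimen x session table.
#'
#' @param rater_table long-format data.frame as above.
#' @return list with `inter` (data.frame per parameter) and `intra`
#'   (data.frame per rater x parameter).
#' @export
icc_report <- function(rater_table) {
  need <- c("specimen", "rater", "session", "parameter", "value")
  if (!all(need %in% names(rater_table)))
    stop("rater table must have columns ", paste(need, collapse = ", "), call. = FALSE)
  pars <- unique(rater_table$parameter)
  inter <- do.call(rbind, lapply(pars, function(p) {
    d <- rater_table[rater_table$parameter == p, ]
    agg <- stats::aggregate(value ~ specimen + rater, d, mean)
    M <- stats::xtabs(value ~ specimen + rater, agg)
    r <- icc(M, "ICC2")
    data.frame(parameter = p, icc2 = r$icc, p_value = r$p_value)
  }))
  raters <- unique(rater_table$rater)
  intra <- do.call(rbind, lapply(raters, function(rt) {
    do.call(rbind, lapply(pars, function(p) {
      d <- rater_table[rater_table$parameter == p & rater_table$rater == rt, ]
      M <- stats::xtabs(value ~ specimen + session, d)
      r <- icc(M, "ICC3")
      data.frame(rater = rt, parameter = p, icc3 = r$icc, p_value = r$p_value)
    }))
  }))
  list(inter = inter, intra = intra)
}
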