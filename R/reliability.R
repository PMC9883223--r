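# Rater-reliability statistics: two-item Cronbach's alpha, absolute
# coordinate differences between raters, paired t tests, and the exact
# noncentral-t sample-size computation for a paired design.

#' Two-item Cronbach's alpha
#'
#' Internal-consistency coefficient for two paired measurement series,
#' `alpha = (k / (k - 1)) * (1 - sum(item variances) / var(item sums))`
#' with `k = 2` items and sample variances (divisor `n - 1`) throughout.
#' Equals exactly 1 when the two series are identical and non-constant.
#'
#' @param measurement_1,measurement_2 Numeric vectors over the same
#'   subjects (length >= 3).
#' @return The alpha coefficient (always <= 1; it can be negative when
#'   the series covary negatively).
#' @export
#' @examples
#' cronbach_alpha(1:10, 1:10)                 # 1: perfect agreement
cronbach_alpha <- function(measurement_1, measurement_2) {
  x <- as.numeric(measurement_1); y <- as.numeric(measurement_2)
  stopifnot(length(x) == length(y), length(x) >= 3L)
  vs <- stats::var(x + y)
  if (vs == 0) stop("degenerate: constant measurements (zero total variance)")
  2 * (1 - (stats::var(x) + stats::var(y)) / vs)
}

#' Per-landmark absolute differences between two rater series
#'
#' For every (subject, landmark) pair computes the absolute coordinate
#' differences `|x_a - x_b|`, `|y_a - y_b|`, `|z_a - z_b|` and the
#' absolute distance difference `|d_a - d_b|`, then summarizes each
#' landmark by the mean and SD of those absolute values across subjects.
#' Symmetric in its two arguments.
#'
#' @param series_a,series_b Data frames with columns `subject`,
#'   `landmark`, `x`, `y`, `z` (mm) and optionally `d` (recomputed from
#'   the coordinates when absent).
#' @return A list with `per_subject` (long data frame of `dx`, `dy`,
#'   `dz`, `dd`) and `summary` (per landmark and component: mean and SD).
#' @export
rater_differences <- function(series_a, series_b) {
  prep <- function(s) {
    s <- as.data.frame(s)
    stopifnot(all(c("subject", "landmark", "x", "y", "z") %in% names(s)))
    if (!"d" %in% names(s)) s$d <- sqrt(s$x^2 + s$y^2 + s$z^2)
    key <- paste(s$subject, s$landmark, sep = "\r")
    if (anyDuplicated(key)) stop("duplicate (subject, landmark) keys in series")
    s[order(key), , drop = FALSE]
  }
  a <- prep(series_a); b <- prep(series_b)
  ka <- paste(a$subject, a$landmark, sep = "\r")
  kb <- paste(b$subject, b$landmark, sep = "\r")
  if (!identical(ka, kb)) {
    miss <- c(setdiff(ka, kb), setdiff(kb, ka))
    stop("mismatched (subject, landmark) keys between series: ",
         paste(gsub("\r", "/", utils::head(miss, 5L)), collapse = ", "))
  }
  per <- data.frame(subject = a$subject, landmark = a$landmark,
                    dx = abs(a$x - b$x), dy = abs(a$y - b$y),
                    dz = abs(a$z - b$z), dd = abs(a$d - b$d))
  comps <- c("dx", "dy", "dz", "dd")
  summ <- do.call(rbind, lapply(split(per, per$landmark), function(g) {
    data.frame(landmark = g$landmark[1], component = comps,
               mean = vapply(comps, function(cc) mean(g[[cc]]), 0),
               sd = vapply(comps, function(cc) stats::sd(g[[cc]]), 0),
               n = nrow(g), row.names = NULL)
  }))
  rownames(summ) <- NULL
  list(per_subject = per, summary = summ)
}

#' Paired t test between two per-subject delta series
#'
#' Classical paired t on the per-subject differences, with the two-sided
#' p value from the Student t distribution on `n - 1` degrees of freedom.
#' Used to compare the digitization precision of two programs from their
#' per-subject inter-examiner deltas.
#'
#' @param deltas_method_1,deltas_method_2 Equal-length numeric vectors
#'   (length >= 2), one value per subject.
#' @return A list with `t`, `df`, `p_value` and `mean_difference`.
#' @export
paired_t_test <- function(deltas_method_1, deltas_method_2) {
  x <- as.numeric(deltas_method_1); y <- as.numeric(deltas_method_2)
  stopifnot(length(x) == length(y), length(x) >= 2L)
  d <- x - y
  if (stats::var(d) == 0)
    stop("degenerate paired test: zero variance of pairwise differences")
  ht <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_difference = mean(d))
}

#' Exact power of a two-sided paired t test
#'
#' @param n Number of pairs.
#' @param effect_size Cohen's dz (mean difference / SD of differences).
#' @param alpha Two-sided significance level.
#' @return Power from the noncentral t distribution with `n - 1` degrees
#'   of freedom and noncentrality `dz * sqrt(n)`.
#' @export
paired_t_power <- function(n, effect_size, alpha = 0.05) {
  stopifnot(n >= 2)
  df <- n - 1
  ncp <- effect_size * sqrt(n)
  crit <- stats::qt(1 - alpha / 2, df)
  stats::pt(-crit, df, ncp = ncp) + stats::pt(crit, df, ncp = ncp,
                                              lower.tail = FALSE)
}

#' Minimum sample size for a paired t test
#'
#' Smallest number of pairs at which a two-sided paired t test reaches
#' the target power, using the exact noncentral-t power function (not the
#' normal approximation) — the G*Power convention, which gives n = 34 at
#' dz = 0.5, alpha = 0.05, power = 0.80.
#'
#' @param effect_size Cohen's dz (> 0).
#' @param alpha Two-sided significance level in (0, 1).
#' @param power Target power in (0, 1).
#' @param n_max Search ceiling.
#' @return The minimal integer n with power(n) >= `power`.
#' @export
#' @examples
#' required_sample_size_paired_t(0.5, 0.05, 0.80)   # 34
required_sample_size_paired_t <- function(effect_size, alpha = 0.05,
                                          power = 0.80, n_max = 1e6L) {
  stopifnot(effect_size > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  for (n in 2:n_max)
    if (paired_t_power(n, effect_size, alpha) >= power) return(as.integer(n))
  stop("unattainable parameters: power ", power,
       " not reached by n = ", n_max)
}

#' Reliability report for a long-format measurement table
#'
#' Reproduces the statistical battery of a two-examiner, two-session
#' landmark digitization study: per-landmark, per-component (x, y, z, d)
#' Cronbach's alpha within each examiner (session 1 vs session 2), alpha
#' between examiners (each examiner represented by the mean of the two
#' sessions), and the inter-examiner absolute-difference summary.
#'
#' @param measurements Data frame with columns `rater`, `session`,
#'   `subject`, `landmark`, `x`, `y`, `z` in mm (`d` recomputed).
#' @return A list with data frames `intra` (rater, landmark, component,
#'   alpha), `inter` (landmark, component, alpha) and `differences`
#'   (the [rater_differences()] summary between the two raters' session
#'   means).
#' @export
reliability_report <- function(measurements) {
  m <- as.data.frame(measurements)
  stopifnot(all(c("rater", "session", "subject", "landmark",
                  "x", "y", "z") %in% names(m)))
  m$d <- sqrt(m$x^2 + m$y^2 + m$z^2)
  comps <- c("x", "y", "z", "d")
  raters <- sort(unique(m$rater))
  sessions <- sort(unique(m$session))
  stopifnot(length(sessions) == 2L)
  pull <- function(rt, ss) {
    g <- m[m$rater == rt & m$session == ss, ]
    g[order(g$subject, g$landmark), ]
  }
  intra <- do.call(rbind, lapply(raters, function(rt) {
    s1 <- pull(rt, sessions[1]); s2 <- pull(rt, sessions[2])
    stopifnot(identical(paste(s1$subject, s1$landmark),
                        paste(s2$subject, s2$landmark)))
    do.call(rbind, lapply(unique(s1$landmark), function(lm) {
      i <- s1$landmark == lm
      data.frame(rater = rt, landmark = lm, component = comps,
                 alpha = vapply(comps, function(cc)
                   cronbach_alpha(s1[[cc]][i], s2[[cc]][i]), 0),
                 row.names = NULL)
    }))
  }))
  # examiner representative value: mean of the two sessions
  rep_series <- lapply(raters, function(rt) {
    s1 <- pull(rt, sessions[1]); s2 <- pull(rt, sessions[2])
    out <- s1[, c("subject", "landmark")]
    for (cc in comps) out[[cc]] <- (s1[[cc]] + s2[[cc]]) / 2
    out
  })
  stopifnot(length(raters) == 2L)
  a <- rep_series[[1]]; b <- rep_series[[2]]
  inter <- do.call(rbind, lapply(unique(a$landmark), function(lm) {
    i <- a$landmark == lm
    data.frame(landmark = lm, component = comps,
               alpha = vapply(comps, function(cc)
                 cronbach_alpha(a[[cc]][i], b[[cc]][i]), 0),
               row.names = NULL)
  }))
  diffs <- rater_differences(a, b)
  list(intra = intra, inter = inter, differences = diffs$summary)
}
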