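#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the D'Agostino (1970) transformed skewness statistic and the
#' Anscombe-Glynn (1983) transformed kurtosis statistic into the omnibus
#' \eqn{K^2 = Z_{skew}^2 + Z_{kurt}^2}, referred to a chi-square
#' distribution with 2 degrees of freedom.
#'
#' @param x Numeric vector; needs n >= 8 for the kurtosis transformation to
#'   be defined (n >= 20 is commonly recommended).
#' @return A list of class \code{htest}-like fields: \code{statistic}
#'   (K^2), \code{p_value}, \code{z_skew}, \code{z_kurt}, \code{n}.
#' @export
dagostino_test <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8L) stop2("D'Agostino-Pearson test needs n >= 8")
  zs <- dagostino_z_skew(x)
  zk <- dagostino_z_kurt(x)
  k2 <- zs^2 + zk^2
  list(statistic = k2, p_value = stats::pchisq(k2, 2, lower.tail = FALSE),
       z_skew = zs, z_kurt = zk, n = n)
}

dagostino_z_skew <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  g1 <- m3 / m2^1.5
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
}

dagostino_z_kurt <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  b2 <- mean((x - m)^4) / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - eb2) / sqrt(vb2)
  sqrt_b1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrt_b1 * (2 / sqrt_b1 + sqrt(1 + 4 / sqrt_b1^2))
  term1 <- 1 - 2 / (9 * a)
  denom <- 1 + xx * sqrt(2 / (a - 4))
  term2 <- sign(denom) * (abs((1 - 2 / a) / abs(denom)))^(1 / 3)
  (term1 - term2) / sqrt(2 / (9 * a))
}

#' Brown-Forsythe test for equality of variances
#'
#' Levene-type test on absolute deviations from group medians (delegates to
#' \code{car::leveneTest} with \code{center = median}).
#'
#' @param values Numeric vector.
#' @param group Group factor.
#' @return A list with \code{statistic}, \code{df}, \code{p_value}.
#' @export
brown_forsythe <- function(values, group) {
  lt <- car::leveneTest(values, factor(group), center = stats::median)
  list(statistic = lt[1, "F value"], df = c(lt[1, "Df"], lt[2, "Df"]),
       p_value = lt[1, "Pr(>F)"])
}

#' Two-group test selection and execution
#'
#' Implements the decision procedure used throughout the analyses: test
#' each group for normality (D'Agostino-Pearson); if either group is
#' non-normal at \code{alpha}, compare with a Mann-Whitney test. Otherwise
#' gate on variance equality (Brown-Forsythe): unequal variances get
#' Welch's correction, equal variances the Student t test. Groups smaller
#' than \code{n_floor} skip the normality test (it is unreliable there) and
#' take the nonparametric branch with a warning.
#'
#' @param a,b Numeric vectors of per-fly values.
#' @param alpha Gate level for both the normality and variance tests.
#' @param n_floor Minimum per-group n for the normality gate.
#' @return An object of class \code{test_decision}: \code{chosen_test}
#'   (\code{"t"}, \code{"welch_t"} or \code{"mann_whitney"}),
#'   \code{normality_p} (per group), \code{variance_p}, plus the final
#'   \code{statistic}, \code{p_value} and \code{effect} (mean or median
#'   difference a - b).
#' @export
choose_two_group_test <- function(a, b, alpha = 0.05, n_floor = 8L) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) stop2("each group needs n >= 2")
  norm_p <- c(a = NA_real_, b = NA_real_)
  var_p <- NA_real_
  if (length(a) < n_floor || length(b) < n_floor) {
    warning("group n below normality-test floor (", n_floor,
            "); using Mann-Whitney", call. = FALSE)
    chosen <- "mann_whitney"
  } else {
    norm_p <- c(a = dagostino_test(a)$p_value, b = dagostino_test(b)$p_value)
    if (any(norm_p < alpha)) {
      chosen <- "mann_whitney"
    } else {
      var_p <- brown_forsythe(c(a, b), rep(c("a", "b"), c(length(a), length(b))))$p_value
      chosen <- if (var_p < alpha) "welch_t" else "t"
    }
  }
  res <- switch(chosen,
    mann_whitney = {
      ht <- suppressWarnings(stats::wilcox.test(a, b))
      list(statistic = unname(ht$statistic), p = ht$p.value,
           effect = stats::median(a) - stats::median(b))
    },
    welch_t = {
      ht <- stats::t.test(a, b, var.equal = FALSE)
      list(statistic = unname(ht$statistic), p = ht$p.value,
           effect = mean(a) - mean(b))
    },
    t = {
      ht <- stats::t.test(a, b, var.equal = TRUE)
      list(statistic = unname(ht$statistic), p = ht$p.value,
           effect = mean(a) - mean(b))
    })
  structure(list(chosen_test = chosen, normality_p = norm_p,
                 variance_p = var_p, alpha = alpha,
                 statistic = res$statistic, p_value = res$p,
                 effect = res$effect, n = c(a = length(a), b = length(b))),
            class = "test_decision")
}

#' @export
print.test_decision <- function(x, ...) {
  cat(sprintf("<test_decision> %s: statistic = %.4f, p = %.4g, effect = %.3f\n",
              x$chosen_test, x$statistic, x$p_value, x$effect))
  cat(sprintf("  normality p: a %.3g, b %.3g; variance p: %.3g (alpha %.3g)\n",
              x$normality_p["a"], x$normality_p["b"], x$variance_p, x$alpha))
  invisible(x)
}

#' Two-way interaction ANOVA with post-hoc contrasts
#'
#' Fits \code{value ~ f1 * f2}, reports the interaction p-value, and runs
#' the requested family of pairwise contrasts (via \pkg{emmeans}): Sidak
#' for planned pairs, Tukey for all pairs, or Dunnett against a control
#' cell.
#'
#' @param data Data frame.
#' @param value,f1,f2 Column names (character) of the response and the two
#'   factors.
#' @param posthoc \code{"tukey"}, \code{"sidak"}, \code{"dunnett"} or
#'   \code{"none"}.
#' @param control For Dunnett, the control level of the crossed factor
#'   (index or name passed to \code{emmeans}).
#' @return An object of class \code{interaction_anova}:
#'   \code{interaction_p}, the full \code{anova_table}, cell means, and the
#'   \code{contrasts} data frame.
#' @export
interaction_anova <- function(data, value, f1, f2,
                              posthoc = c("tukey", "sidak", "dunnett", "none"),
                              control = NULL) {
  posthoc <- match.arg(posthoc)
  data <- data.frame(y = data[[value]],
                     f1 = factor(data[[f1]]), f2 = factor(data[[f2]]))
  if (anyNA(data$y)) data <- data[!is.na(data$y), ]
  cell_n <- table(data$f1, data$f2)
  if (any(cell_n == 0L)) stop2("empty design cell")
  if (any(cell_n < 2L)) stop2("each cell needs n >= 2")
  fit <- stats::lm(y ~ f1 * f2, data = data)
  an <- stats::anova(fit)
  int_row <- grep(":", rownames(an))
  contrasts <- NULL
  if (posthoc != "none") {
    em <- emmeans::emmeans(fit, ~ f1 * f2)
    contrasts <- switch(posthoc,
      tukey = emmeans::contrast(em, method = "pairwise", adjust = "tukey"),
      sidak = emmeans::contrast(em, method = "pairwise", adjust = "sidak"),
      dunnett = emmeans::contrast(em, method = "trt.vs.ctrl",
                                  ref = control %||% 1L, adjust = "dunnett"))
    contrasts <- as.data.frame(contrasts)
  }
  means <- stats::aggregate(y ~ f1 + f2, data, mean)
  structure(list(interaction_p = an[int_row, "Pr(>F)"],
                 interaction_F = an[int_row, "F value"],
                 anova_table = an, cell_means = means,
                 posthoc = posthoc, contrasts = contrasts),
            class = "interaction_anova")
}

#' @export
print.interaction_anova <- function(x, ...) {
  cat(sprintf("<interaction_anova> interaction F = %.3f, p = %.4g (post hoc: %s)\n",
              x$interaction_F, x$interaction_p, x$posthoc))
  invisible(x)
}

#' Dual-control screen-hit rule
#'
#' A driver line is a hit only if its experimental group differs from BOTH
#' its Gal4 control and the shared UAS control at \code{alpha}, with the
#' same sign of effect. Comparisons are pairwise Welch t tests with a Sidak
#' correction over the two control comparisons per line (a Dunnett-T3-style
#' procedure for unequal variances). Lines with a missing control are
#' skipped with a warning.
#'
#' @param lines Named list; each element is a list with numeric vectors
#'   \code{experimental} and \code{gal4_control}.
#' @param uas_control Numeric vector, the control shared by every line.
#' @param alpha Per-line significance level.
#' @return A data frame (class \code{screen_result}), one row per line:
#'   \code{delta_vs_uas} (experimental minus UAS-control mean, the plotted
#'   screen quantity), adjusted p-values vs each control, and \code{hit}.
#' @export
screen_hits <- function(lines, uas_control, alpha = 0.05) {
  rows <- lapply(names(lines), function(nm) {
    ln <- lines[[nm]]
    if (is.null(ln$experimental) || is.null(ln$gal4_control) ||
        length(ln$experimental) < 2L || length(ln$gal4_control) < 2L) {
      warning("line ", nm, " is missing a group; skipped", call. = FALSE)
      return(NULL)
    }
    t_gal4 <- stats::t.test(ln$experimental, ln$gal4_control, var.equal = FALSE)
    t_uas <- stats::t.test(ln$experimental, uas_control, var.equal = FALSE)
    # Sidak over the family of 2 control comparisons
    p_gal4 <- 1 - (1 - t_gal4$p.value)^2
    p_uas <- 1 - (1 - t_uas$p.value)^2
    d_gal4 <- mean(ln$experimental) - mean(ln$gal4_control)
    d_uas <- mean(ln$experimental) - mean(uas_control)
    hit <- p_gal4 < alpha && p_uas < alpha && sign(d_gal4) == sign(d_uas) &&
      d_gal4 != 0
    data.frame(line = nm, delta_vs_uas = d_uas, delta_vs_gal4 = d_gal4,
               p_vs_gal4 = p_gal4, p_vs_uas = p_uas, hit = hit,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  class(out) <- c("screen_result", "data.frame")
  attr(out, "alpha") <- alpha
  out
}

#' Machine-readable comparison report
#'
#' Serializes a \code{test_decision}, \code{interaction_anova} or
#' \code{logrank_test} to the documented JSON schema (test name, statistic,
#' df, p, effect estimate).
#'
#' @param x A test object.
#' @param path Output JSON path, or \code{NULL} to return the list.
#' @export
write_stats_json <- function(x, path = NULL) {
  rep <- if (inherits(x, "test_decision")) {
    list(test = x$chosen_test, statistic = x$statistic, p = x$p_value,
         effect = x$effect, normality_p = as.list(x$normality_p),
         variance_p = x$variance_p, n = as.list(x$n))
  } else if (inherits(x, "logrank_test")) {
    list(test = "logrank", statistic = x$chisq, df = x$df, p = x$p_value)
  } else if (inherits(x, "interaction_anova")) {
    list(test = "two_way_anova", interaction_F = x$interaction_F,
         interaction_p = x$interaction_p, posthoc = x$posthoc)
  } else stop2("unsupported object")
  if (is.null(path)) return(rep)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
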