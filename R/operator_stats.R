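#' Anderson-Darling test of normality
#'
#' Case-3 Anderson-Darling test (mean and variance estimated from the
#' sample) with the usual small-sample correction and piecewise p-value
#' approximation, used to verify whether the analysis variables meet the
#' theoretical conditions of parametric modeling before falling back to the
#' rank-based tests.
#'
#' @param x numeric sample, n >= 8.
#' @return List with \code{statistic} (A^2) and \code{p.value}.
#' @export
andersonDarlingNormality <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 8L)
    stop("insufficient sample: Anderson-Darling needs n >= 8 (got ", length(x), ")")
  if (stats::sd(x) == 0)
    stop("degenerate sample: all values identical, normality is undefined")
  ht <- nortest::ad.test(x)
  list(statistic = unname(ht$statistic), p.value = unname(ht$p.value))
}

#' Kruskal-Wallis test across operator groups
#'
#' Rank-based one-way comparison of k >= 2 independent groups (the
#' nonparametric analogue of the ANOVA F test): mid-ranks for ties,
#' tie-corrected H, chi-square p-value on k - 1 degrees of freedom. When
#' every observation is identical the statistic is defined as H = 0 with
#' p = 1 (no evidence of any group difference).
#'
#' @param groups list of >= 2 numeric vectors, each non-empty, total n >= 3.
#' @return List with \code{statistic} (H), \code{df} and \code{p.value}.
#' @export
kruskalWallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("kruskalWallis needs a list of at least 2 groups")
  if (any(vapply(groups, length, 1L) < 1L)) stop("every group must be non-empty")
  x <- unlist(groups, use.names = FALSE)
  if (length(x) < 3L) stop("total sample size must be >= 3")
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  if (length(unique(x)) == 1L)
    return(list(statistic = 0, df = length(groups) - 1L, p.value = 1))
  ht <- stats::kruskal.test(x, g)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = unname(ht$p.value))
}

#' Wilcoxon-Mann-Whitney rank-sum test for two independent samples
#'
#' Two-sided throughout. Uses the exact null distribution when both samples
#' have n <= 25 and the pooled data are tie-free; otherwise the normal
#' approximation with mid-rank tie correction and continuity correction.
#'
#' @param a,b numeric samples, each n >= 1.
#' @return List with \code{statistic} (the Mann-Whitney W for sample
#'   \code{a}), \code{p.value}, and \code{exact} (logical, which method ran).
#' @export
wilcoxonRankSum <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 1L || length(b) < 1L) stop("both samples must be non-empty")
  exact <- length(a) <= 25L && length(b) <= 25L && !anyDuplicated(c(a, b))
  ht <- stats::wilcox.test(a, b, alternative = "two.sided",
                           exact = exact, correct = TRUE)
  list(statistic = unname(ht$statistic), p.value = min(1, unname(ht$p.value)),
       exact = exact)
}

# The 15 analysis variables of a results table: GSM plus one percentage per
# brightness band.
analysisVariables <- function(table) {
  c("gsm", grep("^pct_", names(table), value = TRUE))
}

#' Compare operators (or devices) within one image category
#'
#' For one image category of a per-image results table, runs the
#' comparability protocol on all 15 variables (GSM and the 14 brightness-
#' range percentages, treated as continuous): a Kruskal-Wallis omnibus test
#' across the groups per variable, and pairwise Wilcoxon-Mann-Whitney tests
#' for every group pair per variable, flagged at the significance level
#' \code{alpha}. Pairwise tests are run regardless of the omnibus outcome,
#' and no multiple-testing correction is applied; the total number of tests
#' is reported in the result instead.
#'
#' @param table results data.frame (see [analyzeImage()] /
#'   [runStudyPipeline()]) containing at least \code{category}, the grouping
#'   column, \code{gsm} and the \code{pct_*} columns.
#' @param category one of \code{"random"}, \code{"standardized"},
#'   \code{"random-normalized"}, \code{"standardized-normalized"}.
#' @param groupBy grouping column: \code{"physician_id"} or
#'   \code{"device_id"}.
#' @param alpha significance level (default 0.05).
#' @return A \linkS4class{StatReport}.
#' @export
compareOperators <- function(table, category,
                             groupBy = c("physician_id", "device_id"),
                             alpha = 0.05) {
  groupBy <- match.arg(groupBy)
  stopifnot(alpha > 0, alpha < 1)
  sub <- table[table$category == category, , drop = FALSE]
  grps <- sort(unique(sub[[groupBy]]))
  if (length(grps) < 2L)
    stop("insufficient groups: category '", category, "' has ",
         length(grps), " level(s) of ", groupBy)
  vars <- analysisVariables(sub)
  if (!length(vars)) stop("results table has no analysis variables")

  om <- lapply(vars, function(v) {
    kw <- kruskalWallis(split(sub[[v]], sub[[groupBy]]))
    data.frame(variable = v, H = kw$statistic, df = kw$df, p = kw$p.value,
               stringsAsFactors = FALSE)
  })
  omnibus <- do.call(rbind, om)

  pairs <- utils::combn(grps, 2L, simplify = FALSE)
  pw <- list()
  for (pr in pairs) {
    xa <- sub[sub[[groupBy]] == pr[1L], , drop = FALSE]
    xb <- sub[sub[[groupBy]] == pr[2L], , drop = FALSE]
    for (v in vars) {
      wt <- wilcoxonRankSum(xa[[v]], xb[[v]])
      pw[[length(pw) + 1L]] <- data.frame(
        variable = v, group_a = pr[1L], group_b = pr[2L],
        W = wt$statistic, p = wt$p.value,
        significant = wt$p.value < alpha, stringsAsFactors = FALSE)
    }
  }
  pairwise <- do.call(rbind, pw)
  new("StatReport", category = category, groupBy = groupBy, alpha = alpha,
      omnibus = omnibus, pairwise = pairwise,
      nTests = nrow(omnibus) + nrow(pairwise))
}

#' Per-pair counts of significant variables
#'
#' @param report a \linkS4class{StatReport}.
#' @return data.frame with \code{group_a}, \code{group_b},
#'   \code{n_significant} (significant variables out of the 15) and
#'   \code{gsm_significant} (whether the GSM itself differed).
#' @export
significantCounts <- function(report) {
  stopifnot(is(report, "StatReport"))
  pw <- report@pairwise
  agg <- stats::aggregate(significant ~ group_a + group_b, data = pw, FUN = sum)
  names(agg)[3L] <- "n_significant"
  gsmFlag <- pw[pw$variable == "gsm", c("group_a", "group_b", "significant")]
  names(gsmFlag)[3L] <- "gsm_significant"
  merge(agg, gsmFlag, by = c("group_a", "group_b"), sort = TRUE)
}

#' Tidy export of a StatReport
#'
#' @param report a \linkS4class{StatReport}.
#' @param path output CSV path.
#' @return Invisibly, \code{path}. The CSV has one row per pairwise test:
#'   variable, group_a, group_b, statistic, p, significant.
#' @export
writeStatReport <- function(report, path) {
  stopifnot(is(report, "StatReport"))
  out <- report@pairwise
  names(out)[names(out) == "W"] <- "statistic"
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
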