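#' Spearman rank correlation test
#'
#' Tie-corrected Spearman's rho (Pearson correlation of mid-ranks) with
#' the asymptotic t approximation on n - 2 degrees of freedom, the
#' convention appropriate for the large samples this pipeline produces.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return A list with `rho`, `statistic` (t), `df`, and `p.value`
#'   (two-sided; `NA` when |rho| = 1 exactly).
#' @export
spearman_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation is undefined for a constant vector")
  rho <- cor(rank(x), rank(y))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  list(rho = rho, statistic = tstat, df = n - 2, p.value = p)
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected Kruskal-Wallis H with the chi-square approximation on
#' g - 1 degrees of freedom (delegated to [stats::kruskal.test()]).
#'
#' @param values numeric response vector.
#' @param groups group labels (>= 2 non-empty groups).
#' @return A list with `statistic` (H), `df`, and `p.value`.
#' @export
kruskal_wallis_test <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stop("need at least 2 non-empty groups")
  if (any(table(groups) == 0)) stop("empty group")
  if (length(unique(values)) == 1) {
    # fully tied data: rank variance is zero, H = 0 by convention
    return(list(statistic = 0, df = nlevels(groups) - 1, p.value = 1))
  }
  kt <- kruskal.test(values, groups)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p.value = kt$p.value)
}

#' Dunn's pairwise test with Holm adjustment
#'
#' Pairwise post-hoc comparisons on pooled mid-ranks with tie correction:
#' for groups i, j the statistic is
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))` with
#' `T = sum(t^3 - t) / (12 (N - 1))` over tie groups, two-sided normal
#' p-values, and Holm's step-down adjustment across all pairs. Following
#' the omnibus-first convention, the pairwise battery only runs when the
#' Kruskal-Wallis test is significant at `gate_alpha` (set
#' `run_anyway = TRUE` to override).
#'
#' @param values numeric response vector.
#' @param groups group labels (>= 2 non-empty groups).
#' @param gate_alpha omnibus significance gate (default 0.05).
#' @param run_anyway run the pairwise tests regardless of the omnibus
#'   result.
#' @return A list with `kruskal` (omnibus result), `gated` (logical: were
#'   pairwise tests skipped?), and `pairs` (data.frame `group1`, `group2`,
#'   `z`, `p.value`, `p.adjusted`), ordered as the groups factor.
#' @export
dunn_holm_test <- function(values, groups, gate_alpha = 0.05,
                           run_anyway = FALSE) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stop("need at least 2 non-empty groups")
  kw <- kruskal_wallis_test(values, groups)
  if (!run_anyway && !(is.finite(kw$p.value) && kw$p.value < gate_alpha)) {
    return(list(kruskal = kw, gated = TRUE,
                pairs = data.frame(group1 = character(0),
                                   group2 = character(0), z = numeric(0),
                                   p.value = numeric(0),
                                   p.adjusted = numeric(0))))
  }
  N <- length(values)
  r <- rank(values)
  rb <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- levels(groups)
  combs <- utils::combn(lev, 2)
  z <- p <- numeric(ncol(combs))
  for (m in seq_len(ncol(combs))) {
    i <- combs[1, m]; j <- combs[2, m]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ns[[i]] + 1 / ns[[j]]))
    if (se == 0) {
      # fully tied data: no evidence of separation
      z[m] <- 0
      p[m] <- 1
    } else {
      z[m] <- (rb[[i]] - rb[[j]]) / se
      p[m] <- 2 * stats::pnorm(-abs(z[m]))
    }
  }
  list(kruskal = kw, gated = FALSE,
       pairs = data.frame(group1 = combs[1, ], group2 = combs[2, ],
                          z = z, p.value = p,
                          p.adjusted = p.adjust(p, method = "holm"),
                          stringsAsFactors = FALSE))
}

#' Compare corridor variables across priority classes
#'
#' The group-comparison battery applied to every requested variable:
#' Kruskal-Wallis across the priority classes and, where the omnibus test
#' is significant, Dunn's pairwise tests with Holm adjustment.
#'
#' @param metrics data.frame of corridor (or node) variables.
#' @param classes priority class per row (low/medium/high factor).
#' @param variables character vector of metric columns to test (default:
#'   all numeric columns).
#' @param gate_alpha omnibus gate passed to [dunn_holm_test()].
#' @return A data.frame with one row per variable and group pair
#'   (`variable`, `test`, `group1`, `group2`, `statistic`, `p.value`,
#'   `p.adjusted`); omnibus rows carry the H statistic and empty group
#'   fields.
#' @export
class_comparison <- function(metrics, classes, variables = NULL,
                             gate_alpha = 0.05) {
  if (is.null(variables))
    variables <- names(metrics)[vapply(metrics, is.numeric, TRUE)]
  out <- list()
  for (v in variables) {
    ok <- !is.na(metrics[[v]]) & !is.na(classes)
    res <- dunn_holm_test(metrics[[v]][ok], classes[ok],
                          gate_alpha = gate_alpha)
    out[[length(out) + 1L]] <-
      data.frame(variable = v, test = "kruskal-wallis", group1 = "",
                 group2 = "", statistic = res$kruskal$statistic,
                 p.value = res$kruskal$p.value, p.adjusted = NA_real_,
                 stringsAsFactors = FALSE)
    if (nrow(res$pairs) > 0) {
      out[[length(out) + 1L]] <-
        data.frame(variable = v, test = "dunn-holm",
                   group1 = res$pairs$group1, group2 = res$pairs$group2,
                   statistic = res$pairs$z, p.value = res$pairs$p.value,
                   p.adjusted = res$pairs$p.adjusted,
                   stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
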