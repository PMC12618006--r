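#' Correlate per-cell % ERK activity with a voltage predictor
#'
#' Pearson correlation of single-cell %ERK values against either
#' `log10([K+]out)` (perfusion experiments; membrane potential is
#' proportional to the logarithm of extracellular K+ by the Nernst
#' relation, so any log base gives the same coefficient) or the clamped
#' voltage in mV. Computed on pooled single cells, not condition means. A
#' linear fit with its 95% confidence band accompanies the coefficient.
#'
#' @param responses Tibble with `percent_erk` and either `k_out` (mM) or
#'   `voltage_mV`; rows with `included == FALSE` are dropped when the
#'   column is present.
#' @param predictor `"log10_k"` or `"voltage"`.
#' @return List with `predictor`, `n`, `r`, `p_value`, `slope`,
#'   `intercept`, `fit` (the `lm` object), `data` (the points used), and
#'   `flagged`/`flag_reason` when the correlation is undefined (fewer than
#'   3 points or zero variance on either axis).
#' @export
correlate_erk <- function(responses, predictor = c("log10_k", "voltage")) {
  predictor <- match.arg(predictor)
  stopifnot("percent_erk" %in% names(responses))
  if ("included" %in% names(responses)) {
    responses <- responses[responses$included %in% TRUE, ]
  }
  x <- switch(predictor,
    log10_k = {
      if (!"k_out" %in% names(responses)) {
        stop("`responses` must carry `k_out` for the log10_k predictor", call. = FALSE)
      }
      log10(responses$k_out)
    },
    voltage = {
      if (!"voltage_mV" %in% names(responses)) {
        stop("`responses` must carry `voltage_mV` for the voltage predictor", call. = FALSE)
      }
      responses$voltage_mV
    }
  )
  y <- responses$percent_erk
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  base <- list(
    predictor = predictor, n = length(x), r = NA_real_, p_value = NA_real_,
    slope = NA_real_, intercept = NA_real_, fit = NULL,
    data = tibble::tibble(predictor = x, percent_erk = y),
    flagged = TRUE, flag_reason = NA_character_
  )
  if (length(x) < 3L) {
    base$flag_reason <- "fewer than 3 points"
    return(base)
  }
  if (stats::sd(x) == 0) {
    base$flag_reason <- "zero predictor variance"
    return(base)
  }
  if (stats::sd(y) == 0) {
    base$flag_reason <- "zero response variance"
    return(base)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  fit <- stats::lm(y ~ x)
  base$r <- unname(ct$estimate)
  base$p_value <- ct$p.value
  base$slope <- unname(stats::coef(fit)[2])
  base$intercept <- unname(stats::coef(fit)[1])
  base$fit <- fit
  base$flagged <- FALSE
  base
}

#' Group comparisons used in the quantification workflows
#'
#' A single dispatcher over the test family the workflows need:
#' Kruskal-Wallis across conditions, Wilcoxon rank-sum between two groups
#' (exact enumeration up to `exact_threshold` observations per group when
#' ties allow, normal approximation with continuity correction above),
#' Welch and paired t-tests, and the one-sample t-test against a null
#' value. Degenerate inputs (zero variance) are flagged rather than
#' raising.
#'
#' @param values Numeric observations.
#' @param groups Group labels aligned with `values`. For `one_sample_t`,
#'   ignored; for two-sample methods exactly two levels are required; for
#'   `paired_t` the two groups must have equal lengths and be ordered as
#'   pairs.
#' @param method One of `"kruskal_wallis"`, `"wilcoxon_rank_sum"`,
#'   `"one_sample_t"`, `"paired_t"`, `"welch_t"`.
#' @param mu Null value for `one_sample_t` (default 1, the no-change
#'   ratio).
#' @param exact_threshold Largest group size for which the rank-sum
#'   p-value is computed by exact enumeration.
#' @return Tibble with `method`, `statistic`, `df`, `p_value`, `exact`,
#'   `flagged`, `note`.
#' @export
group_compare <- function(values, groups = NULL,
                          method = c(
                            "kruskal_wallis", "wilcoxon_rank_sum",
                            "one_sample_t", "paired_t", "welch_t"
                          ),
                          mu = 1, exact_threshold = 50) {
  method <- match.arg(method)
  res <- tibble::tibble(
    method = method, statistic = NA_real_, df = NA_real_,
    p_value = NA_real_, exact = NA, flagged = FALSE, note = NA_character_
  )
  two_groups <- function() {
    g <- factor(groups)
    if (nlevels(g) != 2L) stop("exactly two groups required", call. = FALSE)
    split(values, g)
  }
  if (method == "kruskal_wallis") {
    kt <- stats::kruskal.test(values, factor(groups))
    res$statistic <- unname(kt$statistic)
    res$df <- unname(kt$parameter)
    res$p_value <- kt$p.value
  } else if (method == "wilcoxon_rank_sum") {
    gs <- two_groups()
    use_exact <- max(lengths(gs)) <= exact_threshold &&
      !anyDuplicated(c(gs[[1]], gs[[2]]))
    wt <- stats::wilcox.test(gs[[1]], gs[[2]],
      exact = use_exact,
      correct = !use_exact
    )
    res$statistic <- unname(wt$statistic)
    res$p_value <- wt$p.value
    res$exact <- use_exact
  } else if (method == "one_sample_t") {
    if (stats::sd(values) == 0) {
      res$flagged <- TRUE
      res$note <- "zero variance"
      return(res)
    }
    tt <- stats::t.test(values, mu = mu)
    res$statistic <- unname(tt$statistic)
    res$df <- unname(tt$parameter)
    res$p_value <- tt$p.value
  } else if (method == "paired_t") {
    gs <- two_groups()
    if (length(gs[[1]]) != length(gs[[2]])) {
      stop("paired test requires equal group lengths", call. = FALSE)
    }
    d <- gs[[1]] - gs[[2]]
    if (stats::sd(d) == 0) {
      res$flagged <- TRUE
      res$note <- "zero variance of differences"
      return(res)
    }
    tt <- stats::t.test(gs[[1]], gs[[2]], paired = TRUE)
    res$statistic <- unname(tt$statistic)
    res$df <- unname(tt$parameter)
    res$p_value <- tt$p.value
  } else { # welch_t
    gs <- two_groups()
    if (stats::sd(gs[[1]]) == 0 && stats::sd(gs[[2]]) == 0) {
      res$flagged <- TRUE
      res$note <- "zero variance in both groups"
      return(res)
    }
    tt <- stats::t.test(gs[[1]], gs[[2]], var.equal = FALSE)
    res$statistic <- unname(tt$statistic)
    res$df <- unname(tt$parameter)
    res$p_value <- tt$p.value
  }
  res
}
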