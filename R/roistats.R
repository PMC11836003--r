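#' Region-of-interest statistics of a parameter map
#'
#' Mean, max, SD and voxel count of a voxelwise map over each tumor region
#' (ET, necrosis, edema), the whole tumor (WT = ET + necrosis + edema) and
#' normal-appearing white matter. Missing voxels (`NA`) are excluded; a
#' region absent from the label volume (or empty after exclusion) yields no
#' row.
#'
#' @param map 3D numeric array.
#' @param labels 3D integer array of [phantom_labels] codes (hotspot voxels
#'   are collapsed into ET).
#' @param parameter Name recorded in the output (e.g. `"APTw"`).
#' @return Tibble with columns `region`, `parameter`, `mean`, `max`, `sd`,
#'   `n_voxels`.
#' @export
extract_region_stats <- function(map, labels, parameter = "value") {
  stopifnot(all(dim(map) == dim(labels)))
  labels <- roi_labels(labels)
  regions <- list(
    ET = phantom_labels[["et"]],
    necrosis = phantom_labels[["necrosis"]],
    edema = phantom_labels[["edema"]],
    WT = c(phantom_labels[["et"]], phantom_labels[["necrosis"]],
           phantom_labels[["edema"]]),
    NAWM = phantom_labels[["nawm"]]
  )
  rows <- purrr::imap(regions, function(codes, nm) {
    v <- map[labels %in% codes]
    v <- v[is.finite(v)]
    if (length(v) == 0) return(NULL)
    tibble::tibble(region = nm, parameter = parameter, mean = mean(v),
                   max = max(v), sd = sd(v), n_voxels = length(v))
  })
  dplyr::bind_rows(rows)
}

#' Normalize region statistics to NAWM
#'
#' Divides each region's mean and max by the subject's NAWM mean of the same
#' parameter. K2 is passed through unnormalized: leakage is absent in healthy
#' white matter, so its NAWM mean is a noise quantity and dividing by it
#' would produce large erroneous values. Re-normalizing an already
#' normalized table is an error.
#'
#' @param stats Tibble from [extract_region_stats()] (possibly several
#'   parameters bound together).
#' @return The same tibble with `mean`, `max`, `sd` scaled, plus
#'   `is_normalized` (`FALSE` for K2 rows).
#' @export
normalize_to_nawm <- function(stats) {
  if (isTRUE(attr(stats, "normalized")) || "is_normalized" %in% names(stats)) {
    abort("statistics are already NAWM-normalized")
  }
  out <- dplyr::group_modify(
    dplyr::group_by(stats, .data$parameter),
    function(df, key) {
      if (key$parameter == "K2") {
        df$is_normalized <- FALSE
        return(df)
      }
      ref <- df$mean[df$region == "NAWM"]
      if (length(ref) != 1 || !is.finite(ref) || ref <= 0) {
        abort(sprintf("NAWM mean unavailable or non-positive for %s",
                      key$parameter))
      }
      df$mean <- df$mean / ref
      df$max <- df$max / ref
      df$sd <- df$sd / ref
      df$is_normalized <- TRUE
      df
    }
  )
  out <- dplyr::ungroup(out)
  attr(out, "normalized") <- TRUE
  out
}

#' Mann-Whitney U test between two groups
#'
#' Reports U as the smaller of the two orientations (so U <= n1*n2/2) and a
#' two-sided p-value: exact when there are no ties and `n1*n2 <= 400`,
#' otherwise the normal approximation with tie correction
#' (`spss_compat = TRUE` forces the asymptotic test, matching common
#' statistical-package defaults).
#'
#' @param a,b Numeric samples.
#' @param spss_compat Use the asymptotic test regardless of sample size.
#' @return Tibble with `u`, `p`, `n1`, `n2`.
#' @export
mann_whitney <- function(a, b, spss_compat = FALSE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) == 0 || length(b) == 0) abort("both groups must be non-empty")
  n1 <- length(a); n2 <- length(b)
  if (diff(range(c(a, b))) == 0) {
    # fully tied: no evidence either way
    return(tibble::tibble(u = n1 * n2 / 2, p = 1, n1 = n1, n2 = n2))
  }
  ties <- any(duplicated(c(a, b)))
  exact <- !spss_compat && !ties && n1 * n2 <= 400
  wt <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = !exact)
  )
  u_a <- unname(wt$statistic)           # pairs with a > b
  u <- min(u_a, n1 * n2 - u_a)
  tibble::tibble(u = u, p = wt$p.value, n1 = n1, n2 = n2)
}

#' Nonparametric ROC analysis
#'
#' Computes the trapezoidal (Mann-Whitney) AUC with the positive class
#' oriented so that larger values indicate the positive group -- the
#' orientation is fixed, never flipped, so AUC below 0.5 is reported as is.
#' The standard error follows Hanley & McNeil; the 95% confidence interval
#' is `auc +/- 1.96 * se`, unclipped. The p-value tests AUC = 0.5 via the
#' null-hypothesis standard error.
#'
#' @param values Predictor values.
#' @param labels Logical or 0/1 vector; `TRUE`/1 is the positive class.
#' @return A `roc_result` object.
#' @export
roc_auc <- function(values, labels) {
  labels <- as.logical(labels)
  ok <- is.finite(values) & !is.na(labels)
  values <- values[ok]; labels <- labels[ok]
  pos <- values[labels]; neg <- values[!labels]
  n1 <- length(pos); n2 <- length(neg)
  if (n1 == 0 || n2 == 0) abort("both classes must be present")
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  auc <- mean(cmp)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n2 - 1) * (q2 - auc^2)) / (n1 * n2))
  se0 <- sqrt((0.25 + (n1 + n2 - 2) * (1 / 3 - 0.25)) / (n1 * n2))
  p <- 2 * pnorm(-abs(auc - 0.5) / se0)
  structure(list(auc = auc, se = se, ci = c(auc - 1.96 * se, auc + 1.96 * se),
                 p = p, n_pos = n1, n_neg = n2,
                 values = values, labels = labels),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (SE %.3f, 95%% CI %.3f-%.3f, p = %.3g)\n",
              x$auc, x$se, x$ci[1], x$ci[2], x$p))
  invisible(x)
}

#' @export
tidy.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, se = x$se, ci_low = x$ci[1], ci_high = x$ci[2],
                 p = x$p, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @export
autoplot.roc_result <- function(object, ...) {
  th <- sort(unique(c(-Inf, object$values, Inf)), decreasing = TRUE)
  df <- purrr::map_dfr(th, function(cut) {
    tibble::tibble(
      tpr = mean(object$values[object$labels] >= cut),
      fpr = mean(object$values[!object$labels] >= cut)
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(linetype = "dotted", colour = "grey50") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("AUC = %.2f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Logistic combination of predictors
#'
#' Maximum-likelihood binary logistic regression (no regularization) of the
#' class labels on one or more predictors; the fitted in-sample
#' probabilities are scored with [roc_auc()]. Complete separation is
#' detected and reported via `separated = TRUE` (with AUC 1.0) rather than
#' as divergent coefficients; constant predictor columns are dropped with a
#' warning.
#'
#' @param data Data frame of predictors (numeric columns).
#' @param labels Logical or 0/1 outcome, `TRUE`/1 = positive class.
#' @return A `combined_model` object: coefficients, fitted probabilities,
#'   the `roc_result` of the fitted probabilities, and the predictor names.
#' @export
logistic_combine <- function(data, labels) {
  data <- as.data.frame(data)
  labels <- as.logical(labels)
  stopifnot(nrow(data) == length(labels))
  if (nrow(data) < ncol(data) + 2) abort("need n >= number of predictors + 2")
  keep <- vapply(data, function(x) sd(x) > 0, logical(1))
  if (!all(keep)) {
    warn(sprintf("dropping constant predictor(s): %s",
                 paste(names(data)[!keep], collapse = ", ")))
    data <- data[, keep, drop = FALSE]
  }
  if (ncol(data) == 0) abort("no non-constant predictors left")
  df <- cbind(.y = labels, data)
  fit <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
  probs <- fit$fitted.values
  separated <- max(probs[!labels]) < min(probs[labels])
  roc <- roc_auc(probs, labels)
  structure(list(predictors = names(data), coefficients = coef(fit),
                 fitted = probs, roc = roc, separated = separated,
                 model = fit),
            class = "combined_model")
}

#' @export
print.combined_model <- function(x, ...) {
  cat(sprintf("Logistic combination of %s: AUC = %.3f%s\n",
              paste(x$predictors, collapse = " + "), x$roc$auc,
              if (x$separated) " (complete separation)" else ""))
  invisible(x)
}

#' @export
tidy.combined_model <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @export
glance.combined_model <- function(x, ...) {
  tibble::tibble(auc = x$roc$auc, auc_se = x$roc$se,
                 ci_low = x$roc$ci[1], ci_high = x$roc$ci[2],
                 separated = x$separated,
                 n_predictors = length(x$predictors))
}

#' Cohort report tables
#'
#' From a long table of per-subject NAWM-normalized region statistics,
#' builds the three standard report tables of a two-group study: (a) group
#' summaries with Mann-Whitney U and p per parameter x region x statistic;
#' (b) single-parameter ROC analyses; (c) logistic combinations of ET
#' parameters. Group summary columns are the across-subject mean of the
#' subject means, the across-subject maximum of the subject maxima, and the
#' across-subject SD of the subject means.
#'
#' @param subject_stats Tibble with columns `subject`, `group` (`"gbm"` /
#'   `"met"`), `region`, `parameter`, `mean`, `max` (normalized, K2 raw).
#' @param combinations List of predictor sets for the combination table;
#'   each a character vector of parameter names (ET region).
#' @return List of tibbles `comparison`, `roc`, `combined`.
#' @export
cohort_report <- function(subject_stats,
                          combinations = list(
                            c("APTw", "cCBV"), c("APTw", "CBF"),
                            c("APTw", "K2"), c("APTw", "cCBV", "K2"))) {
  long <- tidyr::pivot_longer(subject_stats, c("mean", "max"),
                              names_to = "statistic", values_to = "value")
  grp <- function(df) {
    g <- df$group == "gbm"
    if (all(g) || !any(g)) return(NULL)
    mw <- mann_whitney(df$value[g], df$value[!g])
    tibble::tibble(
      gbm_mean = mean(df$value[g]), gbm_sd = sd(df$value[g]),
      gbm_n = sum(g), met_mean = mean(df$value[!g]),
      met_sd = sd(df$value[!g]), met_n = sum(!g),
      u = mw$u, p = mw$p
    )
  }
  comparison <- long |>
    dplyr::group_by(.data$parameter, .data$region, .data$statistic) |>
    dplyr::group_modify(~ grp(.x) %||% tibble::tibble()) |>
    dplyr::ungroup()

  roc_tbl <- long |>
    dplyr::group_by(.data$parameter, .data$region, .data$statistic) |>
    dplyr::group_modify(function(df, key) {
      g <- df$group == "gbm"
      if (all(g) || !any(g)) return(tibble::tibble())
      tidy(roc_auc(df$value, g))
    }) |>
    dplyr::ungroup()

  et <- long |> dplyr::filter(.data$region == "ET")
  combined <- purrr::map_dfr(combinations, function(preds) {
    purrr::map_dfr(c("max", "mean"), function(stat) {
      wide <- et |>
        dplyr::filter(.data$statistic == stat, .data$parameter %in% preds) |>
        tidyr::pivot_wider(id_cols = c("subject", "group"),
                           names_from = "parameter", values_from = "value") |>
        tidyr::drop_na()
      if (!all(preds %in% names(wide)) || nrow(wide) < length(preds) + 2 ||
          length(unique(wide$group)) < 2) return(tibble::tibble())
      fit <- tryCatch(
        suppressWarnings(logistic_combine(wide[, preds, drop = FALSE],
                                          wide$group == "gbm")),
        error = function(e) NULL)
      if (is.null(fit)) return(tibble::tibble())
      dplyr::mutate(glance(fit),
                    parameters = paste(preds, collapse = " + "),
                    statistic = stat, .before = 1)
    })
  })
  list(comparison = comparison, roc = roc_tbl, combined = combined)
}

#' Per-subject normalized statistics from parameter maps
#'
#' Runs [extract_region_stats()] for each named parameter map and applies
#' [normalize_to_nawm()].
#'
#' @param maps Named list of 3D arrays (e.g. `APTw`, `APTw_FS`, `CBF`, `CBV`,
#'   `cCBV`, `K2`, `MTT`).
#' @param labels Label volume.
#' @return Normalized statistics tibble.
#' @export
subject_stats <- function(maps, labels) {
  stats <- purrr::imap_dfr(maps, function(m, nm) {
    extract_region_stats(m, labels, parameter = nm)
  })
  normalize_to_nawm(stats)
}
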