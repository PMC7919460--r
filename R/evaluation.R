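#' Rank-based AUC (concordance probability)
#'
#' The Mann-Whitney estimate: the probability a random presence outranks
#' a random absence, with ties counted one half. Invariant under any
#' strictly monotone transform of the scores.
#'
#' @param scores_presence,scores_absence Numeric score vectors (both
#'   non-empty).
#' @return AUC in [0, 1].
#' @export
auc_score <- function(scores_presence, scores_absence) {
  np <- length(scores_presence); na <- length(scores_absence)
  if (np == 0 || na == 0)
    stop("AUC undefined: empty ", if (np == 0) "presence" else "absence",
         " side")
  r <- rank(c(scores_presence, scores_absence))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * na)
}

#' Confusion counts from scores and a threshold
#'
#' Prediction rule: presence if score >= threshold. Background points
#' stand in for absences, the standard convention for presence-background
#' evaluation.
#'
#' @param scores_presence,scores_absence Score vectors.
#' @param threshold Cut value.
#' @return A tibble with `tp`, `fn`, `fp`, `tn`.
#' @export
confusion_counts <- function(scores_presence, scores_absence, threshold) {
  tibble::tibble(
    tp = sum(scores_presence >= threshold),
    fn = sum(scores_presence < threshold),
    fp = sum(scores_absence >= threshold),
    tn = sum(scores_absence < threshold)
  )
}

#' Thresholded performance metrics from confusion counts
#'
#' Kappa uses the standard chance-expected agreement; TSS is
#' sensitivity + specificity - 1; Jaccard = tp / (tp + fp + fn);
#' Sorensen = 2 tp / (2 tp + fp + fn). Metrics with a degenerate
#' denominator are reported as `NA` (undefined), never coerced to 0.
#'
#' @param counts A one-row data frame with `tp`, `fn`, `fp`, `tn`.
#' @return A tibble with `sensitivity`, `specificity`, `kappa`, `tss`,
#'   `jaccard`, `sorensen`.
#' @export
thresholded_metrics <- function(counts) {
  tp <- counts$tp; fn <- counts$fn; fp <- counts$fp; tn <- counts$tn
  stopifnot(all(c(tp, fn, fp, tn) >= 0))
  n <- tp + fn + fp + tn
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (fp + tn > 0) tn / (fp + tn) else NA_real_
  po <- (tp + tn) / n
  pe <- ((tp + fn) * (tp + fp) + (fp + tn) * (fn + tn)) / n^2
  kappa <- if (abs(1 - pe) > 0) (po - pe) / (1 - pe) else NA_real_
  tss <- sens + spec - 1
  jac <- if (tp + fp + fn > 0) tp / (tp + fp + fn) else NA_real_
  sor <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  tibble::tibble(sensitivity = sens, specificity = spec, kappa = kappa,
                 tss = tss, jaccard = jac, sorensen = sor)
}

#' maxTSS threshold selection
#'
#' Scans every unique observed score as a candidate cut (prediction =
#' score >= threshold) and returns the one maximizing TSS; ties are
#' broken toward the lowest threshold.
#'
#' @param scores_presence,scores_absence Score vectors.
#' @return A list: `threshold`, `tss`.
#' @export
max_tss_threshold <- function(scores_presence, scores_absence) {
  if (!length(scores_presence) || !length(scores_absence))
    stop("maxTSS undefined with an empty score vector")
  cand <- sort(unique(c(scores_presence, scores_absence)))
  if (length(cand) == 1) {
    warning("all scores identical; threshold degenerate")
    return(list(threshold = cand, tss = 0))
  }
  tss <- vapply(cand, function(th) {
    sens <- mean(scores_presence >= th)
    spec <- mean(scores_absence < th)
    sens + spec - 1
  }, numeric(1))
  best <- which.max(tss)  # which.max takes the first (lowest) maximizer
  list(threshold = cand[best], tss = tss[best])
}

#' Threshold a suitability map into presence/absence
#'
#' @param suitability A `suitability_map`.
#' @param threshold Cut value in [0, 1]; cells with suitability >=
#'   threshold become presence.
#' @param scenario Scenario label stored on the output.
#' @return A `binary_map`.
#' @export
binarize <- function(suitability, threshold,
                     scenario = suitability$scenario) {
  if (threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]")
  v <- suitability$values
  out <- ifelse(is.na(v), NA_integer_, as.integer(v >= threshold))
  binary_map(out, suitability$grid, species = suitability$species,
             scenario = scenario)
}

#' K-fold evaluation of a niche-model fitting procedure
#'
#' For each fold, the model is refitted on the remaining folds' presences
#' (with a matching background split), the held-out presences and
#' held-out background are scored, the fold's maxTSS threshold is
#' derived, and all five metrics (AUC, Kappa, TSS, Jaccard, Sorensen)
#' computed. The summary reports each metric's mean and standard error;
#' `chosen_threshold` is the maxTSS value of a full-data fit, the value
#' used for binarization downstream.
#'
#' @param occ Occurrence tibble for one species with a `fold` column
#'   (see [assign_folds()]).
#' @param env Calibration [env_stack()].
#' @param background Background tibble (`x`, `y`).
#' @param fit_fun Fitting closure `function(occ, background)` returning a
#'   `maxent_model`; defaults to [fit_maxent()] with `spec`.
#' @param spec [feature_spec()] used by the default `fit_fun`.
#' @param seed Integer seed (background fold split).
#' @return An `evaluation_report`: list with `folds` (tibble, one row
#'   per fold), `summary` (tibble: metric, mean, se), `chosen_threshold`,
#'   `full_model`.
#' @export
kfold_evaluate <- function(occ, env, background, fit_fun = NULL,
                           spec = feature_spec(), seed = 1) {
  stopifnot("fold" %in% names(occ))
  k <- length(unique(occ$fold))
  if (k < 2) stop("k-fold evaluation needs at least 2 folds (no held-out ",
                  "data with k = 1)")
  if (is.null(fit_fun))
    fit_fun <- function(occ, background)
      fit_maxent(occ, env, spec, background)
  bg <- tibble::as_tibble(background)
  bg$fold <- withr::with_seed(seed, sample(rep_len(seq_len(k), nrow(bg))))
  folds <- sort(unique(occ$fold))
  rows <- purrr::map_dfr(folds, function(j) {
    train_p <- occ[occ$fold != j, , drop = FALSE]
    test_p <- occ[occ$fold == j, , drop = FALSE]
    if (!nrow(test_p) || nrow(train_p) < 2) {
      warning("fold ", j, " skipped (insufficient presences)")
      return(NULL)
    }
    m <- fit_fun(train_p, bg[bg$fold != j, c("x", "y")])
    sp <- score_points(m, env, test_p$x, test_p$y)
    sb <- score_points(m, env, bg$x[bg$fold == j], bg$y[bg$fold == j])
    sp <- sp[!is.na(sp)]; sb <- sb[!is.na(sb)]
    th <- max_tss_threshold(sp, sb)
    met <- thresholded_metrics(confusion_counts(sp, sb, th$threshold))
    dplyr::bind_cols(
      tibble::tibble(fold = j, n_test = length(sp),
                     auc = auc_score(sp, sb), threshold = th$threshold),
      met[, c("kappa", "tss", "jaccard", "sorensen")]
    )
  })
  metrics <- c("auc", "kappa", "tss", "jaccard", "sorensen")
  summary <- purrr::map_dfr(metrics, function(mm) {
    v <- rows[[mm]]
    v <- v[!is.na(v)]
    tibble::tibble(metric = mm, mean = mean(v),
                   se = stats::sd(v) / sqrt(length(v)))
  })
  full <- fit_fun(occ, bg[, c("x", "y")])
  sp <- score_points(full, env, occ$x, occ$y)
  sb <- score_points(full, env, bg$x, bg$y)
  chosen <- max_tss_threshold(sp[!is.na(sp)], sb[!is.na(sb)])$threshold
  structure(list(species = occ$species[1] %||% NA_character_,
                 folds = rows, summary = summary,
                 chosen_threshold = chosen, full_model = full),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s: %d folds, threshold %.3f\n",
              x$species, nrow(x$folds), x$chosen_threshold))
  print(x$summary)
  invisible(x)
}

#' @rdname kfold_evaluate
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @export
tidy.evaluation_report <- function(x, ...) x$folds

#' @rdname kfold_evaluate
#' @export
glance.evaluation_report <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary, names_from = "metric",
                             values_from = c("mean", "se"))
  dplyr::bind_cols(tibble::tibble(species = x$species,
                                  chosen_threshold = x$chosen_threshold),
                   wide)
}
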