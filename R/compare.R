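# Repeated-split model comparison with the paired t-test protocol.

#' Paired t-test with degenerate-case handling
#'
#' Classical two-sided paired t-test on `a - b` (df = n - 1), delegating to
#' [stats::t.test()].  When the differences have zero variance the test is
#' degenerate: no finite t statistic exists.  In that case the result is
#' flagged and the p-value reported as `NA` if the mean difference is also
#' zero (the two samples are identical) or as the limiting value 0 if the
#' mean difference is non-zero.
#'
#' @param a,b Equal-length numeric vectors (n >= 2), paired observations.
#' @return Object of class `paired_t`: list with `t`, `df`, `p`,
#'   `mean_diff`, `degenerate`.
#' @examples
#' paired_t_test(c(2, 4, 6), c(1, 2, 3))
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  n <- length(a)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- a - b
  if (sd(d) == 0) {
    res <- list(t = NA_real_, df = n - 1L, p = if (mean(d) == 0) NA_real_
                                               else 0,
                mean_diff = mean(d), degenerate = TRUE)
  } else {
    tt <- stats::t.test(a, b, paired = TRUE)
    res <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value, mean_diff = mean(d), degenerate = FALSE)
  }
  structure(res, class = "paired_t")
}

#' @export
print.paired_t <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("paired t-test: degenerate (zero-variance differences), mean diff %.4g, p %s\n",
                x$mean_diff, format(x$p)))
  } else {
    cat(sprintf("paired t-test: t = %.4f, df = %d, p = %.4g (mean diff %.4g)\n",
                x$t, x$df, x$p, x$mean_diff))
  }
  invisible(x)
}

#' Repeated-split model comparison
#'
#' Full evaluation protocol: for each repetition the slice ids are split
#' into train/validation/test sets, every candidate model is trained on the
#' identical split and evaluated on the shared test set, and per-repetition
#' mean Dice/IoU are recorded.  Across repetitions each model gets a
#' mean +/- SD; the model with the highest mean Dice anchors the comparison
#' and every other model is tested against it with a paired t-test over the
#' per-repetition means, flagged as significant at p < 0.001.
#'
#' @param model_builders Named list (>= 2) of functions `function(seed)`
#'   returning an `orbitnet`, e.g.
#'   `list(proposed = function(s) build_proposed(cfg, s), ...)`.
#' @param manifest Dataset manifest (see [generate_dataset()],
#'   [read_manifest()]).
#' @param tissue Tissue to segment; must appear in the manifest.
#' @param split A [split_spec()] (its `repetitions` drives the protocol).
#' @param config A [train_config()].
#' @param tversky A [tversky_params()].
#' @param window A [window_spec()].
#' @param threshold Binarization threshold at evaluation.
#' @return Object of class `eval_report`: `raw` (one row per model x
#'   repetition with the test-set mean Dice/IoU), `summary` (per model:
#'   mean/SD of both metrics, p-values vs. the best model, significance
#'   flags), `best_model`, `tissue`, `repetitions`.
#' @export
run_comparison <- function(model_builders, manifest, tissue,
                           split = split_spec(), config = train_config(),
                           tversky = tversky_params(),
                           window = window_spec(), threshold = 0.5) {
  if (length(model_builders) < 2L || is.null(names(model_builders))) {
    stop("model_builders must be a named list of at least two builders",
         call. = FALSE)
  }
  ids <- unique(manifest$id[manifest$tissue == tissue])
  if (length(ids) < 10L) {
    stop("need at least 10 slices carrying tissue ", tissue, call. = FALSE)
  }
  raw <- list()
  for (r in seq_len(split$repetitions) - 1L) {
    sp <- split_ids(ids, split, repetition = r)
    train_set <- load_dataset(manifest, tissue, sp$train)
    val_set <- load_dataset(manifest, tissue, sp$val)
    test_set <- load_dataset(manifest, tissue, sp$test)
    for (mi in seq_along(model_builders)) {
      mname <- names(model_builders)[mi]
      net <- model_builders[[mi]](config$seed + 1009L * r + mi)
      cfg_r <- config
      cfg_r$seed <- config$seed + 101L * r
      fit <- train_network(net, train_set, val_set, cfg_r, tversky, window)
      ev <- evaluate_network(fit, test_set, threshold)
      raw[[length(raw) + 1L]] <- data.frame(
        model = mname, tissue = tissue, repetition = r,
        mean_dice = ev$mean_dice, mean_iou = ev$mean_iou,
        best_epoch = fit$best_epoch, stringsAsFactors = FALSE)
    }
  }
  raw <- do.call(rbind, raw)
  summarize_comparison(raw, tissue, split$repetitions)
}

# Aggregate raw per-repetition means into the report (kept separate so the
# report is recomputable from a logged raw table).
summarize_comparison <- function(raw, tissue, repetitions) {
  models <- unique(raw$model)
  agg <- do.call(rbind, lapply(models, function(m) {
    d <- raw[raw$model == m, ]
    data.frame(model = m, tissue = tissue,
               mean_dice = mean(d$mean_dice), sd_dice = sd(d$mean_dice),
               mean_iou = mean(d$mean_iou), sd_iou = sd(d$mean_iou),
               stringsAsFactors = FALSE)
  }))
  best <- agg$model[which.max(agg$mean_dice)]
  bd <- raw[raw$model == best, ]
  bd <- bd[order(bd$repetition), ]
  agg$p_dice <- agg$p_iou <- NA_real_
  agg$degenerate <- FALSE
  for (m in setdiff(models, best)) {
    d <- raw[raw$model == m, ]
    d <- d[order(d$repetition), ]
    td <- paired_t_test(bd$mean_dice, d$mean_dice)
    ti <- paired_t_test(bd$mean_iou, d$mean_iou)
    agg$p_dice[agg$model == m] <- td$p
    agg$p_iou[agg$model == m] <- ti$p
    agg$degenerate[agg$model == m] <- td$degenerate || ti$degenerate
  }
  agg$sig_dice <- !is.na(agg$p_dice) & agg$p_dice < 0.001
  agg$sig_iou <- !is.na(agg$p_iou) & agg$p_iou < 0.001
  structure(list(raw = raw, summary = agg, best_model = best,
                 tissue = tissue, repetitions = repetitions),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Model comparison on tissue '%s' over %d repetitions (best: %s)\n",
              x$tissue, x$repetitions, x$best_model))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s Dice %5.1f +/- %4.1f %%  IoU %5.1f +/- %4.1f %%%s\n",
                s$model[i], 100 * s$mean_dice[i], 100 * s$sd_dice[i],
                100 * s$mean_iou[i], 100 * s$sd_iou[i],
                if (s$model[i] == x$best_model) "  (reference)"
                else sprintf("  p=%s%s", format(s$p_dice[i], digits = 3),
                             if (isTRUE(s$sig_dice[i])) " *" else "")))
  }
  invisible(x)
}

#' Write the raw and summary tables of a comparison report as CSV
#'
#' @param report An `eval_report`.
#' @param dir Output directory.
#' @return Paths of the two files, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "eval_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "metrics_raw.csv")
  p2 <- file.path(dir, "metrics_summary.csv")
  write.csv(report$raw, p1, row.names = FALSE)
  write.csv(report$summary, p2, row.names = FALSE)
  invisible(c(p1, p2))
}
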