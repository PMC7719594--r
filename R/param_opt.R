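# Coordinate-wise grid search: tune one evolution parameter at a time
# against ground truth, fixing each winner before sweeping the next.

tunable_params <- c("alpha", "lam", "eps", "dt", "sigma", "ksize", "mu",
                    "c0", "curvature_weight", "pre_sigma", "kernel")

#' Ordered parameter grid for coordinate-wise tuning
#'
#' @param ... named candidate vectors in sweep order, e.g.
#'   `parameter_grid(alpha = c(1, 2, 3), eps = c(0.5, 1, 1.5, 2, 2.5))`.
#'   Names must be fields of [evolution_params()] (including `kernel` for
#'   the edge pre-smoother family).
#' @param metric selection metric, one of `"accuracy"` (default),
#'   `"dice"`, `"jaccard"`, `"sensitivity"`, `"specificity"`.
#' @return an object of class `parameter_grid`.
#' @export
parameter_grid <- function(..., metric = "accuracy") {
  entries <- list(...)
  if (length(entries) == 0) stop("empty parameter grid", call. = FALSE)
  if (is.null(names(entries)) || any(names(entries) == ""))
    stop("all grid entries must be named", call. = FALSE)
  bad <- setdiff(names(entries), tunable_params)
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(lengths(entries) == 0))
    stop("candidate lists must be non-empty", call. = FALSE)
  metric <- match.arg(metric, c("accuracy", "dice", "jaccard",
                                "sensitivity", "specificity"))
  structure(list(entries = entries, metric = metric),
            class = "parameter_grid")
}

#' Select the best candidate by score
#'
#' Returns the candidate with the maximal score; ties are broken in
#' favor of the smallest candidate value (numerically for numeric
#' candidates, lexicographically otherwise).  `NA` scores mark failed
#' candidates and are excluded.
#'
#' @param candidates vector of candidate values.
#' @param scores numeric vector of the same length.
#' @return the winning candidate.
#' @export
select_best <- function(candidates, scores) {
  if (length(candidates) != length(scores))
    stop("'candidates' and 'scores' must have equal length", call. = FALSE)
  ok <- !is.na(scores)
  if (!any(ok)) stop("all candidates failed (no valid scores)",
                     call. = FALSE)
  candidates <- candidates[ok]; scores <- scores[ok]
  best <- which(scores == max(scores))
  winners <- candidates[best]
  if (is.numeric(winners)) min(winners) else sort(winners)[1]
}

# normalize one tuning case: list(image, truth, box[, box_mode]) or phantom
as_tuning_case <- function(x) {
  if (inherits(x, "phantom"))
    return(list(image = x$image, truth = x$truth, box = x$box,
                box_mode = x$meta$box_mode %||% "around"))
  if (!is.list(x) || !all(c("image", "truth", "box") %in% names(x)))
    stop("each tuning case must be a phantom or a list with image, ",
         "truth and box", call. = FALSE)
  x$box_mode <- x$box_mode %||% "around"
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Coordinate-wise parameter tuning against ground truth
#'
#' For each grid entry in order, every candidate value is evaluated by
#' running [run_segmentation()] on every tuning image and scoring the
#' result against its ground truth; the candidate with the highest mean
#' selection metric is fixed before the next parameter is swept.
#' Candidates whose segmentation fails are recorded and excluded from
#' the argmax rather than aborting the sweep.
#'
#' @param cases list of tuning cases: [make_disk_phantom()] /
#'   [make_ventricle_phantom()] objects, or lists with `image`, `truth`,
#'   `box` (and optional `box_mode`).
#' @param grid a [parameter_grid()].
#' @param base starting [evolution_params()].
#' @param method passed to [run_segmentation()].
#' @param mode definition mode for the rate metrics.
#' @return an object of class `tuning_result`: list with `params` (the
#'   tuned [evolution_params()]), `table` (tibble with one row per
#'   parameter/candidate holding mean and SD of Dice, Jaccard,
#'   sensitivity, specificity, accuracy) and `records` (per-image metric
#'   rows).
#' @export
tune_parameters <- function(cases, grid, base = evolution_params(),
                            method = "modified", mode = "standard") {
  if (!inherits(grid, "parameter_grid"))
    stop("'grid' must be a parameter_grid", call. = FALSE)
  if (length(cases) == 0) stop("empty tuning set", call. = FALSE)
  cases <- lapply(cases, as_tuning_case)
  params <- base
  rows <- list()
  recs <- list()
  metrics <- c("dice", "jaccard", "sensitivity", "specificity", "accuracy")
  for (pname in names(grid$entries)) {
    cands <- grid$entries[[pname]]
    means <- rep(NA_real_, length(cands))
    for (ci in seq_along(cands)) {
      cand <- cands[[ci]]
      p_try <- tryCatch(do.call(update_params,
                                c(list(params), stats::setNames(list(cand),
                                                                pname))),
                        error = function(e) NULL)
      per_img <- NULL
      failed <- is.null(p_try)
      if (!failed) {
        per_img <- lapply(seq_along(cases), function(i) {
          cs <- cases[[i]]
          tryCatch({
            fit <- run_segmentation(cs$image, cs$box, p_try,
                                    method = method,
                                    box_mode = cs$box_mode,
                                    keep_history = FALSE)
            rep <- segmentation_report(fit$mask, cs$truth, mode = mode)
            rep$case <- i
            rep
          }, error = function(e) NULL)
        })
        failed <- any(vapply(per_img, is.null, logical(1)))
      }
      if (failed) {
        fr <- c(list(parameter = pname, candidate = as.character(cand),
                     n = 0L),
                stats::setNames(as.list(rep(NA_real_, 2 * length(metrics))),
                                paste0(rep(metrics, each = 2),
                                       c("_mean", "_sd"))),
                list(failed = TRUE, selected = FALSE))
        rows[[length(rows) + 1L]] <- tibble::as_tibble(fr)
        next
      }
      tab <- do.call(rbind, per_img)
      tab$parameter <- pname
      tab$candidate <- as.character(cand)
      recs[[length(recs) + 1L]] <- tab
      stats_row <- list(parameter = pname, candidate = as.character(cand),
                        n = nrow(tab))
      for (m in metrics) {
        stats_row[[paste0(m, "_mean")]] <- mean(tab[[m]])
        stats_row[[paste0(m, "_sd")]] <- if (nrow(tab) > 1) sd(tab[[m]])
                                         else 0
      }
      stats_row$failed <- FALSE
      stats_row$selected <- FALSE
      rows[[length(rows) + 1L]] <- tibble::as_tibble(stats_row)
      means[ci] <- stats_row[[paste0(grid$metric, "_mean")]]
    }
    winner <- select_best(cands, means)
    params <- do.call(update_params,
                      c(list(params), stats::setNames(list(winner), pname)))
    for (ri in seq_along(rows)) {
      r <- rows[[ri]]
      if (r$parameter == pname && r$candidate == as.character(winner))
        rows[[ri]]$selected <- TRUE
    }
  }
  structure(list(params = params, table = do.call(rbind, rows),
                 records = if (length(recs)) do.call(rbind, recs)
                           else NULL),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat("Coordinate-wise tuning result\n")
  sel <- x$table[x$table$selected, c("parameter", "candidate")]
  for (i in seq_len(nrow(sel)))
    cat(sprintf("  %s = %s\n", sel$parameter[i], sel$candidate[i]))
  invisible(x)
}

#' Write a tuning table as CSV
#'
#' One row per candidate with `mean +/- SD` columns for Dice, Jaccard,
#' sensitivity, specificity and accuracy.
#'
#' @param x a `tuning_result` or its `table` tibble.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_tuning_csv <- function(x, path) {
  tab <- if (inherits(x, "tuning_result")) x$table else x
  fmt <- function(m, s) ifelse(is.na(m), "failed",
                               sprintf("%.4g ± %.2g", m, s))
  out <- data.frame(Parameter = tab$parameter, Candidate = tab$candidate,
                    DI = fmt(tab$dice_mean, tab$dice_sd),
                    JI = fmt(tab$jaccard_mean, tab$jaccard_sd),
                    Sensitivity = fmt(tab$sensitivity_mean,
                                      tab$sensitivity_sd),
                    Specificity = fmt(tab$specificity_mean,
                                      tab$specificity_sd),
                    Accuracy = fmt(tab$accuracy_mean, tab$accuracy_sd),
                    Selected = tab$selected,
                    check.names = FALSE)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
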