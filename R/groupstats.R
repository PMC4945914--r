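#' Wilcoxon rank-sum p-value for a two-group comparison
#'
#' Two-sided rank-sum test: exact enumeration when the combined sample size
#' is at most 12 and there are no ties, normal approximation with tie and
#' continuity correction otherwise.
#'
#' @param a,b numeric samples, each of size >= 2.
#' @return Two-sided p-value.
#' @export
ranksum <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop_fc("ranksum needs at least 2 observations per group (got %d and %d)",
            length(a), length(b))
  }
  comb <- c(a, b)
  exact <- length(comb) <= 12 && !anyDuplicated(comb)
  suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE)$p.value
  )
}

#' Sweep a binarizer parameter grid over a cohort and compute one metric
#'
#' For every subject and every grid point: binarize the subject's weighted
#' connectivity matrix, compute the metric, and record the value — or an
#' explicit missing flag with the failure reason (e.g. undefined
#' assortativity on a degree-regular graph, disconnected weighted graph for
#' mst/mcc). MST and MCC take no parameter; pass the default grid `NA`.
#'
#' @param conns list of [connectivity_matrix()] objects (one per subject).
#' @param groups character group label per subject.
#' @param binarizer `"threshold"`, `"density"`, `"mst"` or `"mcc"`.
#' @param grid numeric parameter grid (ignored, forced to `NA`, for
#'   mst/mcc).
#' @param metric metric name (see [graph_metric()]).
#' @param ... forwarded to [graph_metric()].
#' @return A data.frame of class `metric_sweep` with columns `subject`,
#'   `group`, `estimator`, `binarizer`, `parameter`, `metric`, `value`,
#'   `reason`, and an `n_epochs_used` attribute echoing each subject's
#'   clean-epoch count from the connectivity stage.
#' @export
sweep_metric <- function(conns, groups, binarizer, grid = NULL,
                         metric = "global_efficiency", ...) {
  binarizer <- match.arg(binarizer, binarizer_names())
  metric <- match.arg(metric, metric_names())
  if (binarizer %in% c("mst", "mcc")) {
    grid <- NA_real_
  } else if (is.null(grid) || length(grid) == 0) {
    stop_fc("empty parameter grid for binarizer \"%s\"", binarizer)
  }
  if (length(groups) != length(conns)) stop_fc("one group label per subject required")
  estimator <- if (inherits(conns[[1]], "connectivity_matrix")) conns[[1]]$estimator else NA_character_
  n_epochs_used <- vapply(conns, function(cm) {
    if (inherits(cm, "connectivity_matrix")) cm$n_epochs_used else NA_integer_
  }, integer(1))
  rows <- list()
  for (s in seq_along(conns)) {
    sid <- if (inherits(conns[[s]], "connectivity_matrix")) conns[[s]]$subject_id else sprintf("s%02d", s)
    for (p in grid) {
      val <- NA_real_
      reason <- NA_character_
      res <- tryCatch(
        graph_metric(binarize(conns[[s]], binarizer, p), metric, ...),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        reason <- conditionMessage(res)
      } else if (is.na(res)) {
        reason <- attr(res, "reason") %||% "undefined"
      } else {
        val <- as.numeric(res)
      }
      rows[[length(rows) + 1]] <- data.frame(
        subject = sid, group = groups[s], estimator = estimator,
        binarizer = binarizer, parameter = p, metric = metric,
        value = val, reason = reason, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  names(n_epochs_used) <- vapply(seq_along(conns), function(s) {
    if (inherits(conns[[s]], "connectivity_matrix")) conns[[s]]$subject_id
    else sprintf("s%02d", s)
  }, character(1))
  attr(out, "n_epochs_used") <- n_epochs_used
  class(out) <- c("metric_sweep", class(out))
  out
}

# split rows by grid point, keeping the NA "parameter" of mst/mcc as a group
split_by_parameter <- function(d) {
  split(d, factor(d$parameter, exclude = NULL))
}

#' Compare the two groups at every grid point
#'
#' Wilcoxon rank-sum test of the metric values between the two groups at
#' each binarizer parameter value; no multiple-testing correction by
#' default (set `p_adjust = "BH"` for Benjamini-Hochberg).
#'
#' @param sweep a [sweep_metric()] result containing exactly two groups.
#' @param alpha significance level (default 0.05).
#' @param p_adjust p-value adjustment method (default `"none"`).
#' @return A data.frame of class `group_comparison` with columns
#'   `parameter`, `n_a`, `n_b`, `p`, `significant`; attributes `alpha` and
#'   `groups`.
#' @export
compare_groups <- function(sweep, alpha = 0.05, p_adjust = "none") {
  gl <- sort(unique(sweep$group))
  if (length(gl) != 2) stop_fc("exactly two groups required (found: %s)", paste(gl, collapse = ", "))
  out <- do.call(rbind, lapply(split_by_parameter(sweep), function(d) {
    a <- d$value[d$group == gl[1] & !is.na(d$value)]
    b <- d$value[d$group == gl[2] & !is.na(d$value)]
    p <- if (length(a) >= 2 && length(b) >= 2) ranksum(a, b) else NA_real_
    data.frame(parameter = d$parameter[1], n_a = length(a), n_b = length(b), p = p)
  }))
  out <- out[order(out$parameter), , drop = FALSE]
  out$p_adj <- p.adjust(out$p, method = p_adjust)
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "groups") <- gl
  class(out) <- c("group_comparison", class(out))
  out
}

#' Assemble the figure-style report from a set of sweeps
#'
#' For every completed sweep: group means with standard errors per grid
#' point and the group-comparison significance mask, in the estimator-by-
#' binarizer grid layout. Machine-readable via [jsonlite::toJSON()] or
#' [write_results()].
#'
#' @param sweeps list of [sweep_metric()] results.
#' @param alpha significance level.
#' @param p_adjust p-adjustment method passed to [compare_groups()].
#' @return A list of class `network_report` with one entry per
#'   (estimator, binarizer, metric) cell: `summary` (parameter, group
#'   means/SEs, p, significance) and `n_missing`; plus cohort bookkeeping.
#' @export
assemble_report <- function(sweeps, alpha = 0.05, p_adjust = "none") {
  if (length(sweeps) == 0) stop_fc("at least one completed sweep required")
  cells <- list()
  for (sw in sweeps) {
    gl <- sort(unique(sw$group))
    cmp <- compare_groups(sw, alpha = alpha, p_adjust = p_adjust)
    summ <- do.call(rbind, lapply(split_by_parameter(sw), function(d) {
      row <- data.frame(parameter = d$parameter[1])
      for (g in gl) {
        v <- d$value[d$group == g & !is.na(d$value)]
        row[[paste0("mean_", g)]] <- mean(v)
        row[[paste0("se_", g)]] <- sd(v) / sqrt(length(v))
      }
      row
    }))
    summ <- merge(summ, cmp[, c("parameter", "p", "significant")], by = "parameter", sort = TRUE)
    key <- sprintf("%s_%s_%s", sw$estimator[1], sw$binarizer[1], sw$metric[1])
    cells[[key]] <- list(
      estimator = sw$estimator[1], binarizer = sw$binarizer[1],
      metric = sw$metric[1], summary = summ,
      n_missing = sum(!is.na(sw$reason)),
      missing_reasons = unique(sw$reason[!is.na(sw$reason)])
    )
  }
  first <- sweeps[[1]]
  structure(
    list(cells = cells, alpha = alpha, p_adjust = p_adjust,
         groups = sort(unique(first$group)),
         n_subjects = length(unique(first$subject)),
         n_epochs_used = attr(first, "n_epochs_used")),
    class = "network_report"
  )
}

#' @export
print.network_report <- function(x, ...) {
  cat(sprintf("<network_report> %d cells, %d subjects, alpha = %g\n",
              length(x$cells), x$n_subjects, x$alpha))
  for (key in names(x$cells)) {
    cell <- x$cells[[key]]
    nsig <- sum(cell$summary$significant, na.rm = TRUE)
    cat(sprintf("  %-45s %d/%d grid points significant\n",
                key, nsig, nrow(cell$summary)))
  }
  invisible(x)
}

#' Plot one report cell in the figure style of the sweep panels
#'
#' Group mean metric value versus binarizer parameter with standard-error
#' bars; asterisks mark grid points where the groups differ significantly.
#' Parameter-free binarizers (mst/mcc) are drawn as a two-bar comparison.
#'
#' @param x a `network_report`.
#' @param cell cell name (an element of `names(x$cells)`); default first.
#' @param ... graphical parameters passed on.
#' @return Invisibly, the plotted summary data.frame.
#' @export
plot.network_report <- function(x, cell = names(x$cells)[1], ...) {
  cl <- x$cells[[cell]]
  s <- cl$summary
  gl <- x$groups
  ma <- s[[paste0("mean_", gl[1])]]; mb <- s[[paste0("mean_", gl[2])]]
  ea <- s[[paste0("se_", gl[1])]]; eb <- s[[paste0("se_", gl[2])]]
  if (all(is.na(s$parameter))) {
    bp <- barplot(c(ma, mb), names.arg = gl, col = c("grey30", "grey70"),
                  main = cell, ylab = cl$metric, ...)
    arrows(bp, c(ma - ea, mb - eb), bp, c(ma + ea, mb + eb),
           angle = 90, code = 3, length = 0.06)
    if (isTRUE(s$significant)) text(mean(bp), max(ma + ea, mb + eb), "*", cex = 2)
  } else {
    ylim <- range(c(ma - ea, ma + ea, mb - eb, mb + eb), na.rm = TRUE)
    plot(s$parameter, ma, type = "b", pch = 16, ylim = ylim,
         xlab = sprintf("%s parameter", cl$binarizer), ylab = cl$metric,
         main = cell, ...)
    lines(s$parameter, mb, type = "b", pch = 1, lty = 2)
    arrows(s$parameter, ma - ea, s$parameter, ma + ea, angle = 90, code = 3, length = 0.03)
    arrows(s$parameter, mb - eb, s$parameter, mb + eb, angle = 90, code = 3, length = 0.03)
    sig <- which(s$significant)
    if (length(sig)) text(s$parameter[sig], ylim[2], "*", cex = 1.5)
    legend("bottomright", legend = gl, pch = c(16, 1), lty = c(1, 2), bty = "n")
  }
  invisible(s)
}
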