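## Summaries of the benchmark records: per-cell means with 95% confidence
## intervals across resampling repeats, and a fixed-effects two-way ANOVA
## of metric ~ representation * network. Repeats are treated as
## independent replicates within cells; the optimism this inherits from
## cross-validation reuse is documented, not corrected.

#' Summarise experiment records into means and 95% CIs
#'
#' Per (representation, network) cell: mean with a normal-approximation
#' 95% interval (`mean ± 1.96 sd/sqrt(n)`, or a t quantile if requested),
#' clipped to \[0, 1\], for accuracy and AUROC.
#'
#' @param results an `experiment_result` (or compatible data.frame).
#' @param ci `"normal"` (default) or `"t"`.
#' @return data.frame with one row per cell: representation, network,
#'   mean_accuracy, ci_low, ci_high, mean_auroc, auroc_ci_low,
#'   auroc_ci_high, n.
#' @export
summarize_results <- function(results, ci = c("normal", "t")) {
  ci <- match.arg(ci)
  cells <- unique(results[, c("representation", "network")])
  cells <- cells[order(cells$representation, cells$network), ]
  rows <- lapply(seq_len(nrow(cells)), function(r) {
    sel <- results$representation == cells$representation[r] &
      results$network == cells$network[r]
    a <- results$accuracy[sel]
    u <- results$auroc[sel]
    u <- u[!is.na(u)]
    if (length(a) < 2) stop("cell with fewer than 2 records: ",
                            cells$representation[r], " / ", cells$network[r])
    q <- if (ci == "normal") qnorm(0.975) else stats::qt(0.975, length(a) - 1)
    half_a <- q * sd(a) / sqrt(length(a))
    half_u <- if (length(u) >= 2) q * sd(u) / sqrt(length(u)) else NA_real_
    data.frame(representation = cells$representation[r],
               network = cells$network[r],
               mean_accuracy = mean(a),
               ci_low = max(0, mean(a) - half_a),
               ci_high = min(1, mean(a) + half_a),
               mean_auroc = if (length(u)) mean(u) else NA_real_,
               auroc_ci_low = if (length(u) >= 2) max(0, mean(u) - half_u) else NA_real_,
               auroc_ci_high = if (length(u) >= 2) min(1, mean(u) + half_u) else NA_real_,
               n = length(a), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Two-way fixed-effects ANOVA of a benchmark metric
#'
#' `metric ~ representation * network` on a balanced complete factorial
#' design (equal records per cell); under balance the classical
#' sums-of-squares types coincide. Fit via `stats::aov`.
#'
#' @param results an `experiment_result`.
#' @param metric `"accuracy"` or `"auroc"`.
#' @return data.frame with rows Representation, Deficit, Interaction,
#'   Residual and columns sum_sq, df, mean_sq, F, p.
#' @export
anova_two_way <- function(results, metric = c("accuracy", "auroc")) {
  metric <- match.arg(metric)
  v <- results[[metric]]
  df <- data.frame(value = v,
                   representation = factor(results$representation),
                   network = factor(results$network))
  if (any(is.na(df$value))) stop("metric contains missing values")
  counts <- table(df$representation, df$network)
  if (any(counts == 0)) stop("incomplete design: rerun with every (representation, network) cell populated")
  if (length(unique(as.vector(counts))) != 1 || any(counts < 2)) {
    stop("unbalanced design: rerun with an equal number (>= 2) of records per cell")
  }
  one_way <- nlevels(df$network) < 2
  fit <- if (one_way) aov(value ~ representation, data = df) else
    aov(value ~ representation * network, data = df)
  tab <- summary(fit)[[1]]
  rn <- trimws(rownames(tab))
  pick <- function(label) {
    i <- match(label, rn)
    if (is.na(i)) return(data.frame(`Sum Sq` = 0, Df = 0, `Mean Sq` = NA_real_,
                                    `F value` = NA_real_, `Pr(>F)` = NA_real_,
                                    check.names = FALSE))
    tab[i, c("Sum Sq", "Df", "Mean Sq", "F value", "Pr(>F)"), drop = FALSE]
  }
  out <- do.call(rbind, lapply(list("representation", "network",
                                    "representation:network", "Residuals"),
                               pick))
  data.frame(term = c("Representation", "Deficit", "Interaction", "Residual"),
             sum_sq = out[["Sum Sq"]], df = out[["Df"]],
             mean_sq = out[["Mean Sq"]], F = out[["F value"]],
             p = out[["Pr(>F)"]], stringsAsFactors = FALSE)
}

#' Export summary and ANOVA tables with a run manifest
#'
#' @param summary data.frame from [summarize_results()].
#' @param anova data.frame from [anova_two_way()] (or NULL).
#' @param out_dir output directory (created if absent).
#' @param manifest named list written as JSON (config, seeds, hashes).
#' @param plot if TRUE, writes a polar (spider) accuracy plot per
#'   representation across networks to `accuracy_spider.png`.
#' @return invisibly, a character vector of the files written.
#' @export
export_report <- function(summary, anova = NULL, out_dir, manifest = list(),
                          plot = FALSE) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop("cannot create output directory: ", out_dir)
  }
  files <- character(0)
  p <- file.path(out_dir, "summary.csv")
  write.csv(summary, p, row.names = FALSE)
  files <- c(files, p)
  if (!is.null(anova)) {
    p <- file.path(out_dir, "anova.csv")
    write.csv(anova, p, row.names = FALSE)
    files <- c(files, p)
  }
  p <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, p)
  if (plot) {
    p <- file.path(out_dir, "accuracy_spider.png")
    grDevices::png(p, width = 720, height = 720)
    tryCatch(spider_plot(summary), finally = grDevices::dev.off())
    files <- c(files, p)
  }
  invisible(files)
}

## Polar accuracy plot: one ring per representation across networks,
## origin at chance (0.5).
spider_plot <- function(summary) {
  nets <- sort(unique(summary$network))
  reps <- sort(unique(summary$representation))
  ang <- seq(0, 2 * pi, length.out = length(nets) + 1)[-(length(nets) + 1)]
  graphics::plot(NULL, xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1), asp = 1,
                 axes = FALSE, xlab = "", ylab = "",
                 main = "Balanced accuracy by sub-network (origin = chance)")
  for (ring in c(0.7, 0.8, 0.9, 1.0)) {
    rr <- (ring - 0.5) / 0.5
    graphics::lines(rr * cos(seq(0, 2 * pi, length.out = 180)),
                    rr * sin(seq(0, 2 * pi, length.out = 180)),
                    col = "grey80", lty = 3)
  }
  graphics::text(cos(ang) * 1.07, sin(ang) * 1.07, nets, cex = 0.8)
  cols <- grDevices::hcl.colors(length(reps), "Dark 3")
  for (ri in seq_along(reps)) {
    acc <- vapply(nets, function(nw) {
      summary$mean_accuracy[summary$representation == reps[ri] &
                              summary$network == nw][1]
    }, numeric(1))
    rr <- pmax(0, (acc - 0.5) / 0.5)
    graphics::polygon(rr * cos(ang), rr * sin(ang), border = cols[ri], lwd = 2)
  }
  graphics::legend("topleft", legend = reps, col = cols, lwd = 2, bty = "n")
}
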