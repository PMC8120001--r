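# Report generation: summary CSV plus column-scatter and distance-trace
# plots, with significance annotated in the standard convention (n.s., *,
# **, ***, ****).

#' Column scatter plot with per-cell and per-fish markers
#'
#' Small dots are individual cells, large dots are per-fish means, the
#' horizontal bar the group mean; an optional p-value is annotated with
#' [significance_label()].
#'
#' @param measurements Data frame with columns `group`, `fish`, `value`.
#' @param ylab Axis label (measurement name and units).
#' @param p Optional p-value to annotate.
#' @param main Plot title.
#' @export
plot_column_scatter <- function(measurements, ylab = "value", p = NULL,
                                main = "") {
  groups <- unique(measurements$group)
  k <- length(groups)
  xs <- match(measurements$group, groups)
  set_jitter <- (seq_len(nrow(measurements)) %% 7 - 3) / 30
  graphics::plot(xs + set_jitter, measurements$value, pch = 16, cex = 0.5,
                 col = "grey50", xaxt = "n", xlab = "", ylab = ylab,
                 xlim = c(0.5, k + 0.5), main = main)
  graphics::axis(1, at = seq_len(k), labels = groups)
  fish_means <- aggregate_per_fish(measurements)
  graphics::points(match(fish_means$group, groups), fish_means$value,
                   pch = 16, cex = 1.4)
  for (g in seq_len(k)) {
    gv <- measurements$value[xs == g]
    graphics::segments(g - 0.25, mean(gv), g + 0.25, mean(gv), lwd = 2)
  }
  if (!is.null(p))
    graphics::mtext(sprintf("p = %.3g (%s)", p, significance_label(p)),
                    side = 3, line = 0, cex = 0.9)
  invisible(NULL)
}

#' Distance-vs-time traces for every track
#'
#' @param distances Data frame from [measure_distances()].
#' @param frame_interval Minutes per frame.
#' @param thresholds Optional per-lineage thresholds drawn as dashed lines.
#' @export
plot_distance_traces <- function(distances, frame_interval = 2,
                                 thresholds = default_thresholds()) {
  if (!nrow(distances)) {
    graphics::plot.new()
    graphics::title("no data")
    return(invisible(NULL))
  }
  graphics::plot(NA, xlim = range(distances$frame) * frame_interval,
                 ylim = c(0, max(distances$distance_um) * 1.05),
                 xlab = "time (min)", ylab = "surface distance (um)")
  cols <- c(neutrophil = "magenta3", macrophage = "darkorange2")
  for (key in split(distances,
                    interaction(distances$track_id, distances$lesion_id,
                                drop = TRUE))) {
    key <- key[order(key$frame), ]
    graphics::lines(key$frame * frame_interval, key$distance_um,
                    col = cols[[key$lineage[1]]])
  }
  for (lin in names(thresholds))
    graphics::abline(h = thresholds[[lin]], lty = 2, col = cols[[lin]])
  graphics::legend("topright", legend = names(cols), col = cols, lty = 1,
                   bty = "n")
  invisible(NULL)
}

#' Build a summary report from pipeline outputs
#'
#' Writes `summary.csv` (per-fish, per-lineage interaction summaries with
#' any group comparisons annotated) and, when plotting is enabled, a
#' `report.pdf` with column scatters per measurement and distance traces
#' per fish. Empty inputs produce a report with "no data" placeholders.
#'
#' @param results List of [analyse_movie()] outputs (one per fish).
#' @param groups Optional named character vector mapping fish to group
#'   labels; group comparisons are run per measurement when >= 2 groups
#'   have >= 3 fish each.
#' @param out_dir Output directory.
#' @param plots Whether to write `report.pdf`.
#' @return List with `summary` (data frame), `comparisons` (list of
#'   `ls_test_result`), and the output paths, invisibly.
#' @export
build_report <- function(results, groups = NULL, out_dir, plots = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(results$fish)) results <- list(results)
  summary_df <- do.call(rbind, lapply(results, function(r)
    cbind(fish = r$fish, r$summary$per_lineage)))
  if (is.null(summary_df))
    summary_df <- data.frame(fish = character(0), lineage = character(0),
                             n_events = integer(0),
                             note = character(0))  # "no data" placeholder
  measurements <- do.call(rbind, lapply(results, function(r) {
    if (is.null(r$metrics) || !nrow(r$metrics)) return(NULL)
    data.frame(fish = r$fish, lineage = r$metrics$lineage,
               mean_speed_um_min = r$metrics$mean_speed_um_min,
               directionality_ratio = r$metrics$directionality_ratio)
  }))
  comparisons <- list()
  if (!is.null(groups) && !is.null(measurements)) {
    measurements$group <- groups[measurements$fish]
    for (lin in unique(measurements$lineage)) {
      for (meas in c("mean_speed_um_min", "directionality_ratio")) {
        sub <- data.frame(group = measurements$group,
                          fish = measurements$fish,
                          value = measurements[[meas]])
        sub <- sub[measurements$lineage == lin & is.finite(sub$value), ]
        per_fish <- aggregate_per_fish(sub)
        ok <- table(per_fish$group)
        if (length(ok) >= 2 && all(ok >= 3)) {
          comparisons[[paste(lin, meas, sep = ".")]] <-
            compare_groups(per_fish)
        }
      }
    }
  }
  summary_path <- file.path(out_dir, "summary.csv")
  write.csv(summary_df, summary_path, row.names = FALSE)
  pdf_path <- NULL
  if (plots) {
    pdf_path <- file.path(out_dir, "report.pdf")
    grDevices::pdf(pdf_path, width = 7, height = 5)
    on.exit(grDevices::dev.off())
    if (!length(results) || !nrow(summary_df)) {
      graphics::plot.new(); graphics::title("no data")
    } else {
      if (!is.null(measurements) && !is.null(groups)) {
        for (nm in names(comparisons)) {
          parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
          sub <- data.frame(group = measurements$group,
                            fish = measurements$fish,
                            value = measurements[[parts[2]]])
          sub <- sub[measurements$lineage == parts[1] &
                       is.finite(sub$value), ]
          plot_column_scatter(sub, ylab = parts[2], main = parts[1],
                              p = comparisons[[nm]]$p_value)
        }
      }
      for (r in results)
        if (!is.null(r$distances) && nrow(r$distances))
          plot_distance_traces(r$distances)
    }
  }
  invisible(list(summary = summary_df, comparisons = comparisons,
                 summary_path = summary_path, pdf_path = pdf_path))
}
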