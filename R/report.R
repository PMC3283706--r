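#' Heatmap row order: cluster blocks, descending RR within block
#'
#' Sm/RNP patients first, then Ro/La, then seronegative; within each block
#' patients sort by descending relative ratio. This is the display ordering
#' of the Z-score heatmap.
#'
#' @param assignments A \code{cluster_assignment}.
#' @return Character vector of patient ids (a permutation of all assigned
#'   patients).
#' @export
heatmap_order <- function(assignments) {
  blk <- factor(assignments$label, levels = CLASSES)
  assignments$patient_id[order(as.integer(blk), -assignments$rr)]
}

## draw a clipped, row-ordered Z matrix on the active device
.heatmap_draw <- function(zc, z_max) {
  pal <- grDevices::colorRampPalette(c("black", "green"))(64)
  graphics::par(mar = c(6, 6, 2, 1))
  ## image() draws rows bottom-up; flip so the first patient is on top
  graphics::image(x = seq_len(ncol(zc)), y = seq_len(nrow(zc)),
                  z = t(zc[rev(seq_len(nrow(zc))), , drop = FALSE]),
                  zlim = c(0, z_max), col = pal, axes = FALSE,
                  xlab = "", ylab = "Patients (cluster blocks, RR desc)")
  graphics::axis(1, at = seq_len(ncol(zc)), labels = colnames(zc), las = 2)
  graphics::box()
}

#' Render the Z-score heatmap
#'
#' Writes a PNG or SVG (chosen by file extension) of the patient x antigen
#' Z-score matrix, rows ordered by [heatmap_order()], colors running black
#' (at or below cutoff) to green (saturating at \code{z_max} standard
#' deviations above cutoff). Negative Z is clipped to 0 for display only:
#' sub-cutoff magnitudes carry no display meaning. A CSV manifest of the row
#' order (patient_id, label, rr, pure) is written alongside.
#'
#' @param z Z-score matrix from [z_scores()] (SLE rows are drawn).
#' @param assignments A \code{cluster_assignment} covering the rows to draw.
#' @param file Output image path ending in .png or .svg.
#' @param z_max Display saturation in SD units (default 10).
#' @return Invisibly, the manifest data frame; the manifest CSV path is
#'   \code{file} with extension replaced by \code{_rows.csv}.
#' @export
render_heatmap <- function(z, assignments, file, z_max = 10) {
  ord <- heatmap_order(assignments)
  missing <- setdiff(ord, rownames(z))
  if (length(missing))
    .stopf("Z matrix lacks row(s): %s",
           paste(utils::head(missing, 5), collapse = ", "))
  zi <- z[ord, , drop = FALSE]
  zc <- pmin(pmax(zi, 0), z_max)

  ext <- tolower(sub(".*\\.", "", file))
  if (ext == "svg") grDevices::svg(file, width = 7, height = 9)
  else grDevices::png(file, width = 700, height = 900)
  on.exit(grDevices::dev.off(), add = TRUE)
  .heatmap_draw(zc, z_max)

  manifest <- data.frame(
    patient_id = ord,
    label = assignments$label[match(ord, assignments$patient_id)],
    rr = assignments$rr[match(ord, assignments$patient_id)],
    pure = assignments$pure[match(ord, assignments$patient_id)],
    stringsAsFactors = FALSE)
  manifest_file <- sub("\\.[^.]+$", "_rows.csv", file)
  utils::write.csv(manifest, manifest_file, row.names = FALSE)
  invisible(manifest)
}

#' Per-antigen summary table with diagnostic performance and titer CIs
#'
#' One row per antigen: sensitivity and specificity at the supplied cutoffs
#' and arithmetic mean titer with normal-theory 95% CI (mean +/- 1.96
#' SD/sqrt(n)) per group. The CI is deliberately the plain normal interval,
#' so a skewed titer distribution can produce a negative lower bound;
#' geometric means are the quantity used for log-scale testing, not here.
#'
#' @param cohort Cohort data frame with both groups.
#' @param stats A \code{control_stats}; its mean + 3 SD cutoffs are used.
#' @param panel Antigens to summarize.
#' @return Data frame: antigen, cutoff, sensitivity, specificity,
#'   mean_hc, ci_lo_hc, ci_hi_hc, mean_sle, ci_lo_sle, ci_hi_sle.
#' @export
antigen_summary <- function(cohort, stats, panel = stats$antigen) {
  ci <- function(v) {
    h <- stats::qnorm(0.975) * stats::sd(v) / sqrt(length(v))
    c(mean(v), mean(v) - h, mean(v) + h)
  }
  lk <- .stats_lookup(stats, panel)
  sle <- cohort[cohort$group == "SLE", , drop = FALSE]
  hc <- cohort[cohort$group == "CONTROL", , drop = FALSE]
  rows <- lapply(panel, function(ag) {
    perf <- diagnostic_performance(cohort, ag, lk$cutoff[[ag]])
    chc <- ci(.titer_matrix(hc, ag)[, 1])
    csl <- ci(.titer_matrix(sle, ag)[, 1])
    data.frame(antigen = ag, cutoff = lk$cutoff[[ag]],
               sensitivity = perf$sensitivity,
               specificity = perf$specificity,
               mean_hc = chc[1], ci_lo_hc = chc[2], ci_hi_hc = chc[3],
               mean_sle = csl[1], ci_lo_sle = csl[2], ci_hi_sle = csl[3],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## render a data frame as a GitHub-style markdown table
.df_to_markdown <- function(df, digits = 4) {
  fmt <- function(v) if (is.numeric(v)) signif(v, digits) else v
  cells <- vapply(df, function(v) as.character(fmt(v)),
                  character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r)
    paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}

#' Write summary tables as CSV and Markdown
#'
#' Emits the per-antigen performance table, the cluster prevalence table and
#' the association table to an output directory, each as both CSV and
#' Markdown containing identical numbers.
#'
#' @param performance Data frame from [antigen_summary()].
#' @param prevalence A \code{cluster_prevalence}.
#' @param associations Data frame from [association_screen()] (optional).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
summary_tables <- function(performance, prevalence, associations = NULL,
                           out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(df, name) {
    csv <- file.path(out_dir, paste0(name, ".csv"))
    md <- file.path(out_dir, paste0(name, ".md"))
    utils::write.csv(df, csv, row.names = FALSE)
    writeLines(.df_to_markdown(df), md)
    files <<- c(files, csv, md)
  }
  emit(performance, "antigen_performance")
  prev_df <- data.frame(
    cluster = c("SM_RNP", "RO_LA", "SERONEGATIVE"),
    n = c(prevalence$n_smrnp, prevalence$n_rola, prevalence$n_seroneg),
    percent = round_half_away(c(prevalence$pct_smrnp, prevalence$pct_rola,
                                prevalence$pct_seroneg)),
    n_pure = c(prevalence$n_pure_smrnp, prevalence$n_pure_rola, NA),
    stringsAsFactors = FALSE)
  emit(prev_df, "cluster_prevalence")
  if (!is.null(associations)) emit(associations, "associations")
  invisible(files)
}
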