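#' Rank array components by association with blood type
#'
#' One-way fixed-effects ANOVA of the log2 signal on the blood-type factor,
#' computed per component for one isotype channel, via `stats::lm`.
#' Components are returned sorted by ascending p-value. Degenerate cases
#' are handled explicitly: a constant signal gives F = 0, p = 1; perfect
#' group separation (zero within-group variance with distinct means) gives
#' F = Inf with the p-value floored at 1e-300, the floor applied to every
#' p-value to keep the sorted output finite. A Bonferroni-adjusted column
#' is emitted for information only; the ranking itself uses raw p-values.
#'
#' @param profiles a `glycan_profiles` object.
#' @param labels named vector sample -> blood type; by default the 4-level
#'   ABO factor, collapsed to A/AB vs B/O when `collapse = TRUE`.
#' @param isotype `"IgG"` or `"IgM"`.
#' @param collapse collapse the factor to the two pooled groups
#'   (default FALSE).
#' @return data.frame with one row per component: `component`, `isotype`,
#'   `f_statistic`, `p_value`, `p_bonferroni`, one `mean_<type>` column per
#'   group, and `flagged` (TRUE when any group has fewer than 2 samples;
#'   flagged components sort last).
#' @export
anova_rank <- function(profiles, labels, isotype = c("IgG", "IgM"),
                       collapse = FALSE) {
  isotype <- match.arg(isotype)
  stopifnot(inherits(profiles, "glycan_profiles"))
  labels <- labels[sample_ids(profiles)]
  stopifnot(!anyNA(labels))
  g <- as.character(labels)
  if (collapse) {
    g <- ifelse(g %in% c("A", "AB"), "A/AB", "B/O")
  }
  g <- factor(g)
  if (nlevels(g) < 2L) stop("need at least 2 blood-type groups")
  if (sum(table(g) >= 2L) < 2L) {
    stop("need at least 2 groups with at least 2 samples each")
  }
  flagged_groups <- any(table(g) < 2L)

  mat <- if (isotype == "IgG") profiles$igg else profiles$igm
  p_floor <- 1e-300

  one <- function(sig) {
    if (stats::var(sig) == 0) return(c(f = 0, p = 1))
    ssw <- sum(unlist(tapply(sig, g, function(x) (x - mean(x))^2)))
    if (ssw == 0) return(c(f = Inf, p = p_floor))  # perfect separation
    fit <- stats::anova(stats::lm(sig ~ g))
    c(f = fit[["F value"]][1L], p = max(fit[["Pr(>F)"]][1L], p_floor))
  }
  res <- t(apply(mat, 2L, one))
  means <- t(apply(mat, 2L, function(sig) tapply(sig, g, mean)))
  colnames(means) <- paste0("mean_", colnames(means))

  out <- data.frame(component = colnames(mat), isotype = isotype,
                    f_statistic = res[, "f"], p_value = res[, "p"],
                    p_bonferroni = pmin(res[, "p"] * ncol(mat), 1),
                    means, flagged = flagged_groups,
                    stringsAsFactors = FALSE, check.names = FALSE)
  ord <- order(out$flagged, out$p_value, -out$f_statistic, out$component)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export an ordered signal heat map
#'
#' Writes the signal matrix with samples grouped by blood-type label and
#' components ordered by rank (strongest association first) — the standard
#' overview of anti-glycan antibody signals versus blood type. The ordered
#' matrix is always written as a TSV (deterministic bytes for identical
#' inputs); a PNG image is rendered as well when `png_path` is given.
#' Plotting failure downgrades to a warning so pipelines are not aborted.
#'
#' @param profiles a `glycan_profiles` object (must be non-empty).
#' @param labels named vector sample -> blood type.
#' @param ranking data.frame from [anova_rank()] (determines component
#'   order and isotype); defaults to ranking computed on the fly for IgG.
#' @param path output TSV path.
#' @param png_path optional PNG path.
#' @return the ordered matrix (samples x components), invisibly.
#' @export
heatmap_export <- function(profiles, labels, ranking = NULL,
                           path, png_path = NULL) {
  stopifnot(inherits(profiles, "glycan_profiles"))
  if (nrow(profiles$igg) == 0L || ncol(profiles$igg) == 0L) {
    stop("empty profile matrix")
  }
  if (is.null(ranking)) ranking <- anova_rank(profiles, labels, "IgG")
  isotype <- ranking$isotype[1L]
  mat <- if (isotype == "IgG") profiles$igg else profiles$igm
  labels <- labels[sample_ids(profiles)]
  sample_ord <- order(labels, sample_ids(profiles))
  comp_ord <- match(ranking$component, colnames(mat))
  mat <- mat[sample_ord, comp_ord, drop = FALSE]

  out <- data.frame(sample_id = rownames(mat), blood_type = labels[sample_ord],
                    mat, stringsAsFactors = FALSE, check.names = FALSE)
  out[colnames(mat)] <- lapply(out[colnames(mat)], function(v) sprintf("%.17g", v))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)

  if (!is.null(png_path)) {
    tryCatch({
      grDevices::png(png_path, width = 200 + 12 * ncol(mat),
                     height = 200 + 10 * nrow(mat))
      on.exit(grDevices::dev.off(), add = TRUE)
      graphics::image(t(mat[rev(seq_len(nrow(mat))), , drop = FALSE]),
                      axes = FALSE,
                      col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                      main = paste(isotype, "signals (log2 RFU)"))
    }, error = function(e) warning("heat map rendering failed: ",
                                   conditionMessage(e), call. = FALSE))
  }
  invisible(mat)
}
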